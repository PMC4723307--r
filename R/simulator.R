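#' Default simulator parameter values (reference cultivar)
#'
#' Concrete values consumed by the surrogate daily wheat model, taken from the
#' nominal entries of the packaged registry. Curve traits are reduced to the
#' form the simulator consumes (stage-constant curves to their mean `y`,
#' response curves kept as lookup tables).
#'
#' @return Named list of simulator parameters and curves.
#' @keywords internal
.default_crop_params <- function() {
  list(
    tt_emerg = 100, tt_juv = 555, tt_fi = 555, tt_sgf = 120, tt_gf = 580,
    photop_sens = 3.0, vern_sens = 1.5,
    rue = 1.24, k_ext = 0.42, sla = 0.025, te_cf = 6.0, ll_mod = 1.0,
    gpg_stem = 25, pgfr = 7.7e-5, max_gs = 0.041, frac_pod = 0.3,
    sen_rate = 0.008,
    tgf = list(x = c(0, 16, 35, 45), y = c(0, 1, 1, 0)),
    tgn = list(x = c(0, 10, 35, 45), y = c(0, 1, 1, 0)),
    swd = list(x = c(0.1, 1.1), y = c(0, 1)),
    co2_rue = list(x = c(350, 700), y = c(1, 1.35)),
    co2_te = list(x = c(350, 700), y = c(1, 1.37))
  )
}

.interp1 <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = x, rule = 2)$y
}

# Translate a virtual genotype's concrete values onto the simulator parameter
# list. Unknown (placeholder) parameters are ignored, which is what makes them
# inert in the screen.
.crop_params_from_genotype <- function(genotype) {
  p <- .default_crop_params()
  v <- if (inherits(genotype, "virtual_genotype")) genotype$values else genotype
  if (is.null(v)) return(p)
  take <- function(name) v[[name]]
  if (!is.null(take("ll_modifier"))) p$ll_mod <- take("ll_modifier")
  if (!is.null(take("tt_end_of_juvenile"))) p$tt_juv <- take("tt_end_of_juvenile")
  if (!is.null(take("tt_floral_initiation"))) p$tt_fi <- take("tt_floral_initiation")
  if (!is.null(take("tt_start_grain_fill"))) p$tt_sgf <- take("tt_start_grain_fill")
  if (!is.null(take("photop_sens"))) p$photop_sens <- take("photop_sens")
  if (!is.null(take("vern_sens"))) p$vern_sens <- take("vern_sens")
  if (!is.null(take("transp_eff_cf"))) p$te_cf <- take("transp_eff_cf")
  if (!is.null(take("potential_grain_filling_rate"))) p$pgfr <- take("potential_grain_filling_rate")
  if (!is.null(take("grains_per_gram_stem"))) p$gpg_stem <- take("grains_per_gram_stem")
  if (!is.null(take("max_grain_size"))) p$max_gs <- take("max_grain_size")
  if (!is.null(take("senescence_rate"))) p$sen_rate <- take("senescence_rate")
  if (!is.null(take("y_rue"))) p$rue <- mean(take("y_rue")$y)
  if (!is.null(take("y_extinct_coef"))) p$k_ext <- mean(take("y_extinct_coef")$y)
  if (!is.null(take("y_sla"))) p$sla <- mean(take("y_sla")$y)
  if (!is.null(take("y_frac_pod"))) p$frac_pod <- mean(take("y_frac_pod")$y)
  if (!is.null(take("x_temp_grain_fill"))) p$tgf <- take("x_temp_grain_fill")
  if (!is.null(take("x_temp_grain_n_filling"))) p$tgn <- take("x_temp_grain_n_filling")
  if (!is.null(take("x_sw_demand_ratio"))) p$swd <- take("x_sw_demand_ratio")
  if (!is.null(take("co2_rue_modifier"))) p$co2_rue <- take("co2_rue_modifier")
  if (!is.null(take("y_co2_te_modifier"))) p$co2_te <- take("y_co2_te_modifier")
  p
}

#' Daily thermal time accumulation
#'
#' The development clock used by the simulator: a trapezoid cardinal-
#' temperature response of the daily mean temperature with base 0 degC,
#' optimum 26 degC (peak accumulation 26 degCd/day) and maximum 34 degC.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC), vectorised.
#' @return Thermal time in degCd per day.
#' @export
thermal_time <- function(tmin, tmax) {
  stopifnot(all(tmin <= tmax))
  thermal_time_cpp(as.numeric(tmin), as.numeric(tmax))
}

#' Run one crop season
#'
#' Simulates a wheat crop on a daily time step from sowing to maturity:
#' thermal-time phenology modulated by photoperiod and vernalisation, Beer's
#' law light interception, biomass gain as the minimum of radiation-limited
#' and transpiration-limited growth, a layered soil water bucket driving a
#' supply/demand stress ratio, a simple mineral nitrogen pool, and grain set
#' at flowering followed by assimilate- and temperature-limited grain filling.
#'
#' @param genotype A `virtual_genotype` from [materialize_genotype()], a named
#'   list of concrete parameter values, or `NULL` for the reference cultivar.
#' @param env An environment built by [build_environment()]: weather window,
#'   soil profile, management plan and CO2 level.
#' @param return_daily If `TRUE`, attach the daily state trajectory (stage,
#'   supply/demand ratio, nitrogen factor, LAI, biomass).
#'
#' @return A list of class `crop_outputs` with the eight integrated outputs
#'   (`flowering_das`, `maturity_das`, `lai_flowering`, `biomass`,
#'   `grain_number`, `grain_size`, `grain_protein`, `yield`), the seasonal
#'   `water_stress` and `nitrogen_stress` indices in \[0, 1\], a `failed`
#'   flag, and an `audit` list (carbon and water balance components).
#' @export
run_crop <- function(genotype = NULL, env, return_daily = FALSE) {
  p <- .crop_params_from_genotype(genotype)
  f_co2_rue <- .interp1(env$co2, p$co2_rue$x, p$co2_rue$y)
  f_co2_te <- .interp1(env$co2, p$co2_te$x, p$co2_te$y)
  pars <- list(
    tt_emerg = p$tt_emerg, tt_juv = p$tt_juv, tt_fi = p$tt_fi,
    tt_sgf = p$tt_sgf, tt_gf = p$tt_gf,
    photop_sens = p$photop_sens, vern_sens = p$vern_sens,
    rue = p$rue, k_ext = p$k_ext, sla = p$sla, te_cf = p$te_cf,
    ll_mod = p$ll_mod, gpg_stem = p$gpg_stem, pgfr = p$pgfr,
    max_gs = p$max_gs, frac_pod = p$frac_pod, sen_rate = p$sen_rate,
    f_co2_rue = f_co2_rue, f_co2_te = f_co2_te
  )
  curves <- list(tgf_x = p$tgf$x, tgf_y = p$tgf$y,
                 tgn_x = p$tgn$x, tgn_y = p$tgn$y,
                 swd_x = p$swd$x, swd_y = p$swd$y)
  w <- env$weather
  soil <- env$soil
  mgmt <- env$management
  # the photoperiod response acts on civil-twilight day length, approximated
  # as astronomical day length + 1.2 h
  out <- simulate_crop_cpp(
    radn = w$radn, maxt = w$maxt, mint = w$mint, rain = w$rain,
    daylength = w$daylength + 1.2,
    sow_idx = env$sow_idx,
    soil = list(thick = soil$thick, ll = soil$ll, dul = soil$dul, kl = soil$kl,
                sw0 = soil$sw0, no3 = soil$no3 * 0.1,  # kg/ha -> g/m2
                mineralisation = soil$mineralisation * 0.1),
    mgmt = list(amount = mgmt$applications$amount * 0.1,
                stage = mgmt$applications$stage_code,
                condition = mgmt$applications$condition_code,
                threshold = mgmt$applications$threshold),
    pars = pars, curves = curves, return_daily = return_daily
  )
  class(out) <- "crop_outputs"
  out
}

#' @export
print.crop_outputs <- function(x, ...) {
  cat("<crop_outputs>",
      if (isTRUE(x$failed)) "(failed crop)" else "", "\n")
  cat(sprintf("  flowering %s d, maturity %s d after sowing\n",
              format(x$flowering_das), format(x$maturity_das)))
  cat(sprintf("  yield %.2f t/ha  biomass %.2f t/ha  grains %.0f /m2  grain size %.4f g\n",
              x$yield, x$biomass, x$grain_number, x$grain_size))
  cat(sprintf("  protein %.1f %%  water stress %.2f  N stress %.2f\n",
              x$grain_protein, x$water_stress, x$nitrogen_stress))
  invisible(x)
}

#' Integrated outputs as a one-row data frame
#' @param x A `crop_outputs` object.
#' @param ... Unused.
#' @return One-row `data.frame` of the eight integrated outputs plus stress
#'   indices and failure flag.
#' @export
as.data.frame.crop_outputs <- function(x, ...) {
  data.frame(flowering_das = x$flowering_das, maturity_das = x$maturity_das,
             lai_flowering = x$lai_flowering, biomass = x$biomass,
             grain_number = x$grain_number, grain_size = x$grain_size,
             grain_protein = x$grain_protein, yield = x$yield,
             water_stress = x$water_stress, nitrogen_stress = x$nitrogen_stress,
             failed = x$failed)
}
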