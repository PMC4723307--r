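# Fixtures are built in code: a hand-sized registry, controlled constant
# weather environments, and an independent brute-force computation of Morris
# indices straight from the design rows (no use of the engine's transition
# annotations).

tiny_registry <- function() {
  parameter_registry(list(
    parameter_def("a", "scalar", 10),
    parameter_def("b", "scalar", 2),
    parameter_def("c1", "scalar", 1, group = "g1"),
    parameter_def("c2", "scalar", 4, group = "g1"),
    parameter_def("d", "curve", x = c(0, 1), y = c(0.5, 1.5))
  ))
}

# Constant-weather environment with configurable water and nitrogen supply.
# rain_mm: daily rainfall; sw_frac: initial profile fill between lower limit
# and drained upper limit; n0: initial mineral N (kg/ha).
fixture_env <- function(rain_mm = 0, sw_frac = 1, n0 = 150, co2 = 380,
                        days = 500, tmax = 22, tmin = 10, radn = 20,
                        fert = NULL, mineralisation = 0.8) {
  thick <- rep(300, 4)
  ll <- rep(0.15, 4)
  dul <- rep(0.32, 4)
  soil <- list(thick = thick, ll = ll, dul = dul, kl = c(0.08, 0.06, 0.04, 0.03),
               pawc = sum((dul - ll) * thick),
               sw0 = ll * thick + sw_frac * (dul - ll) * thick,
               no3 = n0, mineralisation = mineralisation)
  weather <- data.frame(year = 1, day = seq_len(days), radn = radn, maxt = tmax,
                        mint = tmin, rain = rain_mm,
                        daylength = 12)
  if (is.null(fert)) {
    fert <- data.frame(amount = 100, stage_code = 0L, condition_code = 0L,
                       threshold = 0)
  }
  mgmt <- structure(list(site = "fixture", sowing_tag = "tpe", sow_doy = 1L,
                         n_tag = "tpe", co2 = co2, applications = fert),
                    class = "management_plan")
  structure(list(site = "fixture", year = 1, weather = weather, sow_idx = 1L,
                 soil = soil, management = mgmt, co2 = co2),
            class = "crop_environment")
}

no_stress_env <- function(...) fixture_env(rain_mm = 5, sw_frac = 1, n0 = 250, ...)
terminal_drought_env <- function(...) fixture_env(rain_mm = 0, sw_frac = 0, n0 = 60, ...)

# Brute-force Morris indices: enumerate transitions directly from the row
# list, find the moved factor by comparing coordinates, divide by the signed
# coordinate change. Independent of the engine's bookkeeping.
brute_force_indices <- function(design, y) {
  g <- design$g
  ee <- matrix(NA_real_, g, design$r)
  for (t in seq_len(design$r)) {
    idx <- which(design$trajectory == t)
    for (k in 2:length(idx)) {
      a <- design$rows[idx[k - 1L], ]
      b <- design$rows[idx[k], ]
      moved <- which(abs(b - a) > 1e-12)
      stopifnot(length(moved) == 1L)
      ee[moved, t] <- (y[idx[k]] - y[idx[k - 1L]]) / (b[moved] - a[moved])
    }
  }
  list(mu_star = rowMeans(abs(ee)), sigma = apply(ee, 1L, stats::sd),
       effects = ee)
}

# Summed Euclidean distance between all row pairs of two trajectories
# (plain double loop; used to cross-check the space-filling selection).
pairwise_traj_dist <- function(rows_a, rows_b) {
  s <- 0
  for (i in seq_len(nrow(rows_a))) {
    for (j in seq_len(nrow(rows_b))) {
      s <- s + sqrt(sum((rows_a[i, ] - rows_b[j, ])^2))
    }
  }
  s
}

water_closure_error <- function(out) {
  a <- out$audit
  a$sw_init + a$rain - (a$sw_final + a$transpiration + a$evaporation + a$drainage)
}

carbon_audit_error <- function(out) {
  a <- out$audit
  out$biomass - (a$gains_cum + a$biomass_init - a$sen_loss)
}
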