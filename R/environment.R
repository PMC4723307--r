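#' Day length from latitude and day of year
#'
#' Standard solar-declination formula with the conventional sunrise/sunset
#' definition (solar elevation -0.83 degrees, i.e. including refraction and
#' the solar half-disc).
#'
#' @param latitude Latitude in degrees, `abs(latitude) < 66.5`.
#' @param day_of_year Day of year (1-366); vectorised.
#' @return Day length in hours, in (0, 24).
#' @export
daylength_hours <- function(latitude, day_of_year) {
  if (any(abs(latitude) >= 66.5)) stop("polar latitudes not supported")
  phi <- latitude * pi / 180
  # NOAA-style declination approximation (two harmonics of the mean anomaly)
  g <- 2 * pi / 365.25 * (day_of_year - 2)
  decl <- asin(0.39779 * cos(2 * pi / 365.25 * (day_of_year + 10) +
                               2 * 0.0167 * sin(g)))
  decl <- -decl
  cosh0 <- (sin(-0.83 * pi / 180) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cosh0 <- pmin(1, pmax(-1, cosh0))
  24 / pi * acos(cosh0)
}

.make_soil <- function(pawc, thick, kl, ll_vol, shares, sowing_pawc, initial_n,
                       mineralisation = 0.4) {
  ll_vol <- rep_len(ll_vol, length(thick))
  dul_vol <- ll_vol + shares * pawc / thick
  ll_mm <- ll_vol * thick
  # top-down fill of the sowing plant-available water
  left <- sowing_pawc
  fill <- numeric(length(thick))
  for (j in seq_along(thick)) {
    cap <- (dul_vol[j] - ll_vol[j]) * thick[j]
    fill[j] <- min(left, cap)
    left <- left - fill[j]
  }
  list(thick = thick, ll = ll_vol, dul = dul_vol, kl = kl,
       pawc = sum((dul_vol - ll_vol) * thick),
       sw0 = ll_mm + fill, no3 = initial_n, mineralisation = mineralisation)
}

#' Packaged site archetypes of the target population of environments
#'
#' Four Australian wheatbelt archetypes spanning summer-dominant,
#' evenly-distributed and winter-dominant rainfall regimes, with their
#' climate normals, four-layer soil profiles (plant available water capacity
#' 133.5, 217.5, 190.8 and 101.1 mm), initial water and nitrogen at sowing,
#' and the local split nitrogen schedules including the conditional
#' application rules (rainfall since sowing, plant-available water).
#'
#' @return Named list of `site_archetype` objects.
#' @export
site_archetypes <- function() {
  mk <- function(name, latitude, annual_rain, seasonal_rain, pattern, tmean, tamp,
                 radn_mean, wet_prob, soil, napp) {
    structure(list(name = name, latitude = latitude, annual_rain = annual_rain,
                   seasonal_rain = seasonal_rain, pattern = pattern,
                   tmean = tmean, tamp = tamp, radn_mean = radn_mean,
                   wet_prob = wet_prob, soil = soil, n_schedule = napp),
              class = "site_archetype")
  }
  # applications: amount kg/ha; stage 0 sowing, 1 end of tillering,
  # 2 mid-stem elongation; condition 0 none, 1 rain since sowing > threshold mm,
  # 2 plant available water > threshold * PAWC, 3 plant available water > threshold mm
  napp <- function(amount, stage, condition, threshold) {
    data.frame(amount = amount, stage_code = stage, condition_code = condition,
               threshold = threshold)
  }
  list(
    Emerald = mk("Emerald", -23.53, 635, 170, "summer-dominant", 18.4, 6.5, 18.3, 0.20,
                 .make_soil(133.5, c(300, 300, 400, 500), c(0.08, 0.06, 0.04, 0.03),
                            0.20, c(0.30, 0.30, 0.25, 0.15), 132, 30),
                 napp(50, 0L, 0L, 0)),
    Narrabri = mk("Narrabri", -30.32, 650, 249, "summer-dominant", 13.9, 7.5, 15.7, 0.22,
                  .make_soil(217.5, c(300, 300, 500, 700), c(0.08, 0.06, 0.04, 0.03),
                             0.22, c(0.25, 0.30, 0.25, 0.20), 175, 30),
                  napp(130, 0L, 0L, 0)),
    Yanco = mk("Yanco", -34.61, 425, 228, "evenly-distributed", 11.9, 7.0, 13.3, 0.28,
               .make_soil(190.8, c(300, 300, 500, 600), c(0.08, 0.06, 0.04, 0.03),
                          0.18, c(0.28, 0.30, 0.25, 0.17), 99, 50),
               napp(c(40, 40, 40), c(0L, 1L, 2L), c(0L, 1L, 2L), c(0, 100, 0.6))),
    Merredin = mk("Merredin", -31.50, 303, 209, "winter-dominant", 13.1, 6.5, 14.5, 0.25,
                  .make_soil(101.1, c(200, 300, 300, 300), c(0.08, 0.06, 0.04, 0.03),
                             0.12, c(0.30, 0.30, 0.25, 0.15), 39, 30),
                  napp(c(20, 20, 30), c(0L, 1L, 2L), c(0L, 0L, 3L), c(0, 0, 60)))
  )
}

#' @export
print.site_archetype <- function(x, ...) {
  cat(sprintf("<site_archetype> %s (lat %.2f): %s rainfall, %.0f mm/yr, PAWC %.1f mm\n",
              x$name, x$latitude, x$pattern, x$annual_rain, x$soil$pawc), sep = "")
  invisible(x)
}

# Mean of cos(2*pi*(doy - peak)/365.25) over the 1 May - 1 Nov window when the
# peak sits at the window centre (mid-July); used to convert growing-season
# normals to annual harmonic parameters.
.SEASON_WEIGHT <- 0.609
.SEASON_FRAC <- 184 / 365

# Rainfall harmonic: peak phase from the declared pattern, amplitude calibrated
# so the expected May-Nov share matches the archetype's seasonal/annual ratio.
.pattern_spec <- function(site) {
  share <- site$seasonal_rain / site$annual_rain
  if (site$pattern == "summer-dominant") {
    amp <- (1 - share / .SEASON_FRAC) / .SEASON_WEIGHT
    peak <- 15
  } else {
    amp <- (share / .SEASON_FRAC - 1) / .SEASON_WEIGHT
    peak <- 196
  }
  list(peak = peak, amp = min(0.9, max(0.05, amp)))
}

#' Generate synthetic daily weather for a site archetype
#'
#' Rainfall is a seasonal Bernoulli occurrence process with gamma amounts,
#' parameterised so the expected daily total follows a seasonal harmonic whose
#' phase and amplitude encode the archetype's rainfall pattern and whose
#' integral equals the archetype's annual mean. Temperature and radiation are
#' seasonal sinusoids with autocorrelated (AR1) and white noise respectively.
#' Years are 365 days; day length comes from [daylength_hours()].
#'
#' @param site A `site_archetype`.
#' @param year_count Number of synthetic years.
#' @param seed Integer seed; the series is reproducible per seed.
#' @return `data.frame` with columns `year`, `day`, `radn` (MJ m-2), `maxt`,
#'   `mint` (degC), `rain` (mm), `daylength` (h).
#' @export
generate_weather <- function(site, year_count, seed = 1L) {
  stopifnot(inherits(site, "site_archetype"), year_count >= 1L)
  set.seed(seed)
  n <- year_count * 365L
  doy <- rep(1:365, year_count)
  ps <- .pattern_spec(site)
  harm <- cos(2 * pi * (doy - ps$peak) / 365.25)

  e_rain <- site$annual_rain / 365 * (1 + ps$amp * harm)
  p_wet <- pmin(0.6, pmax(0.02, site$wet_prob * (1 + 0.5 * ps$amp * harm)))
  wet <- stats::runif(n) < p_wet
  shape <- 0.75
  rain <- numeric(n)
  rain[wet] <- stats::rgamma(sum(wet), shape = shape,
                             scale = e_rain[wet] / (p_wet[wet] * shape))

  # tmean / radn_mean are May-Nov (growing season) normals: convert to the
  # annual sinusoid whose seasonal window mean reproduces them
  tharm <- cos(2 * pi * (doy - 15) / 365.25)
  t_annual <- site$tmean + .SEASON_WEIGHT * site$tamp
  ar <- stats::filter(stats::rnorm(n, 0, 1.8 * sqrt(1 - 0.6^2)), 0.6,
                      method = "recursive")
  tavg <- t_annual + site$tamp * tharm + as.numeric(ar)
  dtr <- pmin(18, pmax(6, 12 + stats::rnorm(n, 0, 1.5)))
  maxt <- tavg + dtr / 2
  mint <- tavg - dtr / 2

  ramp <- 0.25 + 0.006 * abs(site$latitude)
  r_annual <- site$radn_mean / (1 - .SEASON_WEIGHT * ramp)
  radn <- pmin(35, pmax(1, r_annual * (1 + ramp * tharm) + stats::rnorm(n, 0, 1.2)))

  data.frame(year = rep(seq_len(year_count), each = 365L), day = doy,
             radn = radn, maxt = maxt, mint = mint, rain = rain,
             daylength = daylength_hours(site$latitude, doy))
}

#' Read / write weather in the tabular met layout
#'
#' Plain whitespace-separated text with columns `year day radn maxt mint rain`,
#' the de-facto crop-model met layout; comment lines starting with `!` or `#`
#' are tolerated on reading.
#'
#' @param weather Weather `data.frame` as from [generate_weather()].
#' @param path File path.
#' @param latitude If given, `read_met()` recomputes the `daylength` column.
#' @export
write_met <- function(weather, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("! synthetic daily weather (traitscreen)", con)
  writeLines("year day radn maxt mint rain", con)
  utils::write.table(format(weather[c("year", "day", "radn", "maxt", "mint", "rain")],
                            digits = 8, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_met
#' @export
read_met <- function(path, latitude = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[!#]", lines) & nzchar(trimws(lines))]
  has_header <- grepl("^\\s*year", lines[1], ignore.case = TRUE)
  d <- if (has_header) {
    utils::read.table(text = lines, header = TRUE)
  } else {
    utils::read.table(text = lines,
                      col.names = c("year", "day", "radn", "maxt", "mint", "rain"))
  }
  names(d) <- c("year", "day", "radn", "maxt", "mint", "rain")
  if (!is.null(latitude)) d$daylength <- daylength_hours(latitude, d$day)
  d
}

#' Build a management plan
#'
#' Encodes the sowing date, the site's split nitrogen doses with their
#' conditional triggers (evaluated at run time by the simulator), and the CO2
#' level. The low nitrogen level halves every scheduled dose; the high level
#' adds 50 kg/ha at sowing on top of the local schedule.
#'
#' @param site A `site_archetype`.
#' @param sowing_tag `"early"` (21 Apr), `"tpe"` (15 May) or `"late"` (7 Jun).
#' @param n_tag `"low"`, `"tpe"` or `"high"`.
#' @param co2 CO2 concentration in ppm (380 or 555 for the packaged plans).
#' @return List of class `management_plan` with `sow_doy`, `applications`
#'   (amount kg/ha, stage and condition codes, threshold), `n_tag`, `co2`.
#' @export
management_plan <- function(site, sowing_tag = c("tpe", "early", "late"),
                            n_tag = c("tpe", "low", "high"), co2 = 380) {
  sowing_tag <- match.arg(sowing_tag)
  n_tag <- match.arg(n_tag)
  sow_doy <- switch(sowing_tag, early = 111L, tpe = 135L, late = 158L)
  app <- site$n_schedule
  if (n_tag == "low") {
    app$amount <- app$amount * 0.5
  } else if (n_tag == "high") {
    app <- rbind(app, data.frame(amount = 50, stage_code = 0L,
                                 condition_code = 0L, threshold = 0))
  }
  structure(list(site = site$name, sowing_tag = sowing_tag, sow_doy = sow_doy,
                 n_tag = n_tag, co2 = co2, applications = app),
            class = "management_plan")
}

#' Cartesian environment grid
#'
#' @param sites Character vector of site names.
#' @param years Integer vector of (synthetic) year indices.
#' @param sowings Sowing tags.
#' @param n_levels Nitrogen tags.
#' @param co2_levels CO2 levels (ppm).
#' @return `data.frame` with one row per environment and a unique `env_id`.
#' @export
build_environment_grid <- function(sites, years, sowings = "tpe",
                                   n_levels = "tpe", co2_levels = 380) {
  stopifnot(length(sites) > 0, length(years) > 0, length(sowings) > 0,
            length(n_levels) > 0, length(co2_levels) > 0)
  g <- expand.grid(site = sites, year = years, sowing = sowings,
                   n_level = n_levels, co2 = co2_levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$env_id <- sprintf("%s_y%03d_%s_%s_%d", g$site, g$year, g$sowing,
                      g$n_level, g$co2)
  stopifnot(!anyDuplicated(g$env_id))
  g
}

#' Assemble one concrete growing environment
#'
#' Slices a two-season weather window starting in the given synthetic year
#' (so late crops can mature past 31 December), and bundles it with the site
#' soil at its sowing initial conditions and the management plan.
#'
#' @param site A `site_archetype`.
#' @param weather Site weather from [generate_weather()] (needs `year + 1`
#'   available, or the window is truncated at the series end).
#' @param year Synthetic year index of sowing.
#' @param sowing_tag,n_tag,co2 Passed to [management_plan()].
#' @return List of class `crop_environment`.
#' @export
build_environment <- function(site, weather, year, sowing_tag = "tpe",
                              n_tag = "tpe", co2 = 380) {
  mgmt <- management_plan(site, sowing_tag, n_tag, co2)
  start <- (year - 1L) * 365L + 1L
  stop_ <- min(nrow(weather), start + 730L - 1L)
  if (start > nrow(weather)) stop("year outside the generated weather series")
  w <- weather[start:stop_, , drop = FALSE]
  structure(list(site = site$name, year = year, weather = w,
                 sow_idx = mgmt$sow_doy, soil = site$soil,
                 management = mgmt, co2 = co2),
            class = "crop_environment")
}
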