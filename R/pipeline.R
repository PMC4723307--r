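#' Derive a per-stage child seed from the master seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage k
#' uses a deterministic child (a Lehmer step offset by the stage index), kept
#' below 2^31.
#'
#' @param seed Master integer seed.
#' @param k Stage index.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Configure a screening run
#'
#' The `"paper"` preset mirrors the full study conditions (90 factors,
#' 6 levels, 100 trajectories; 4 sites x 125 years x 3 sowings x 3 N x 2 CO2
#' = 9000 environments; planning only at this scale). The `"desk"` preset is
#' the packaged single-CPU scale: the 20-factor desk set
#' ([desk_factors()]), 20 trajectories, and 2 sites x 5 synthetic years x
#' 1 sowing x 2 N x 2 CO2 = 40 environments (16 800 simulations).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... Overrides for any config field.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(preset = "desk", factors = desk_factors(),
         n_levels = 6L, r = 20L, n_candidates = 30L,
         sites = c("Yanco", "Merredin"), years = 1:5,
         sowings = "tpe", n_tags = c("low", "tpe"), co2_levels = c(380, 555),
         seed = 42L, impact_threshold = 0.02,
         et_thresholds = c(mild = 0.2, severe = 0.5), k = 3L,
         out_dir = file.path(tempdir(), "traitscreen_run"), jobs = 1L)
  } else {
    list(preset = "paper", factors = NULL,
         n_levels = 6L, r = 100L, n_candidates = 500L,
         sites = c("Emerald", "Narrabri", "Yanco", "Merredin"), years = 1:125,
         sowings = c("early", "tpe", "late"), n_tags = c("low", "tpe", "high"),
         co2_levels = c(380, 555),
         seed = 42L, impact_threshold = 0.02,
         et_thresholds = c(mild = 0.2, severe = 0.5), k = 3L,
         out_dir = file.path(tempdir(), "traitscreen_run"), jobs = 1L)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

.config_registry <- function(config) {
  reg <- wheat_registry()
  if (!is.null(config$factors)) reg <- subset_registry(reg, config$factors)
  reg
}

#' Dry-run manifest: design, environment and simulation counts
#'
#' @param config A [run_config()].
#' @return List with `g`, `design_rows` (r\*(g+1)), `environments` and
#'   `total_simulations`; no simulation is performed.
#' @export
plan_run <- function(config) {
  g <- count_factors(.config_registry(config))
  rows <- (g + 1L) * config$r
  envs <- length(config$sites) * length(config$years) * length(config$sowings) *
    length(config$n_tags) * length(config$co2_levels)
  list(g = g, r = config$r, design_rows = rows, environments = envs,
       total_simulations = as.double(rows) * envs)
}

#' Screen traits across a set of environments
#'
#' The core Morris screen: materialises every design row as a virtual
#' genotype, simulates each genotype in each environment, and computes raw
#' and environment-standardized sensitivity indices per factor, environment
#' and output variable. Baseline (reference cultivar) runs per environment
#' provide the seasonal stress indices and the drought environment type.
#'
#' @param registry A [parameter_registry()].
#' @param design A [morris_design()] over the registry's factors.
#' @param env_grid Environment table from [build_environment_grid()].
#' @param site_weather Named list of weather tables (one per site).
#' @param sites Named list of `site_archetype`s (default [site_archetypes()]).
#' @param outputs Output variables to index (default all eight integrated
#'   outputs).
#' @param jobs Number of worker processes over environments (results are
#'   independent of the worker count).
#' @return List with `indices` (long data.frame: factor, environment, output,
#'   mu_star, sigma, standardized), `environments` (env grid plus baseline
#'   yield, stress indices, drought type) and `outputs` (long simulation
#'   outputs per genotype x environment).
#' @export
screen_traits <- function(registry, design, env_grid, site_weather,
                          sites = site_archetypes(),
                          outputs = c("flowering_das", "maturity_das",
                                      "lai_flowering", "biomass",
                                      "grain_number", "grain_size",
                                      "grain_protein", "yield"),
                          jobs = 1L) {
  genos <- apply(design$rows, 1L, function(lv) {
    materialize_genotype(registry, stats::setNames(lv, design$factor_names))
  })

  one_env <- function(i) {
    e <- env_grid[i, ]
    env <- build_environment(sites[[e$site]], site_weather[[e$site]], e$year,
                             e$sowing, e$n_level, e$co2)
    sim <- vapply(genos, function(gn) {
      o <- run_crop(gn, env)
      c(flowering_das = as.numeric(o$flowering_das),
        maturity_das = as.numeric(o$maturity_das),
        lai_flowering = o$lai_flowering, biomass = o$biomass,
        grain_number = o$grain_number, grain_size = o$grain_size,
        grain_protein = o$grain_protein, yield = o$yield,
        water_stress = o$water_stress, nitrogen_stress = o$nitrogen_stress)
    }, numeric(10))
    sim <- t(sim)

    idx <- lapply(outputs, function(ov) {
      raw <- morris_indices(elementary_effects(design, sim[, ov]))
      z <- as.numeric(standardize_by_environment(sim[, ov, drop = FALSE]))
      std <- morris_indices(elementary_effects(design, z), standardized = TRUE)
      rbind(
        data.frame(factor = raw$factor, environment = e$env_id, output = ov,
                   mu_star = raw$mu_star, sigma = raw$sigma,
                   standardized = FALSE, stringsAsFactors = FALSE),
        data.frame(factor = std$factor, environment = e$env_id, output = ov,
                   mu_star = std$mu_star, sigma = std$sigma,
                   standardized = TRUE, stringsAsFactors = FALSE)
      )
    })

    base <- run_crop(NULL, env, return_daily = TRUE)
    et <- drought_type(1 - base$daily$sd_ratio, base$flowering_das + 1L)
    list(indices = do.call(rbind, idx),
         env = data.frame(env_id = e$env_id, site = e$site, year = e$year,
                          sowing = e$sowing, n_level = e$n_level, co2 = e$co2,
                          baseline_yield = base$yield,
                          water_stress = base$water_stress,
                          nitrogen_stress = base$nitrogen_stress,
                          drought_type = et, stringsAsFactors = FALSE),
         outputs = data.frame(env_id = e$env_id, design_row = seq_len(nrow(sim)),
                              sim, stringsAsFactors = FALSE))
  }

  res <- if (jobs > 1L) {
    parallel::mclapply(seq_len(nrow(env_grid)), one_env, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(env_grid)), one_env)
  }
  list(indices = do.call(rbind, lapply(res, `[[`, "indices")),
       environments = do.call(rbind, lapply(res, `[[`, "env")),
       outputs = do.call(rbind, lapply(res, `[[`, "outputs")))
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$jobs <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (!file.exists(p)) return(NULL)
  tryCatch(jsonlite::read_json(p, simplifyVector = TRUE), error = function(e) NULL)
}

#' Run the full screening pipeline
#'
#' Stages: build the Morris design, generate site weather, simulate all
#' genotype x environment combinations, compute sensitivity indices, and run
#' the downstream analysis (impact classification, Ward clustering of
#' impactful traits, eta-squared variance decomposition, drought typing and
#' stress-index regressions of standardized yield impact). Stage artifacts
#' are written as CSV under `config$out_dir` with their checksums recorded in
#' `manifest.json`; a second invocation with an identical configuration
#' reuses intact cached artifacts and recomputes any stage whose file is
#' missing or fails its checksum. All randomness derives from
#' `config$seed` via [child_seed()].
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   results (`indices`, `environments`, `classification`, `eta2`,
#'   `stress_regression`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest <- .read_manifest(config$out_dir)
  fresh <- is.null(manifest) || !identical(manifest$config_hash, hash)
  if (fresh) manifest <- list(config_hash = hash, files = list())
  files <- as.list(manifest$files)
  say <- function(...) if (!quiet) message(...)

  cache_ok <- function(name) {
    path <- file.path(config$out_dir, name)
    rec <- files[[name]]
    !fresh && !is.null(rec) && file.exists(path) &&
      identical(unname(tools::md5sum(path)), rec)
  }
  save_csv <- function(val, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(val, path, row.names = FALSE)
    files[[name]] <<- unname(tools::md5sum(path))
    val
  }
  cached <- function(name, compute, write_fn = save_csv,
                     read_fn = function(p) utils::read.csv(p, stringsAsFactors = FALSE)) {
    if (cache_ok(name)) {
      say("stage ", name, ": cache hit")
      return(read_fn(file.path(config$out_dir, name)))
    }
    say("stage ", name, ": computing")
    val <- compute()
    write_fn(val, name)
    val
  }

  registry <- .config_registry(config)
  g <- count_factors(registry)

  design <- cached("design.csv",
    function() morris_design(g, config$n_levels, config$r, config$n_candidates,
                             seed = child_seed(config$seed, 1L),
                             factor_names = factor_names(registry)),
    write_fn = function(v, name) {
      write_design(v, file.path(config$out_dir, name))
      files[[name]] <<- unname(tools::md5sum(file.path(config$out_dir, name)))
      v
    },
    read_fn = read_design)

  sites <- site_archetypes()[config$sites]
  site_weather <- lapply(seq_along(sites), function(i) {
    generate_weather(sites[[i]], max(config$years) + 1L,
                     seed = child_seed(config$seed, 10L + i))
  })
  names(site_weather) <- names(sites)

  env_grid <- build_environment_grid(config$sites, config$years, config$sowings,
                                     config$n_tags, config$co2_levels)

  if (cache_ok("indices.csv") && cache_ok("environments.csv")) {
    say("stage simulate: cache hit")
    indices <- utils::read.csv(file.path(config$out_dir, "indices.csv"),
                               stringsAsFactors = FALSE)
    environments <- utils::read.csv(file.path(config$out_dir, "environments.csv"),
                                    stringsAsFactors = FALSE)
  } else {
    say("stage simulate: computing (", plan_run(config)$total_simulations,
        " simulations)")
    screen <- screen_traits(registry, design, env_grid, site_weather,
                            sites = sites, jobs = config$jobs)
    indices <- save_csv(screen$indices, "indices.csv")
    environments <- save_csv(screen$environments, "environments.csv")
  }

  raw_yield <- indices[!indices$standardized & indices$output == "yield", ]
  classification <- cached("classification.csv",
    function() classify_traits(raw_yield, config$impact_threshold))

  impactful <- classification$factor[classification$group == "impactful"]

  eta2 <- cached("eta2.csv",
    function() {
      rows <- lapply(impactful, function(tr) {
        d <- raw_yield[raw_yield$factor == tr, ]
        d <- merge(d, environments, by.x = "environment", by.y = "env_id")
        vd <- eta_squared(d$mu_star,
                          data.frame(site = d$site, sowing = d$sowing,
                                     co2 = d$co2, nitrogen = d$n_level))
        data.frame(factor = tr, t(vd$eta2), residual = vd$residual,
                   stringsAsFactors = FALSE)
      })
      if (length(rows) == 0L) {
        data.frame(factor = character(), site = numeric(), sowing = numeric(),
                   co2 = numeric(), nitrogen = numeric(), residual = numeric())
      } else do.call(rbind, rows)
    })

  # trait x output matrix (mean standardized impact across environments)
  cl <- NULL
  if (length(impactful) >= 2L) {
    std <- indices[indices$standardized & indices$factor %in% impactful, ]
    mat <- tapply(std$mu_star, list(std$factor, std$output), mean)
    cl <- cluster_impactful(mat, k = min(config$k, nrow(mat)))
    dendrogram_newick(cl$hclust, file.path(config$out_dir, "dendrogram.nwk"))
    files[["dendrogram.nwk"]] <- unname(tools::md5sum(file.path(config$out_dir, "dendrogram.nwk")))
  }

  stressreg <- cached("stress_regression.csv",
    function() {
      std_yield <- indices[indices$standardized & indices$output == "yield", ]
      rows <- lapply(intersect(c("y_rue", "ll_modifier", "tt_end_of_juvenile",
                                 "potential_grain_filling_rate"), impactful),
                     function(tr) {
        d <- merge(std_yield[std_yield$factor == tr, ], environments,
                   by.x = "environment", by.y = "env_id")
        tab <- table(d$drought_type)
        keep <- names(tab)[tab >= 3L]
        d <- d[d$drought_type %in% keep, ]
        ok <- vapply(split(d$water_stress, d$drought_type),
                     function(s) stats::sd(s) > 0, logical(1))
        d <- d[d$drought_type %in% names(ok)[ok], ]
        if (nrow(d) == 0L) return(NULL)
        cbind(factor = tr,
              stress_regression(d$mu_star, d$water_stress, d$drought_type))
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows) == 0L) {
        data.frame(factor = character(), type = character(), slope = numeric(),
                   intercept = numeric(), r = numeric(), n = integer())
      } else do.call(rbind, rows)
    })

  manifest <- list(config_hash = hash, files = files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(out_dir = config$out_dir, design = design, indices = indices,
                 environments = environments, classification = classification,
                 eta2 = eta2, clustering = cl, stress_regression = stressreg))
}
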