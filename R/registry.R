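#' Define a model parameter (component trait)
#'
#' A parameter is either a single scalar or a "function" parameter: a pair of
#' equal-length vectors where `x` pilots a state variable (e.g. stage code,
#' temperature) and `y` carries the trait value. Nominal values describe the
#' reference cultivar; variation ranges are derived from them by
#' [apply_range_rule()].
#'
#' @param name Parameter identifier.
#' @param kind `"scalar"` or `"curve"`.
#' @param nominal Nominal scalar value (scalar parameters only).
#' @param x,y Numeric vectors of equal length with strictly increasing `x`
#'   (curve parameters only).
#' @param units Free-text units.
#' @param hard_lower,hard_upper Optional physical bounds on the scalar value.
#' @param scaling_mode `"full"` (scale the scalar, or every `y` entry) or
#'   `"point"` (scale a single entry of `x` or `y`).
#' @param point_axis,point_index For `scaling_mode = "point"`: which axis
#'   (`"x"` or `"y"`) and which position is scaled.
#' @param group Optional meta-parameter group id; grouped parameters share one
#'   Morris factor.
#' @param process Free-text physiological process label.
#' @param active Whether the surrogate simulator consumes the parameter.
#'   Inactive parameters are still screened (and must come out with zero
#'   effect).
#'
#' @return An object of class `parameter_def`.
#' @export
parameter_def <- function(name, kind = c("scalar", "curve"), nominal = NA_real_,
                          x = NULL, y = NULL, units = "",
                          hard_lower = NA_real_, hard_upper = NA_real_,
                          scaling_mode = c("full", "point"),
                          point_axis = NA_character_, point_index = NA_integer_,
                          group = NA_character_, process = "", active = FALSE) {
  kind <- match.arg(kind)
  scaling_mode <- match.arg(scaling_mode)
  if (kind == "curve") {
    if (is.null(x) || is.null(y) || length(x) != length(y)) {
      stop("curve parameter '", name, "' needs equal-length x and y vectors")
    }
    if (any(diff(x) <= 0)) {
      stop("curve parameter '", name, "' must have strictly increasing x")
    }
    if (scaling_mode == "point") {
      if (!point_axis %in% c("x", "y")) {
        stop("point scaling for '", name, "' needs point_axis 'x' or 'y'")
      }
      if (is.na(point_index) || point_index < 1L || point_index > length(x)) {
        stop("point_index out of range for parameter '", name, "'")
      }
    }
  } else {
    if (!is.finite(nominal)) stop("scalar parameter '", name, "' needs a finite nominal")
    if (!is.na(hard_lower) && nominal < hard_lower) {
      stop("nominal of '", name, "' below its hard lower bound")
    }
    if (!is.na(hard_upper) && nominal > hard_upper) {
      stop("nominal of '", name, "' above its hard upper bound")
    }
  }
  structure(list(
    name = name, kind = kind, nominal = nominal,
    x = x, y = y, units = units,
    hard_lower = hard_lower, hard_upper = hard_upper,
    scaling_mode = scaling_mode,
    point_axis = point_axis, point_index = as.integer(point_index),
    group = group, process = process, active = isTRUE(active)
  ), class = "parameter_def")
}

#' Assemble parameters into a registry
#'
#' The registry is the ordered inventory of screened parameters together with
#' its meta-parameter groups. Grouped parameters vary together: each group
#' contributes a single independent Morris factor, so the factor count is
#' `#parameters - #grouped + #groups`.
#'
#' @param params List of [parameter_def()] objects.
#' @return Object of class `parameter_registry`.
#' @export
parameter_registry <- function(params) {
  nm <- vapply(params, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate parameter names in registry")
  names(params) <- nm
  groups <- split(nm, vapply(params, function(p) p$group, character(1)))
  groups <- groups[!is.na(names(groups)) & names(groups) != "NA"]
  if (any(lengths(groups) < 2L)) {
    stop("meta-parameter groups must contain at least two members")
  }
  structure(list(params = params, groups = groups), class = "parameter_registry")
}

#' @export
print.parameter_registry <- function(x, ...) {
  np <- length(x$params)
  ng <- length(x$groups)
  nmem <- sum(lengths(x$groups))
  cat("<parameter_registry>\n")
  cat("  parameters: ", np, " (",
      sum(vapply(x$params, function(p) p$kind == "scalar", logical(1))),
      " scalar, ",
      sum(vapply(x$params, function(p) p$kind == "curve", logical(1))),
      " curve)\n", sep = "")
  cat("  meta-parameter groups: ", ng, " over ", nmem, " members\n", sep = "")
  cat("  independent factors: ", count_factors(x), "\n", sep = "")
  invisible(x)
}

#' Variation range for a scalar parameter
#'
#' Applies the fixed-width rule used for the screen: every parameter varies
#' over a total width of 40% of its nominal value. Where both endpoints are
#' feasible this is the symmetric multiplicative range (0.8, 1.2) x nominal;
#' where a hard bound would be violated the full 40% width is placed on the
#' feasible side of the nominal. A zero nominal gives a zero-width range and
#' the parameter is treated as fixed (it contributes no factor).
#'
#' @param nominal Finite nominal value.
#' @param hard_lower,hard_upper Optional bounds; `NA` means unbounded.
#' @return A list of class `variation_range` with `lower`, `upper`,
#'   `one_sided` (`"none"`, `"below"` or `"above"`) and `fixed`.
#' @examples
#' apply_range_rule(1.5)            # (1.2, 1.8)
#' apply_range_rule(555)            # (444, 666)
#' apply_range_rule(1, hard_upper = 1)  # (0.6, 1.0)
#' @export
apply_range_rule <- function(nominal, hard_lower = NA_real_, hard_upper = NA_real_) {
  stopifnot(is.finite(nominal))
  if (nominal == 0) {
    return(structure(list(lower = 0, upper = 0, one_sided = "none", fixed = TRUE),
                     class = "variation_range"))
  }
  w <- 0.4 * abs(nominal)
  lo <- nominal - w / 2
  hi <- nominal + w / 2
  one_sided <- "none"
  if (!is.na(hard_upper) && hi > hard_upper) {
    hi <- nominal
    lo <- nominal - w
    one_sided <- "below"
  } else if (!is.na(hard_lower) && lo < hard_lower) {
    lo <- nominal
    hi <- nominal + w
    one_sided <- "above"
  }
  if (!is.na(hard_lower)) lo <- max(lo, hard_lower)
  if (!is.na(hard_upper)) hi <- min(hi, hard_upper)
  structure(list(lower = lo, upper = hi, one_sided = one_sided, fixed = FALSE),
            class = "variation_range")
}

#' Scale a curve parameter to a normalised level
#'
#' The scaling factor is linear in the normalised level: 0.8 at level 0,
#' 1 at level 0.5 (the nominal curve) and 1.2 at level 1. In `"full"` mode
#' every `y` entry is scaled; in `"point"` mode only the designated `x` or `y`
#' entry is. Point scaling of an `x` entry that would break the strict
#' monotonicity of `x` is an error, not a silent re-sort.
#'
#' @param param A curve [parameter_def()].
#' @param level Normalised level in \[0, 1\].
#' @return List with scaled `x` and `y` vectors.
#' @export
scale_curve <- function(param, level) {
  stopifnot(inherits(param, "parameter_def"), param$kind == "curve",
            level >= 0, level <= 1)
  f <- 0.8 + 0.4 * level
  x <- param$x
  y <- param$y
  if (param$scaling_mode == "full") {
    y <- y * f
  } else if (param$point_axis == "y") {
    y[param$point_index] <- y[param$point_index] * f
  } else {
    x[param$point_index] <- x[param$point_index] * f
    if (any(diff(x) <= 0)) {
      stop("x-point scaling breaks monotonicity for parameter '", param$name, "'")
    }
  }
  list(x = x, y = y)
}

# Ordered independent factor names: ungrouped parameters keep their own name,
# each group appears once at the position of its first member. Zero-nominal
# scalars are fixed and excluded.
#' Names of the independent Morris factors of a registry
#' @param registry A [parameter_registry()].
#' @return Character vector of factor names, in registry order.
#' @export
factor_names <- function(registry) {
  stopifnot(inherits(registry, "parameter_registry"))
  seen <- character(0)
  out <- character(0)
  for (p in registry$params) {
    if (p$kind == "scalar") {
      rng <- apply_range_rule(p$nominal, p$hard_lower, p$hard_upper)
      if (rng$fixed) next
    }
    id <- if (is.na(p$group)) p$name else p$group
    if (!id %in% seen) {
      seen <- c(seen, id)
      out <- c(out, id)
    }
  }
  out
}

#' Count independent factors
#'
#' Grouped parameters are collapsed onto their meta-parameter, so the count is
#' `#parameters - #grouped members + #groups` (fixed, zero-nominal parameters
#' excluded).
#'
#' @param registry A [parameter_registry()].
#' @return Integer factor count.
#' @export
count_factors <- function(registry) {
  length(factor_names(registry))
}

#' Materialise a virtual genotype from normalised factor levels
#'
#' Maps one row of the normalised Morris design to concrete parameter values.
#' Scalars are placed linearly inside their [apply_range_rule()] interval
#' (`lower + level * (upper - lower)`); curves go through [scale_curve()].
#' Every member of a meta-parameter group receives the level of its group
#' factor.
#'
#' @param registry A [parameter_registry()].
#' @param levels Numeric vector of levels in \[0, 1\], one per independent
#'   factor, named or in [factor_names()] order.
#' @return Object of class `virtual_genotype`: list with `levels` (named) and
#'   `values` (named list of concrete scalars / curves).
#' @export
materialize_genotype <- function(registry, levels) {
  fn <- factor_names(registry)
  if (is.null(names(levels))) {
    if (length(levels) != length(fn)) {
      stop("expected ", length(fn), " factor levels, got ", length(levels))
    }
    names(levels) <- fn
  } else if (!all(names(levels) %in% fn)) {
    bad <- setdiff(names(levels), fn)
    stop("unknown factor name(s): ", paste(bad, collapse = ", "))
  }
  if (any(levels < 0 | levels > 1)) stop("factor levels must lie in [0, 1]")
  values <- list()
  for (p in registry$params) {
    id <- if (is.na(p$group)) p$name else p$group
    if (!id %in% names(levels)) {
      # fixed parameter (zero nominal) or factor not screened: keep nominal
      values[[p$name]] <- if (p$kind == "scalar") p$nominal else list(x = p$x, y = p$y)
      next
    }
    l <- unname(levels[[id]])
    if (p$kind == "scalar") {
      rng <- apply_range_rule(p$nominal, p$hard_lower, p$hard_upper)
      values[[p$name]] <- rng$lower + l * (rng$upper - rng$lower)
    } else {
      values[[p$name]] <- scale_curve(p, l)
    }
  }
  structure(list(levels = levels, values = values), class = "virtual_genotype")
}

#' @export
print.virtual_genotype <- function(x, ...) {
  cat("<virtual_genotype> ", length(x$levels), " factors, ",
      length(x$values), " concrete parameters\n", sep = "")
  invisible(x)
}

.serialize_vec <- function(v) {
  if (is.null(v)) "" else paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                                collapse = ";")
}

.deserialize_vec <- function(s) {
  if (is.na(s) || !nzchar(s)) NULL else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Read / write a parameter registry as CSV
#'
#' One row per parameter with columns `name, kind, nominal, x, y, units,
#' hard_lower, hard_upper, scaling_mode, point_axis, point_index, group,
#' process, active`; curve vectors are semicolon-separated.
#'
#' @param path File path.
#' @return `read_registry()` returns a [parameter_registry()].
#' @export
read_registry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  params <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    parameter_def(
      name = r$name, kind = r$kind,
      nominal = if (is.na(r$nominal)) NA_real_ else as.numeric(r$nominal),
      x = .deserialize_vec(r$x), y = .deserialize_vec(r$y),
      units = if (is.na(r$units)) "" else r$units,
      hard_lower = as.numeric(r$hard_lower), hard_upper = as.numeric(r$hard_upper),
      scaling_mode = r$scaling_mode,
      point_axis = r$point_axis,
      point_index = if (is.na(r$point_index)) NA_integer_ else as.integer(r$point_index),
      group = r$group,
      process = if (is.na(r$process)) "" else r$process,
      active = isTRUE(as.logical(r$active))
    )
  })
  parameter_registry(params)
}

#' @rdname read_registry
#' @param registry A [parameter_registry()].
#' @export
write_registry <- function(registry, path) {
  rows <- lapply(registry$params, function(p) {
    data.frame(
      name = p$name, kind = p$kind,
      nominal = p$nominal,
      x = .serialize_vec(p$x), y = .serialize_vec(p$y),
      units = p$units,
      hard_lower = p$hard_lower, hard_upper = p$hard_upper,
      scaling_mode = p$scaling_mode,
      point_axis = p$point_axis, point_index = p$point_index,
      group = p$group, process = p$process, active = p$active,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged wheat parameter registry
#'
#' Loads the registry shipped with the package: 103 parameters (62 scalar,
#' 41 curve) of which 20 are collapsed into 7 meta-parameter groups, giving
#' 90 independent factors. Twenty entries carry real semantics in the
#' surrogate simulator (flagged `active`); the remainder are inert
#' placeholders named after conventional wheat-model parameters, kept so the
#' inventory bookkeeping and null-impact screening behave like a full model
#' parameter file.
#'
#' @return A [parameter_registry()].
#' @export
wheat_registry <- function() {
  read_registry(system.file("extdata", "registry.csv", package = "traitscreen",
                            mustWork = TRUE))
}

#' Restrict a registry to a subset of parameters
#'
#' @param registry A [parameter_registry()].
#' @param names Parameter names to keep. Groups are preserved when at least two
#'   members are kept; a single kept member of a group becomes its own factor.
#' @return A [parameter_registry()].
#' @export
subset_registry <- function(registry, names) {
  keep <- registry$params[names]
  if (any(vapply(keep, is.null, logical(1)))) {
    stop("unknown parameter(s): ",
         paste(names[vapply(keep, is.null, logical(1))], collapse = ", "))
  }
  keep <- lapply(keep, function(p) {
    if (!is.na(p$group)) {
      members <- intersect(registry$groups[[p$group]], names)
      if (length(members) < 2L) p$group <- NA_character_
    }
    p
  })
  parameter_registry(keep)
}

#' Factor set used by the desk-scale screening runs
#'
#' Sixteen simulator-active parameters plus four inert placeholders: large
#' enough to exercise the null / low / impactful classification, small enough
#' for a single-CPU run.
#'
#' @return Character vector of 20 parameter names.
#' @export
desk_factors <- function() {
  c("ll_modifier", "tt_end_of_juvenile", "tt_floral_initiation",
    "photop_sens", "vern_sens", "y_rue", "y_extinct_coef", "y_sla",
    "transp_eff_cf", "potential_grain_filling_rate", "grains_per_gram_stem",
    "max_grain_size", "y_frac_pod", "x_temp_grain_fill",
    "y_co2_te_modifier", "x_sw_demand_ratio",
    "tt_emerg_limit", "min_tpla", "grain_water_content", "leaf_no_at_emerg")
}
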