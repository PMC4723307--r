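#' Build a Morris one-at-a-time screening design
#'
#' Generates `r` randomised OAT trajectories on an `n_levels` grid over `g`
#' independent factors, following the classic randomised-orientation scheme:
#' a random base point on the lower `n_levels / 2` grid levels, a random move
#' direction per factor and a random factor order, with step
#' `delta = n_levels / (2 * (n_levels - 1))` (0.6 for six levels). When
#' `n_candidates > r`, a space-filling subset is chosen greedily by maximising
#' the sum of pairwise inter-trajectory distances (the distance between two
#' trajectories being the sum of Euclidean distances between all row pairs).
#'
#' @param g Number of independent factors.
#' @param n_levels Even number of grid levels (default 6).
#' @param r Number of trajectories kept (default 100).
#' @param n_candidates Size of the random candidate pool (default `r`, i.e.
#'   no selection).
#' @param seed Integer seed; the design is reproducible for a fixed seed.
#' @param factor_names Optional factor names (length `g`).
#'
#' @return Object of class `morris_design`: list with `rows` (numeric matrix,
#'   r\*(g+1) rows), `trajectory`, `step_index`, `moved_factor` (index,
#'   `NA` on each trajectory's first row), `signed_step`, `delta`, `g`,
#'   `n_levels`, `r`.
#' @export
morris_design <- function(g, n_levels = 6L, r = 100L, n_candidates = r,
                          seed = 1L, factor_names = NULL) {
  stopifnot(g >= 1L, n_levels >= 2L, n_levels %% 2L == 0L, r >= 1L,
            n_candidates >= r)
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(g))
  stopifnot(length(factor_names) == g)
  delta <- n_levels / (2 * (n_levels - 1))
  base_levels <- (seq_len(n_levels / 2) - 1) / (n_levels - 1)

  set.seed(seed)
  cand <- vector("list", n_candidates)
  for (k in seq_len(n_candidates)) {
    xstar <- sample(base_levels, g, replace = TRUE)
    dir <- sample(c(-1, 1), g, replace = TRUE)
    ord <- sample.int(g)
    rows <- matrix(0, nrow = g + 1L, ncol = g)
    start <- xstar + ifelse(dir < 0, delta, 0)
    rows[1L, ] <- start
    moved <- integer(g)
    step <- numeric(g)
    cur <- start
    for (s in seq_len(g)) {
      f <- ord[s]
      cur[f] <- cur[f] + dir[f] * delta
      rows[s + 1L, ] <- cur
      moved[s] <- f
      step[s] <- dir[f] * delta
    }
    cand[[k]] <- list(rows = rows, moved = moved, step = step)
  }

  keep <- if (n_candidates > r) {
    .select_trajectories(cand, r)
  } else {
    seq_len(r)
  }
  cand <- cand[keep]

  rows <- do.call(rbind, lapply(cand, `[[`, "rows"))
  colnames(rows) <- factor_names
  structure(list(
    rows = rows,
    trajectory = rep(seq_len(r), each = g + 1L),
    step_index = rep(seq_len(g + 1L), times = r),
    moved_factor = as.integer(unlist(lapply(cand, function(tr) c(NA_integer_, tr$moved)))),
    signed_step = unlist(lapply(cand, function(tr) c(NA_real_, tr$step))),
    delta = delta, g = g, n_levels = n_levels, r = r,
    factor_names = factor_names, seed = seed
  ), class = "morris_design")
}

# Pairwise trajectory distance matrix, then greedy selection maximising the
# sum of pairwise distances among the kept set (start from the farthest pair,
# then repeatedly add the trajectory with the largest summed distance to the
# current set; ties resolved to the lowest index).
.trajectory_distances <- function(cand) {
  m <- length(cand)
  all_rows <- do.call(rbind, lapply(cand, `[[`, "rows"))
  npts <- nrow(cand[[1L]]$rows)
  sq <- rowSums(all_rows^2)
  D <- matrix(0, m, m)
  for (l in seq_len(m - 1L)) {
    ridx <- ((l - 1L) * npts + 1L):(l * npts)
    rest <- (l * npts + 1L):nrow(all_rows)
    cross <- outer(sq[ridx], sq[rest], "+") - 2 * tcrossprod(all_rows[ridx, , drop = FALSE],
                                                             all_rows[rest, , drop = FALSE])
    cross[cross < 0] <- 0
    cross <- sqrt(cross)
    # fold the npts x (remaining rows) block into per-trajectory sums
    grp <- rep(seq_len(m - l), each = npts)
    sums <- tapply(colSums(cross), grp, sum)
    D[l, (l + 1L):m] <- sums
    D[(l + 1L):m, l] <- sums
  }
  D
}

.select_trajectories <- function(cand, r) {
  D <- .trajectory_distances(cand)
  m <- nrow(D)
  if (r == m) return(seq_len(m))
  best <- which(D == max(D), arr.ind = TRUE)[1L, ]
  sel <- sort(as.integer(best))
  while (length(sel) < r) {
    remaining <- setdiff(seq_len(m), sel)
    gain <- colSums(D[sel, remaining, drop = FALSE])
    sel <- c(sel, remaining[which.max(gain)])
  }
  sort(sel)
}

#' @export
print.morris_design <- function(x, ...) {
  cat("<morris_design> g = ", x$g, ", levels = ", x$n_levels,
      ", r = ", x$r, ", rows = ", nrow(x$rows),
      ", delta = ", format(x$delta), "\n", sep = "")
  invisible(x)
}

#' Export / import a Morris design as a plain table
#'
#' The tabular layout (trajectory id, step index, moved factor, signed step,
#' then one column per factor) allows farming simulations out and re-importing
#' outputs against the same row order.
#'
#' @param design A [morris_design()].
#' @param path File path (CSV).
#' @export
write_design <- function(design, path) {
  d <- data.frame(trajectory = design$trajectory,
                  step_index = design$step_index,
                  moved_factor = design$moved_factor,
                  signed_step = design$signed_step)
  d <- cbind(d, as.data.frame(design$rows))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- setdiff(names(d), c("trajectory", "step_index", "moved_factor", "signed_step"))
  rows <- as.matrix(d[fcols])
  g <- length(fcols)
  r <- max(d$trajectory)
  lev <- sort(unique(round(as.vector(rows), 12)))
  n_levels <- length(lev)
  structure(list(rows = rows, trajectory = d$trajectory, step_index = d$step_index,
                 moved_factor = d$moved_factor, signed_step = d$signed_step,
                 delta = n_levels / (2 * (n_levels - 1)), g = g,
                 n_levels = n_levels, r = r, factor_names = fcols, seed = NA_integer_),
            class = "morris_design")
}

#' Elementary effects from design rows and model outputs
#'
#' For each within-trajectory transition that moves factor `i` by a signed
#' step `s`, the elementary effect is `(y_after - y_before) / s`, i.e. the
#' output change per full normalised factor range. Missing outputs propagate
#' as missing effects with a warning.
#'
#' @param design A [morris_design()].
#' @param y Numeric vector of model outputs, one per design row.
#' @return Object of class `elementary_effects`: matrix `g x r` plus metadata.
#' @export
elementary_effects <- function(design, y) {
  stopifnot(inherits(design, "morris_design"))
  if (length(y) != nrow(design$rows)) {
    stop("y must have one value per design row (", nrow(design$rows), ")")
  }
  if (anyNA(y)) warning("missing model outputs: the affected elementary effects are NA")
  ee <- matrix(NA_real_, nrow = design$g, ncol = design$r,
               dimnames = list(design$factor_names, NULL))
  idx <- which(!is.na(design$moved_factor))
  eff <- (y[idx] - y[idx - 1L]) / design$signed_step[idx]
  ee[cbind(design$moved_factor[idx], design$trajectory[idx])] <- eff
  structure(list(effects = ee, g = design$g, r = design$r), class = "elementary_effects")
}

#' Morris sensitivity indices
#'
#' `mu_star` is the mean of the absolute elementary effects of a factor (its
#' overall main influence); `sigma` is the sample standard deviation of the
#' signed effects (non-linearity and/or interactions). Both are computed over
#' the available (non-missing) effects, with the count reported.
#'
#' @param ee An [elementary_effects()] object, or a numeric `g x r` matrix.
#' @param standardized Flag recorded in the result: whether outputs were
#'   z-scored within environment before the effects were computed.
#' @return `data.frame` with columns `factor`, `mu_star`, `sigma`, `n_effects`
#'   and attribute `standardized`.
#' @export
morris_indices <- function(ee, standardized = FALSE) {
  m <- if (inherits(ee, "elementary_effects")) ee$effects else as.matrix(ee)
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  n_eff <- rowSums(!is.na(m))
  if (any(n_eff < 1L)) stop("factor with no available elementary effects")
  out <- data.frame(
    factor = rownames(m),
    mu_star = rowMeans(abs(m), na.rm = TRUE),
    sigma = apply(m, 1L, stats::sd, na.rm = TRUE),
    n_effects = n_eff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$sigma[n_eff < 2L] <- NA_real_
  attr(out, "standardized") <- standardized
  out
}

#' Z-score model outputs within each environment
#'
#' Standardises a genotype-by-environment output matrix to zero mean and unit
#' sample standard deviation within each environment (column), so sensitivity
#' indices are comparable across output variables and growing conditions.
#' Degenerate environments (zero variance) standardise to all zeros.
#'
#' @param outputs Numeric matrix, genotypes in rows, environments in columns.
#' @return Matrix of the same shape.
#' @export
standardize_by_environment <- function(outputs) {
  m <- as.matrix(outputs)
  if (nrow(m) < 2L) stop("need at least two genotypes per environment")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  z
}
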