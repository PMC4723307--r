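#' Classify screened factors by mean yield impact
#'
#' Partitions factors into the null / low / impactful groups: *null* factors
#' have a zero main effect in every environment; *low* factors have a mean
#' main effect (over environments) at or below the threshold (default
#' 0.02 t/ha, boundary inclusive); *impactful* factors exceed it.
#'
#' @param impacts `data.frame` with columns `factor`, `environment`,
#'   `mu_star` (raw, t/ha for yield), complete over the environment set.
#' @param threshold Impact threshold in output units (default 0.02 t/ha).
#' @return `data.frame` with `factor`, `mean_mu_star`, `max_mu_star`, `group`
#'   (factor with levels null/low/impactful).
#' @export
classify_traits <- function(impacts, threshold = 0.02) {
  stopifnot(all(c("factor", "environment", "mu_star") %in% names(impacts)))
  if (any(impacts$mu_star < 0, na.rm = TRUE)) stop("mu_star must be non-negative")
  mean_mu <- tapply(impacts$mu_star, impacts$factor, mean)
  max_mu <- tapply(impacts$mu_star, impacts$factor, max)
  grp <- ifelse(max_mu == 0, "null",
                ifelse(mean_mu <= threshold, "low", "impactful"))
  out <- data.frame(factor = names(mean_mu),
                    mean_mu_star = as.numeric(mean_mu),
                    max_mu_star = as.numeric(max_mu),
                    group = factor(grp, levels = c("null", "low", "impactful")),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean_mu_star), ]
}

#' Ward clustering of impactful traits against the integrated outputs
#'
#' Hierarchically clusters the trait-by-output impact matrix (traits in rows)
#' with Ward linkage on Euclidean distance, after standardising each output
#' column so impacts are comparable across integrated traits.
#'
#' @param mat Numeric matrix, impactful traits x output variables.
#' @param k Number of flat groups to cut (default 3).
#' @param standardize Z-score each column first (default `TRUE`).
#' @return List with `hclust` (the full merge tree), `groups` (named cut at
#'   `k`) and `matrix` (the standardised matrix used).
#' @export
cluster_impactful <- function(mat, k = 3L, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds the number of traits")
  m <- if (standardize) {
    sdv <- apply(mat, 2L, stats::sd)
    scale(mat, scale = ifelse(sdv > 0, sdv, 1))
  } else mat
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  list(hclust = hc, groups = stats::cutree(hc, k = k), matrix = m)
}

#' Export a trait dendrogram as Newick text
#'
#' @param hc An `hclust` object (e.g. from [cluster_impactful()]).
#' @param path Optional file path; if omitted the Newick string is returned.
#' @return Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Variance decomposition of trait impacts across management factors
#'
#' Fits the additive fixed-effects model (no interactions)
#' `impact ~ site + sowing + co2 + nitrogen` on a balanced environment grid
#' and reports each factor's share of the total sum of squares (eta squared);
#' climate (year) variability and factor interactions are pooled in the
#' residual share. On a balanced grid the sequential sums of squares equal
#' the marginal ones, so term order is irrelevant.
#'
#' @param impacts Numeric vector of a trait's main effects, one per
#'   environment.
#' @param factors `data.frame` with columns `site`, `sowing`, `co2`,
#'   `nitrogen` (coerced to factors), aligned with `impacts`. Factors with a
#'   single level contribute a zero share.
#' @return List of class `variance_decomposition` with `eta2` (named shares
#'   for site, sowing, co2, nitrogen), `residual`, and `degenerate` (`TRUE`
#'   when the impact vector is constant, in which case all shares are zero).
#' @export
eta_squared <- function(impacts, factors) {
  need <- c("site", "sowing", "co2", "nitrogen")
  stopifnot(all(need %in% names(factors)), length(impacts) == nrow(factors))
  f <- lapply(factors[need], function(x) factor(x))
  combos <- table(interaction(f, drop = FALSE))
  if (length(unique(as.integer(combos))) != 1L) {
    stop("unbalanced environment grid: every factor-level combination must occur equally often")
  }
  tss <- sum((impacts - mean(impacts))^2)
  eta <- stats::setNames(numeric(4), need)
  if (tss <= .Machine$double.eps * length(impacts)) {
    out <- list(eta2 = eta, residual = 0, degenerate = TRUE)
    class(out) <- "variance_decomposition"
    return(out)
  }
  use <- need[vapply(f, nlevels, integer(1)) > 1L]
  d <- data.frame(y = impacts, f[use])
  fit <- stats::aov(stats::reformulate(use, "y"), data = d)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- attr(stats::terms(fit), "term.labels")
  eta[terms] <- ss[seq_along(terms)] / tss
  out <- list(eta2 = eta, residual = 1 - sum(eta), degenerate = FALSE)
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition>",
      if (x$degenerate) "(constant impacts)", "\n")
  shares <- c(x$eta2, residual = x$residual)
  print(round(shares, 4))
  invisible(x)
}

#' Classify a drought environment type from the water-stress trajectory
#'
#' Rule-based typing of the seasonal water-stress trajectory (0 = no stress,
#' 1 = extreme stress) into four drought environment types, from mean stress
#' in the vegetative (sowing to flowering) and grain-filling (flowering to
#' maturity) windows: ET1 "low" (both below the mild threshold), ET4 "severe"
#' (both at or above the severe threshold), ET3 "mild-early" (stress
#' concentrated before flowering and relieved later), ET2 "mild-late"
#' (stress mainly during grain filling).
#'
#' @param stress Numeric vector of daily stress values covering sowing to
#'   maturity.
#' @param flowering_das Day (index into `stress`) of flowering.
#' @param thresholds Named vector with `mild` and `severe` mean-stress
#'   thresholds (defaults 0.2 and 0.5).
#' @return Character scalar: `"ET1"`, `"ET2"`, `"ET3"` or `"ET4"`.
#' @export
drought_type <- function(stress, flowering_das,
                         thresholds = c(mild = 0.2, severe = 0.5)) {
  n <- length(stress)
  if (anyNA(stress) || is.na(flowering_das) || flowering_das < 1 || flowering_das >= n) {
    stop("incomplete stress trajectory")
  }
  veg <- mean(stress[seq_len(flowering_das)])
  gf <- mean(stress[(flowering_das + 1L):n])
  if (veg < thresholds["mild"] && gf < thresholds["mild"]) return("ET1")
  if (veg >= thresholds["severe"] && gf >= thresholds["severe"]) return("ET4")
  if (veg >= gf) "ET3" else "ET2"
}

#' Per-type regression of standardized trait impact on a stress index
#'
#' Ordinary least squares of the standardized main effect against the
#' seasonal stress index, fitted separately within each drought environment
#' type.
#'
#' @param impact Standardized mu-star values, one per environment.
#' @param stress Seasonal stress index per environment.
#' @param type Drought environment type label per environment.
#' @return `data.frame` with `type`, `slope`, `intercept`, `r` (Pearson) and
#'   `n` per type.
#' @export
stress_regression <- function(impact, stress, type) {
  stopifnot(length(impact) == length(stress), length(stress) == length(type))
  out <- lapply(split(seq_along(type), type), function(idx) {
    if (length(idx) < 3L) stop("need at least 3 environments per type")
    s <- stress[idx]
    if (stats::sd(s) == 0) stop("constant stress index within a type")
    fit <- stats::lm(impact[idx] ~ s)
    data.frame(type = type[idx][1L],
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = stats::cor(s, impact[idx]),
               n = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
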