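test_that("designs have r*(g+1) rows on the 6-level grid with delta = 0.6", {
  d <- morris_design(g = 5, n_levels = 6, r = 4, seed = 2)
  expect_equal(nrow(d$rows), 4 * 6)
  expect_equal(d$delta, 0.6)
  grid <- seq(0, 1, by = 0.2)
  off_grid <- apply(abs(outer(as.vector(d$rows), grid, "-")), 1, min)
  expect_true(all(off_grid < 1e-12))
})

test_that("every trajectory is one-at-a-time: one factor per step, each factor once", {
  for (seed in 1:5) {
    d <- morris_design(g = 7, n_levels = 6, r = 6, seed = seed)
    for (t in seq_len(d$r)) {
      idx <- which(d$trajectory == t)
      moved <- integer(0)
      for (k in 2:length(idx)) {
        diffs <- which(abs(d$rows[idx[k], ] - d$rows[idx[k - 1], ]) > 1e-12)
        expect_length(diffs, 1L)
        expect_equal(unname(abs(d$rows[idx[k], diffs] - d$rows[idx[k - 1], diffs])),
                     d$delta)
        moved <- c(moved, diffs)
      }
      expect_setequal(moved, seq_len(d$g))
    }
  }
})

test_that("a single two-factor trajectory has the documented OAT structure", {
  d <- morris_design(g = 2, n_levels = 6, r = 1, seed = 3)
  expect_equal(nrow(d$rows), 3)
  m1 <- which(abs(d$rows[2, ] - d$rows[1, ]) > 1e-12)
  m2 <- which(abs(d$rows[3, ] - d$rows[2, ]) > 1e-12)
  expect_length(m1, 1)
  expect_length(m2, 1)
  expect_false(m1 == m2)
})

test_that("space-filling selection picks the most dispersed candidate pair", {
  # same seed => the candidate pool of the unselected design is identical,
  # so the selected pair can be checked against exhaustive enumeration
  pool <- morris_design(g = 2, n_levels = 6, r = 4, n_candidates = 4, seed = 9)
  sel <- morris_design(g = 2, n_levels = 6, r = 2, n_candidates = 4, seed = 9)
  traj_rows <- function(d, t) d$rows[d$trajectory == t, , drop = FALSE]
  pairs <- utils::combn(4, 2)
  dists <- apply(pairs, 2, function(p)
    pairwise_traj_dist(traj_rows(pool, p[1]), traj_rows(pool, p[2])))
  best <- pairs[, which.max(dists)]
  got <- vapply(1:2, function(t) {
    rows <- traj_rows(sel, t)
    which(vapply(1:4, function(c0)
      isTRUE(all.equal(rows, traj_rows(pool, c0), check.attributes = FALSE)),
      logical(1)))
  }, integer(1))
  expect_setequal(got, best)
})

test_that("designs are reproducible for a fixed seed and exportable as a table", {
  d1 <- morris_design(g = 4, r = 3, seed = 11)
  d2 <- morris_design(g = 4, r = 3, seed = 11)
  expect_identical(d1$rows, d2$rows)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d1, path)
  back <- read_design(path)
  expect_equal(back$rows, d1$rows, ignore_attr = TRUE)
  expect_equal(back$moved_factor, d1$moved_factor)
  expect_equal(back$signed_step, d1$signed_step)
})

test_that("elementary effects recover linear coefficients exactly", {
  d <- morris_design(g = 2, r = 10, seed = 1)
  y <- 2 * d$rows[, 1] + 3 * d$rows[, 2]
  ee <- elementary_effects(d, y)
  expect_equal(unname(ee$effects[1, ]), rep(2, 10))
  expect_equal(unname(ee$effects[2, ]), rep(3, 10))

  idx <- morris_indices(ee)
  expect_equal(idx$mu_star, c(2, 3))
  expect_equal(idx$sigma, c(0, 0))

  y0 <- rep(5, nrow(d$rows))
  expect_equal(unname(morris_indices(elementary_effects(d, y0))$mu_star), c(0, 0))
})

test_that("interaction effects for y = x1*x2 equal the co-factor's current value", {
  d <- morris_design(g = 2, r = 8, seed = 0)
  y <- d$rows[, 1] * d$rows[, 2]
  ee <- elementary_effects(d, y)
  for (t in seq_len(d$r)) {
    idx <- which(d$trajectory == t)
    for (k in 2:length(idx)) {
      f <- d$moved_factor[idx[k]]
      other <- d$rows[idx[k], -f]  # co-factor unchanged across the transition
      expect_equal(unname(ee$effects[f, t]), unname(other))
    }
  }
  idx <- morris_indices(ee)
  expect_gt(idx$sigma[1], 0)
  expect_gt(idx$sigma[2], 0)
})

test_that("missing outputs propagate as missing effects with a warning", {
  d <- morris_design(g = 3, r = 4, seed = 5)
  y <- as.numeric(d$rows %*% c(1, 1, 1))
  y[2] <- NA
  expect_warning(ee <- elementary_effects(d, y), "missing")
  expect_true(anyNA(ee$effects))
  idx <- morris_indices(ee)
  expect_true(all(is.finite(idx$mu_star)))
  expect_true(any(idx$n_effects < d$r))
})

test_that("mu-star and sigma match their textbook definitions", {
  ee <- matrix(c(2, 2, 2, -1, 1, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("p", "q"), NULL))
  idx <- morris_indices(ee)
  expect_equal(idx$mu_star, c(2, 2 / 3))
  expect_equal(idx$sigma, c(0, 1))

  expect_equal(morris_indices(matrix(c(-1, 1), 1))$mu_star, 1)
  expect_equal(morris_indices(matrix(c(-1, 1), 1))$sigma, sqrt(2))

  set.seed(8)
  v <- stats::rnorm(50)
  idx <- morris_indices(matrix(v, 1))
  expect_equal(idx$mu_star, mean(abs(v)))
  expect_equal(idx$sigma, stats::sd(v))
})

test_that("engine indices agree with brute-force enumeration to 1e-10", {
  fns <- list(
    function(m) 2 * m[, 1] + 3 * m[, 2] - m[, 3],
    function(m) m[, 1] * m[, 2] + m[, 3]^2,
    function(m) sin(m[, 1]) + exp(m[, 2] * m[, 3])
  )
  for (fn in fns) {
    d <- morris_design(g = 3, r = 12, seed = 21)
    y <- fn(d$rows)
    got <- morris_indices(elementary_effects(d, y))
    ref <- brute_force_indices(d, y)
    expect_equal(got$mu_star, ref$mu_star, tolerance = 1e-10)
    expect_equal(got$sigma, ref$sigma, tolerance = 1e-10)
  }
})

test_that("sigma flags non-linearity: zero for linear maps, positive for x1*x2", {
  d <- morris_design(g = 3, r = 10, seed = 13)
  lin <- morris_indices(elementary_effects(d, as.numeric(d$rows %*% c(4, -2, 0.5))))
  expect_true(all(lin$sigma / pmax(lin$mu_star, 1e-300) <= 1e-10))
  inter <- morris_indices(elementary_effects(d, d$rows[, 1] * d$rows[, 2]))
  expect_gt(inter$sigma[1], 0)
  expect_gt(inter$sigma[2], 0)
})

test_that("standardization is per environment with the degenerate rule", {
  m <- cbind(e1 = c(1, 2, 3), e2 = c(5, 5, 5))
  z <- standardize_by_environment(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_equal(unname(z[, 2]), c(0, 0, 0))

  set.seed(2)
  m2 <- matrix(stats::rnorm(40, mean = c(2, 50)), ncol = 2, byrow = TRUE)
  z2 <- standardize_by_environment(m2)
  expect_equal(colMeans(z2), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z2, 2, stats::sd), c(1, 1), tolerance = 1e-12)

  expect_error(standardize_by_environment(m[1, , drop = FALSE]), "two genotypes")
})
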