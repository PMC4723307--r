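make_impacts <- function(per_factor) {
  do.call(rbind, lapply(names(per_factor), function(f) {
    data.frame(factor = f, environment = paste0("e", seq_along(per_factor[[f]])),
               mu_star = per_factor[[f]], stringsAsFactors = FALSE)
  }))
}

test_that("trait classification partitions factors with an inclusive boundary", {
  imp <- make_impacts(list(
    zero = c(0, 0, 0),
    boundary = c(0.01, 0.02, 0.03),   # mean exactly 0.02 -> low
    strong = c(0.04, 0.05, 0.06),
    faint = c(0, 0, 0.003)
  ))
  cls <- classify_traits(imp)
  got <- stats::setNames(as.character(cls$group), cls$factor)
  expect_equal(got[["zero"]], "null")
  expect_equal(got[["boundary"]], "low")
  expect_equal(got[["strong"]], "impactful")
  expect_equal(got[["faint"]], "low")  # nonzero somewhere, so not null
  # partition: every factor in exactly one group
  expect_equal(sort(cls$factor), sort(unique(imp$factor)))
  expect_false(anyNA(cls$group))
  expect_error(classify_traits(transform(imp, mu_star = -mu_star)), "non-negative")
})

test_that("Ward clustering merges identical traits first and heights increase", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 0, 2),
             d = c(8.5, 1.2, 0.3, 2.2))
  cl <- cluster_impactful(m, k = 2, standardize = FALSE)
  expect_equal(cl$hclust$height[1], 0)
  first <- sort(-cl$hclust$merge[1, ])
  expect_equal(rownames(m)[first], c("a", "b"))
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  expect_equal(cl$groups[["a"]], cl$groups[["b"]])
  expect_equal(cl$groups[["c"]], cl$groups[["d"]])
})

test_that("three well-separated blobs are recovered exactly at k = 3", {
  set.seed(30)
  centers <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 50))
  m <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(stats::rnorm(5 * 3, sd = 0.3), 5, 3), 2, centers[b, ], "+")))
  rownames(m) <- paste0("t", 1:15)
  cl <- cluster_impactful(m, k = 3, standardize = FALSE)
  truth <- rep(1:3, each = 5)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$groups, truth))), 3L)
  expect_error(cluster_impactful(m, k = 20), "exceeds")
})

test_that("dendrograms export as parseable Newick text", {
  m <- matrix(stats::rnorm(24), 6, 4,
              dimnames = list(paste0("tr", 1:6), NULL))
  cl <- cluster_impactful(m, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(cl$hclust, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("eta squared recovers constructed variance shares to 1e-6", {
  grid <- expand.grid(site = paste0("S", 1:4), sowing = paste0("w", 1:3),
                      co2 = c("380", "555"), nitrogen = paste0("n", 1:3),
                      rep = 1:2, stringsAsFactors = FALSE)
  target <- c(site = 0.4, sowing = 0.3, co2 = 0.2, nitrogen = 0.1)
  effects <- list(site = c(-1, -0.5, 0.5, 1), sowing = c(-1, 0, 1),
                  co2 = c(-1, 1), nitrogen = c(-1, 0.2, 0.8))
  y <- rep(0, nrow(grid))
  for (f in names(target)) {
    lev <- effects[[f]][as.integer(factor(grid[[f]]))]
    lev <- lev - mean(lev)
    ss <- sum(lev^2)
    y <- y + lev * sqrt(target[[f]] / ss)  # scale to the wanted sum of squares
  }
  vd <- eta_squared(y, grid)
  expect_equal(unname(vd$eta2), unname(target), tolerance = 1e-6)
  expect_equal(sum(vd$eta2) + vd$residual, 1, tolerance = 1e-9)
  expect_equal(vd$residual, 0, tolerance = 1e-6)
})

test_that("eta squared handles pure, constant and noisy impact patterns", {
  grid <- expand.grid(site = c("A", "B"), sowing = c("s1", "s2"),
                      co2 = c("380", "555"), nitrogen = c("lo", "hi"),
                      stringsAsFactors = FALSE)
  # pure site effect
  vd <- eta_squared(ifelse(grid$site == "A", 1, 3), grid)
  expect_equal(unname(vd$eta2["site"]), 1, tolerance = 1e-12)
  expect_equal(unname(vd$eta2[c("sowing", "co2", "nitrogen")]), c(0, 0, 0),
               tolerance = 1e-12)
  # constant: degenerate, all zero
  vd0 <- eta_squared(rep(2, nrow(grid)), grid)
  expect_true(vd0$degenerate)
  expect_equal(sum(vd0$eta2) + vd0$residual, 0)
  # additive + noise: shares still sum to one with the residual
  set.seed(3)
  yn <- ifelse(grid$site == "A", 1, 2) + stats::rnorm(nrow(grid), 0, 0.5)
  vdn <- eta_squared(yn, grid)
  expect_equal(sum(vdn$eta2) + vdn$residual, 1, tolerance = 1e-9)
  expect_true(all(vdn$eta2 >= 0 & vdn$eta2 <= 1))
})

test_that("term order is irrelevant on a balanced grid", {
  grid <- expand.grid(site = c("A", "B", "C"), sowing = c("s1", "s2"),
                      co2 = c("380", "555"), nitrogen = c("lo", "hi"),
                      stringsAsFactors = FALSE)
  set.seed(9)
  y <- stats::rnorm(nrow(grid)) + as.integer(factor(grid$site))
  vd1 <- eta_squared(y, grid)
  vd2 <- eta_squared(y, grid[, c("nitrogen", "co2", "sowing", "site")])
  expect_equal(vd1$eta2, vd2$eta2, tolerance = 1e-12)
})

test_that("unbalanced grids are rejected", {
  grid <- expand.grid(site = c("A", "B"), sowing = c("s1", "s2"),
                      co2 = "380", nitrogen = c("lo", "hi"),
                      stringsAsFactors = FALSE)
  grid <- grid[-1, ]
  expect_error(eta_squared(stats::rnorm(nrow(grid)), grid), "unbalanced")
})

test_that("drought typing follows the window rules", {
  expect_equal(drought_type(rep(0, 120), 70), "ET1")
  expect_equal(drought_type(rep(0.8, 120), 70), "ET4")
  # stress rising only after flowering, crossing the mild threshold
  late <- c(rep(0.05, 70), seq(0.1, 0.6, length.out = 50))
  expect_equal(drought_type(late, 70), "ET2")
  # early severe stress relieved during grain filling
  early <- c(rep(0.6, 70), rep(0.15, 50))
  expect_equal(drought_type(early, 70), "ET3")
  expect_error(drought_type(c(0.1, NA, 0.3), 2), "incomplete")
  expect_error(drought_type(rep(0.1, 10), 10), "incomplete")
})

test_that("stress regressions match closed-form least squares", {
  # exact line
  s <- seq(0, 1, length.out = 10)
  fit <- stress_regression(2 + 3 * s, s, rep("ET1", 10))
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  # pure noise: negligible correlation at n = 1000
  set.seed(12)
  sn <- stats::runif(1000)
  yn <- stats::rnorm(1000)
  expect_lt(abs(stress_regression(yn, sn, rep("ET2", 1000))$r), 0.1)

  # small fixture against the normal equations
  set.seed(5)
  s2 <- stats::runif(8)
  y2 <- 1 + 0.5 * s2 + stats::rnorm(8, 0, 0.1)
  fit2 <- stress_regression(y2, s2, rep("ET3", 8))
  beta <- stats::cov(s2, y2) / stats::var(s2)
  expect_equal(fit2$slope, beta, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(y2) - beta * mean(s2), tolerance = 1e-12)

  expect_error(stress_regression(1:2, c(0.1, 0.2), c("a", "a")), "at least 3")
  expect_error(stress_regression(1:3, rep(0.2, 3), rep("a", 3)), "constant")
})
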