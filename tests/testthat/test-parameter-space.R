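test_that("range rule gives symmetric +/-20% multiplicative ranges when unbounded", {
  r <- apply_range_rule(1.5)
  expect_equal(c(r$lower, r$upper), c(1.2, 1.8))
  expect_equal(r$one_sided, "none")

  r <- apply_range_rule(555)
  expect_equal(c(r$lower, r$upper), c(444, 666))

  # multiplicative property over many magnitudes
  for (nom in c(1e-4, 0.3, 7, 555, 1e5)) {
    r <- apply_range_rule(nom)
    expect_equal(r$upper / nom, 1.2)
    expect_equal(r$lower / nom, 0.8)
  }
})

test_that("range rule places the full 40% width on the feasible side at hard bounds", {
  r <- apply_range_rule(1, hard_upper = 1)
  expect_equal(c(r$lower, r$upper), c(0.6, 1.0))
  expect_equal(r$one_sided, "below")

  r <- apply_range_rule(0.1, hard_lower = 0.1)
  expect_equal(c(r$lower, r$upper), c(0.1, 0.14))
  expect_equal(r$one_sided, "above")

  # respects bounds after shifting
  r <- apply_range_rule(0.9, hard_lower = 0.8, hard_upper = 1)
  expect_gte(r$lower, 0.8)
  expect_lte(r$upper, 1)
})

test_that("zero nominal yields a fixed, zero-width parameter instead of dividing", {
  r <- apply_range_rule(0)
  expect_true(r$fixed)
  expect_equal(r$lower, r$upper)
  reg <- parameter_registry(list(parameter_def("z", "scalar", 0),
                                 parameter_def("a", "scalar", 1)))
  expect_equal(count_factors(reg), 1L)
  expect_equal(factor_names(reg), "a")
})

test_that("curve scaling interpolates 0.8-1.2 and preserves the nominal at midpoint", {
  p <- parameter_def("cv", "curve", x = c(1, 2), y = c(0.1, 0.3))
  expect_equal(scale_curve(p, 1)$y, c(0.12, 0.36))
  expect_equal(scale_curve(p, 0.5)$y, c(0.1, 0.3))
  expect_equal(scale_curve(p, 0)$y, c(0.08, 0.24))
  expect_equal(scale_curve(p, 0.5)$x, c(1, 2))

  py <- parameter_def("pt", "curve", x = c(1, 2, 3), y = c(0, 1, 1),
                      scaling_mode = "point", point_axis = "y", point_index = 3L)
  expect_equal(scale_curve(py, 0)$y, c(0, 1, 0.8))
  expect_equal(scale_curve(py, 0.5)$y, c(0, 1, 1))
})

test_that("x-point scaling that breaks monotonicity fails loudly, naming the parameter", {
  px <- parameter_def("tight", "curve", x = c(1, 1.1, 3), y = c(0, 1, 1),
                      scaling_mode = "point", point_axis = "x", point_index = 2L)
  expect_error(scale_curve(px, 0), "tight")   # 1.1 * 0.8 = 0.88 < 1
  expect_silent(scale_curve(px, 0.5))
})

test_that("materialized genotypes hit nominals at 0.5 and range endpoints at 0/1", {
  reg <- tiny_registry()
  fn <- factor_names(reg)
  g_mid <- materialize_genotype(reg, rep(0.5, length(fn)))
  expect_equal(g_mid$values$a, 10)
  expect_equal(g_mid$values$b, 2)
  expect_equal(g_mid$values$d$y, c(0.5, 1.5))

  # all-0 and all-1 match per-parameter range-rule endpoints computed
  # independently, and grouped members move with their group factor
  g_lo <- materialize_genotype(reg, rep(0, length(fn)))
  g_hi <- materialize_genotype(reg, rep(1, length(fn)))
  for (p in reg$params) {
    if (p$kind != "scalar") next
    r <- apply_range_rule(p$nominal, p$hard_lower, p$hard_upper)
    expect_equal(g_lo$values[[p$name]], r$lower)
    expect_equal(g_hi$values[[p$name]], r$upper)
  }

  # the group factor drives both members to their own endpoints
  lv <- stats::setNames(rep(0.5, length(fn)), fn)
  lv["g1"] <- 1
  g <- materialize_genotype(reg, lv)
  expect_equal(g$values$c1, 1.2)
  expect_equal(g$values$c2, 4.8)
})

test_that("normalised levels round-trip through materialisation", {
  reg <- tiny_registry()
  fn <- factor_names(reg)
  set.seed(4)
  for (i in 1:20) {
    lv <- stats::setNames(sample(seq(0, 1, by = 0.2), length(fn), TRUE), fn)
    g <- materialize_genotype(reg, lv)
    for (p in reg$params) {
      if (p$kind != "scalar") next
      r <- apply_range_rule(p$nominal, p$hard_lower, p$hard_upper)
      id <- if (is.na(p$group)) p$name else p$group
      back <- (g$values[[p$name]] - r$lower) / (r$upper - r$lower)
      expect_equal(back, unname(lv[id]), tolerance = 1e-12)
    }
  }
})

test_that("materialisation validates factor names and level bounds", {
  reg <- tiny_registry()
  expect_error(materialize_genotype(reg, c(nope = 0.5)), "unknown factor")
  expect_error(materialize_genotype(reg, rep(1.5, length(factor_names(reg)))),
               "\\[0, 1\\]")
  expect_error(materialize_genotype(reg, c(0.5, 0.5)), "expected")
})

test_that("factor counting collapses groups and conserves the bookkeeping", {
  reg5 <- parameter_registry(lapply(letters[1:5], function(n)
    parameter_def(n, "scalar", 1)))
  expect_equal(count_factors(reg5), 5L)

  reg3 <- parameter_registry(list(
    parameter_def("a", "scalar", 1),
    parameter_def("b", "scalar", 1),
    parameter_def("g1a", "scalar", 1, group = "g1"),
    parameter_def("g1b", "scalar", 1, group = "g1")
  ))
  expect_equal(count_factors(reg3), 3L)

  # conservation: factors + grouped members - groups = parameters
  for (reg in list(reg5, reg3, tiny_registry(), wheat_registry())) {
    expect_equal(count_factors(reg) + sum(lengths(reg$groups)) - length(reg$groups),
                 length(reg$params))
  }
})

test_that("the packaged registry matches the screened inventory", {
  reg <- wheat_registry()
  kinds <- vapply(reg$params, function(p) p$kind, character(1))
  expect_length(reg$params, 103L)
  expect_equal(sum(kinds == "scalar"), 62L)
  expect_equal(sum(kinds == "curve"), 41L)
  expect_length(reg$groups, 7L)
  expect_equal(sum(lengths(reg$groups)), 20L)
  expect_equal(count_factors(reg), 90L)
  # printed anchors of the reference cultivar
  expect_equal(reg$params$vern_sens$nominal, 1.5)
  expect_equal(reg$params$tt_end_of_juvenile$nominal, 555)
  expect_equal(reg$params$photop_sens$nominal, 3.0)
})

test_that("registries survive a CSV round trip", {
  reg <- tiny_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(factor_names(back), factor_names(reg))
  expect_equal(back$params$a$nominal, 10)
  expect_equal(back$params$d$y, c(0.5, 1.5))
  expect_equal(back$groups, reg$groups)
})

test_that("subsetting a registry keeps groups only when two members remain", {
  reg <- tiny_registry()
  sub <- subset_registry(reg, c("a", "c1", "c2"))
  expect_equal(count_factors(sub), 2L)        # a + group g1
  solo <- subset_registry(reg, c("a", "c1"))
  expect_equal(count_factors(solo), 2L)       # c1 became its own factor
  expect_equal(factor_names(solo), c("a", "c1"))
  expect_error(subset_registry(reg, "missing"), "unknown parameter")
})
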