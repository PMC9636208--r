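test_that("spearman matches the rank-Pearson oracle, including ties", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$r, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$r, -1)
  ## tied example: average ranks (1, 2.5, 2.5, 4) vs (1, 3, 2, 4)
  res <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.948683298050514, tolerance = 1e-12)
  expect_equal(res$n, 4L)
  ## cross-check against the independent base-R implementation
  set.seed(6)
  for (i in 1:10) {
    x <- sample(20, 15, replace = TRUE); y <- x + rnorm(15, 0, 5)
    expect_equal(spearman_cor(x, y)$r, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  ## invariance under strictly monotone transforms
  x <- runif(12); y <- runif(12)
  expect_equal(spearman_cor(exp(3 * x), y)$r, spearman_cor(x, y)$r)
  expect_equal(spearman_cor(x, y^3)$r, spearman_cor(x, y)$r)
  ## missing pairs removed; constants refuse
  expect_equal(spearman_cor(c(1, 2, NA, 4), c(2, 4, 5, 8))$n, 3L)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("fisher z is the antisymmetric atanh with exact round-trip", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.96), 1.94591014905531, tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_false(is.unsorted(fisher_z(r), strictly = TRUE))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("dependent-correlation comparison: null, worked value, monotonicity", {
  ## symmetric null: equal correlations give Z = 0, one-sided p = 0.5
  eq <- compare_dependent_correlations(0.7, 0.7, 0.5, 35)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p, 0.5)
  ## worked example (frozen from direct evaluation of the Steiger formula)
  st <- compare_dependent_correlations(0.96, 0.81, 0.8266, 35)
  expect_equal(st$z_stat, 4.41939470888543, tolerance = 1e-10)
  expect_lt(st$p, 1e-4)
  fi <- compare_dependent_correlations(0.96, 0.81, 0.8266, 35,
                                       variant = "fisher_independent")
  expect_equal(fi$z_stat, 3.27552449202248, tolerance = 1e-10)
  ## Z strictly increasing in r12 at fixed (r13, r23, n)
  zs <- vapply(seq(0.5, 0.95, by = 0.05), function(r12)
    compare_dependent_correlations(r12, 0.6, 0.5, 30)$z_stat, numeric(1))
  expect_false(is.unsorted(zs, strictly = TRUE))
  expect_error(compare_dependent_correlations(1, 0.5, 0.5, 30), "degenerate")
})

test_that("ordinary least squares and r-squared match closed forms", {
  ex <- linreg_r2(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 0)
  expect_equal(ex$r_squared, 1)
  hand <- linreg_r2(c(0, 1, 2), c(0, 1, 1))
  expect_equal(hand$slope, 0.5)
  expect_equal(hand$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(hand$r_squared, 0.75, tolerance = 1e-12)
  const <- linreg_r2(c(0, 1, 2, 3), c(5, 5, 5, 5))
  expect_equal(const$r_squared, 0)
  expect_error(linreg_r2(rep(2, 4), 1:4), "constant")
  ## r^2 invariant under scale/shift of either variable
  set.seed(8)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  expect_equal(linreg_r2(3 * x + 1, y)$r_squared, linreg_r2(x, y)$r_squared)
  expect_equal(linreg_r2(x, -5 * y + 2)$r_squared, linreg_r2(x, y)$r_squared)
})

test_that("the correlation report has the contract schema and sane content", {
  set.seed(9)
  n <- 12
  cpa <- sort(runif(n, 0.5, 8))
  stage <- findInterval(cpa, c(1.5, 3, 5))
  animals <- data.frame(mean_cpa = cpa,
                        hyp_ug_per_g = 45 * cpa + 130 + rnorm(n, 0, 60),
                        ishak = stage)
  rep <- correlation_report(animals, score_cols = "ishak")
  expect_identical(names(rep),
                   c("system", "r_CPA", "r_HYP", "r23", "n", "Z", "p_one_sided"))
  expect_equal(rep$n, n)
  expect_true(abs(rep$r_CPA) <= 1 && abs(rep$r_HYP) <= 1)
  ## stage is a deterministic function of CPA here, so CPA must win
  expect_gte(rep$r_CPA, rep$r_HYP)
  expect_error(correlation_report(animals[1:3, ], score_cols = "ishak"),
               "at least 4")
})
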