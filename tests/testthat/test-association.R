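test_that("Spearman matrix is symmetric with unit diagonal and monotone
           invariance", {
  set.seed(41)
  x <- rnorm(30)
  tab <- data.frame(x = x, expx = exp(x), negx = -x, z = rnorm(30))
  sp <- spearman_matrix(tab)
  expect_equal(sp$rho["x", "expx"], 1)
  expect_equal(sp$rho["x", "negx"], -1)
  expect_equal(unname(diag(sp$rho)), rep(1, 4))
  expect_equal(sp$rho, t(sp$rho))
  expect_lt(sp$p["x", "expx"], 1e-6)

  tab$const <- 5
  expect_warning(spc <- spearman_matrix(tab), "const")
  expect_true(is.na(spc$rho["const", "x"]))
})

test_that("Mantel self-correlation gives r = 1 at the minimal p-value", {
  set.seed(42)
  d <- as.matrix(dist(matrix(rnorm(20 * 2), 20)))
  m <- mantel_test(d, d, n_perm = 99, seed = 9)
  expect_equal(m$r_obs, 1)
  expect_equal(m$p_value, 1 / 100)
  expect_error(mantel_test(d, d[-1, -1]), class = "dimension_error")
})

test_that("Mantel agrees with vegan on the observed statistic and detects a
           real association", {
  skip_if_not_installed("vegan")
  set.seed(43)
  X <- matrix(rnorm(25 * 3), 25)
  d1 <- as.matrix(dist(X))
  d2 <- as.matrix(dist(X + 0.5 * matrix(rnorm(25 * 3), 25)))
  m <- mantel_test(d1, d2, n_perm = 499, seed = 11)
  v <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 499)
  expect_equal(m$r_obs, unname(v$statistic), tolerance = 1e-12)
  expect_lt(m$p_value, 0.01)
  expect_gte(m$p_value, 1 / 500)
})

test_that("simple regression recovers exact lines and the OLS band shape", {
  x <- seq(0, 10, length.out = 25)
  f <- simple_regression(x, 3 * x + 1)
  expect_equal(f$slope, 3, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  set.seed(44)
  y <- 2 * x + rnorm(25)
  b <- simple_regression(x, y, band_at = seq(0, 10, 0.5))$band
  width <- b$upper - b$lower
  expect_equal(b$x[which.min(width)], b$x[which.min(abs(b$x - mean(x)))])
  expect_error(simple_regression(rep(1, 5), rnorm(5)),
               class = "degenerate_regressor")
})

test_that("AICc matches its closed form, limits and penalty monotonicity", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7, tolerance = 1e-12)
  expect_lt(abs(aicc(-100, 3, 1e5) - (2 * 100 + 2 * 3)), 0.01)
  expect_gt(aicc(-10, 4, 50), aicc(-10, 3, 50))
  expect_error(aicc(-1, 5, 6), class = "small_sample")
})

test_that("model averaging degenerates to OLS with one candidate and
           normalizes importances", {
  set.seed(45)
  x <- rnorm(100); y <- 0.6 * x + rnorm(100)
  ma <- all_subsets_average(y, data.frame(x = x))
  ols <- unname(coef(lm(scale(y) ~ scale(x)))[2])
  # the averaging set may include the null model, whose weight is tiny here
  expect_equal(ma$coefficients$estimate, ols, tolerance = 0.02)
  expect_equal(ma$coefficients$importance, 100)
  expect_equal(ma$models$delta[1], 0)
  expect_equal(sum(ma$models$weight), 1, tolerance = 1e-9)

  p4 <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100),
                   x = x)
  ma4 <- all_subsets_average(y, p4)
  expect_equal(sum(ma4$coefficients$importance), 100, tolerance = 0.1)
})

test_that("model averaging is invariant to predictor column order", {
  set.seed(46)
  X <- data.frame(a = rnorm(120), b = rnorm(120), c = rnorm(120))
  y <- 0.5 * X$a - 0.3 * X$c + rnorm(120)
  m1 <- all_subsets_average(y, X)
  m2 <- all_subsets_average(y, X[, c("c", "a", "b")])
  ord <- match(m1$coefficients$predictor, m2$coefficients$predictor)
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate[ord],
               tolerance = 1e-10)
  expect_equal(m1$coefficients$importance, m2$coefficients$importance[ord],
               tolerance = 1e-10)
})

test_that("the dominant true predictor wins the importance ranking", {
  top <- vapply(1:10, function(r) {
    set.seed(300 + r)
    X <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200),
                    x4 = rnorm(200), true = rnorm(200))
    y <- 0.7 * X$true + rnorm(200)
    ma <- all_subsets_average(y, X)
    ma$coefficients$predictor[which.max(ma$coefficients$importance)]
  }, character(1))
  expect_true(all(top == "true"))
})

test_that("synthetic stability recovery: ICV rises with CWM.LT", {
  ds <- synth_dataset(synthetic_config(n_sites = 300,
                                       beta_stability_lt = 0.5, seed = 8))
  m <- site_metrics(ds)
  fit <- simple_regression(m$CWM.LT, m$ICV)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
})
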