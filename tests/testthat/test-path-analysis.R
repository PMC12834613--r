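test_that("path specifications validate structure and parse the edge-list
           format", {
  expect_error(path_spec(c("a -> b", "b -> a")), class = "dag_error")
  expect_error(path_spec(data.frame(from = "a", to = "b"),
                         variables = "a"), class = "invalid_spec")
  spec <- path_spec(c("# comment", "x -> m", "m -> y"))
  expect_equal(spec$edges$from, c("x", "m"))
  f <- tempfile()
  write_path_spec(spec, f)
  expect_equal(read_path_spec(f)$edges, spec$edges)
})

test_that("composites take the first correlation-PCA axis with a stable
           orientation", {
  set.seed(61)
  x <- rnorm(40)
  two <- data.frame(a = x, b = x)
  cp <- build_composite(two)
  expect_equal(abs(cor(cp$scores, x)), 1, tolerance = 1e-12)
  expect_equal(mean(cp$scores), 0, tolerance = 1e-12)

  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  c1 <- build_composite(X)
  c2 <- build_composite(-X)
  # negating every indicator flips the composite but preserves the
  # alignment contract on both sides
  expect_equal(abs(cor(c1$scores, c2$scores)), 1, tolerance = 1e-10)
  expect_gte(cor(c1$scores, rowMeans(scale(X))), 0)
  expect_gte(cor(c2$scores, rowMeans(scale(-X))), 0)

  X$d <- 1
  expect_error(build_composite(X), "d", class = "degenerate_error")
})

test_that("the BC composite recovers the generator's latent factor", {
  env <- generate_environment(synthetic_config(n_sites = 300, seed = 7))
  comp <- build_composite(env[, c("DCa", "DMg", "DNa", "DK")])
  expect_gt(cor(comp$scores, attr(env, "latents")$bc), 0.85)
})

test_that("single-edge models reduce to the bivariate correlation", {
  set.seed(62)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  f <- fit_path_model(path_spec("x -> y"), data.frame(x = x, y = y))
  expect_equal(f$edges$estimate, cor(x, y), tolerance = 1e-10)
  expect_equal(unname(f$r_squared["y"]), cor(x, y)^2, tolerance = 1e-10)
})

test_that("saturated models fit perfectly: chi2 ~ 0, df = 0, rmsea = 0", {
  set.seed(63)
  d <- data.frame(x = rnorm(100))
  d$m <- 0.5 * d$x + rnorm(100)
  d$y <- 0.3 * d$x + 0.4 * d$m + rnorm(100)
  f <- fit_path_model(path_spec(c("x -> m", "x -> y", "m -> y")), d)
  expect_equal(f$df, 0)
  expect_lt(abs(f$chi2), 1e-8)
  expect_equal(f$rmsea, 0)
  expect_gt(f$gfi, 0.999)
})

test_that("chi-square is invariant to variable declaration order and rmsea
           vanishes when chi2 <= df", {
  set.seed(64)
  d <- data.frame(x = rnorm(150))
  d$m <- 0.6 * d$x + rnorm(150)
  d$y <- 0.5 * d$m + rnorm(150)
  spec1 <- path_spec(c("x -> m", "m -> y"))
  spec2 <- path_spec(data.frame(from = c("m", "x"), to = c("y", "m")),
                     variables = c("y", "m", "x"))
  f1 <- fit_path_model(spec1, d)
  f2 <- fit_path_model(spec2, d[, c(3, 1, 2)])
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-10)
  if (f1$chi2 <= f1$df) expect_equal(f1$rmsea, 0)
})

test_that("a known causal chain is recovered with a well-fitting model", {
  hits <- vapply(1:30, function(r) {
    set.seed(700 + r)
    n <- 500
    x <- rnorm(n)
    m <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    y <- 0.5 * m + sqrt(1 - 0.25) * rnorm(n)
    f <- fit_path_model(path_spec(c("x -> m", "m -> y")),
                        data.frame(x = x, m = m, y = y))
    ok_coef <- abs(f$edges$estimate[1] - 0.6) < 0.1 &&
      abs(f$edges$estimate[2] - 0.5) < 0.1
    c(ok_coef, f$chi2_p > 0.05)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("pruning removes only weak edges, never strong ones, and alpha = 1
           disables it", {
  set.seed(65)
  n <- 500
  x <- rnorm(n); m <- 0.6 * x + rnorm(n); y <- 0.6 * m + rnorm(n)
  z <- rnorm(n)
  d <- data.frame(x = x, m = m, y = y, z = z)

  strong <- prune_model(path_spec(c("x -> m", "m -> y")), d)
  expect_equal(nrow(strong$log), 0)

  removed_first <- vapply(1:20, function(r) {
    set.seed(800 + r)
    x <- rnorm(n); m <- 0.6 * x + rnorm(n); y <- 0.6 * m + rnorm(n)
    d <- data.frame(x = x, m = m, y = y, z = rnorm(n))
    pr <- prune_model(path_spec(c("x -> m", "m -> y", "z -> y")), d)
    nrow(pr$log) >= 1 && pr$log$from[1] == "z"
  }, logical(1))
  expect_gte(mean(removed_first), 0.9)

  noprune <- prune_model(path_spec(c("x -> m", "m -> y", "z -> y")), d,
                         alpha = 1)
  expect_equal(nrow(noprune$log), 0)
  expect_equal(nrow(noprune$fit$edges), 3)
})

test_that("the shipped prior model has the expected deposition structure", {
  spec <- prior_model("FRic")
  expect_s3_class(spec, "path_spec")   # construction implies acyclicity
  key <- paste(spec$edges$from, spec$edges$to)
  expect_true("BCdep FRic" %in% key)
  expect_true("Ndep DpH" %in% key)
  expect_true("Ndep STP" %in% key)
})
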