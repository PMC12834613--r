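# Correlation screening, Mantel permutation tests, simple regressions and
# all-subsets AICc multimodel averaging.

#' Spearman rank-correlation matrix with p-values
#'
#' Pairwise Spearman rho (mid-ranks for ties) and two-sided p-values over
#' the numeric columns of a table.  Constant columns give missing entries
#' with a warning.
#'
#' @param table data.frame or matrix of per-site variables.
#' @return list with symmetric matrices `rho` (unit diagonal) and `p`.
#' @export
spearman_matrix <- function(table) {
  X <- table
  if (is.data.frame(X))
    X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  k <- ncol(X)
  if (nrow(X) < 3L)
    stop_fd("need >= 3 observations", class = "domain_error")
  constant <- apply(X, 2L, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(constant))
    warning("constant variable(s) give missing correlations: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  pv <- rho
  diag(rho) <- 1
  diag(pv) <- NA_real_
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (constant[i] || constant[j]) next
    ok <- stats::complete.cases(X[, i], X[, j])
    if (sum(ok) < 3L) next
    ct <- suppressWarnings(
      stats::cor.test(X[ok, i], X[ok, j], method = "spearman",
                      exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(rho = rho, p = pv)
}

#' Mantel permutation test between two distance matrices
#'
#' The observed statistic is the Pearson correlation of the upper-triangle
#' entries.  The null distribution is built by simultaneously permuting the
#' rows and columns of `d2`; the one-sided upper-tail p-value is
#' `(1 + #permuted r >= observed r) / (1 + n_perm)`.
#'
#' @param d1,d2 symmetric zero-diagonal distance matrices, same dimension
#'   (>= 4).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class `mantel_result`: `r_obs`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  D1 <- as_numeric_matrix(d1, "d1")
  D2 <- as_numeric_matrix(d2, "d2")
  n <- nrow(D1)
  if (!all(dim(D1) == dim(D2)))
    stop_fd("distance matrices differ in dimension", class = "dimension_error")
  if (n < 4L)
    stop_fd("Mantel test needs >= 4 objects", class = "domain_error")
  n_perm <- check_count(n_perm, "n_perm", lower = 1L)
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  r_obs <- stats::cor(v1, D2[ut])
  set.seed(seed)
  v1c <- v1 - mean(v1)
  v1s <- v1c / sqrt(sum(v1c^2))
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    v2 <- D2[idx, idx][ut]
    v2c <- v2 - mean(v2)
    r_perm <- sum(v1s * v2c) / sqrt(sum(v2c^2))
    if (r_perm >= r_obs) count <- count + 1L
  }
  structure(list(r_obs = r_obs, p_value = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, one-sided p = %.4f (%d permutations)\n",
              x$r_obs, x$p_value, x$n_perm))
  invisible(x)
}

#' Simple linear regression with a 95 percent confidence band
#'
#' @param x,y numeric vectors (n >= 3).
#' @param band_at points at which to evaluate the pointwise confidence
#'   band for the mean response (default: sorted unique x).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   and `band` (data.frame x, fit, lower, upper).
#' @export
simple_regression <- function(x, y, band_at = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  if (length(x) < 3L)
    stop_fd("need n >= 3", class = "domain_error")
  if (stats::sd(x) == 0)
    stop_fd("zero-variance predictor", class = "degenerate_regressor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  if (is.null(band_at)) band_at <- sort(unique(x))
  pr <- stats::predict(fit, newdata = data.frame(x = band_at),
                       interval = "confidence", level = 0.95)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2L, 4L]),
       n = length(x),
       band = data.frame(x = band_at, fit = pr[, "fit"],
                         lower = pr[, "lwr"], upper = pr[, "upr"]))
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param log_likelihood model log-likelihood.
#' @param k number of estimated parameters (including the error variance).
#' @param n sample size (must exceed k + 1).
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1)
    stop_fd("AICc undefined for n <= k + 1 (n = %s, k = %s)", n, k,
            class = "small_sample")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets OLS with AICc ranking and model averaging
#'
#' Standardizes the response and every predictor, fits OLS on every
#' predictor subset of size up to `max_predictors` (including the
#' intercept-only model), ranks by AICc, and averages standardized
#' coefficients over models with `delta AICc <= delta_cutoff` using Akaike
#' weights.  Averaging is full-model (zero-substitution): a predictor
#' absent from a model contributes 0.  Relative importance of predictor j
#' is `100 |avg estimate_j| / sum_m |avg estimate_m|`; the
#' variance-explained weighting is also reported as
#' `importance_r2` for comparison.  Confidence intervals use unconditional
#' (model-averaged) standard errors.
#'
#' @param response numeric vector.
#' @param predictors data.frame or matrix of candidate predictors.
#' @param max_predictors largest subset size (default: all predictors).
#' @param delta_cutoff AICc window for the averaging set (default 4).
#' @return list of class `model_averaging`: `coefficients` (data.frame
#'   with estimate, se, lower, upper, importance, importance_r2) and
#'   `models` (subset, k, aicc, delta, weight).
#' @export
all_subsets_average <- function(response, predictors, max_predictors = NULL,
                                delta_cutoff = 4) {
  X <- predictors
  if (is.data.frame(X))
    X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  X <- as_numeric_matrix(as.matrix(X), "predictors")
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(X) != n)
    stop_fd("response/predictor length mismatch", class = "dimension_error")
  p <- ncol(X)
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- nm
  max_predictors <- min(max_predictors %||% p, p)
  ys <- scale1(y)
  Xs <- scale(X)

  subsets <- list(integer(0))
  for (m in seq_len(max_predictors))
    subsets <- c(subsets, utils::combn(p, m, simplify = FALSE))

  fits <- lapply(subsets, function(idx) {
    k <- length(idx) + 2L  # coefficients (incl. intercept) + error variance
    if (n <= k + 1) return(NULL)
    if (length(idx)) {
      Xi <- Xs[, idx, drop = FALSE]
      if (length(idx) > 1L && kappa(stats::cor(Xi)) > 1e8) {
        warning("skipping collinear subset: ", paste(nm[idx], collapse = "+"),
                call. = FALSE)
        return(NULL)
      }
      fit <- stats::lm.fit(cbind(1, Xi), ys)
      res <- fit$residuals
      coefs <- fit$coefficients[-1L]
      XtXinv <- chol2inv(chol(crossprod(cbind(1, Xi))))
      s2 <- sum(res^2) / (n - length(idx) - 1L)
      ses <- sqrt(diag(XtXinv) * s2)[-1L]
    } else {
      res <- ys - mean(ys)
      coefs <- numeric(0)
      ses <- numeric(0)
    }
    ll <- -n / 2 * (log(2 * pi) + log(sum(res^2) / n) + 1)
    list(idx = idx, coefs = coefs, ses = ses, k = k,
         aicc = aicc(ll, k, n), r2 = 1 - sum(res^2) / sum((ys - mean(ys))^2))
  })
  fits <- Filter(Negate(is.null), fits)
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aiccs - min(aiccs)
  w_all <- exp(-delta / 2)
  w_all <- w_all / sum(w_all)

  in_set <- delta <= delta_cutoff
  w <- w_all[in_set] / sum(w_all[in_set])
  avg <- rep(0, p); avg_se2 <- rep(0, p); imp_r2 <- rep(0, p)
  sel <- fits[in_set]
  for (m in seq_along(sel)) {
    b <- rep(0, p); se <- rep(0, p)
    b[sel[[m]]$idx] <- sel[[m]]$coefs
    se[sel[[m]]$idx] <- sel[[m]]$ses
    avg <- avg + w[m] * b
    imp_r2[sel[[m]]$idx] <- imp_r2[sel[[m]]$idx] + w[m] * sel[[m]]$r2
  }
  for (m in seq_along(sel)) {
    b <- rep(0, p); se <- rep(0, p)
    b[sel[[m]]$idx] <- sel[[m]]$coefs
    se[sel[[m]]$idx] <- sel[[m]]$ses
    avg_se2 <- avg_se2 + w[m] * (se^2 + (b - avg)^2)
  }
  se_u <- sqrt(avg_se2)
  importance <- if (sum(abs(avg)) > 0) 100 * abs(avg) / sum(abs(avg)) else
    rep(NA_real_, p)
  importance_r2 <- if (sum(imp_r2) > 0) 100 * imp_r2 / sum(imp_r2) else
    rep(NA_real_, p)

  coef_tab <- data.frame(
    predictor = nm, estimate = avg, se = se_u,
    lower = avg - 1.96 * se_u, upper = avg + 1.96 * se_u,
    importance = importance, importance_r2 = importance_r2,
    stringsAsFactors = FALSE)
  model_tab <- data.frame(
    subset = vapply(fits, function(f)
      if (length(f$idx)) paste(nm[f$idx], collapse = "+") else "(null)",
      character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aicc = aiccs, delta = delta, weight = w_all,
    stringsAsFactors = FALSE)
  model_tab <- model_tab[order(model_tab$aicc), ]
  rownames(model_tab) <- NULL
  structure(list(coefficients = coef_tab, models = model_tab,
                 delta_cutoff = delta_cutoff),
            class = "model_averaging")
}

#' @export
print.model_averaging <- function(x, ...) {
  cat(sprintf("AICc all-subsets averaging (%d models, delta <= %g set)\n",
              nrow(x$models), x$delta_cutoff))
  print(transform(x$coefficients,
                  estimate = round(estimate, 3), se = round(se, 3),
                  lower = round(lower, 3), upper = round(upper, 3),
                  importance = round(importance, 1),
                  importance_r2 = round(importance_r2, 1)))
  invisible(x)
}
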