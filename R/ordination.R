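# PCA of the site x CWM-trait matrix (the leaf-strategy spectrum) and
# simple regressions of trait axes on environmental covariates.

#' Correlation-matrix PCA of community-weighted trait means
#'
#' Eigendecomposition of the trait correlation matrix (traits have
#' heterogeneous units, so covariance PCA would be dominated by scale).
#' Loading signs are fixed deterministically: each component is oriented
#' so that its largest-magnitude loading is positive.
#'
#' @param cwm_table site x trait data.frame or matrix of CWM values (a
#'   `site` column, if present, is used for score rownames).
#' @return list of class `cwm_pca`: `loadings` (trait x component,
#'   orthonormal), `scores` (site x component), `var_explained`,
#'   `cumulative`.
#' @export
cwm_pca <- function(cwm_table) {
  X <- cwm_table
  site <- NULL
  if (is.data.frame(X) && "site" %in% names(X)) {
    site <- X$site
    X <- X[, setdiff(names(X), "site"), drop = FALSE]
  }
  X <- as_numeric_matrix(X, "cwm_table")
  if (nrow(X) < 3L)
    stop_fd("PCA needs at least 3 sites", class = "domain_error")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0))
    stop_fd("constant trait column(s): %s",
            paste(colnames(X)[sds <= 0], collapse = ", "),
            class = "degenerate_column")
  Z <- scale(X)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(ncol(L))))
  scores <- Z %*% L
  rownames(scores) <- site %||% rownames(X)
  ve <- pmax(ev$values, 0) / sum(pmax(ev$values, 0))
  structure(list(loadings = L, scores = scores, var_explained = ve,
                 cumulative = cumsum(ve)),
            class = "cwm_pca")
}

#' @export
print.cwm_pca <- function(x, n = 2L, ...) {
  n <- min(n, ncol(x$loadings))
  cat("Correlation-matrix PCA of CWM traits\n")
  print(round(x$loadings[, seq_len(n), drop = FALSE], 3))
  cat(sprintf("Variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(n)]),
                    collapse = ", "),
              100 * x$cumulative[n]))
  invisible(x)
}

#' Simple regression of a trait axis on an environmental covariate
#'
#' Ordinary least-squares regression of per-site PCA axis scores on a
#' single covariate; for a simple regression the returned R-squared equals
#' the squared Pearson correlation.
#'
#' @param scores numeric vector of per-site axis scores.
#' @param env numeric vector of the covariate, same sites.
#' @return list with `r_squared`, `slope`, `intercept`, `p_value`, `n`.
#' @export
axis_env_r2 <- function(scores, env) {
  ok <- stats::complete.cases(scores, env)
  x <- as.numeric(env)[ok]
  y <- as.numeric(scores)[ok]
  if (length(x) < 3L)
    stop_fd("need >= 3 paired complete observations", class = "domain_error")
  if (stats::sd(x) == 0)
    stop_fd("zero-variance covariate", class = "degenerate_regressor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = unname(sm$coefficients[2L, 4L]),
       n = length(x))
}

#' Axis-environment screening table
#'
#' Runs [axis_env_r2()] for each of the first `n_axes` components against
#' every numeric covariate.
#'
#' @param pca a [cwm_pca()] result.
#' @param env_table data.frame with a `site` column and covariates.
#' @param n_axes number of leading axes (default 2).
#' @return tidy data.frame: axis, covariate, r_squared, slope, p_value, n.
#' @export
axis_env_table <- function(pca, env_table, n_axes = 2L) {
  stopifnot(inherits(pca, "cwm_pca"))
  covs <- setdiff(names(env_table)[vapply(env_table, is.numeric, TRUE)],
                  "distance")
  sites <- rownames(pca$scores)
  env <- env_table[match(sites, env_table$site), , drop = FALSE]
  out <- list()
  for (a in seq_len(min(n_axes, ncol(pca$scores)))) {
    for (v in covs) {
      r <- axis_env_r2(pca$scores[, a], env[[v]])
      out[[length(out) + 1L]] <- data.frame(
        axis = paste0("PC", a), covariate = v, r_squared = r$r_squared,
        slope = r$slope, p_value = r$p_value, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
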