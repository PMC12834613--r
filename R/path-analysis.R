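# Composite-variable construction and recursive observed-variable path
# models.  All variables are observed (or first-PCA-axis composites), every
# structural model is a recursive DAG, and each endogenous variable is
# fitted by least squares on its parents -- which coincides with the global
# maximum-likelihood solution for recursive models.  Chi-square, GFI and
# RMSEA are computed from the Wishart ML discrepancy between the sample and
# model-implied correlation matrices.

#' Construct a directed-acyclic path model specification
#'
#' @param edges data.frame with columns `from` and `to`, or a character
#'   vector of `"cause -> effect"` lines.
#' @param variables optional variable list (defaults to the union of edge
#'   endpoints, in first-appearance order).
#' @return list of class `path_spec` with `variables` and `edges`.
#' @export
path_spec <- function(edges, variables = NULL) {
  if (is.character(edges)) {
    lines <- trimws(edges)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop_fd("each edge line must be 'cause -> effect'", class = "parse_error")
    edges <- data.frame(from = trimws(vapply(parts, `[[`, "", 1L)),
                        to = trimws(vapply(parts, `[[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- edges[, c("from", "to")]
  vars <- variables %||% unique(c(rbind(edges$from, edges$to)))
  unknown <- setdiff(c(edges$from, edges$to), vars)
  if (length(unknown))
    stop_fd("edge endpoints not declared: %s",
            paste(unknown, collapse = ", "), class = "invalid_spec")
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop_fd("duplicated edges in spec", class = "invalid_spec")
  spec <- structure(list(variables = vars, edges = edges),
                    class = "path_spec")
  if (is.null(topological_order(spec)))
    stop_fd("path specification contains a cycle", class = "dag_error")
  spec
}

topological_order <- function(spec) {
  vars <- spec$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (v in spec$edges$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  edges <- spec$edges
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    edges <- edges[edges$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) != length(vars)) NULL else order
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("Path model: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write the plain-text edge-list format
#' @param path file with one `cause -> effect` edge per line.
#' @return a [path_spec()].
#' @export
read_path_spec <- function(path) path_spec(readLines(path))

#' @rdname read_path_spec
#' @param spec a `path_spec`.
#' @export
write_path_spec <- function(spec, path) {
  writeLines(paste(spec$edges$from, "->", spec$edges$to), path)
  invisible(path)
}

#' First-principal-axis composite of an indicator block
#'
#' Correlation-matrix PCA of the indicators; per-site scores on the first
#' axis, sign-oriented so that the score correlates non-negatively with
#' the mean of the standardized indicators.
#'
#' @param indicators site x indicator data.frame or matrix (>= 2 columns,
#'   >= 3 rows, no constant column).
#' @return list of class `composite_variable`: `scores` (mean 0),
#'   `loadings`, `indicators`, `orientation` (+1 or -1 relative to the raw
#'   first eigenvector), `var_explained`.
#' @export
build_composite <- function(indicators) {
  X <- indicators
  if (is.data.frame(X)) X <- as.matrix(X)
  X <- as_numeric_matrix(X, "indicators")
  if (ncol(X) < 2L)
    stop_fd("composite needs >= 2 indicators", class = "domain_error")
  if (nrow(X) < 3L)
    stop_fd("composite needs >= 3 sites", class = "domain_error")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0))
    stop_fd("constant indicator(s): %s",
            paste(colnames(X)[sds <= 0], collapse = ", "),
            class = "degenerate_error")
  Z <- scale(X)
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  scores <- as.numeric(Z %*% v1)
  orientation <- 1
  if (stats::cor(scores, rowMeans(Z)) < 0) {
    orientation <- -1
    scores <- -scores
    v1 <- -v1
  }
  structure(list(scores = scores, loadings = stats::setNames(v1, colnames(X)),
                 indicators = colnames(X), orientation = orientation,
                 var_explained = ev$values[1L] / sum(ev$values)),
            class = "composite_variable")
}

#' Fit a recursive path model by per-equation least squares with ML fit
#' statistics
#'
#' All variables are standardized; each endogenous variable is regressed
#' on its parents (for recursive models this reproduces the global ML
#' solution).  The model-implied correlation matrix is
#' \eqn{\Sigma = (I-B)^{-1} \Psi (I-B)^{-T}} with the exogenous block of
#' \eqn{\Psi} fixed at the sample values and diagonal endogenous residual
#' variances.  Fit statistics use the Wishart discrepancy
#' \eqn{F = \log|\Sigma| - \log|S| + tr(S\Sigma^{-1}) - p}:
#' \eqn{\chi^2 = (n-1)F},
#' \eqn{GFI = 1 - tr[(\Sigma^{-1}S - I)^2]/tr[(\Sigma^{-1}S)^2]},
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}}.
#'
#' @param spec a [path_spec()].
#' @param data data.frame with one column per spec variable.
#' @return object of class `path_fit` with elements `edges` (from, to,
#'   estimate, se, p_value), `r_squared`, `chi2`, `df`, `chi2_p`, `gfi`,
#'   `rmsea`, `n`, `spec`.
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- spec$variables
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_fd("variables absent from data: %s",
            paste(missing_vars, collapse = ", "), class = "lookup_error")
  X <- as_numeric_matrix(as.matrix(data[, vars, drop = FALSE]), "data")
  n <- nrow(X)
  p <- length(vars)
  Z <- scale(X)
  S <- stats::cor(X)
  endo <- unique(spec$edges$to)
  exo <- setdiff(vars, endo)
  q <- length(exo)
  n_par <- nrow(spec$edges) + length(endo) + q * (q + 1) / 2
  # identification: the sample covariance must be full rank and every
  # structural equation estimable (the exogenous block is fixed at sample
  # moments, so it does not consume regression degrees of freedom)
  max_eq <- if (nrow(spec$edges)) max(table(spec$edges$to)) else 0L
  if (n < p + 2L || n <= max_eq + 2L)
    stop_fd("model underidentified by sample size: n = %d for %d variables
and up to %d predictors per equation", n, p, max_eq,
            class = "identification_error")

  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi[exo, exo] <- S[exo, exo]
  edge_est <- edge_se <- edge_p <- numeric(nrow(spec$edges))
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (v in endo) {
    pa <- spec$edges$from[spec$edges$to == v]
    fit <- stats::lm(Z[, v] ~ Z[, pa, drop = FALSE])
    sm <- summary(fit)$coefficients
    beta <- stats::coef(fit)[-1L]
    B[v, pa] <- beta
    Psi[v, v] <- S[v, v] - sum(beta * S[pa, v])
    r2[v] <- 1 - Psi[v, v] / S[v, v]
    rows <- which(spec$edges$to == v)
    ord <- match(spec$edges$from[rows], pa)
    edge_est[rows] <- beta[ord]
    edge_se[rows] <- sm[-1L, 2L][ord]
    edge_p[rows] <- sm[-1L, 4L][ord]
  }

  A <- solve(diag(p) - B)
  Sigma <- A %*% Psi %*% t(A)
  df <- p * (p + 1) / 2 - n_par
  Sinv <- solve(Sigma)
  Fml <- determinant(Sigma, logarithm = TRUE)$modulus -
    determinant(S, logarithm = TRUE)$modulus + sum(diag(S %*% Sinv)) - p
  Fml <- max(as.numeric(Fml), 0)
  chi2 <- (n - 1) * Fml
  chi2_p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
    NA_real_
  M <- Sinv %*% S
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0

  structure(list(
    edges = data.frame(spec$edges, estimate = edge_est, se = edge_se,
                       p_value = edge_p, stringsAsFactors = FALSE),
    r_squared = r2, chi2 = chi2, df = df, chi2_p = chi2_p,
    gfi = gfi, rmsea = rmsea, n = n, implied = Sigma, sample = S,
    spec = spec), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf(
    "Recursive path model (n = %d): chi2 = %.3f, df = %d, p = %s\n",
    x$n, x$chi2, x$df,
    ifelse(is.na(x$chi2_p), "NA", sprintf("%.3f", x$chi2_p))))
  cat(sprintf("  GFI = %.3f, RMSEA = %.3f\n", x$gfi, x$rmsea))
  e <- x$edges
  cat(sprintf("  %s -> %s: %s%.3f (p = %.3g)\n", e$from, e$to,
              ifelse(e$estimate >= 0, " ", ""), e$estimate, e$p_value),
      sep = "")
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) {
  stats::setNames(object$edges$estimate,
                  paste(object$edges$from, "->", object$edges$to))
}

#' @export
summary.path_fit <- function(object, ...) {
  out <- list(edges = object$edges, r_squared = object$r_squared,
              fit = c(chi2 = object$chi2, df = object$df,
                      chi2_p = object$chi2_p, gfi = object$gfi,
                      rmsea = object$rmsea, n = object$n))
  class(out) <- "summary.path_fit"
  out
}

#' @export
print.summary.path_fit <- function(x, ...) {
  cat("Edges:\n"); print(x$edges)
  cat("R-squared of endogenous variables:\n"); print(round(x$r_squared, 3))
  cat("Fit:\n"); print(round(x$fit, 4))
  invisible(x)
}

#' Evaluate conventional fit-acceptance criteria for a path fit
#' @param fit a `path_fit`.
#' @param chi2_alpha,gfi_min,rmsea_max conventional cutoffs.
#' @return logical: does the model meet all three criteria?
#' @export
path_fit_acceptable <- function(fit, chi2_alpha = 0.05, gfi_min = 0.90,
                                rmsea_max = 0.08) {
  chi_ok <- is.na(fit$chi2_p) || fit$chi2_p > chi2_alpha
  chi_ok && fit$gfi >= gfi_min && fit$rmsea <= rmsea_max
}

#' Backward pruning of nonsignificant paths
#'
#' Iteratively removes the single retained path with the largest p-value
#' above `alpha`, refits, and repeats until every remaining path is
#' significant (or no edges remain).
#'
#' @param spec a [path_spec()].
#' @param data data.frame of observed/composite variables.
#' @param alpha significance threshold (default 0.05); `alpha = 1` never
#'   prunes.
#' @return list with `spec` (final), `fit` (final `path_fit`) and `log`
#'   (data.frame of removed edges with their p-values, in removal order).
#' @export
prune_model <- function(spec, data, alpha = 0.05) {
  log <- data.frame(from = character(0), to = character(0),
                    p_value = numeric(0), stringsAsFactors = FALSE)
  fit <- fit_path_model(spec, data)
  repeat {
    e <- fit$edges
    bad <- which(e$p_value > alpha)
    if (!length(bad) || nrow(e) == 0L) break
    drop <- bad[which.max(e$p_value[bad])]
    log <- rbind(log, data.frame(from = e$from[drop], to = e$to[drop],
                                 p_value = e$p_value[drop],
                                 stringsAsFactors = FALSE))
    keep <- e[-drop, c("from", "to")]
    if (!nrow(keep)) {
      spec <- structure(list(variables = spec$variables, edges = keep),
                        class = "path_spec")
      fit <- NULL
      break
    }
    spec <- path_spec(keep, variables = spec$variables)
    fit <- fit_path_model(spec, data)
  }
  list(spec = spec, fit = fit, log = log)
}

#' Default prior path model for one diversity response
#'
#' A reconstruction of the study-type prior structure: exogenous
#' deposition drivers (S deposition, N deposition composite, BC deposition
#' composite) act on deposition pH and soil mediators (SOC, STP, SpH,
#' SAKP, SBG), and both depositions and mediators act on the functional
#' diversity response.  One instance per response index; user-overridable
#' via [path_spec()].
#'
#' @param response name of the response variable (default `"FDis"`).
#' @return a [path_spec()].
#' @export
prior_model <- function(response = "FDis") {
  dep <- c("Sdep", "Ndep", "BCdep")
  med <- c("DpH", "SOC", "STP", "SpH", "SAKP", "SBG")
  edges <- rbind(
    expand.grid(from = dep, to = med, stringsAsFactors = FALSE),
    data.frame(from = dep, to = response, stringsAsFactors = FALSE),
    data.frame(from = med, to = response, stringsAsFactors = FALSE))
  path_spec(edges, variables = c(dep, med, response))
}
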