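# Community-weighted means, coefficient-of-variation classification and the
# inverse-CV community stability index.

#' Construct and validate a community profile
#'
#' Bundles one site's species list, relative abundances and replicate
#' (quadrat) biomasses.  Abundances must be non-negative and sum to 1
#' within 1e-9; biomasses must be non-negative.
#'
#' @param species_ids character vector of species identifiers.
#' @param relative_abundance numeric vector aligned with `species_ids`.
#' @param biomass_replicates optional species x replicate matrix of biomass
#'   (g); rownames must match `species_ids`.
#' @return list of class `community_profile`.
#' @export
community_profile <- function(species_ids, relative_abundance,
                              biomass_replicates = NULL) {
  p <- as.numeric(relative_abundance)
  if (length(p) != length(species_ids))
    stop_fd("abundance length != species count", class = "dimension_error")
  if (any(p < 0))
    stop_fd("relative abundances must be non-negative", class = "domain_error")
  if (abs(sum(p) - 1) > 1e-9)
    stop_fd("relative abundances must sum to 1 (got %.10f)", sum(p),
            class = "normalization_error")
  if (!is.null(biomass_replicates)) {
    B <- as_numeric_matrix(biomass_replicates, "biomass_replicates")
    if (any(B < 0))
      stop_fd("biomass values must be non-negative", class = "domain_error")
    if (is.null(rownames(B))) rownames(B) <- species_ids
    biomass_replicates <- B
  }
  structure(list(species_ids = as.character(species_ids),
                 relative_abundance = p,
                 biomass_replicates = biomass_replicates),
            class = "community_profile")
}

#' Community-weighted mean of each trait
#'
#' \eqn{CWM_t = \sum_i P_i \, x_{it}} over the community's species.  A
#' missing trait value for any community species makes that trait's CWM
#' missing (no silent renormalization over the remaining species).
#'
#' @param profile a [community_profile()].
#' @param traits species x trait matrix or data.frame with species rownames.
#' @return named numeric vector, one entry per trait; each finite value
#'   lies within the range of the community's species trait values.
#' @export
compute_cwm <- function(profile, traits) {
  stopifnot(inherits(profile, "community_profile"))
  Tm <- traits
  if (is.data.frame(Tm)) Tm <- as.matrix(Tm)
  storage.mode(Tm) <- "double"
  missing_sp <- setdiff(profile$species_ids, rownames(Tm))
  if (length(missing_sp))
    stop_fd("species absent from trait table: %s",
            paste(missing_sp, collapse = ", "), class = "lookup_error")
  X <- Tm[profile$species_ids, , drop = FALSE]
  p <- profile$relative_abundance
  cwm <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (anyNA(xj[p > 0])) return(NA_real_)
    sum(p * ifelse(is.na(xj), 0, xj))
  }, numeric(1))
  names(cwm) <- colnames(X)
  cwm
}

#' Coefficient of variation (percent)
#'
#' 100 x sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L)
    stop_fd("CV needs at least 2 values", class = "domain_error")
  m <- mean(v)
  if (m == 0)
    stop_fd("CV undefined for zero mean", class = "undefined_cv")
  100 * stats::sd(v) / m
}

#' Classify a coefficient of variation
#'
#' Variation bands: weak for CV in `[0, 15]` percent, moderate for
#' `(15, 35]`, large above 35.  The half-open intervals close the gaps the
#' printed anchor points (0-15, 16-35, >36) leave between bands.
#'
#' @param cv CV in percent, >= 0 (vectorized).
#' @return factor with levels weak, moderate, large.
#' @export
classify_cv <- function(cv) {
  cv <- as.numeric(cv)
  if (any(cv < 0))
    stop_fd("CV cannot be negative", class = "domain_error")
  cut(cv, breaks = c(-Inf, 15, 35, Inf),
      labels = c("weak", "moderate", "large"))
}

#' Inverse coefficient of variation of species biomass (community stability)
#'
#' Each species' biomass is first averaged across quadrat replicates; under
#' the default `"across_species"` reading \eqn{\mu} is the mean and
#' \eqn{\sigma} the sample SD of those per-species means, and
#' \eqn{ICV = \mu/\sigma}.  The alternative `"within_species"` reading
#' computes \eqn{\mu_i/\sigma_i} per species across its replicates and
#' averages; the choice is an explicit switch because the verbal definition
#' admits both.  Higher ICV is read as higher community stability.
#'
#' @param profile a [community_profile()] carrying biomass replicates for
#'   at least 2 species.
#' @param method `"across_species"` (default) or `"within_species"`.
#' @return list of class `stability_result` with `icv`, `mu`, `sigma`;
#'   `icv` is `+Inf` (with a warning) when `sigma` is 0.
#' @export
compute_icv <- function(profile, method = c("across_species",
                                            "within_species")) {
  stopifnot(inherits(profile, "community_profile"))
  method <- match.arg(method)
  B <- profile$biomass_replicates
  if (is.null(B) || nrow(B) < 2L)
    stop_fd("ICV needs biomass replicates for at least 2 species",
            class = "domain_error")
  per_species_mean <- rowMeans(B)
  if (method == "across_species") {
    mu <- mean(per_species_mean)
    sigma <- stats::sd(per_species_mean)
    icv <- if (sigma == 0) {
      warning("zero between-species SD: infinite-stability sentinel",
              call. = FALSE)
      Inf
    } else mu / sigma
  } else {
    per_sd <- apply(B, 1L, stats::sd)
    if (any(per_sd == 0))
      warning("zero within-species SD for some species: infinite terms",
              call. = FALSE)
    ratios <- per_species_mean / per_sd
    icv <- mean(ratios)
    mu <- mean(per_species_mean)
    sigma <- mean(per_sd)
  }
  structure(list(icv = icv, mu = mu, sigma = sigma, method = method),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("ICV = %.4f (mu = %.4f, sigma = %.4f, %s reading)\n",
              x$icv, x$mu, x$sigma, x$method))
  invisible(x)
}

site_profile <- function(dataset, site) {
  A <- as_numeric_matrix(dataset$abundance_table, "abundance_table")
  if (!site %in% rownames(A))
    stop_fd("site '%s' not found", site, class = "lookup_error")
  sp <- colnames(A)[A[site, ] > 0]
  p <- A[site, sp]
  B <- NULL
  bt <- dataset$biomass_table
  if (!is.null(bt)) {
    b <- bt[bt$site == site & bt$species %in% sp, , drop = FALSE]
    if (nrow(b)) {
      B <- tapply(b$biomass, list(b$species, b$replicate), mean)
      B <- B[sp[sp %in% rownames(B)], , drop = FALSE]
    }
  }
  community_profile(sp, p / sum(p), B)
}

#' Per-site community-weighted means and stability
#'
#' @param dataset list with `trait_matrix`, `abundance_table`,
#'   `biomass_table` (long format: site, species, replicate, biomass).
#' @param icv_method passed to [compute_icv()].
#' @return data.frame with one row per site: CWM of every trait
#'   (columns `CWM.<trait>`) and `ICV`.
#' @export
site_metrics <- function(dataset, icv_method = "across_species") {
  A <- as_numeric_matrix(dataset$abundance_table, "abundance_table")
  traits <- dataset$trait_matrix
  rows <- lapply(rownames(A), function(s) {
    pr <- site_profile(dataset, s)
    cwm <- compute_cwm(pr, traits)
    icv <- if (!is.null(pr$biomass_replicates) &&
               nrow(pr$biomass_replicates) >= 2L)
      suppressWarnings(compute_icv(pr, icv_method)$icv) else NA_real_
    out <- data.frame(site = s, t(cwm), ICV = icv, stringsAsFactors = FALSE)
    names(out) <- c("site", paste0("CWM.", names(cwm)), "ICV")
    out
  })
  do.call(rbind, rows)
}
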