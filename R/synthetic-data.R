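# Synthetic deposition-gradient communities with known injected effects.
#
# The generator emulates the sampling design of a short spatial gradient
# downwind of emission sources (distances 0-2000 m, three 1x1 m quadrat
# replicates per site) and produces the statistical structure the analysis
# chain assumes: base-cation (BC) ions sharing a latent factor, soil Na
# coupled to that factor, a trait pool with a conservative/acquisitive
# two-factor correlation structure, Gaussian-niche abundances whose
# trait-space breadth shrinks with the BC composite, and replicate
# biomasses whose between-species spread shrinks with community-mean leaf
# thickness.  Every injected effect size is recorded in a truth record.

TRAIT_NAMES <- c("SLA", "LDMC", "LC", "LT", "LD", "LTC", "LTN", "LTP")
DISTANCES <- c(0, 500, 1000, 1500, 2000)

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the emulated field design: 45 sites (3 emission sources
#' x 5 distances x 3 sampling points), 3 quadrat replicates, 8 leaf
#' traits, and a species pool of 30.  `beta_bc_fd` is the standardized
#' effect of the BC deposition composite on (log) community niche breadth;
#' `beta_stability_lt` the standardized effect of community-mean leaf
#' thickness on biomass evenness (hence stability).
#'
#' @param n_sites number of sites (>= 3).
#' @param n_species_pool pool size (>= n_traits + 2).
#' @param n_traits number of leaf traits (default 8).
#' @param n_replicates quadrats per site (default 3).
#' @param beta_bc_fd standardized BC -> dispersion effect (default -0.5).
#' @param beta_stability_lt standardized CWM.LT -> stability effect
#'   (default 0.5).
#' @param noise_sd dimensionless noise multiplier (>= 0; 0 gives exact
#'   distance-trend means).
#' @param bc_soil_na coupling between the BC latent factor and soil Na.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 45L, n_species_pool = 30L,
                             n_traits = 8L, n_replicates = 3L,
                             beta_bc_fd = -0.5, beta_stability_lt = 0.5,
                             noise_sd = 1, bc_soil_na = 0.8, seed = 1L) {
  cfg <- list(
    n_sites = check_count(n_sites, "n_sites", lower = 3L),
    n_species_pool = check_count(n_species_pool, "n_species_pool", lower = 3L),
    n_traits = check_count(n_traits, "n_traits", lower = 1L),
    n_replicates = check_count(n_replicates, "n_replicates", lower = 2L),
    beta_bc_fd = check_number(beta_bc_fd, "beta_bc_fd", -1, 1),
    beta_stability_lt = check_number(beta_stability_lt, "beta_stability_lt",
                                     -1, 1),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
    bc_soil_na = check_number(bc_soil_na, "bc_soil_na", -1, 1),
    seed = check_count(seed, "seed", lower = 0L))
  if (cfg$n_species_pool < cfg$n_traits + 2L)
    stop_fd("n_species_pool must be >= n_traits + 2", class = "invalid_config")
  structure(cfg, class = "synthetic_config")
}

scale1 <- function(x) as.numeric(scale(x))

#' Generate a gradient-structured site-by-covariate environment table
#'
#' Sites cycle through the sampling distances 0, 500, 1000, 1500, 2000 m;
#' every covariate is a distance-decaying deterministic trend plus Gaussian
#' noise scaled by `noise_sd`.  The four BC ions (DCa, DMg, DNa, DK) load
#' on a common latent factor so their first PCA axis is well defined, and
#' soil Na is coupled to that factor with coefficient `bc_soil_na` (its
#' Pearson correlation with the latent at `noise_sd = 1`).
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns site, distance, ion depositions (DSO,
#'   DNO, DNH, DCa, DMg, DNa, DK), DpH, and soil covariates (SOC, STN,
#'   STP, SpH, SCa, SMg, SNa, SK, SAKP, SBG).  Latent factor scores are
#'   attached as attribute `"latents"`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_sites
  ns <- config$noise_sd
  set.seed(child_seed(config$seed, 1L))
  d <- rep(DISTANCES, length.out = n)
  fz <- scale1(exp(-d / 800))

  latent <- function() scale1(fz + ns * stats::rnorm(n))
  mix <- function(load, lat) load * lat + sqrt(1 - load^2) * ns * stats::rnorm(n)

  Lbc <- latent(); Ln <- latent(); Ls <- latent()
  env <- data.frame(
    site = sprintf("site_%03d", seq_len(n)),
    distance = d,
    DSO = 20 + 6 * mix(0.90, Ls),
    DNO = 8 + 2 * mix(0.80, Ln),
    DNH = 6 + 1.5 * mix(0.80, Ln),
    DCa = 12 + 3 * mix(0.95, Lbc),
    DMg = 4 + 1 * mix(0.90, Lbc),
    DNa = 6 + 1.5 * mix(0.85, Lbc),
    DK = 3 + 0.8 * mix(0.80, Lbc),
    DpH = 6.8 - 0.15 * Ls - 0.12 * Ln + 0.1 * ns * stats::rnorm(n),
    SOC = 6 + 1.5 * (0.30 * fz + 0.95 * ns * stats::rnorm(n)),
    STN = 0.25 + 0.06 * (0.30 * fz + 0.95 * ns * stats::rnorm(n)),
    STP = 0.30 + 0.06 * (0.30 * Ln + 0.20 * Lbc + 0.93 * ns * stats::rnorm(n)),
    SpH = 8.9 + 0.15 * (0.25 * Lbc + 0.97 * ns * stats::rnorm(n)),
    SCa = 2.0 + 0.5 * mix(0.60, Lbc),
    SMg = 0.8 + 0.2 * mix(0.55, Lbc),
    SNa = 0.35 + 0.1 * mix(config$bc_soil_na, Lbc),
    SK = 0.5 + 0.12 * mix(0.50, Lbc),
    SAKP = 50 + 10 * (-0.30 * Ln + 0.95 * ns * stats::rnorm(n)),
    SBG = 30 + 8 * (-0.20 * Ls + 0.95 * ns * stats::rnorm(n)),
    stringsAsFactors = FALSE)
  attr(env, "latents") <- list(bc = Lbc, n = Ln, s = Ls)
  env
}

trait_pool <- function(config) {
  k <- config$n_traits
  nm <- if (k <= 8L) TRAIT_NAMES[seq_len(k)] else
    c(TRAIT_NAMES, sprintf("T%d", 9:k))[seq_len(k)]
  # two-factor structure: conservative axis u (LDMC, LTC, LD high, LT
  # opposite) and acquisitive axis v (LTN, SLA)
  lu <- c(SLA = -0.30, LDMC = 0.80, LC = 0.50, LT = -0.80, LD = 0.75,
          LTC = 0.80, LTN = 0.00, LTP = 0.00)
  lv <- c(SLA = 0.60, LDMC = 0.00, LC = 0.20, LT = 0.00, LD = 0.00,
          LTC = 0.00, LTN = 0.70, LTP = 0.35)
  mu <- c(SLA = 8, LDMC = 0.35, LC = 40, LT = 0.30, LD = 0.40,
          LTC = 400, LTN = 20, LTP = 1.5)
  sdv <- c(SLA = 2.5, LDMC = 0.08, LC = 8, LT = 0.08, LD = 0.10,
           LTC = 60, LTN = 5, LTP = 0.4)
  lu <- lu[nm]; lv <- lv[nm]; mu <- mu[nm]; sdv <- sdv[nm]
  lu[is.na(lu)] <- 0.2; lv[is.na(lv)] <- 0.2
  mu[is.na(mu)] <- 10; sdv[is.na(sdv)] <- 2
  np <- config$n_species_pool
  u <- stats::rnorm(np)
  v <- stats::rnorm(np)
  uniq <- pmax(1 - lu^2 - lv^2, 0.15)
  Z <- outer(u, lu) + outer(v, lv) +
    sweep(matrix(stats::rnorm(np * length(nm)), np), 2L, sqrt(uniq), `*`)
  X <- sweep(sweep(Z, 2L, sdv, `*`), 2L, mu, `+`)
  dimnames(X) <- list(sprintf("sp_%02d", seq_len(np)), nm)
  list(traits = X, niche = cbind(u = u, v = v))
}

#' Generate gradient communities with known effect sizes
#'
#' Species trait values are drawn once from a correlated pool
#' distribution.  Per-site abundances follow a Gaussian niche response in
#' the pool's latent trait plane whose breadth is
#' \eqn{\sigma_s = \sigma_0 \exp(\tau(\beta \, BC_s + \sqrt{1-\beta^2}\,\eta_s))}
#' with \eqn{\beta} = `beta_bc_fd` and standardized BC scores, so the
#' injected standardized BC -> dispersion effect equals \eqn{\beta} by
#' construction and realized FRic/FDis decline with BC when \eqn{\beta<0}.
#' Replicate biomasses are drawn with a between-species spread that
#' contracts as community-mean leaf thickness rises (`beta_stability_lt`
#' > 0), so the ICV stability index increases with CWM.LT.
#'
#' @param env environment table from [generate_environment()].
#' @param config the same [synthetic_config()].
#' @return list of class `synthetic_dataset` with `trait_matrix`,
#'   `abundance_table` (rows sum to 1), `biomass_table` (long:
#'   site/species/replicate/biomass), `env_table`, and `truth` (injected
#'   effects and per-site latent quantities).
#' @export
generate_communities <- function(env, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(env) != config$n_sites)
    stop_fd("env has %d sites but config says %d", nrow(env), config$n_sites,
            class = "dimension_error")
  set.seed(child_seed(config$seed, 2L))
  n <- config$n_sites
  np <- config$n_species_pool
  ns <- config$noise_sd

  pool <- trait_pool(config)
  lat <- attr(env, "latents")
  bcz <- if (!is.null(lat)) scale1(lat$bc) else
    scale1(stats::prcomp(scale(env[, c("DCa", "DMg", "DNa", "DK")]))$x[, 1L])

  beta <- config$beta_bc_fd
  tau <- 0.5
  sigma0 <- 0.6
  eta <- stats::rnorm(n)
  log_sigma <- log(sigma0) + tau * (beta * bcz + sqrt(1 - beta^2) * eta)
  sigma <- exp(log_sigma)

  mu_site <- cbind(0.6 * stats::rnorm(n), 0.6 * stats::rnorm(n))
  A <- matrix(0, n, np, dimnames = list(env$site, rownames(pool$traits)))
  for (s in seq_len(n)) {
    d2 <- (pool$niche[, "u"] - mu_site[s, 1L])^2 +
      (pool$niche[, "v"] - mu_site[s, 2L])^2
    ll <- -d2 / (2 * sigma[s]^2) + 0.1 * ns * stats::rnorm(np)
    p <- exp(ll - max(ll))
    p <- p / sum(p)
    p[p < 0.005] <- 0         # detection threshold: rare species unobserved
    p <- p / sum(p)
    A[s, ] <- p
  }

  # community-mean leaf thickness drives biomass evenness between species
  lt_col <- if ("LT" %in% colnames(pool$traits)) "LT" else
    colnames(pool$traits)[1L]
  cwm_lt <- as.numeric(A %*% pool$traits[, lt_col])
  ltz <- scale1(cwm_lt)
  gamma <- exp(-config$beta_stability_lt * ltz)

  reps <- config$n_replicates
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    sp <- which(A[s, ] > 0)
    total <- exp(log(80) + 0.3 * stats::rnorm(1))
    m <- A[s, sp]^gamma[s]
    m <- total * m / sum(m)
    b <- rep(m, each = reps) * exp(0.15 * stats::rnorm(length(sp) * reps))
    rows[[s]] <- data.frame(
      site = env$site[s],
      species = rep(colnames(A)[sp], each = reps),
      replicate = rep(seq_len(reps), times = length(sp)),
      biomass = b, stringsAsFactors = FALSE)
  }

  structure(list(
    trait_matrix = pool$traits,
    abundance_table = A,
    biomass_table = do.call(rbind, rows),
    env_table = env,
    truth = list(beta_bc_fd = beta, beta_stability_lt = config$beta_stability_lt,
                 bc_soil_na = config$bc_soil_na, bc_latent = bcz,
                 log_sigma = log_sigma, gamma = gamma,
                 niche = pool$niche, seed = config$seed)),
    class = "synthetic_dataset")
}

#' Generate a full synthetic dataset in one call
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset`; see [generate_communities()].
#' @export
synth_dataset <- function(config = synthetic_config()) {
  generate_communities(generate_environment(config), config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic gradient dataset: %d sites, %d species pool, %d traits\n",
    nrow(x$abundance_table), ncol(x$abundance_table), ncol(x$trait_matrix)))
  cat(sprintf("  injected effects: beta_bc_fd = %.2f, beta_stability_lt = %.2f\n",
              x$truth$beta_bc_fd, x$truth$beta_stability_lt))
  invisible(x)
}

#' Fixed hand-checkable example dataset
#'
#' A deterministic 5-species, 3-trait, 3-site dataset whose diversity
#' indices are simple enough to verify against the brute-force oracles by
#' hand.  Site 2 carries a zero-abundance species, and the biomass
#' replicates are fixed integers.
#'
#' @return a `synthetic_dataset` (without latent truth effects).
#' @export
worked_example <- function() {
  traits <- matrix(c(0.0, 0.0, 0.1,
                     1.0, 0.1, 0.0,
                     0.1, 1.0, 0.3,
                     0.2, 0.1, 1.0,
                     1.1, 0.9, 0.8),
                   5L, 3L, byrow = TRUE,
                   dimnames = list(paste0("sp", 1:5), c("T1", "T2", "T3")))
  A <- rbind(site1 = c(0.2, 0.2, 0.2, 0.2, 0.2),
             site2 = c(0.4, 0.3, 0.2, 0.1, 0.0),
             site3 = c(0.1, 0.1, 0.2, 0.3, 0.3))
  colnames(A) <- rownames(traits)
  base <- rbind(site1 = c(4, 6, 5, 7, 8),
                site2 = c(10, 8, 6, 4, NA),
                site3 = c(3, 4, 6, 9, 10))
  rows <- list()
  for (s in rownames(A)) for (i in seq_len(5L)) {
    if (A[s, i] == 0 || is.na(base[s, i])) next
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, species = colnames(A)[i], replicate = 1:3,
      biomass = base[s, i] + c(-1, 0, 1), stringsAsFactors = FALSE)
  }
  env <- data.frame(site = rownames(A), distance = c(0, 1000, 2000),
                    DCa = c(15, 12, 10), DMg = c(5, 4, 3.2),
                    DNa = c(7.5, 6, 5), DK = c(3.8, 3, 2.5),
                    DNO = c(10, 8, 7), DNH = c(7.5, 6, 5.2),
                    DSO = c(26, 20, 17), DpH = c(6.4, 6.8, 7.0),
                    stringsAsFactors = FALSE)
  structure(list(trait_matrix = traits, abundance_table = A,
                 biomass_table = do.call(rbind, rows), env_table = env,
                 truth = NULL),
            class = "synthetic_dataset")
}

#' Write a dataset's four tables (CSV) and truth record (JSON) to disk
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.frame(species = rownames(dataset$trait_matrix),
                   dataset$trait_matrix, stringsAsFactors = FALSE,
                   row.names = NULL)
  ab <- data.frame(site = rownames(dataset$abundance_table),
                   dataset$abundance_table, stringsAsFactors = FALSE,
                   row.names = NULL)
  paths <- c(traits = file.path(dir, "traits.csv"),
             abundance = file.path(dir, "abundance.csv"),
             biomass = file.path(dir, "biomass.csv"),
             env = file.path(dir, "env.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(tr, paths["traits"], row.names = FALSE)
  utils::write.csv(ab, paths["abundance"], row.names = FALSE)
  utils::write.csv(dataset$biomass_table, paths["biomass"], row.names = FALSE)
  utils::write.csv(dataset$env_table, paths["env"], row.names = FALSE)
  truth <- dataset$truth
  if (!is.null(truth)) {
    truth$niche <- NULL
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  } else {
    jsonlite::write_json(list(), paths["truth"], auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Read a dataset previously written by [write_dataset()]
#' @param dir directory containing traits/abundance/biomass/env CSVs.
#' @return a `synthetic_dataset` (truth present only if stored).
#' @export
read_dataset <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "traits.csv"),
                        stringsAsFactors = FALSE)
  traits <- as.matrix(tr[, -1L, drop = FALSE])
  rownames(traits) <- tr[[1L]]
  ab <- utils::read.csv(file.path(dir, "abundance.csv"),
                        stringsAsFactors = FALSE)
  A <- as.matrix(ab[, -1L, drop = FALSE])
  rownames(A) <- ab[[1L]]
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  if (is.list(truth) && !length(truth)) truth <- NULL
  structure(list(
    trait_matrix = traits, abundance_table = A,
    biomass_table = utils::read.csv(file.path(dir, "biomass.csv"),
                                    stringsAsFactors = FALSE),
    env_table = utils::read.csv(file.path(dir, "env.csv"),
                                stringsAsFactors = FALSE),
    truth = truth), class = "synthetic_dataset")
}
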