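# End-to-end orchestration: synthesize or load the four input tables, run
# metrics -> diversity -> ordination -> association -> path stages, and
# write every stage's artifact plus a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input_dir directory with traits/abundance/biomass/env CSVs
#'   (see [write_dataset()]); `NULL` requests synthesis.
#' @param synth a [synthetic_config()] used when `input_dir` is `NULL`.
#' @param out_dir output directory for stage artifacts.
#' @param weighting abundance weighting for the diversity indices
#'   (`"abundance"` or `"biomass"`).
#' @param hull_dim FRic hull dimensionality cap (1-3).
#' @param icv_method ICV aggregation reading (see [compute_icv()]).
#' @param n_perm Mantel permutations.
#' @param delta_cutoff,max_predictors multimodel-averaging options.
#' @param alpha pruning significance threshold.
#' @param seed master seed; per-stage child seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synth = synthetic_config(),
                            out_dir = tempfile("fdgradient_run_"),
                            weighting = c("abundance", "biomass"),
                            hull_dim = 3L,
                            icv_method = c("across_species",
                                           "within_species"),
                            n_perm = 999L, delta_cutoff = 4,
                            max_predictors = 3L, alpha = 0.05, seed = 1L) {
  structure(list(
    input_dir = input_dir, synth = synth, out_dir = out_dir,
    weighting = match.arg(weighting),
    hull_dim = check_count(hull_dim, "hull_dim", lower = 1L),
    icv_method = match.arg(icv_method),
    n_perm = check_count(n_perm, "n_perm", lower = 1L),
    delta_cutoff = check_number(delta_cutoff, "delta_cutoff", lower = 0),
    max_predictors = check_count(max_predictors, "max_predictors", lower = 1L),
    alpha = check_number(alpha, "alpha", lower = 0, upper = 1),
    seed = check_count(seed, "seed", lower = 0L)),
    class = "pipeline_config")
}

#' Validate the four input tables
#'
#' Report-only checks: abundance rows sum to 1, abundances and biomasses
#' non-negative, site keys aligned across tables, every abundant species
#' present in the trait table, no missing trait values.
#'
#' @param dataset a `synthetic_dataset` (or list with the same tables).
#' @return data.frame of violations (`table`, `where`, `issue`); zero rows
#'   when clean.
#' @export
validate_inputs <- function(dataset) {
  v <- list()
  add <- function(table, where, issue)
    v[[length(v) + 1L]] <<- data.frame(table = table, where = where,
                                       issue = issue, stringsAsFactors = FALSE)
  A <- dataset$abundance_table
  for (s in rownames(A)) {
    if (any(A[s, ] < 0))
      add("abundance", s, "negative abundance")
    tot <- sum(A[s, ])
    if (abs(tot - 1) > 1e-9)
      add("abundance", s, sprintf("row sums to %.6f, not 1", tot))
  }
  sp_missing <- setdiff(colnames(A)[colSums(A > 0) > 0],
                        rownames(dataset$trait_matrix))
  for (sp in sp_missing)
    add("traits", sp, "species missing from trait table")
  if (anyNA(dataset$trait_matrix)) {
    na_sp <- rownames(dataset$trait_matrix)[
      apply(dataset$trait_matrix, 1L, anyNA)]
    for (sp in na_sp) add("traits", sp, "missing trait value")
  }
  bt <- dataset$biomass_table
  if (!is.null(bt)) {
    bad <- which(bt$biomass < 0)
    for (i in bad)
      add("biomass", sprintf("row %d (%s/%s)", i, bt$site[i], bt$species[i]),
          "negative biomass")
    extra <- setdiff(unique(bt$site), rownames(A))
    for (s in extra) add("biomass", s, "site absent from abundance table")
  }
  env <- dataset$env_table
  if (!is.null(env)) {
    for (s in setdiff(env$site, rownames(A)))
      add("env", s, "site absent from abundance table")
    for (s in setdiff(rownames(A), env$site))
      add("abundance", s, "site absent from env table")
    if (anyNA(env[vapply(env, is.numeric, TRUE)]))
      add("env", "(any)", "missing covariate values")
  }
  if (!length(v))
    return(data.frame(table = character(0), where = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

dep_composites <- function(env) {
  data.frame(
    site = env$site,
    Sdep = scale1(env$DSO),
    Ndep = build_composite(env[, c("DNO", "DNH")])$scores,
    BCdep = build_composite(env[, c("DCa", "DMg", "DNa", "DK")])$scores,
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes synthesize/load -> validate -> community metrics -> diversity
#' indices -> CWM PCA -> Spearman/Mantel screening -> stability
#' regressions -> AICc averaging -> composite construction and path-model
#' pruning, writing one artifact per stage plus a manifest with the seed,
#' configuration and MD5 checksums (identical config and seed reproduce
#' identical checksums).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  dataset <- if (is.null(config$input_dir)) {
    synth <- config$synth
    synth$seed <- config$seed
    class(synth) <- "synthetic_config"
    synth_dataset(synth)
  } else read_dataset(config$input_dir)
  write_dataset(dataset, file.path(config$out_dir, "data"))

  viol <- validate_inputs(dataset)
  if (nrow(viol))
    stop_fd("stage validate: %d violation(s); first: %s / %s / %s",
            nrow(viol), viol$table[1L], viol$where[1L], viol$issue[1L],
            class = "validation_error")

  metrics <- site_metrics(dataset, icv_method = config$icv_method)
  utils::write.csv(metrics, out("site_metrics.csv"), row.names = FALSE)

  fd <- fd_table(dataset, weighting = config$weighting,
                 hull_dim = config$hull_dim)
  utils::write.csv(fd, out("fd_indices.csv"), row.names = FALSE)

  cwm_cols <- grep("^CWM\\.", names(metrics), value = TRUE)
  pca <- cwm_pca(metrics[, c("site", cwm_cols)])
  utils::write.csv(data.frame(trait = rownames(pca$loadings),
                              pca$loadings, row.names = NULL),
                   out("pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site = rownames(pca$scores), pca$scores,
                              row.names = NULL),
                   out("pca_scores.csv"), row.names = FALSE)
  env <- dataset$env_table
  utils::write.csv(axis_env_table(pca, env), out("axis_env_r2.csv"),
                   row.names = FALSE)

  env_num <- env[, setdiff(names(env)[vapply(env, is.numeric, TRUE)],
                           "distance"), drop = FALSE]
  screen_tab <- cbind(fd[, c("fric", "feve", "fdis", "raoq")],
                      ICV = metrics$ICV, env_num)
  sp <- spearman_matrix(screen_tab)
  utils::write.csv(data.frame(variable = rownames(sp$rho), sp$rho,
                              row.names = NULL),
                   out("spearman_rho.csv"), row.names = FALSE)

  dep_cols <- intersect(c("DSO", "DNO", "DNH", "DCa", "DMg", "DNa", "DK",
                          "DpH"), names(env_num))
  soil_cols <- setdiff(names(env_num), dep_cols)
  blocks <- list(deposition = dep_cols)
  if (length(soil_cols) >= 2L) blocks$soil <- soil_cols
  mantel_rows <- list()
  stage_seed <- child_seed(config$seed, 3L)
  for (idx in c("fric", "feve", "fdis", "raoq")) {
    keep <- !is.na(fd[[idx]])
    if (sum(keep) < 4L) next
    d_idx <- as.matrix(stats::dist(scale1(fd[[idx]][keep])))
    for (bl in names(blocks)) {
      d_env <- as.matrix(stats::dist(scale(env_num[keep, blocks[[bl]]])))
      mt <- mantel_test(d_idx, d_env, n_perm = config$n_perm,
                        seed = stage_seed)
      mantel_rows[[length(mantel_rows) + 1L]] <- data.frame(
        index = idx, block = bl, r = mt$r_obs, p_value = mt$p_value,
        n_perm = mt$n_perm, seed = mt$seed, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, mantel_rows), out("mantel_tests.csv"),
                   row.names = FALSE)

  reg_rows <- list()
  for (v in c("fric", "feve", "fdis", "raoq", cwm_cols)) {
    x <- if (v %in% names(fd)) fd[[v]] else metrics[[v]]
    if (sum(stats::complete.cases(x, metrics$ICV)) < 3L ||
        stats::sd(x, na.rm = TRUE) == 0) next
    r <- simple_regression(x, metrics$ICV)
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      predictor = v, response = "ICV", slope = r$slope,
      intercept = r$intercept, r_squared = r$r_squared,
      p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, reg_rows), out("regressions.csv"),
                   row.names = FALSE)

  avg_cols <- intersect(c("DCa", "DMg", "DNa", "DNH", "DpH", "DSO",
                          "SAKP", "SBG", "SOC", "SpH", "STP"),
                        names(env_num))
  avg_rows <- list(); rank_rows <- list()
  for (idx in c("fric", "feve", "fdis", "raoq")) {
    keep <- !is.na(fd[[idx]])
    if (sum(keep) < length(avg_cols) + 5L) next
    ma <- all_subsets_average(fd[[idx]][keep], env_num[keep, avg_cols],
                              max_predictors = config$max_predictors,
                              delta_cutoff = config$delta_cutoff)
    avg_rows[[idx]] <- data.frame(index = idx, ma$coefficients,
                                  stringsAsFactors = FALSE)
    top <- utils::head(ma$models, 10L)
    rank_rows[[idx]] <- data.frame(index = idx, top,
                                   stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, avg_rows), out("model_averaging.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, rank_rows), out("model_ranking.csv"),
                   row.names = FALSE)

  comp <- dep_composites(env)
  sem_data <- data.frame(comp[, c("Sdep", "Ndep", "BCdep")],
                         scale(env[, intersect(c("DpH", "SOC", "STP", "SpH",
                                                 "SAKP", "SBG"),
                                               names(env))]),
                         FRic = scale1(fd$fric), FEve = scale1(fd$feve),
                         FDis = scale1(fd$fdis), RaoQ = scale1(fd$raoq))
  edge_rows <- list(); fit_stats <- list(); prune_rows <- list()
  for (resp in c("FRic", "FEve", "FDis", "RaoQ")) {
    spec <- prior_model(resp)
    rows <- stats::complete.cases(sem_data[, spec$variables])
    if (sum(rows) < length(spec$variables) + 2L) next
    sub <- sem_data[rows, , drop = FALSE]
    pruned <- prune_model(spec, sub, alpha = config$alpha)
    prior_fit <- fit_path_model(spec, sub)
    edge_rows[[resp]] <- rbind(
      data.frame(response = resp, stage = "prior", prior_fit$edges,
                 stringsAsFactors = FALSE),
      if (!is.null(pruned$fit))
        data.frame(response = resp, stage = "final", pruned$fit$edges,
                   stringsAsFactors = FALSE))
    f <- pruned$fit %||% prior_fit
    fit_stats[[resp]] <- list(chi2 = f$chi2, df = f$df, chi2_p = f$chi2_p,
                              gfi = f$gfi, rmsea = f$rmsea, n = f$n,
                              acceptable = path_fit_acceptable(f))
    if (nrow(pruned$log))
      prune_rows[[resp]] <- data.frame(response = resp, pruned$log,
                                       stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, edge_rows), out("path_edges.csv"),
                   row.names = FALSE)
  jsonlite::write_json(fit_stats, out("path_fit.json"), auto_unbox = TRUE,
                       digits = NA)
  prune_log <- if (length(prune_rows)) do.call(rbind, prune_rows) else
    data.frame(response = character(0), from = character(0),
               to = character(0), p_value = numeric(0))
  utils::write.csv(prune_log, out("pruning_log.csv"), row.names = FALSE)

  artifacts <- c("site_metrics.csv", "fd_indices.csv", "pca_loadings.csv",
                 "pca_scores.csv", "axis_env_r2.csv", "spearman_rho.csv",
                 "mantel_tests.csv", "regressions.csv",
                 "model_averaging.csv", "model_ranking.csv",
                 "path_edges.csv", "path_fit.json", "pruning_log.csv")
  sums <- tools::md5sum(vapply(artifacts, out, character(1)))
  names(sums) <- artifacts
  manifest <- list(
    package_version = as.character(utils::packageVersion("fdgradient")),
    seed = config$seed,
    config = config[setdiff(names(config), c("synth", "out_dir"))],
    synth = if (is.null(config$input_dir)) unclass(config$synth) else NULL,
    n_sites = nrow(fd), n_species_pool = ncol(dataset$abundance_table),
    artifacts = as.list(sums))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
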