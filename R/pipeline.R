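#' @title End-to-end analysis pipeline
#'
#' @description
#' Orchestrates the full analysis from a declarative config list and writes
#' the headline artifacts: the rate-matrix correlation table, the per-pair
#' Arrhenius partition and predictions, regression summaries, and
#' (optionally) the cross-validated classifier report. Every stage is a pure
#' function of the inputs, the config and the seeds, so two runs of the same
#' config are identical.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param ddg_path Path to a ddG matrix CSV; `NULL` uses the bundled
#'   proteome matrix.
#' @param scan_path Optional site-scan table to summarize instead of reading
#'   a matrix.
#' @param dat_paths Named character vector of PAML dat files; defaults to
#'   the bundled DSO78/JTT/LG fixtures.
#' @param reference Name of the empirical matrix that anchors the partition
#'   (default `"LG"`).
#' @param metric Proximity metric for [assign_arrhenius_groups()].
#' @param params [arrhenius_params()].
#' @param run_classifier Run the ML stage (default FALSE; it dominates the
#'   runtime).
#' @param classifier_models,grid_size Passed to [train_evaluate()].
#' @param seed Integer seed for all stochastic stages.
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir,
                            ddg_path = NULL,
                            scan_path = NULL,
                            dat_paths = c(
                              DSO78 = substitution_model_file("dayhoff"),
                              JTT = substitution_model_file("jones"),
                              LG = substitution_model_file("lg")),
                            reference = "LG",
                            metric = "linear_vertical",
                            params = arrhenius_params(),
                            run_classifier = FALSE,
                            classifier_models = "random_forest",
                            grid_size = 27,
                            seed = 1) {
  list(out_dir = out_dir, ddg_path = ddg_path, scan_path = scan_path,
       dat_paths = dat_paths, reference = reference, metric = metric,
       params = params, run_classifier = run_classifier,
       classifier_models = classifier_models, grid_size = grid_size,
       seed = seed)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain the ddG matrix (bundled fixture, CSV, or a site-scan
#' summarization); (2) build normalized rate matrices from the dat files and
#' verify detailed balance; (3) fit the single-factor Arrhenius model,
#' partition the pairs against the reference matrix, predict rates and
#' correlate all matrices; (4) optionally run the genetic-code classifier.
#' Artifacts written to `config$out_dir`: `q_correlations.csv`,
#' `pair_table.csv`, `comparison.json`, `rank_association.json`,
#' optionally `ml_performance.csv`, plus `run_log.txt` with input checksums
#' and parameters.
#'
#' @param config List from [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("seed:", config$seed),
                 paste("reference:", config$reference),
                 paste("metric:", config$metric),
                 paste("a_levels:", paste(config$params$a_levels, collapse = " ")),
                 paste("b:", config$params$b))

  # stage 1: ddG matrix
  if (!is.null(config$scan_path)) {
    if (!file.exists(config$scan_path))
      stop("missing input: site-scan table ", config$scan_path, call. = FALSE)
    ddg <- summarize_site_scans(read_site_scans(config$scan_path))
    log_lines <- c(log_lines, paste("ddg from scans:", config$scan_path,
                                    unname(tools::md5sum(config$scan_path))))
  } else if (!is.null(config$ddg_path)) {
    if (!file.exists(config$ddg_path))
      stop("missing input: ddG matrix ", config$ddg_path, call. = FALSE)
    ddg <- read_ddg_matrix(config$ddg_path)
    log_lines <- c(log_lines, paste("ddg:", config$ddg_path,
                                    unname(tools::md5sum(config$ddg_path))))
  } else {
    ddg <- ddg_human_proteome()
    log_lines <- c(log_lines, "ddg: bundled proteome fixture")
  }
  E <- offdiagonal_vector(energy_barrier(ddg))

  # stage 2: empirical rate matrices
  missing <- config$dat_paths[!file.exists(config$dat_paths)]
  if (length(missing))
    stop("missing input: dat file ", paste(missing, collapse = ", "),
         call. = FALSE)
  rate_mats <- lapply(config$dat_paths, function(p) {
    parsed <- parse_paml_dat(p)
    build_rate_matrix(parsed$S, parsed$pi, normalize = TRUE)
  })
  for (nm in names(rate_mats)) {
    viol <- check_detailed_balance(rate_mats[[nm]])
    log_lines <- c(log_lines, paste0("detailed balance ", nm, ": ",
                                     format(viol)))
    if (viol > 1e-10)
      warning("detailed balance violated for ", nm)
  }
  q_emp <- lapply(rate_mats, offdiagonal_rates)

  # stage 3: Arrhenius model
  if (!config$reference %in% names(q_emp))
    stop("reference matrix ", config$reference, " not among dat inputs",
         call. = FALSE)
  q_ref <- q_emp[[config$reference]]
  sfit <- single_factor_fit(E, q_ref)
  groups <- assign_arrhenius_groups(E, q_ref, config$params, config$metric)
  q_hat <- predict_rates(E, groups, config$params)
  comparisons <- lapply(q_emp, function(q) compare_matrices(q_hat, q))
  ctab <- correlation_table(c(q_emp, list(Q_Arrh = q_hat)))
  rank_assoc <- rank_association(ddg)

  utils::write.csv(as.data.frame(ctab),
                   file.path(config$out_dir, "q_correlations.csv"),
                   row.names = TRUE)
  pair_table <- data.frame(canonical_pairs(), E = E,
                           do.call(cbind, q_emp),
                           group = groups,
                           a = config$params$a_levels[groups],
                           q_hat = q_hat)
  utils::write.csv(pair_table, file.path(config$out_dir, "pair_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(single_factor = sfit, comparisons = comparisons),
    file.path(config$out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    rank_assoc[c("r_squared", "p_value", "slope_sign")],
    file.path(config$out_dir, "rank_association.json"),
    auto_unbox = TRUE, digits = NA)

  # stage 4: classifier (optional)
  ml <- NULL
  if (isTRUE(config$run_classifier)) {
    feats <- preprocess_features(feature_table())
    ml <- train_evaluate(feats, groups, models = config$classifier_models,
                         grid_size = config$grid_size, seed = config$seed)
    utils::write.csv(ml, file.path(config$out_dir, "ml_performance.csv"),
                     row.names = FALSE)
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(ddg = ddg, E = E, rate_matrices = rate_mats,
                 single_factor = sfit, groups = groups, q_hat = q_hat,
                 comparisons = comparisons, correlations = ctab,
                 rank_association = rank_assoc, ml = ml))
}
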