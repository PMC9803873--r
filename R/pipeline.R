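#' Build and validate a full-analysis run configuration
#'
#' Exactly one of `expression`/`metadata` paths (with optional `gmt`) or a
#' `simulate` block (arguments for [cohort_config()]) must be given.
#'
#' @param expression,metadata,gmt Input file paths (load mode).
#' @param simulate Named list of [cohort_config()] arguments (simulate mode).
#' @param period Period in hours (default 24).
#' @param fdr FDR threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param ora_min_set ORA minimum query members per set (default 20).
#' @param psea_min_set PSEA minimum diurnal members per set (default 5).
#' @param sumabsv_grid,nspc_grid Predictor CV grids.
#' @param outlier_k Outlier-flagging SD multiplier (default 4).
#' @param use_wall_time Use wall instead of internal time as the time axis
#'   (sensitivity analysis; default FALSE).
#' @param moderate Moderate cosinor residual variances (default TRUE for
#'   the full pipeline).
#' @param output_dir Output directory (default "skindiurnal_run").
#' @param seed Integer seed for all randomness.
#' @return Validated config of class `run_config`.
#' @export
run_config <- function(expression = NULL, metadata = NULL, gmt = NULL,
                       simulate = NULL, period = 24, fdr = 0.05,
                       fc_threshold = 1.5, ora_min_set = 20, psea_min_set = 5,
                       sumabsv_grid = c(1, 1.5, 2, 3), nspc_grid = c(2, 3),
                       outlier_k = 4, use_wall_time = FALSE, moderate = TRUE,
                       output_dir = "skindiurnal_run", seed = 1) {
  has_files <- !is.null(expression) || !is.null(metadata)
  if (has_files == !is.null(simulate))
    stopf("exactly one of input files or a simulate block must be given")
  if (has_files && (is.null(expression) || is.null(metadata)))
    stopf("load mode needs both expression and metadata paths")
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) stopf("fdr must lie in (0, 1)")
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stopf("fc_threshold must exceed 1")
  if (period <= 0) stopf("period must be positive")
  if (outlier_k < 0) stopf("outlier_k must be non-negative")
  structure(list(expression = expression, metadata = metadata, gmt = gmt,
                 simulate = simulate, period = period, fdr = fdr,
                 fc_threshold = fc_threshold, ora_min_set = ora_min_set,
                 psea_min_set = psea_min_set, sumabsv_grid = sumabsv_grid,
                 nspc_grid = nspc_grid, outlier_k = outlier_k,
                 use_wall_time = use_wall_time, moderate = moderate,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full diurnal-rhythm analysis
#'
#' Stages: input (load or simulate) -> outlier flagging -> per-layer
#' population rhythm scans -> differential-rhythmicity categorization ->
#' mixed-model variability table (genes rhythmic in at least one layer) ->
#' ORA and PSEA (when gene sets are available) -> leave-one-subject-out
#' predictor CV per layer.  Per-stage TSVs, a JSON summary and a log are
#' written under `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param max_variability_genes Cap on the number of genes sent to the
#'   mixed-model stage (keeps runtime bounded; default 200, NULL = no cap).
#' @return The summary list, invisibly.
#' @export
run_full_analysis <- function(config, max_variability_genes = 200) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  logf <- file.path(config$output_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat(sprintf("skindiurnal %s | R %s | seed %d | fdr %g | fc %g | period %g\n",
              as.character(utils::packageVersion("skindiurnal")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed, config$fdr, config$fc_threshold, config$period),
      file = logf)

  truth <- NULL
  collections <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("input", {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      simulate_cohort(do.call(cohort_config, args))
    })
    mat <- sim$matrix; records <- sim$records; truth <- sim$truth
    log_line("input: simulated ", nrow(mat), " genes x ", ncol(mat), " samples")
  } else {
    mat <- stage("input", load_expression(config$expression,
                                          dialect_of(config$expression)))
    records <- stage("input", load_metadata(config$metadata,
                                            dialect_of(config$metadata)))
    records <- to_internal_time(records)
    validate_records(records, mat, require_internal = TRUE)
    log_line("input: loaded ", nrow(mat), " genes x ", ncol(mat), " samples")
  }
  if (!is.null(config$gmt)) collections <- stage("input", load_gmt(config$gmt))
  if (config$use_wall_time) records$internal_time_h <- records$wall_time_h

  flagged <- stage("outliers", {
    by_layer <- lapply(unique(records$layer), function(L) {
      ids <- records$sample_id[records$layer == L]
      flag_outlier_samples(mat[, ids, drop = FALSE], config$outlier_k)
    })
    unique(unlist(by_layer))
  })
  log_line("outliers flagged: ", if (length(flagged)) paste(flagged, collapse = ", ") else "none")
  if (length(flagged) > 0L) {
    keep <- setdiff(colnames(mat), flagged)
    mat <- mat[, keep, drop = FALSE]
    records <- records[records$sample_id %in% keep, ]
  }

  layers <- sort(unique(records$layer))
  scans <- stage("rhythms", lapply(layers, function(L)
    layerwise_rhythm_scan(mat, records, L, config$period,
                          moderate = config$moderate)))
  names(scans) <- layers
  for (L in layers)
    utils::write.table(scans[[L]],
                       file.path(config$output_dir, paste0("rhythms_", L, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  diff_tab <- stage("differential", {
    categorize(differential_rhythm_scan(mat, records, config$period),
               fdr = config$fdr, fc_threshold = config$fc_threshold)
  })
  utils::write.table(diff_tab, file.path(config$output_dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat_summary <- summarize_categories(diff_tab)

  rhythmic_sets <- rhythmic_genes_by_layer(diff_tab)
  rhythmic_any <- unique(unlist(rhythmic_sets))
  phase_pairs <- diff_tab[diff_tab$category %in%
                            c("both_indistinguishable", "both_differential"), ]
  phase_stats <- if (nrow(phase_pairs) > 0L)
    circular_phase_stats(phase_pairs[[paste0("acrophase_h_", layers[1])]],
                         phase_pairs[[paste0("acrophase_h_", layers[2])]],
                         config$period)
  else list(mean_difference_h = NA, rayleigh_R = NA, p_value = NA, n = 0)

  vg <- rhythmic_any
  if (!is.null(max_variability_genes) && length(vg) > max_variability_genes)
    vg <- vg[seq_len(max_variability_genes)]
  var_tab <- stage("variability", variability_table(mat, records, vg, config$period))
  if (nrow(var_tab) > 0L)
    utils::write.table(var_tab, file.path(config$output_dir, "variability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  enr <- list(ora = NULL, psea = NULL)
  if (!is.null(collections)) {
    enr <- stage("enrichment", {
      query <- rhythmic_sets[[1]]
      background <- rownames(mat)
      phases <- diff_tab[[paste0("acrophase_h_", layers[1])]]
      names(phases) <- diff_tab$gene_id
      list(ora = hypergeom_ora(query, collections, background,
                               min_set = config$ora_min_set),
           psea = psea(phases[rhythmic_any], collections,
                       min_set = config$psea_min_set, period = config$period))
    })
    utils::write.table(enr$ora, file.path(config$output_dir, "ora.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr$psea, file.path(config$output_dir, "psea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cvs <- stage("predictor", lapply(layers, function(L) {
    rec <- records[records$layer == L, ]
    loso_cv(mat[, rec$sample_id, drop = FALSE], rec,
            sumabsv_grid = config$sumabsv_grid, nspc_grid = config$nspc_grid,
            period = config$period)
  }))
  names(cvs) <- layers
  cv_grids <- lapply(cvs, function(cv) cv$grid)
  for (L in layers)
    utils::write.table(cv_grids[[L]],
                       file.path(config$output_dir, paste0("predictor_cv_", L, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    input = list(n_genes = nrow(mat), n_samples = ncol(mat),
                 n_subjects = length(unique(records$subject_id)),
                 layers = as.list(stats::setNames(
                   as.integer(table(records$layer)[layers]), layers)),
                 outliers_flagged = flagged, seed = config$seed),
    rhythms = lapply(scans, function(s) {
      amp_ok <- s$fold_change > config$fc_threshold
      list(n_genes = nrow(s),
           n_q_below_fdr = sum(s$q < config$fdr),
           n_q_and_fc = sum(s$q < config$fdr & amp_ok))
    }),
    differential = c(cat_summary,
                     list(mean_phase_difference_h = phase_stats$mean_difference_h,
                          rayleigh_R = phase_stats$rayleigh_R,
                          rayleigh_p = phase_stats$p_value)),
    variability = list(
      n_genes = nrow(var_tab),
      median_f_m = stats::median(var_tab$f_m, na.rm = TRUE),
      median_f_A = stats::median(var_tab$f_A, na.rm = TRUE),
      median_f_phase = stats::median(var_tab$f_phase, na.rm = TRUE)),
    enrichment = list(
      n_ora_sets_tested = if (is.null(enr$ora)) 0L else nrow(enr$ora),
      n_ora_significant = if (is.null(enr$ora)) 0L else sum(enr$ora$q < config$fdr),
      n_psea_sets_tested = if (is.null(enr$psea)) 0L else nrow(enr$psea),
      n_psea_significant = if (is.null(enr$psea)) 0L else sum(enr$psea$significant)),
    predictor = lapply(cv_grids, function(g) {
      b <- g[which.min(g$mae_h), ]
      list(best_sumabsv = b$sumabsv, best_nspc = b$nSPC,
           best_mae_h = b$mae_h, n_genes_selected = b$n_genes_selected)
    })
  )
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(summary)
}

dialect_of <- function(path) if (grepl("\\.csv$", path)) "csv" else "tsv"

#' Count genes per rhythmicity category and per-layer totals
#'
#' Per-layer totals follow the partition identity: a layer's total equals
#' the indistinguishable genes + its layer-only genes + the differential
#' genes whose fold change in that layer exceeds the threshold.
#'
#' @param categorized Output of [categorize()].
#' @return List: per-category counts and `total_<layer>` per layer.
#' @export
summarize_categories <- function(categorized) {
  layers <- attr(categorized, "layers")
  if (is.null(layers)) stopf("input must come from categorize()")
  known <- c("not_rhythmic", "both_indistinguishable", "both_differential",
             paste0(layers, "_only"))
  bad <- setdiff(unique(categorized$category), known)
  if (length(bad) > 0L)
    stopf("unknown category label(s): %s", paste(bad, collapse = ", "))
  counts <- lapply(known, function(k) sum(categorized$category == k))
  names(counts) <- known
  per_layer <- rhythmic_genes_by_layer(categorized)
  for (L in layers) counts[[paste0("total_", L)]] <- length(per_layer[[L]])
  counts
}
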