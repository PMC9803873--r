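#' Read a genes x samples log2 expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers, returning a numeric matrix of
#' log2 intensities.  Duplicate gene rows are rejected: probe-level matrices
#' must be collapsed with [average_probes_to_genes()] first.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @seealso [load_metadata()], [average_probes_to_genes()]
#' @export
load_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(header) < 2L) stopf("missing or malformed header row in %s", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stopf("duplicated gene id(s) in %s: %s (average probes to genes first)",
          path, paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-numeric or non-finite expression value at gene '%s', sample '%s'",
          gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]])
  dimnames(num) <- list(gene_ids, colnames(vals))
  num
}

#' Read a sample metadata table
#'
#' Expected columns: `sample_id`, `subject_id`, `layer` (exactly two labels,
#' canonically `dermis`/`epidermis`), `wall_time_h` (hours since study-day
#' midnight; unwrapped, so a final sample at 32 h stays 32) and `msf_sc_h`
#' (chronotype as sleep-corrected mid-sleep on free days, hours).
#' Internal time is added by [to_internal_time()].
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A data.frame of sample records.
#' @export
load_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_records(df, require_internal = FALSE)
  df
}

#' Validate a sample-record table against an expression matrix
#' @noRd
validate_records <- function(records, matrix = NULL, require_internal = FALSE) {
  need <- c("sample_id", "subject_id", "layer", "wall_time_h", "msf_sc_h")
  if (require_internal) need <- c(need, "internal_time_h")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  layers <- unique(records$layer)
  if (length(layers) > 2L)
    stopf("more than two layer labels found: %s", paste(layers, collapse = ", "))
  key <- paste(records$subject_id, records$layer, records$wall_time_h)
  if (anyDuplicated(key))
    stopf("duplicated (subject, layer, wall_time) combination: %s",
          key[duplicated(key)][1])
  if (!is.null(matrix)) {
    if (!setequal(colnames(matrix), records$sample_id))
      stopf("expression sample ids do not match metadata sample ids")
  }
  invisible(records)
}

#' Convert wall time to internal (chronotype-corrected) time
#'
#' Internal time is wall time minus the subject's chronotype MSF_sc
#' (mid-sleep on free days, sleep-debt corrected), so hour 0 is the
#' individual's mid-sleep.  Times are kept unwrapped (they may exceed 24 h);
#' periodic model fits reduce time modulo the period internally.
#'
#' @param records Data.frame with `wall_time_h` and `msf_sc_h` columns.
#' @return The same data.frame with `internal_time_h` populated.
#' @export
to_internal_time <- function(records) {
  if (is.null(records$wall_time_h) || is.null(records$msf_sc_h))
    stopf("records need wall_time_h and msf_sc_h columns")
  bad <- !is.finite(records$msf_sc_h)
  if (any(bad))
    stopf("missing MSF_sc for subject(s): %s",
          paste(unique(records$subject_id[bad]), collapse = ", "))
  records$internal_time_h <- records$wall_time_h - records$msf_sc_h
  records
}

#' Average probe rows mapping to the same gene
#'
#' Collapses a probes x samples matrix to genes x samples by taking the
#' arithmetic mean of each gene's probe rows on the log2 scale.  Probes
#' absent from the mapping are dropped (a message reports the count).
#'
#' @param probe_matrix Numeric matrix with probe ids as rownames.
#' @param probe_to_gene Named character vector: names = probe ids,
#'   values = gene ids.
#' @return Genes x samples numeric matrix.
#' @export
average_probes_to_genes <- function(probe_matrix, probe_to_gene) {
  if (length(probe_to_gene) == 0L) stopf("empty probe-to-gene mapping")
  probes <- rownames(probe_matrix)
  mapped <- probes %in% names(probe_to_gene)
  if (sum(!mapped) > 0L)
    message(sum(!mapped), " unmapped probe(s) dropped")
  pm <- probe_matrix[mapped, , drop = FALSE]
  genes <- probe_to_gene[rownames(pm)]
  out <- rowsum(pm, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(out)])
  out <- out / counts
  out
}

#' Flag samples far from the centroid in PC1-PC2 space
#'
#' Projects samples onto the first two principal components of the
#' expression matrix and flags samples whose Euclidean distance from the
#' centroid exceeds the mean distance by more than `k` standard deviations
#' of the distances (a z-score rule on the centroid distance).  This is a
#' screening aid; the caller decides removal.
#'
#' When samples form well-separated clusters (e.g. two skin layers split
#' along PC1), every sample sits far from the global centroid at a nearly
#' constant distance, which makes this rule degenerate; flag within each
#' cluster (layer) instead, as [run_full_analysis()] does.
#'
#' @param matrix Genes x samples numeric matrix (>= 3 samples).
#' @param k SD multiplier (default 4).  `k = 0` degenerates to flagging
#'   every sample whose distance exceeds the mean distance.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(matrix, k = 4) {
  if (ncol(matrix) < 3L) stopf("need at least 3 samples to flag outliers")
  x <- t(matrix)
  x <- sweep(x, 2, colMeans(x))
  npc <- min(2L, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = npc, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(npc)], npc, npc)
  d <- sqrt(rowSums(sweep(scores, 2, colMeans(scores))^2))
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) return(character(0))
  colnames(matrix)[d > mean(d) + k * s]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (duplicates within a set removed);
#'   attribute `"description"` holds the per-set description.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stopf("GMT line %d has fewer than 3 fields", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (any(vapply(sets, length, 1L) == 0L)) stopf("GMT contains an empty set")
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
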