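#' Joint two-layer cosinor fit for one gene
#'
#' Single least-squares fit with layer-specific intercept, cosine and sine
#' terms (6 coefficients).  Because the design is block-diagonal by layer,
#' the joint coefficients equal two independent per-layer cosinor fits; the
#' joint formulation exists so that the any-rhythm and differential F tests
#' share one residual variance.
#'
#' @param values Log2 expression values from both layers' samples.
#' @param times Internal times in hours.
#' @param layer_labels Layer label per sample (exactly two distinct labels).
#' @param period Period in hours (default 24).
#' @return Object of class `joint_cosinor_fit`: coefficients per layer,
#'   coefficient covariance, residual variance, RSS and df.
#' @export
fit_joint_model <- function(values, times, layer_labels, period = 24) {
  layers <- sort(unique(as.character(layer_labels)))
  if (length(layers) != 2L)
    stopf("need exactly two layers, got: %s", paste(layers, collapse = ", "))
  n <- length(values)
  if (n < 8L) stopf("need >= 8 observations for the joint model, got %d", n)
  w <- omega_for(period)
  X <- joint_design(times, layer_labels, layers, w)
  qrX <- qr(X)
  if (qrX$rank < 6L) stopf("rank-deficient joint design")
  cf <- qr.coef(qrX, values)
  res <- values - X %*% cf
  rss <- sum(res^2)
  df2 <- n - 6L
  if (df2 < 1L) stopf("insufficient residual degrees of freedom")
  s2 <- rss / df2
  XtXinv <- chol2inv(qr.R(qrX))
  per_layer <- lapply(seq_along(layers), function(i) {
    idx <- (i - 1L) * 3L + 1:3
    m <- cf[idx[1]]; a <- cf[idx[2]]; b <- cf[idx[3]]
    list(layer = layers[i], mesor = unname(m), a = unname(a), b = unname(b),
         amplitude = unname(sqrt(a^2 + b^2)),
         acrophase_h = unname((atan2(b, a) / w) %% period))
  })
  names(per_layer) <- layers
  structure(list(
    layers = layers, coefficients = unname(cf), per_layer = per_layer,
    delta_a = unname(cf[5] - cf[2]), delta_b = unname(cf[6] - cf[3]),
    vcov = s2 * XtXinv, resid_var = s2, rss = rss, df_resid = df2,
    n_obs = n, period = period,
    times = times, layer_labels = as.character(layer_labels), values = values
  ), class = "joint_cosinor_fit")
}

joint_design <- function(times, layer_labels, layers, w) {
  cs <- cos(w * times); sn <- sin(w * times)
  out <- matrix(0, length(times), 6L)
  for (i in seq_along(layers)) {
    sel <- layer_labels == layers[i]
    idx <- (i - 1L) * 3L
    out[sel, idx + 1L] <- 1
    out[sel, idx + 2L] <- cs[sel]
    out[sel, idx + 3L] <- sn[sel]
  }
  colnames(out) <- paste0(rep(layers, each = 3), "_", c("m", "a", "b"))
  out
}

restricted_rss <- function(fit, X0) {
  cf <- qr.coef(qr(X0), fit$values)
  sum((fit$values - X0 %*% cf)^2)
}

#' F test that a gene is rhythmic in at least one layer
#'
#' Tests \eqn{H_0: a_d = b_d = a_e = b_e = 0} (both layers flat) against the
#' joint two-layer cosinor model, with (4, n - 6) degrees of freedom.
#'
#' @param fit A `joint_cosinor_fit`.
#' @return P-value.
#' @export
test_any_rhythm <- function(fit) {
  stopifnot(inherits(fit, "joint_cosinor_fit"))
  X0 <- matrix(0, fit$n_obs, 2L)
  for (i in 1:2) X0[fit$layer_labels == fit$layers[i], i] <- 1
  rss0 <- restricted_rss(fit, X0)
  Fstat <- ((rss0 - fit$rss) / 4) / (fit$rss / fit$df_resid)
  stats::pf(Fstat, 4, fit$df_resid, lower.tail = FALSE)
}

#' F test of differential rhythmicity between layers
#'
#' Tests \eqn{H_0: (a_d, b_d) = (a_e, b_e)} -- the rhythm coefficients are
#' equal across layers (layer-specific intercepts retained) -- with
#' (2, n - 6) degrees of freedom.
#'
#' @param fit A `joint_cosinor_fit`.
#' @return P-value.
#' @export
test_differential <- function(fit) {
  stopifnot(inherits(fit, "joint_cosinor_fit"))
  w <- omega_for(fit$period)
  X0 <- matrix(0, fit$n_obs, 4L)
  for (i in 1:2) X0[fit$layer_labels == fit$layers[i], i] <- 1
  X0[, 3] <- cos(w * fit$times)
  X0[, 4] <- sin(w * fit$times)
  rss0 <- restricted_rss(fit, X0)
  Fstat <- ((rss0 - fit$rss) / 2) / (fit$rss / fit$df_resid)
  stats::pf(Fstat, 2, fit$df_resid, lower.tail = FALSE)
}

#' Genome-wide differential rhythmicity scan
#'
#' Fits the joint two-layer model for every gene and computes both null
#' hypotheses: any-rhythm (all sine/cosine terms zero) and differential
#' (terms equal across layers).
#'
#' @param matrix Genes x samples log2 expression matrix.
#' @param records Metadata with `internal_time_h` populated; must contain
#'   exactly two layers.
#' @param period Period in hours (default 24).
#' @return Data.frame with per-layer rhythm parameters, `p_any` and `p_diff`
#'   per gene (q-values and categories are added by [categorize()]).
#' @export
differential_rhythm_scan <- function(matrix, records, period = 24) {
  validate_records(records, matrix, require_internal = TRUE)
  layers <- sort(unique(records$layer))
  if (length(layers) != 2L) stopf("need exactly two layers in metadata")
  ids <- records$sample_id
  Y <- t(matrix[, ids, drop = FALSE])
  times <- records$internal_time_h
  w <- omega_for(period)
  X <- joint_design(times, records$layer, layers, w)
  n <- nrow(Y)
  if (n - 6L < 1L) stopf("insufficient residual degrees of freedom")
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)                               # 6 x genes
  rss <- colSums((Y - X %*% coefs)^2)
  df2 <- n - 6L
  # restricted designs
  X_int <- X[, c(1, 4), drop = FALSE]
  rss_flat <- colSums((Y - X_int %*% qr.coef(qr(X_int), Y))^2)
  X_shared <- cbind(X[, c(1, 4)], cos(w * times), sin(w * times))
  rss_shared <- colSums((Y - X_shared %*% qr.coef(qr(X_shared), Y))^2)
  p_any <- stats::pf(((rss_flat - rss) / 4) / (rss / df2), 4, df2,
                     lower.tail = FALSE)
  p_diff <- stats::pf(((rss_shared - rss) / 2) / (rss / df2), 2, df2,
                      lower.tail = FALSE)
  out <- data.frame(gene_id = colnames(Y), row.names = NULL)
  for (i in seq_along(layers)) {
    idx <- (i - 1L) * 3L
    a <- coefs[idx + 2L, ]; b <- coefs[idx + 3L, ]
    amp <- sqrt(a^2 + b^2)
    out[[paste0("mesor_", layers[i])]] <- coefs[idx + 1L, ]
    out[[paste0("a_", layers[i])]] <- a
    out[[paste0("b_", layers[i])]] <- b
    out[[paste0("amplitude_", layers[i])]] <- amp
    out[[paste0("fold_change_", layers[i])]] <- 2^(2 * amp)
    out[[paste0("acrophase_h_", layers[i])]] <- (atan2(b, a) / w) %% period
  }
  out$delta_a <- coefs[5, ] - coefs[2, ]
  out$delta_b <- coefs[6, ] - coefs[3, ]
  out$p_any <- p_any
  out$p_diff <- p_diff
  out$n <- n
  attr(out, "layers") <- layers
  out
}

#' Categorize genes by layer-specific rhythmicity
#'
#' Applies the two-stage decision rule.  Gate: a gene is diurnal in at least
#' one layer when its any-rhythm BH q-value is below `fdr` AND its larger
#' layer fold change exceeds `fc_threshold` (strict).  Among gated genes,
#' differential q-values are BH-corrected within the gated set.  Gated genes
#' whose rhythms are statistically indistinguishable (q_diff >= fdr) count
#' as rhythmic in BOTH layers even when one layer's fold change is
#' sub-threshold.  Gated genes with q_diff < fdr are assigned by per-layer
#' fold change: above threshold in both layers -> `both_differential`; in
#' one only -> `<layer>_only`.
#'
#' @param results Output of [differential_rhythm_scan()].
#' @param fdr FDR threshold (default 0.05).
#' @param fc_threshold Peak-to-trough fold-change threshold (default 1.5).
#' @return The input with `q_any`, `q_diff` and `category` columns added;
#'   `category` is one of `not_rhythmic`, `<layer1>_only`, `<layer2>_only`,
#'   `both_differential`, `both_indistinguishable`.
#' @export
categorize <- function(results, fdr = 0.05, fc_threshold = 1.5) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1)
    stopf("fdr must lie in (0, 1)")
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stopf("fc_threshold must exceed 1")
  layers <- attr(results, "layers")
  if (is.null(layers)) {
    fc_cols <- grep("^fold_change_", names(results), value = TRUE)
    layers <- sub("^fold_change_", "", fc_cols)
  }
  if (length(layers) != 2L) stopf("cannot identify the two layers")
  fc1 <- results[[paste0("fold_change_", layers[1])]]
  fc2 <- results[[paste0("fold_change_", layers[2])]]
  results$q_any <- bh_fdr(results$p_any)
  gate <- results$q_any < fdr & pmax(fc1, fc2) > fc_threshold
  q_diff <- rep(NA_real_, nrow(results))
  q_diff[gate] <- bh_fdr(results$p_diff[gate])
  results$q_diff <- q_diff
  category <- rep("not_rhythmic", nrow(results))
  indist <- gate & q_diff >= fdr
  diffr <- gate & q_diff < fdr
  category[indist] <- "both_indistinguishable"
  category[diffr & fc1 > fc_threshold & fc2 > fc_threshold] <- "both_differential"
  category[diffr & fc1 > fc_threshold & fc2 <= fc_threshold] <- paste0(layers[1], "_only")
  category[diffr & fc1 <= fc_threshold & fc2 > fc_threshold] <- paste0(layers[2], "_only")
  results$category <- category
  attr(results, "layers") <- layers
  attr(results, "fdr") <- fdr
  attr(results, "fc_threshold") <- fc_threshold
  results
}

#' Rhythmic gene ids per layer implied by the categorization
#'
#' A layer's rhythmic set is: indistinguishable genes (both layers, even if
#' one layer's FC is sub-threshold) + layer-only genes + differential genes
#' whose fold change in that layer exceeds the threshold.
#'
#' @param categorized Output of [categorize()].
#' @return Named list of gene-id vectors, one per layer.
#' @export
rhythmic_genes_by_layer <- function(categorized) {
  layers <- attr(categorized, "layers")
  thr <- attr(categorized, "fc_threshold")
  if (is.null(layers) || is.null(thr)) stopf("input must come from categorize()")
  out <- lapply(layers, function(L) {
    fc <- categorized[[paste0("fold_change_", L)]]
    sel <- categorized$category == "both_indistinguishable" |
      categorized$category == paste0(L, "_only") |
      (categorized$category == "both_differential" & fc > thr)
    categorized$gene_id[sel]
  })
  names(out) <- layers
  out
}

#' Circular statistics of paired acrophase differences
#'
#' Pairwise differences are wrapped to (-period/2, period/2]; the circular
#' mean difference, the mean resultant length R of the difference angles and
#' a Rayleigh test p-value for non-uniformity of the differences are
#' returned.
#'
#' @param phases_layer1,phases_layer2 Paired acrophases in hours.
#' @param period Period in hours (default 24).
#' @return List with `mean_difference_h`, `rayleigh_R`, `p_value`, `n`.
#' @export
circular_phase_stats <- function(phases_layer1, phases_layer2, period = 24) {
  if (length(phases_layer1) != length(phases_layer2))
    stopf("phase lists differ in length")
  n <- length(phases_layer1)
  if (n < 1L) stopf("need at least one pair")
  d <- wrap_half_period(phases_layer1 - phases_layer2, period)
  theta <- 2 * pi * d / period
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  mean_diff <- wrap_half_period(atan2(S, C) * period / (2 * pi), period)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(mean_difference_h = mean_diff, rayleigh_R = R,
       p_value = min(max(p, 0), 1), n = n)
}
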