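#' Cosinor (harmonic) regression of one gene against internal time
#'
#' Fits \eqn{y = m + a\cos(\omega t) + b\sin(\omega t)} by ordinary least
#' squares with \eqn{\omega = 2\pi/\mathrm{period}} and tests rhythmicity via
#' the F test of \eqn{H_0: a = b = 0} with (2, n - 3) degrees of freedom.
#' Non-uniform sampling times are supported; chronotype correction makes
#' internal times unevenly spaced, which rules out rank-based detectors that
#' require uniform designs.
#'
#' Amplitude is \eqn{A = \sqrt{a^2 + b^2}} (half the peak-to-trough swing on
#' the log2 scale, so peak-to-trough fold change is \eqn{2^{2A}}); the
#' acrophase is the peak time \eqn{(\mathrm{atan2}(b, a)/\omega) \bmod
#' \mathrm{period}}, in hours after internal time 0 (i.e. after MSF_sc when
#' times are internal).
#'
#' @param values Numeric vector of log2 expression values.
#' @param times Numeric vector of (internal) times in hours, same length.
#' @param period Rhythm period in hours (default 24).
#' @return Object of class `cosinor_fit`: a list with `mesor`, `coef_a`,
#'   `coef_b`, `amplitude`, `acrophase_h`, `resid_var`, `p_rhythm`, `n_obs`,
#'   `df_resid`, `rss`, `rss0`.
#' @export
fit_cosinor <- function(values, times, period = 24) {
  if (length(values) != length(times))
    stopf("values and times differ in length")
  n <- length(values)
  if (n < 4L) stopf("need at least 4 observations, got %d", n)
  if (!all(is.finite(values)) || !all(is.finite(times)))
    stopf("values and times must be finite")
  w <- omega_for(period)
  X <- cbind(1, cos(w * times), sin(w * times))
  if (qr(X)$rank < 3L)
    stopf("rank-deficient cosinor design: times degenerate modulo the period")
  fit <- stats::lm.fit(X, values)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  df2 <- n - 3L
  Fstat <- ((rss0 - rss) / 2) / (rss / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  a <- cf[2]; b <- cf[3]
  structure(list(
    mesor = unname(cf[1]), coef_a = unname(a), coef_b = unname(b),
    amplitude = unname(sqrt(a^2 + b^2)),
    acrophase_h = unname((atan2(b, a) / w) %% period),
    resid_var = rss / df2, p_rhythm = unname(p),
    n_obs = n, df_resid = df2, rss = rss, rss0 = rss0, period = period
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h): mesor %.3f, amplitude %.3f (FC %.2f), acrophase %.2f h, p = %.3g (n = %d)\n",
    x$period, x$mesor, x$amplitude, amplitude_to_fold_change(x$amplitude),
    x$acrophase_h, x$p_rhythm, x$n_obs))
  invisible(x)
}

#' Convert a log2 cosinor amplitude to peak-to-trough fold change
#'
#' On log2 data the fitted curve swings from mesor - A to mesor + A, so the
#' peak-to-trough fold change is \eqn{2^{2A}}.
#'
#' @param amplitude Non-negative log2 amplitude(s).
#' @return Fold change(s), >= 1.
#' @seealso [fc_to_amplitude()]
#' @export
amplitude_to_fold_change <- function(amplitude) {
  if (any(amplitude < 0)) stopf("amplitude must be non-negative")
  2^(2 * amplitude)
}

#' Convert peak-to-trough fold change to log2 amplitude
#' @param fc Fold change(s), >= 1.
#' @return Log2 amplitude(s).
#' @export
fc_to_amplitude <- function(fc) {
  if (any(fc < 1)) stopf("fold change must be >= 1")
  log2(fc) / 2
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control across a family of p-values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Genome-wide cosinor scan of one skin layer
#'
#' Fits the population cosinor model to every gene using all of the layer's
#' samples pooled across subjects (the population rhythm: the diurnal
#' pattern averaged over the cohort) and controls FDR across genes.
#'
#' With `moderate = TRUE`, residual variances are moderated across genes by
#' empirical Bayes ([limma::squeezeVar()]) before forming the F statistic,
#' borrowing strength in small designs; with `moderate = FALSE` the
#' ordinary per-gene F test (exact null distribution) is used.
#'
#' @param matrix Genes x samples log2 expression matrix.
#' @param records Sample metadata with `internal_time_h` populated.
#' @param layer Layer label to scan.
#' @param period Period in hours (default 24).
#' @param moderate Moderate residual variances across genes (default FALSE).
#' @return Data.frame with one row per gene: `gene_id`, `layer`, `mesor`,
#'   `a`, `b`, `amplitude`, `fold_change`, `acrophase_h`, `p`, `q`, `n`.
#' @export
layerwise_rhythm_scan <- function(matrix, records, layer, period = 24,
                                  moderate = FALSE) {
  validate_records(records, matrix, require_internal = TRUE)
  sel <- records$layer == layer
  if (!any(sel)) stopf("layer '%s' absent from metadata", layer)
  ids <- records$sample_id[sel]
  times <- records$internal_time_h[sel]
  Y <- t(matrix[, ids, drop = FALSE])            # samples x genes
  if (ncol(Y) == 0L) {
    return(data.frame(gene_id = character(0), layer = character(0),
                      mesor = numeric(0), a = numeric(0), b = numeric(0),
                      amplitude = numeric(0), fold_change = numeric(0),
                      acrophase_h = numeric(0), p = numeric(0), q = numeric(0),
                      n = integer(0)))
  }
  n <- nrow(Y)
  if (n < 4L) stopf("layer '%s' has %d samples; need >= 4", layer, n)
  w <- omega_for(period)
  X <- cbind(1, cos(w * times), sin(w * times))
  qrX <- qr(X)
  if (qrX$rank < 3L) stopf("degenerate time design in layer '%s'", layer)
  coefs <- qr.coef(qrX, Y)                       # 3 x genes
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  df2 <- n - 3L
  msr <- (rss0 - rss) / 2
  if (moderate) {
    sq <- limma::squeezeVar(rss / df2, df = df2)
    df_prior <- sq$df.prior
    if (!is.finite(df_prior)) df_prior <- 10 * n   # effectively pooled variance
    Fstat <- msr / sq$var.post
    p <- stats::pf(Fstat, 2, df2 + df_prior, lower.tail = FALSE)
  } else {
    Fstat <- msr / (rss / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  }
  a <- coefs[2, ]; b <- coefs[3, ]
  amp <- sqrt(a^2 + b^2)
  data.frame(
    gene_id = colnames(Y), layer = layer,
    mesor = coefs[1, ], a = a, b = b, amplitude = amp,
    fold_change = 2^(2 * amp),
    acrophase_h = (atan2(b, a) / w) %% period,
    p = p, q = bh_fdr(p), n = n,
    row.names = NULL
  )
}
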