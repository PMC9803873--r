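#' Per-gene linear mixed model with crossed subject and layer effects
#'
#' Fits, by maximum likelihood, the model
#' \deqn{g(t) = (m + \Delta m_{subj} + \Delta m_{layer})
#'   + (a + \Delta a_{subj} + \Delta a_{layer})\cos\omega t
#'   + (b + \Delta b_{subj} + \Delta b_{layer})\sin\omega t + \epsilon,}
#' where the subject deviations of (MESOR, cos, sin) follow a full 3x3
#' covariance \eqn{\Sigma_{subj}} and the layer deviations a diagonal 3x3
#' covariance \eqn{\Sigma_{layer}} (diagonal to keep the parameter count
#' tractable with only two layer levels).  Estimation uses [lme4::lmer()]
#' with `REML = FALSE`; variance components at the boundary (zero, singular
#' fits) are permitted and reported.
#'
#' @param values Log2 expression values across subjects, layers and times.
#' @param times Internal times in hours.
#' @param subject_ids Subject identifier per observation (>= 2 subjects).
#' @param layer_labels Layer label per observation (exactly 2 layers).
#' @param period Period in hours (default 24).
#' @param gene_id Optional gene label carried into the result.
#' @return Object of class `mixed_fit`: `fixed` (m, a, b), `sigma_subj`
#'   (3x3), `sigma_layer` (diagonal 3x3), `resid_var`, `loglik`,
#'   `converged`, `singular`, `n_obs`.
#' @export
fit_gene_lmm <- function(values, times, subject_ids, layer_labels,
                         period = 24, gene_id = NA_character_) {
  if (length(unique(subject_ids)) < 2L)
    stopf("need >= 2 subjects (use fit_gene_lmm_single_layer for one layer)")
  if (length(unique(layer_labels)) != 2L)
    stopf("need exactly 2 layers (use fit_gene_lmm_single_layer otherwise)")
  lmm_fit_impl(values, times, subject_ids, layer_labels, period, gene_id,
               with_layer = TRUE)
}

#' Per-gene linear mixed model within a single layer
#'
#' Same model as [fit_gene_lmm()] but with subject random effects only,
#' for quantifying inter-subject variability separately per layer.
#'
#' @inheritParams fit_gene_lmm
#' @return `mixed_fit` with `sigma_layer = NULL`.
#' @export
fit_gene_lmm_single_layer <- function(values, times, subject_ids,
                                      period = 24, gene_id = NA_character_) {
  if (length(unique(subject_ids)) < 2L) stopf("need >= 2 subjects")
  lmm_fit_impl(values, times, subject_ids, NULL, period, gene_id,
               with_layer = FALSE)
}

lmm_fit_impl <- function(values, times, subject_ids, layer_labels, period,
                         gene_id, with_layer) {
  w <- omega_for(period)
  df <- data.frame(y = values, cosw = cos(w * times), sinw = sin(w * times),
                   subject = factor(subject_ids))
  if (length(unique(round(times %% period, 8))) < 4L)
    stopf("need >= 4 distinct times modulo the period")
  if (with_layer) {
    df$layer <- factor(layer_labels)
    form <- y ~ cosw + sinw + (cosw + sinw | subject) + (cosw + sinw || layer)
  } else {
    form <- y ~ cosw + sinw + (cosw + sinw | subject)
  }
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  warned <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = FALSE, control = ctrl),
    warning = function(wn) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  vc <- lme4::VarCorr(fit)
  sigma_subj <- extract_vc_block(vc, "subject")
  sigma_layer <- if (with_layer) extract_layer_diag(vc) else NULL
  conv_ok <- !warned && length(fit@optinfo$conv$lme4) == 0
  structure(list(
    gene_id = gene_id,
    fixed = stats::setNames(unname(lme4::fixef(fit)[c("(Intercept)", "cosw", "sinw")]),
                            c("m", "a", "b")),
    sigma_subj = sigma_subj,
    sigma_layer = sigma_layer,
    resid_var = stats::sigma(fit)^2,
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv_ok,
    singular = lme4::isSingular(fit, tol = 1e-4),
    n_obs = length(values),
    period = period
  ), class = "mixed_fit")
}

# 3x3 covariance of (intercept, cos, sin) for a named grouping factor
extract_vc_block <- function(vc, group) {
  m <- as.matrix(vc[[group]])
  ord <- c("(Intercept)", "cosw", "sinw")
  m <- m[ord, ord, drop = FALSE]
  dimnames(m) <- list(c("m", "a", "b"), c("m", "a", "b"))
  m
}

# the double-bar expansion stores layer terms as separate 1x1 blocks
extract_layer_diag <- function(vc) {
  vars <- c(m = 0, a = 0, b = 0)
  map <- c("(Intercept)" = "m", cosw = "a", sinw = "b")
  for (nm in names(vc)) {
    if (!startsWith(nm, "layer")) next
    block <- as.matrix(vc[[nm]])
    for (term in rownames(block)) vars[[map[[term]]]] <- block[term, term]
  }
  diag(vars)
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("mixed cosinor fit%s: m %.3f, a %.3f, b %.3f (A %.3f); logLik %.2f%s%s\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$fixed["m"], x$fixed["a"], x$fixed["b"],
              sqrt(sum(x$fixed[c("a", "b")]^2)), x$loglik,
              if (x$singular) ", boundary fit" else "",
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Delta-method standard deviation of the amplitude
#'
#' Propagates a 3x3 covariance of (MESOR, cos, sin) deviations to the
#' amplitude \eqn{A = \sqrt{a^2+b^2}} via the Jacobian
#' \eqn{J_A = (0, a/A, b/A)}: \eqn{\sigma_A = \sqrt{J_A \Sigma J_A^T}}.
#'
#' @param fixed Numeric vector (m, a, b) of fixed effects.
#' @param cov 3x3 covariance matrix of the (m, a, b) deviations.
#' @return Standard deviation of the amplitude (log2 units).
#' @export
propagate_amplitude_sd <- function(fixed, cov) {
  a <- fixed[[2]]; b <- fixed[[3]]
  A <- sqrt(a^2 + b^2)
  if (A == 0) stopf("amplitude is zero; Jacobian undefined")
  J <- c(0, a / A, b / A)
  sqrt(drop(J %*% cov %*% J))
}

#' Delta-method standard deviation of the acrophase
#'
#' Propagates a 3x3 covariance of (MESOR, cos, sin) deviations to the phase
#' \eqn{\phi = \mathrm{atan2}(b, a)} via \eqn{J_\phi = (0, -b/A^2, a/A^2)}
#' (radians), then converts to hours by `period / (2 pi)`.  The
#' linearization is accurate for small phase spread (roughly below 2 h).
#'
#' @inheritParams propagate_amplitude_sd
#' @param period Period in hours (default 24).
#' @return Standard deviation of the acrophase in hours.
#' @export
propagate_phase_sd <- function(fixed, cov, period = 24) {
  a <- fixed[[2]]; b <- fixed[[3]]
  A2 <- a^2 + b^2
  if (A2 == 0) stopf("amplitude is zero; Jacobian undefined")
  J <- c(0, -b / A2, a / A2)
  sqrt(drop(J %*% cov %*% J)) * period / (2 * pi)
}

#' Fraction of variance explained by subject
#'
#' \eqn{f = \sigma^2_{subj} / (\sigma^2_{subj} + \sigma^2_{layer})}: values
#' near 1 mean a rhythm parameter varies mostly between subjects, near 0
#' mostly between layers.
#'
#' @param var_subj,var_layer Non-negative variances, not both zero.
#' @return Fraction in \[0, 1\]; `NaN` with a warning when both are zero.
#' @export
variance_fraction <- function(var_subj, var_layer) {
  if (any(var_subj < 0) || any(var_layer < 0))
    stopf("variances must be non-negative")
  tot <- var_subj + var_layer
  if (any(tot == 0))
    warning("both variances zero for some gene(s); fraction undefined (NaN)")
  var_subj / tot
}

#' Variability decomposition across a gene list
#'
#' Runs [fit_gene_lmm()] per gene and propagates both covariance sources to
#' amplitude and phase SDs, amplitude coefficients of variation
#' (\eqn{\sigma_A / A}) and subject variance fractions per parameter.
#' Relative phase variability is reported as \eqn{\sigma_\phi /
#' \mathrm{period}} (a CV of a circular quantity is ill-defined).
#'
#' @param matrix Genes x samples log2 expression matrix.
#' @param records Metadata with `internal_time_h` populated (two layers).
#' @param gene_list Genes to analyze (subset of rownames).
#' @param period Period in hours (default 24).
#' @return Data.frame, one row per gene: fixed effects, amplitude,
#'   acrophase, `{sd_m, sd_A, sd_phase, cv_A}` for subj and layer sources,
#'   `f_m`, `f_A`, `f_phase`, `phase_linearization_ok` (both sources'
#'   \eqn{\sigma_\phi < 2} h), `converged`, `singular`.
#' @export
variability_table <- function(matrix, records, gene_list, period = 24) {
  validate_records(records, matrix, require_internal = TRUE)
  missing <- setdiff(gene_list, rownames(matrix))
  if (length(missing) > 0L)
    stopf("gene(s) absent from matrix: %s", paste(utils::head(missing, 5), collapse = ", "))
  if (length(gene_list) == 0L) {
    return(data.frame(gene_id = character(0)))
  }
  ids <- records$sample_id
  rows <- lapply(gene_list, function(g) {
    fit <- fit_gene_lmm(matrix[g, ids], records$internal_time_h,
                        records$subject_id, records$layer, period, gene_id = g)
    f <- fit$fixed
    A <- sqrt(f[["a"]]^2 + f[["b"]]^2)
    one_source <- function(S) {
      if (A == 0) return(c(sd_m = sqrt(S[1, 1]), sd_A = NA, sd_phase = NA, cv_A = NA))
      c(sd_m = sqrt(S[1, 1]),
        sd_A = propagate_amplitude_sd(f, S),
        sd_phase = propagate_phase_sd(f, S, period),
        cv_A = propagate_amplitude_sd(f, S) / A)
    }
    su <- one_source(fit$sigma_subj)
    la <- one_source(fit$sigma_layer)
    data.frame(
      gene_id = g, m = f[["m"]], a = f[["a"]], b = f[["b"]], amplitude = A,
      acrophase_h = (atan2(f[["b"]], f[["a"]]) / omega_for(period)) %% period,
      sd_m_subj = su[["sd_m"]], sd_A_subj = su[["sd_A"]],
      sd_phase_subj = su[["sd_phase"]], cv_A_subj = su[["cv_A"]],
      sd_m_layer = la[["sd_m"]], sd_A_layer = la[["sd_A"]],
      sd_phase_layer = la[["sd_phase"]], cv_A_layer = la[["cv_A"]],
      f_m = suppressWarnings(variance_fraction(su[["sd_m"]]^2, la[["sd_m"]]^2)),
      f_A = if (A == 0) NA_real_ else
        suppressWarnings(variance_fraction(su[["sd_A"]]^2, la[["sd_A"]]^2)),
      f_phase = if (A == 0) NA_real_ else
        suppressWarnings(variance_fraction(su[["sd_phase"]]^2, la[["sd_phase"]]^2)),
      phase_linearization_ok = if (A == 0) NA else
        (su[["sd_phase"]] < 2 && la[["sd_phase"]] < 2),
      converged = fit$converged, singular = fit$singular,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
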