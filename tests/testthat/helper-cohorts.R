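# Shared fixture builders.  All data are generated in code at test time.

# study-like sampling frame: subjects x layers x 4-h wall times
make_records <- function(n_subjects = 11, timepoints = seq(8, 32, 4),
                         layers = c("dermis", "epidermis"),
                         msf = NULL, seed = 1) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  if (is.null(msf)) msf <- stats::setNames(runif(n_subjects, 2.5, 6), subjects)
  rec <- expand.grid(wall_time_h = timepoints, layer = layers,
                     subject_id = subjects, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec$msf_sc_h <- msf[rec$subject_id]
  rec$sample_id <- sprintf("%s_%s_T%02d", toupper(substr(rec$layer, 1, 1)),
                           rec$subject_id, rec$wall_time_h)
  to_internal_time(rec)
}

# one-layer clock cohort for predictor tests: n_rhythmic genes with evenly
# spread acrophases plus flat genes, no subject heterogeneity beyond noise
make_clock_cohort <- function(n_subjects = 11, n_rhythmic = 10, n_flat = 40,
                              amplitude = 0.5, resid_sd = 0.15, seed = 1) {
  cfg <- cohort_config(
    n_subjects = n_subjects, n_genes = n_rhythmic + n_flat,
    frac_rhythmic = n_rhythmic / (n_rhythmic + n_flat),
    amp_meanlog = c(dermis = log(amplitude), epidermis = log(amplitude)),
    amp_sdlog = 0.05, phase_kappa = 0.01,     # ~uniform phases
    sigma_subj = diag(c(0.05, 0.02, 0.02)^2), sigma_layer = diag(rep(0, 3)),
    resid_sd = resid_sd, seed = seed)
  sim <- simulate_cohort(cfg)
  rec <- sim$records[sim$records$layer == "dermis", ]
  list(matrix = sim$matrix[, rec$sample_id], records = rec, truth = sim$truth)
}

# independent circular wrap used by test oracles
wrap12 <- function(d, period = 24) {
  m <- d %% period
  ifelse(m > period / 2, m - period, m)
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
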