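sim_lmm_gene <- function(rec, fixed = c(m = 8, a = 0.4, b = 0.3),
                         sigma_subj = diag(rep(0, 3)),
                         sigma_layer = diag(rep(0, 3)),
                         resid_sd = 0.1) {
  w <- 2 * pi / 24
  subjects <- unique(rec$subject_id)
  layers <- unique(rec$layer)
  ev <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3)
  }
  us <- matrix(rnorm(3 * length(subjects)), length(subjects)) %*% t(ev(sigma_subj))
  ul <- matrix(rnorm(3 * length(layers)), length(layers)) %*% t(ev(sigma_layer))
  rownames(us) <- subjects; rownames(ul) <- layers
  t <- rec$internal_time_h
  co <- cbind(1, cos(w * t), sin(w * t))
  beta <- matrix(fixed, nrow(rec), 3, byrow = TRUE) +
    us[rec$subject_id, , drop = FALSE] + ul[rec$layer, , drop = FALSE]
  rowSums(co * beta) + rnorm(nrow(rec), 0, resid_sd)
}

test_that("mixed model recovers fixed effects and boundary variance truth", {
  rec <- make_records(seed = 51)
  set.seed(52)
  # zero random-effect truth: variance estimates collapse to the boundary
  y <- sim_lmm_gene(rec, resid_sd = 0.1)
  fit <- fit_gene_lmm(y, rec$internal_time_h, rec$subject_id, rec$layer)
  expect_true(all(abs(fit$sigma_subj) < 0.05^2 * 25))  # entries are variances
  expect_true(all(sqrt(abs(diag(fit$sigma_subj))) < 0.05))
  expect_true(all(sqrt(diag(fit$sigma_layer)) < 0.05))
  expect_close(fit$fixed, c(m = 8, a = 0.4, b = 0.3), 0.05)

  # near-noiseless data generated exactly from the fixed effects
  y0 <- sim_lmm_gene(rec, resid_sd = 1e-6)
  fit0 <- fit_gene_lmm(y0, rec$internal_time_h, rec$subject_id, rec$layer)
  expect_close(fit0$fixed, c(m = 8, a = 0.4, b = 0.3), 1e-5)
  expect_true(all(abs(diag(fit0$sigma_subj)) < 1e-8))

  expect_error(fit_gene_lmm(y, rec$internal_time_h,
                            rep("s1", nrow(rec)), rec$layer), "2 subjects")
  expect_error(fit_gene_lmm(y, rec$internal_time_h, rec$subject_id,
                            rep("dermis", nrow(rec))), "2 layers")
})

test_that("variance components are recovered on average at study size", {
  rec <- make_records(seed = 53)
  S_subj <- diag(c(0.2, 0.1, 0.1)^2)
  S_layer <- diag(c(0.3, 0.05, 0.05)^2)
  set.seed(54)
  ests <- replicate(50, {
    y <- sim_lmm_gene(rec, sigma_subj = S_subj, sigma_layer = S_layer,
                      resid_sd = 0.1)
    fit <- fit_gene_lmm(y, rec$internal_time_h, rec$subject_id, rec$layer)
    c(diag(fit$sigma_subj), fit$resid_var)
  })
  mean_est <- rowMeans(ests)
  truth <- c(diag(S_subj), 0.1^2)
  expect_true(all(abs(mean_est - truth) / truth < 0.25),
              label = paste("relative errors:",
                            paste(round(abs(mean_est - truth) / truth, 3),
                                  collapse = " ")))
})

test_that("single-layer fit without subject spread reduces to the pooled cosinor", {
  rec <- make_records(seed = 55)
  d_rec <- rec[rec$layer == "dermis", ]
  set.seed(56)
  w <- 2 * pi / 24
  y <- 8 + 0.5 * cos(w * d_rec$internal_time_h) + rnorm(nrow(d_rec), 0, 0.1)
  fit <- fit_gene_lmm_single_layer(y, d_rec$internal_time_h, d_rec$subject_id)
  expect_null(fit$sigma_layer)
  m <- matrix(y, 1, dimnames = list("g1", d_rec$sample_id))
  scan <- layerwise_rhythm_scan(m, d_rec, "dermis")
  expect_equal(unname(fit$fixed), c(scan$mesor, scan$a, scan$b),
               tolerance = 1e-4)

  # two subjects with identical data: no between-subject spread
  t7 <- seq(8, 32, 4)
  y2 <- rep(8 + 0.5 * cos(w * t7), 2) + 1e-3 * rep(rnorm(7), 2)
  fit2 <- fit_gene_lmm_single_layer(rep(y2[1:7], 2), rep(t7, 2),
                                    rep(c("sA", "sB"), each = 7))
  expect_true(all(sqrt(diag(fit2$sigma_subj)) < 1e-3))
})

test_that("ML log-likelihood dominates the zero-random-effect OLS likelihood", {
  rec <- make_records(seed = 57)
  set.seed(58)
  for (i in 1:3) {
    y <- sim_lmm_gene(rec, sigma_subj = diag(c(0.2, 0.1, 0.1)^2),
                      resid_sd = 0.2)
    fit <- fit_gene_lmm(y, rec$internal_time_h, rec$subject_id, rec$layer)
    w <- 2 * pi / 24
    X <- cbind(1, cos(w * rec$internal_time_h), sin(w * rec$internal_time_h))
    res <- stats::lm.fit(X, y)$residuals
    n <- length(y)
    s2_ml <- sum(res^2) / n
    ll_ols <- -n / 2 * (log(2 * pi * s2_ml) + 1)
    expect_gte(fit$loglik, ll_ols - 1e-6)
  }
})

test_that("delta-method propagation matches closed forms and Monte Carlo", {
  # isotropy in (a, b): sigma_A equals the common SD regardless of mesor SD
  expect_equal(propagate_amplitude_sd(c(5, 1, 2), diag(c(9, 0.04, 0.04))), 0.2)
  # axis-aligned: a = 1, b = 0, only var(a) = 0.04 -> sigma_A = 0.2
  expect_equal(propagate_amplitude_sd(c(0, 1, 0), diag(c(0, 0.04, 0))), 0.2)
  # phase closed form: sigma_phi = (sigma / A) * period / (2 pi)
  expect_equal(propagate_phase_sd(c(0, 2, 0), diag(c(1, 0.04, 0.04))),
               (0.2 / 2) * 24 / (2 * pi))
  # a = 0, b = 1, var(a) = 0.01 -> 0.1 rad
  expect_equal(propagate_phase_sd(c(0, 0, 1), diag(c(0, 0.01, 0))),
               0.1 * 24 / (2 * pi))
  expect_error(propagate_amplitude_sd(c(1, 0, 0), diag(3)), "zero")
  expect_error(propagate_phase_sd(c(1, 0, 0), diag(3)), "zero")

  # Monte-Carlo oracle in the small-variance regime (sigma_A / A < 0.2)
  set.seed(61)
  for (i in 1:5) {
    ab <- rnorm(2, sd = 1) + c(1.5, 0)
    A <- sqrt(sum(ab^2))
    sd_ab <- runif(2, 0.02, 0.15) * A
    rho <- runif(1, -0.5, 0.5)
    S <- diag(c(0.1, sd_ab)^2)
    S[2, 3] <- S[3, 2] <- rho * sd_ab[1] * sd_ab[2]
    da <- rnorm(1e6, 0, sd_ab[1]); db0 <- rnorm(1e6)
    db <- rho * sd_ab[2] / sd_ab[1] * da +
      sqrt(1 - rho^2) * sd_ab[2] * db0
    amp_mc <- sd(sqrt((ab[1] + da)^2 + (ab[2] + db)^2))
    phi_mc_h <- sd(wrap12(
      (atan2(ab[2] + db, ab[1] + da) - atan2(ab[2], ab[1])) * 24 / (2 * pi)))
    expect_close(propagate_amplitude_sd(c(0, ab), S) / amp_mc, 1, 0.05)
    expect_close(propagate_phase_sd(c(0, ab), S) / phi_mc_h, 1, 0.05)
  }
})

test_that("amplitude SD is invariant under joint rotation of (a, b) and its covariance", {
  set.seed(62)
  ab <- c(0.8, -0.4)
  B <- matrix(rnorm(4, sd = 0.05), 2)
  S <- diag(3) * 0.01
  S[2:3, 2:3] <- B %*% t(B)
  base <- propagate_amplitude_sd(c(0, ab), S)
  for (th in runif(4, 0, 2 * pi)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    ab_r <- drop(R %*% ab)
    S_r <- S
    S_r[2:3, 2:3] <- R %*% S[2:3, 2:3] %*% t(R)
    expect_equal(propagate_amplitude_sd(c(0, ab_r), S_r), base,
                 tolerance = 1e-10)
  }
})

test_that("variance fractions and the variability table point the right way", {
  expect_equal(variance_fraction(3, 1), 0.75)
  expect_equal(variance_fraction(0, 2), 0)
  expect_equal(variance_fraction(7, 7), 0.5)
  expect_warning(f0 <- variance_fraction(0, 0), "undefined")
  expect_true(is.nan(f0))
  expect_error(variance_fraction(-1, 1), "non-negative")

  # genes with larger subject than layer variance in (a, b): f_A > 0.5;
  # genes with layer-shifted mesor only: f_m < 0.5
  rec <- make_records(seed = 63)
  set.seed(64)
  n_g <- 12
  w <- 2 * pi / 24
  mk <- function(sigma_subj, sigma_layer) {
    t(replicate(n_g, sim_lmm_gene(rec, fixed = c(m = 8, a = 0.5, b = 0.3),
                                  sigma_subj = sigma_subj,
                                  sigma_layer = sigma_layer, resid_sd = 0.1)))
  }
  m_subjvar <- mk(diag(c(0.05, 0.25, 0.25)^2), diag(c(0.05, 0.02, 0.02)^2))
  m_layermes <- mk(diag(c(0.02, 0.02, 0.02)^2), diag(c(0.4, 0.02, 0.02)^2))
  mat <- rbind(m_subjvar, m_layermes)
  rownames(mat) <- sprintf("G%02d", 1:(2 * n_g))
  colnames(mat) <- rec$sample_id
  vt <- variability_table(mat, rec, rownames(mat))
  expect_gt(median(vt$f_A[1:n_g], na.rm = TRUE), 0.5)
  expect_lt(median(vt$f_m[(n_g + 1):(2 * n_g)], na.rm = TRUE), 0.5)

  # deterministic across runs
  vt2 <- variability_table(mat, rec, rownames(mat))
  expect_identical(vt, vt2)
  expect_error(variability_table(mat, rec, "NOPE"), "absent")
})
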