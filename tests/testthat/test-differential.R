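two_layer_frame <- function(n_subjects = 11, seed = 1) {
  rec <- make_records(n_subjects = n_subjects, seed = seed)
  list(rec = rec, t = rec$internal_time_h, lay = rec$layer, w = 2 * pi / 24)
}

test_that("joint two-layer fit equals per-layer OLS and nails noiseless cases", {
  fr <- two_layer_frame()
  # identical noiseless rhythms in both layers -> zero deltas exactly
  y <- 8 + 0.7 * cos(fr$w * (fr$t - 4))
  fit <- fit_joint_model(y, fr$t, fr$lay)
  expect_equal(fit$delta_a, 0, tolerance = 1e-10)
  expect_equal(fit$delta_b, 0, tolerance = 1e-10)

  # dermis flat, epidermis amplitude 1, noiseless
  y2 <- ifelse(fr$lay == "epidermis", 8 + cos(fr$w * fr$t), 8)
  fit2 <- fit_joint_model(y2, fr$t, fr$lay)
  expect_equal(fit2$per_layer$dermis$a, 0, tolerance = 1e-10)
  expect_equal(fit2$per_layer$dermis$b, 0, tolerance = 1e-10)
  expect_equal(fit2$per_layer$epidermis$amplitude, 1, tolerance = 1e-10)

  # random data: joint coefficients equal two independent per-layer fits
  set.seed(9)
  y3 <- rnorm(length(fr$t), 8, 1)
  fit3 <- fit_joint_model(y3, fr$t, fr$lay)
  for (L in c("dermis", "epidermis")) {
    sel <- fr$lay == L
    percos <- fit_cosinor(y3[sel], fr$t[sel])
    expect_equal(fit3$per_layer[[L]]$mesor, percos$mesor, tolerance = 1e-10)
    expect_equal(fit3$per_layer[[L]]$a, percos$coef_a, tolerance = 1e-10)
    expect_equal(fit3$per_layer[[L]]$b, percos$coef_b, tolerance = 1e-10)
  }
  expect_error(fit_joint_model(y3[fr$lay == "dermis"], fr$t[fr$lay == "dermis"],
                               fr$lay[fr$lay == "dermis"]), "two layers")
})

test_that("any-rhythm and differential F tests match lm/anova RSS oracles", {
  fr <- two_layer_frame(seed = 2)
  set.seed(31)
  y <- 8 + ifelse(fr$lay == "epidermis", 0.3, 0.1) * cos(fr$w * fr$t) +
    0.2 * sin(fr$w * fr$t) + rnorm(length(fr$t), 0, 0.3)
  fit <- fit_joint_model(y, fr$t, fr$lay)
  L <- factor(fr$lay)
  cw <- cos(fr$w * fr$t); sw <- sin(fr$w * fr$t)
  full <- lm(y ~ 0 + L + L:cw + L:sw)
  p_any_oracle <- anova(lm(y ~ 0 + L), full)[2, "Pr(>F)"]
  p_diff_oracle <- anova(lm(y ~ 0 + L + cw + sw), full)[2, "Pr(>F)"]
  expect_equal(test_any_rhythm(fit), p_any_oracle, tolerance = 1e-10)
  expect_equal(test_differential(fit), p_diff_oracle, tolerance = 1e-10)
})

test_that("both tests are calibrated under their nulls and powered at study size", {
  fr <- two_layer_frame(seed = 3)
  set.seed(41)
  # null of any rhythm: both layers flat
  p_null <- replicate(200, {
    y <- 8 + rnorm(length(fr$t), 0, 0.2)
    test_any_rhythm(fit_joint_model(y, fr$t, fr$lay))
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)

  # null of differential rhythmicity: equal coefficients in both layers
  p_diff_null <- replicate(200, {
    y <- 8 + 0.5 * cos(fr$w * fr$t) + rnorm(length(fr$t), 0, 0.2)
    test_differential(fit_joint_model(y, fr$t, fr$lay))
  })
  expect_gt(ks.test(p_diff_null, "punif")$p.value, 0.01)

  # power: one layer rhythmic with A = 0.5, sigma = 0.2, n = 154
  y_pow <- 8 + ifelse(fr$lay == "epidermis", 0.5, 0) * cos(fr$w * fr$t) +
    rnorm(length(fr$t), 0, 0.2)
  expect_lt(test_any_rhythm(fit_joint_model(y_pow, fr$t, fr$lay)), 1e-6)

  # antiphase layers: a_e = -a_d = 0.5
  y_anti <- 8 + ifelse(fr$lay == "epidermis", 0.5, -0.5) * cos(fr$w * fr$t) +
    rnorm(length(fr$t), 0, 0.2)
  expect_lt(test_differential(fit_joint_model(y_anti, fr$t, fr$lay)), 1e-6)
})

test_that("categorization applies the gate, sub-threshold inclusion and partition", {
  # constructed table: one clearly rhythmic gene with indistinguishable
  # rhythms, dermis FC 1.6, epidermis FC 1.2 -> counted rhythmic in BOTH
  mk <- function(p_any, p_diff, fc_d, fc_e) {
    amp_d <- fc_to_amplitude(fc_d); amp_e <- fc_to_amplitude(fc_e)
    df <- data.frame(gene_id = sprintf("g%02d", seq_along(p_any)),
                     fold_change_dermis = fc_d, fold_change_epidermis = fc_e,
                     amplitude_dermis = amp_d, amplitude_epidermis = amp_e,
                     p_any = p_any, p_diff = p_diff)
    attr(df, "layers") <- c("dermis", "epidermis")
    df
  }
  tab <- categorize(mk(p_any = c(1e-8, 0.9), p_diff = c(0.5, 0.6),
                       fc_d = c(1.6, 1.0), fc_e = c(1.2, 1.0)))
  expect_equal(tab$category, c("both_indistinguishable", "not_rhythmic"))
  # the sub-threshold layer still counts the gene as rhythmic
  sets <- rhythmic_genes_by_layer(tab)
  expect_equal(sets$dermis, "g01")
  expect_equal(sets$epidermis, "g01")

  # all-flat table -> everything not_rhythmic
  flat <- categorize(mk(p_any = runif(5, 0.2, 1), p_diff = runif(5),
                        fc_d = rep(1, 5), fc_e = rep(1, 5)))
  expect_true(all(flat$category == "not_rhythmic"))

  expect_error(categorize(mk(1e-8, 0.5, 1.6, 1.2), fdr = 1.5), "\\(0, 1\\)")
  expect_error(categorize(mk(1e-8, 0.5, 1.6, 1.2), fc_threshold = 0.8),
               "exceed 1")
})

test_that("categories partition genes and respect layer-swap symmetry", {
  cfg <- cohort_config(n_genes = 200, frac_rhythmic = 0.2, seed = 17,
                       layer_mode = "fixed_contrast",
                       sigma_subj = diag(c(0.05, 0.03, 0.03)^2),
                       resid_sd = 0.2)
  sim <- simulate_cohort(cfg)
  tab <- categorize(differential_rhythm_scan(sim$matrix, sim$records))
  counts <- summarize_categories(tab)
  expect_equal(counts$not_rhythmic + counts$both_indistinguishable +
                 counts$both_differential + counts$dermis_only +
                 counts$epidermis_only, nrow(tab))
  # partition identity per layer
  diff_above_d <- sum(tab$category == "both_differential" &
                        tab$fold_change_dermis > 1.5)
  expect_equal(counts$total_dermis,
               counts$both_indistinguishable + counts$dermis_only + diff_above_d)

  # swapping layer labels swaps the *_only counts, p_diff invariant
  rec_sw <- sim$records
  rec_sw$layer <- ifelse(rec_sw$layer == "dermis", "epidermis", "dermis")
  tab_sw <- categorize(differential_rhythm_scan(sim$matrix, rec_sw))
  counts_sw <- summarize_categories(tab_sw)
  expect_equal(counts_sw$dermis_only, counts$epidermis_only)
  expect_equal(counts_sw$epidermis_only, counts$dermis_only)
  expect_equal(tab_sw$p_diff, tab$p_diff, tolerance = 1e-10)
})

test_that("circular phase statistics follow vector-sum geometry", {
  ph <- c(1, 5, 13, 22)
  same <- circular_phase_stats(ph, ph)
  expect_equal(same$mean_difference_h, 0)
  expect_equal(same$rayleigh_R, 1)

  # two pairs at +3 and -3 h: mean 0, R = cos(3 * 2pi / 24)
  st <- circular_phase_stats(c(3, 21), c(0, 0))
  expect_equal(st$mean_difference_h, 0, tolerance = 1e-10)
  expect_equal(st$rayleigh_R, cos(3 * 2 * pi / 24), tolerance = 1e-10)

  # uniform differences -> tiny resultant
  set.seed(8)
  u <- runif(10000, 0, 24)
  expect_lt(circular_phase_stats(u, rep(0, 10000))$rayleigh_R, 0.05)

  # wrap-around differences land in (-12, 12]
  st2 <- circular_phase_stats(23, 1)
  expect_equal(st2$mean_difference_h, -2)
  expect_error(circular_phase_stats(1:3, 1:2), "length")
})
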