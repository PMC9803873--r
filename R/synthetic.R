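# Synthetic two-layer skin cohort generator.  Data are drawn from the same
# generative model the variability analysis assumes: per-gene fixed cosinor
# coefficients plus per-subject (full 3x3 covariance) and per-layer
# (diagonal covariance) random deviations of (MESOR, cos, sin), additive
# Gaussian residual noise, and wall-clock sampling identical across
# subjects so that internal-time non-uniformity emerges from chronotype
# exactly as in a real cohort.

#' Configuration for a synthetic skin cohort
#'
#' Defaults emulate the study conditions the analysis is designed for:
#' 11 subjects x 2 layers x 7 wall timepoints at 4 h spacing over 24 h
#' (8:00 through 32:00, unwrapped), chronotypes (MSF_sc) uniform over a
#' 3.5 h interval, ~10% rhythmic genes, bimodal acrophases concentrated
#' near 1 h and 13 h after MSF_sc, lognormal amplitudes with a larger
#' epidermis median, a full 3x3 subject covariance and a diagonal layer
#' covariance on the (MESOR, cos, sin) coefficients, and additive Gaussian
#' residual noise.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param timepoints Wall sampling times in hours (default seq(8, 32, 4)).
#' @param layers Layer labels (default dermis, epidermis).
#' @param msf_range Chronotype range in hours, width <= 3.5 (default
#'   c(2.5, 6)).
#' @param n_genes Number of genes (default 1000).
#' @param frac_rhythmic Fraction of rhythmic genes (default 0.10).
#' @param amp_meanlog Named meanlog of the lognormal log2-amplitude law per
#'   layer (defaults: dermis log(0.35), epidermis log(0.5)).
#' @param amp_sdlog Lognormal sdlog of amplitudes (default 0.4).
#' @param phase_centers_h Acrophase mixture centers in internal hours
#'   (default c(1, 13)).
#' @param phase_kappa Von Mises concentration of each mixture component
#'   (default 2).
#' @param phase_weights Mixture weights (default equal).
#' @param mesor_mean,mesor_sd Law of gene MESORs in log2 units (defaults 8,
#'   1.5).
#' @param sigma_subj 3x3 subject covariance of (MESOR, cos, sin) deviations
#'   (default: SDs 0.15/0.10/0.10 with correlation 0.3).
#' @param sigma_layer Diagonal 3x3 layer covariance (default: SDs
#'   0.30/0.05/0.05 -- MESOR more layer-variable than rhythm coefficients).
#' @param resid_sd Residual noise SD in log2 units (default 0.2).
#' @param layer_mode `"random"` (default): layer deviations drawn per gene
#'   per layer from `sigma_layer`, matching the diagonal-covariance model;
#'   `"fixed_contrast"`: per-layer amplitudes drawn from the layer-specific
#'   amplitude laws so the epidermis-larger-amplitude regime is generated
#'   deterministically.
#' @param seed Mandatory integer master seed.
#' @return Validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 11,
                          timepoints = seq(8, 32, by = 4),
                          layers = c("dermis", "epidermis"),
                          msf_range = c(2.5, 6),
                          n_genes = 1000,
                          frac_rhythmic = 0.10,
                          amp_meanlog = c(dermis = log(0.35), epidermis = log(0.5)),
                          amp_sdlog = 0.4,
                          phase_centers_h = c(1, 13),
                          phase_kappa = 2,
                          phase_weights = c(0.5, 0.5),
                          mesor_mean = 8, mesor_sd = 1.5,
                          sigma_subj = default_sigma_subj(),
                          sigma_layer = diag(c(0.30, 0.05, 0.05)^2),
                          resid_sd = 0.2,
                          layer_mode = c("random", "fixed_contrast"),
                          seed) {
  if (missing(seed) || !is_count(seed)) stopf("an integer seed is mandatory")
  layer_mode <- match.arg(layer_mode)
  if (frac_rhythmic < 0 || frac_rhythmic > 1)
    stopf("frac_rhythmic must lie in [0, 1]")
  if (diff(range(msf_range)) > 3.5)
    stopf("msf_range wider than 3.5 h")
  check_cov <- function(S, name, diagonal = FALSE) {
    if (!is.matrix(S) || any(dim(S) != 3L) || !isSymmetric(unname(S)))
      stopf("%s must be a symmetric 3x3 matrix", name)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stopf("%s is not positive semi-definite", name)
    if (diagonal && any(abs(S[upper.tri(S)]) > 0))
      stopf("%s must be diagonal", name)
  }
  check_cov(sigma_subj, "sigma_subj")
  check_cov(sigma_layer, "sigma_layer", diagonal = TRUE)
  if (length(layers) != 2L) stopf("exactly two layers required")
  if (is.null(names(amp_meanlog))) names(amp_meanlog) <- layers
  structure(list(
    n_subjects = n_subjects, timepoints = timepoints, layers = layers,
    msf_range = msf_range, n_genes = n_genes, frac_rhythmic = frac_rhythmic,
    amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
    phase_centers_h = phase_centers_h, phase_kappa = phase_kappa,
    phase_weights = phase_weights, mesor_mean = mesor_mean,
    mesor_sd = mesor_sd, sigma_subj = sigma_subj, sigma_layer = sigma_layer,
    resid_sd = resid_sd, layer_mode = layer_mode, seed = as.integer(seed)
  ), class = "cohort_config")
}

default_sigma_subj <- function() {
  sds <- c(0.15, 0.10, 0.10)
  R <- matrix(0.3, 3, 3); diag(R) <- 1
  diag(sds) %*% R %*% diag(sds)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), mu/output radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (u[2] < c_ * (2 - c_) || u[2] <= c_ * exp(1 - c_)) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

rmvnorm3 <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
  matrix(stats::rnorm(3 * n), n, 3) %*% t(L)
}

#' Simulate a synthetic two-layer cohort with known truth
#'
#' Generates expression as fixed cosinor part + layer deviation + subject
#' deviation + Gaussian noise, with internal time = wall time - MSF_sc.
#' Identical seeds give bit-identical outputs.
#'
#' @param config A [cohort_config()].
#' @return List with `matrix` (genes x samples log2), `records` (sample
#'   metadata data.frame with internal time populated) and `truth`
#'   (per-gene fixed effects and rhythmic flags, realized per-subject and
#'   per-layer effect matrices, per-subject MSF_sc, config echo).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  msf <- stats::setNames(
    stats::runif(cfg$n_subjects, cfg$msf_range[1], cfg$msf_range[2]), subjects)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_rhythmic <- round(cfg$n_genes * cfg$frac_rhythmic)
  rhythmic <- c(rep(TRUE, n_rhythmic), rep(FALSE, cfg$n_genes - n_rhythmic))
  w <- omega_for(24)

  mesor <- stats::rnorm(cfg$n_genes, cfg$mesor_mean, cfg$mesor_sd)
  comp <- sample(seq_along(cfg$phase_centers_h), cfg$n_genes, replace = TRUE,
                 prob = cfg$phase_weights)
  phase <- vapply(seq_len(cfg$n_genes), function(i)
    rvonmises(1, cfg$phase_centers_h[comp[i]] * w, cfg$phase_kappa) / w, 0)

  # per-layer amplitude laws; fixed effects are the layer average
  amp_by_layer <- sapply(cfg$layers, function(L)
    stats::rlnorm(cfg$n_genes, cfg$amp_meanlog[[L]], cfg$amp_sdlog))
  amp_by_layer[!rhythmic, ] <- 0
  if (cfg$layer_mode == "fixed_contrast") {
    a_layer <- amp_by_layer * cos(w * phase)
    b_layer <- amp_by_layer * sin(w * phase)
    a_fix <- rowMeans(a_layer); b_fix <- rowMeans(b_layer)
    layer_eff <- lapply(seq_along(cfg$layers), function(i)
      cbind(m = stats::rnorm(cfg$n_genes, 0, sqrt(cfg$sigma_layer[1, 1])),
            a = a_layer[, i] - a_fix, b = b_layer[, i] - b_fix))
  } else {
    amp_fix <- exp(rowMeans(log(amp_by_layer)))  # geometric layer-mean law
    a_fix <- amp_fix * cos(w * phase)
    b_fix <- amp_fix * sin(w * phase)
    layer_eff <- lapply(seq_along(cfg$layers), function(i)
      rmvnorm3(cfg$n_genes, cfg$sigma_layer))
  }
  a_fix[!rhythmic] <- 0; b_fix[!rhythmic] <- 0
  for (i in seq_along(layer_eff)) {
    colnames(layer_eff[[i]]) <- c("m", "a", "b")
    rownames(layer_eff[[i]]) <- genes
  }
  names(layer_eff) <- cfg$layers

  subj_eff <- lapply(subjects, function(s) {
    e <- rmvnorm3(cfg$n_genes, cfg$sigma_subj)
    dimnames(e) <- list(genes, c("m", "a", "b"))
    e
  })
  names(subj_eff) <- subjects

  records <- expand.grid(wall_time_h = cfg$timepoints, layer = cfg$layers,
                         subject_id = subjects, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  records$msf_sc_h <- msf[records$subject_id]
  records$sample_id <- sprintf("%s_%s_T%02d", toupper(substr(records$layer, 1, 1)),
                               records$subject_id, records$wall_time_h)
  records <- to_internal_time(records)
  records <- records[, c("sample_id", "subject_id", "layer", "wall_time_h",
                         "msf_sc_h", "internal_time_h")]

  M <- matrix(0, cfg$n_genes, nrow(records),
              dimnames = list(genes, records$sample_id))
  for (j in seq_len(nrow(records))) {
    s <- records$subject_id[j]; L <- records$layer[j]
    t <- records$internal_time_h[j]
    mj <- mesor + subj_eff[[s]][, "m"] + layer_eff[[L]][, "m"]
    aj <- a_fix + subj_eff[[s]][, "a"] + layer_eff[[L]][, "a"]
    bj <- b_fix + subj_eff[[s]][, "b"] + layer_eff[[L]][, "b"]
    M[, j] <- mj + aj * cos(w * t) + bj * sin(w * t)
  }
  M <- M + matrix(stats::rnorm(length(M), 0, cfg$resid_sd), nrow(M))

  truth_genes <- data.frame(
    gene_id = genes, rhythmic = rhythmic, m = mesor, a = a_fix, b = b_fix,
    amplitude = sqrt(a_fix^2 + b_fix^2),
    acrophase_h = ifelse(rhythmic, (atan2(b_fix, a_fix) / w) %% 24, NA_real_),
    resid_sd = cfg$resid_sd, row.names = NULL)
  list(matrix = M, records = records,
       truth = list(genes = truth_genes, subject_effects = subj_eff,
                    layer_effects = layer_eff, msf_sc = msf, config = cfg))
}

#' Compare ground truth with analysis estimates
#'
#' Per shared numeric quantity: bias (mean estimate - truth), RMSE and
#' Spearman rank correlation; phases use circular differences; categorical
#' columns report accuracy (fraction of exact matches).
#'
#' @param truth Data.frame with `gene_id` plus truth columns.
#' @param estimates Data.frame with `gene_id` plus columns named like the
#'   truth columns.
#' @param period Period for circular quantities (default 24); any column
#'   whose name contains "phase" or "acrophase" is treated as circular.
#' @return Data.frame: `quantity`, `n`, `bias`, `rmse`, `rank_cor`,
#'   `accuracy`.
#' @export
truth_vs_estimates_report <- function(truth, estimates, period = 24) {
  if (!all(c("gene_id") %in% names(truth)) ||
      !all(c("gene_id") %in% names(estimates)))
    stopf("both tables need a gene_id column")
  common_genes <- intersect(truth$gene_id, estimates$gene_id)
  if (length(common_genes) == 0L) stopf("no shared gene ids")
  tr <- truth[match(common_genes, truth$gene_id), ]
  es <- estimates[match(common_genes, estimates$gene_id), ]
  qs <- setdiff(intersect(names(truth), names(estimates)), "gene_id")
  rows <- lapply(qs, function(q) {
    tv <- tr[[q]]; ev <- es[[q]]
    keep <- !is.na(tv) & !is.na(ev)
    tv <- tv[keep]; ev <- ev[keep]
    if (length(tv) == 0L) return(NULL)
    if (is.numeric(tv)) {
      circular <- grepl("phase", q)
      d <- if (circular) wrap_half_period(ev - tv, period) else ev - tv
      data.frame(quantity = q, n = length(tv), bias = mean(d),
                 rmse = sqrt(mean(d^2)),
                 rank_cor = suppressWarnings(
                   stats::cor(tv, ev, method = "spearman")),
                 accuracy = NA_real_, row.names = NULL)
    } else {
      data.frame(quantity = q, n = length(tv), bias = NA_real_,
                 rmse = NA_real_, rank_cor = NA_real_,
                 accuracy = mean(as.character(tv) == as.character(ev)),
                 row.names = NULL)
    }
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
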