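# Single-sample internal-time prediction from sparse principal components
# of periodic expression curves (the ZeitZeiger idea, re-specified
# self-containedly: periodic harmonic basis + penalized-matrix-decomposition
# sparse PCA + Gaussian maximum-likelihood decoding on a time grid).

#' Periodic harmonic basis matrix
#' @noRd
periodic_basis <- function(t, period, order) {
  w <- omega_for(period)
  out <- matrix(1, length(t), 1 + 2 * order)
  for (k in seq_len(order)) {
    out[, 2 * k] <- cos(k * w * t)
    out[, 2 * k + 1] <- sin(k * w * t)
  }
  out
}

#' Fit periodic mean curves for every gene
#'
#' Least-squares fit, per gene, of a periodic harmonic basis (orders 1 to
#' `n_knots - 1`) to expression versus time modulo the period.
#'
#' @param matrix Genes x samples numeric matrix.
#' @param internal_times Internal time in hours per sample.
#' @param period Period in hours (default 24).
#' @param n_knots Flexibility: harmonics up to order `n_knots - 1`
#'   (default 3, i.e. two harmonics, 5 coefficients).
#' @return Object of class `periodic_curves` with a coefficient matrix
#'   (genes x basis); evaluate with [predict_curves()].
#' @export
fit_periodic_curves <- function(matrix, internal_times, period = 24,
                                n_knots = 3) {
  order <- n_knots - 1L
  p <- 1L + 2L * order
  tmod <- round(internal_times %% period, 8)
  if (length(unique(tmod)) < 2L * n_knots)
    stopf("need >= %d distinct times modulo the period, got %d",
          2L * n_knots, length(unique(tmod)))
  B <- periodic_basis(internal_times, period, order)
  qrB <- qr(B)
  if (qrB$rank < p) stopf("degenerate time support for the periodic basis")
  coef <- t(qr.coef(qrB, t(matrix)))             # genes x p
  if (is.null(dim(coef))) coef <- matrix(coef, nrow = 1,
                                         dimnames = list(rownames(matrix), NULL))
  structure(list(coef = coef, period = period, order = order,
                 gene_ids = rownames(matrix)),
            class = "periodic_curves")
}

#' Evaluate fitted periodic curves at given times
#' @param curves A `periodic_curves` object.
#' @param t Times in hours.
#' @return Genes x times matrix of curve values.
#' @export
predict_curves <- function(curves, t) {
  B <- periodic_basis(t, curves$period, curves$order)
  out <- curves$coef %*% t(B)
  rownames(out) <- curves$gene_ids
  out
}

# scale |v|_1 to <= c on the unit l2 sphere via soft thresholding
l1_unit_project <- function(z, c) {
  v <- z / sqrt(sum(z^2))
  if (sum(abs(v)) <= c) return(v)
  lo <- 0; hi <- max(abs(z))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- sign(z) * pmax(abs(z) - mid, 0)
    ns <- sqrt(sum(s^2))
    if (ns == 0) { hi <- mid; next }
    if (sum(abs(s / ns)) > c) lo <- mid else hi <- mid
  }
  s <- sign(z) * pmax(abs(z) - hi, 0)
  s / sqrt(sum(s^2))
}

#' Sparse principal components by penalized matrix decomposition
#'
#' Computes `nSPC` sparse loading vectors over genes: each component solves
#' \eqn{\max u^T X v} subject to \eqn{\|u\|_2 \le 1, \|v\|_2 \le 1,
#' \|v\|_1 \le \mathrm{sumabsv}} by alternating soft-thresholded power
#' iterations, with rank-1 deflation between components and deterministic
#' initialization from the leading singular vector.  `sumabsv = 1` forces a
#' single nonzero loading; `sumabsv >= sqrt(n_genes)` leaves the constraint
#' inactive (dense PCA loadings).
#'
#' @param curve_matrix Genes x timegrid matrix of fitted curve values
#'   (rows are centered internally).
#' @param sumabsv L1 bound on each loading column (>= 1).
#' @param nSPC Number of components.
#' @return Genes x nSPC loading matrix (unit l2 columns, l1 <= sumabsv);
#'   attribute `"d"` holds the singular values.
#' @export
sparse_pcs <- function(curve_matrix, sumabsv, nSPC) {
  if (sumabsv < 1) stopf("sumabsv must be >= 1 (unit l2 vectors have l1 >= 1)")
  cm <- curve_matrix - rowMeans(curve_matrix)
  X <- t(cm)                                     # time x genes
  ng <- ncol(X)
  V <- matrix(0, ng, nSPC, dimnames = list(rownames(curve_matrix), NULL))
  d <- numeric(nSPC)
  for (comp in seq_len(nSPC)) {
    sv <- svd(X, nu = 1, nv = 1)
    if (sv$d[1] < 1e-12) break                   # nothing left to explain
    v <- l1_unit_project(sv$v[, 1], sumabsv)
    for (it in 1:200) {
      xu <- X %*% v
      nu <- sqrt(sum(xu^2))
      if (nu == 0) break
      u <- xu / nu
      z <- drop(crossprod(X, u))
      v_new <- l1_unit_project(z, sumabsv)
      if (sqrt(sum((v_new - v)^2)) < 1e-9) { v <- v_new; break }
      v <- v_new
    }
    u <- X %*% v; u <- u / sqrt(sum(u^2))
    dc <- drop(crossprod(u, X %*% v))
    # deterministic sign: largest-|loading| gene positive
    s <- sign(v[which.max(abs(v))])
    V[, comp] <- v * s
    d[comp] <- dc
    X <- X - dc * u %*% t(v)
  }
  attr(V, "d") <- d
  V
}

#' Train a single-sample internal-time predictor
#'
#' Pipeline: per-gene centering/scaling on the training samples -> periodic
#' curve fit per gene -> sparse principal components of the curve matrix
#' evaluated on a time grid -> projection of training samples onto the
#' loadings -> periodic mean curve plus constant Gaussian variance per SPC
#' score.  Train one predictor per layer (pass one layer's samples).
#'
#' @param matrix Genes x samples log2 expression matrix (one layer).
#' @param records Metadata for those samples, `internal_time_h` populated.
#' @param sumabsv L1 bound for [sparse_pcs()].
#' @param nSPC Number of sparse components.
#' @param period Period in hours (default 24).
#' @param n_knots Periodic-basis flexibility (default 3).
#' @param grid_step Curve-evaluation grid step in hours (default 0.5).
#' @return Object of class `time_predictor`.
#' @export
train_predictor <- function(matrix, records, sumabsv, nSPC, period = 24,
                            n_knots = 3, grid_step = 0.5) {
  ids <- intersect(colnames(matrix), records$sample_id)
  if (length(ids) < nSPC + 2L)
    stopf("need at least nSPC + 2 = %d samples, got %d", nSPC + 2L, length(ids))
  records <- records[match(ids, records$sample_id), ]
  M <- matrix[, ids, drop = FALSE]
  times <- records$internal_time_h
  ctr <- rowMeans(M)
  scl <- apply(M, 1, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Ms <- (M - ctr) / scl
  curves <- fit_periodic_curves(Ms, times, period, n_knots)
  tgrid <- seq(0, period - grid_step, by = grid_step)
  cm <- predict_curves(curves, tgrid)
  V <- sparse_pcs(cm, sumabsv, nSPC)
  scores <- t(Ms) %*% V                           # samples x nSPC
  score_curves <- fit_periodic_curves(t(scores), times, period, n_knots)
  fitted <- t(predict_curves(score_curves, times))
  resid_var <- colSums((scores - fitted)^2) /
    max(1, nrow(scores) - ncol(score_curves$coef))
  resid_var <- pmax(resid_var, 1e-12)
  curve_range <- apply(predict_curves(score_curves, tgrid), 1,
                       function(x) diff(range(x)))
  structure(list(
    gene_ids = rownames(M), center = ctr, scale = scl,
    loadings = V, n_genes_selected = sum(rowSums(abs(V)) > 0),
    score_curve_coef = score_curves$coef, score_resid_var = resid_var,
    sumabsv = sumabsv, nSPC = nSPC, period = period, n_knots = n_knots,
    uninformative = all(curve_range < 1e-8)
  ), class = "time_predictor")
}

#' @export
print.time_predictor <- function(x, ...) {
  cat(sprintf("time predictor: %d SPC(s), sumabsv %g, %d gene(s) with nonzero loadings%s\n",
              x$nSPC, x$sumabsv, x$n_genes_selected,
              if (x$uninformative) " [UNINFORMATIVE: flat score curves]" else ""))
  invisible(x)
}

#' Predict internal time from one expression sample
#'
#' Maximizes, over a time grid, the Gaussian log-likelihood of the sample's
#' SPC scores given the per-SPC periodic mean curves and constant
#' variances.  Ties break to the earliest grid time.
#'
#' @param model A `time_predictor`.
#' @param sample Named numeric vector of log2 expression covering the
#'   model's genes.
#' @param grid_resolution Decoding grid step in hours (default 0.1).
#' @return Predicted internal time in hours, in \[0, period).
#' @export
predict_time <- function(model, sample, grid_resolution = 0.1) {
  missing <- setdiff(model$gene_ids, names(sample))
  if (length(missing) > 0L)
    stopf("sample is missing model gene(s): %s",
          paste(utils::head(missing, 10), collapse = ", "))
  x <- (sample[model$gene_ids] - model$center) / model$scale
  scores <- drop(crossprod(model$loadings, x))   # nSPC
  tgrid <- seq(0, model$period - grid_resolution, by = grid_resolution)
  B <- periodic_basis(tgrid, model$period, model$n_knots - 1L)
  means <- B %*% t(model$score_curve_coef)       # grid x nSPC
  ll <- -0.5 * colSums((t(means) - scores)^2 / model$score_resid_var)
  tgrid[which.max(ll)]
}

#' Leave-one-subject-out cross-validation of the time predictor
#'
#' For each held-out subject, trains on the remaining subjects and predicts
#' every held-out sample; the error is the circular absolute difference
#' between predicted and true internal time (in \[0, period/2\]) and the MAE
#' is the median error over all held-out samples, one per
#' (sumabsv, nSPC) grid point.
#'
#' @param matrix Genes x samples log2 expression matrix (one layer).
#' @param records Metadata for those samples.
#' @param sumabsv_grid Candidate l1 bounds (default c(1, 1.5, 2, 3)).
#' @param nspc_grid Candidate component counts (default c(2, 3)).
#' @param period Period in hours (default 24).
#' @param ... Passed to [train_predictor()].
#' @return Object of class `cv_result`: `grid` data.frame with `sumabsv`,
#'   `nSPC`, `mae_h`, `n_genes_selected`; `errors` (per grid point, per
#'   held-out sample); `best` row index.
#' @export
loso_cv <- function(matrix, records, sumabsv_grid = c(1, 1.5, 2, 3),
                    nspc_grid = c(2, 3), period = 24, ...) {
  subjects <- unique(records$subject_id)
  if (length(subjects) < 3L) stopf("need >= 3 subjects for LOSO CV")
  grid <- expand.grid(sumabsv = sumabsv_grid, nSPC = nspc_grid,
                      KEEP.OUT.ATTRS = FALSE)
  errors <- vector("list", nrow(grid))
  genes_sel <- integer(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    errs <- c()
    nsel <- c()
    for (s in subjects) {
      train_rec <- records[records$subject_id != s, ]
      test_rec <- records[records$subject_id == s, ]
      if (nrow(test_rec) == 0L) {
        warning("subject ", s, " has no samples; skipped")
        next
      }
      model <- train_predictor(matrix[, train_rec$sample_id, drop = FALSE],
                               train_rec, grid$sumabsv[gi], grid$nSPC[gi],
                               period, ...)
      nsel <- c(nsel, model$n_genes_selected)
      pred <- vapply(test_rec$sample_id, function(id)
        predict_time(model, matrix[, id]), 0)
      errs <- c(errs, circ_abs_diff(pred, test_rec$internal_time_h, period))
    }
    errors[[gi]] <- errs
    genes_sel[gi] <- round(mean(nsel))
  }
  grid$mae_h <- vapply(errors, stats::median, 0)
  grid$n_genes_selected <- genes_sel
  structure(list(grid = grid, errors = errors,
                 best = which.min(grid$mae_h), period = period),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("leave-one-subject-out CV (MAE in hours):\n")
  print(x$grid, row.names = FALSE)
  b <- x$grid[x$best, ]
  cat(sprintf("best: sumabsv %g, nSPC %d -> MAE %.2f h (%d genes)\n",
              b$sumabsv, b$nSPC, b$mae_h, b$n_genes_selected))
  invisible(x)
}

#' Serialize a time predictor to JSON
#' @param model A `time_predictor`.
#' @param path Output path.
#' @export
write_time_predictor <- function(model, path) {
  obj <- unclass(model)
  obj$loadings <- list(genes = rownames(model$loadings),
                       values = unname(as.data.frame(model$loadings)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized time predictor
#' @param path Path written by [write_time_predictor()].
#' @return A `time_predictor`.
#' @export
read_time_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(as.data.frame(obj$loadings$values))
  rownames(L) <- obj$loadings$genes
  colnames(L) <- NULL
  obj$loadings <- L
  obj$center <- stats::setNames(obj$center, obj$gene_ids)
  obj$scale <- stats::setNames(obj$scale, obj$gene_ids)
  obj$score_curve_coef <- matrix(unlist(obj$score_curve_coef),
                                 nrow = obj$nSPC, byrow = FALSE)
  structure(obj, class = "time_predictor")
}
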