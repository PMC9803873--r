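#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a query
#' list against a caller-supplied background universe (no default: analyses
#' legitimately use different universes, e.g. all expressed genes vs all
#' diurnal genes).  Sets are intersected with the background before testing.
#' Sets with fewer than `min_set` query members are excluded before the BH
#' correction.
#'
#' @param query Character vector of query gene ids (must be contained in
#'   the background).
#' @param collections Named list of gene sets (see [load_gmt()]).
#' @param background Character vector: the gene universe.
#' @param min_set Minimum number of query genes a set must contain to be
#'   tested (default 20).
#' @return Data.frame: `set_name`, `overlap` (k), `set_size_in_background`
#'   (K), `query_size` (n), `background_size` (N), `p`, `q`; sorted by `p`.
#' @export
hypergeom_ora <- function(query, collections, background, min_set = 20) {
  background <- unique(background)
  if (length(background) == 0L) stopf("empty background")
  query <- unique(query)
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg) > 0L)
    stopf("query gene(s) not in background: %s",
          paste(utils::head(out_of_bg, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collections), function(nm) {
    set_bg <- intersect(collections[[nm]], background)
    K <- length(set_bg)
    k <- length(intersect(set_bg, query))
    data.frame(set_name = nm, overlap = k, set_size_in_background = K,
               query_size = n, background_size = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_name = character(0), overlap = integer(0),
                      set_size_in_background = integer(0),
                      query_size = integer(0), background_size = integer(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- out[out$overlap >= min_set, , drop = FALSE]
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Kuiper test of circular uniformity for acrophases
#'
#' Maps phases to \[0, 1) fractions of the period and computes the Kuiper
#' statistic \eqn{V = D^+ + D^-} against the uniform CDF.  Unlike the
#' Kolmogorov-Smirnov statistic, V is invariant to rotating all phases by a
#' constant, which is essential on the circle.  The asymptotic p-value uses
#' Stephens' small-sample correction
#' \eqn{\lambda = V(\sqrt{n} + 0.155 + 0.24/\sqrt{n})} with the series
#' \eqn{p = 2\sum_{j\ge1}(4j^2\lambda^2 - 1)e^{-2j^2\lambda^2}}; a
#' Monte-Carlo p-value is available for small n.
#'
#' @param phases Acrophases in hours (n >= 5).
#' @param period Period in hours (default 24).
#' @param p_method `"asymptotic"` (default) or `"montecarlo"`.
#' @param n_mc Monte-Carlo draws when `p_method = "montecarlo"`.
#' @return List with `V` and `p`.
#' @export
kuiper_uniform_test <- function(phases, period = 24,
                                p_method = c("asymptotic", "montecarlo"),
                                n_mc = 10000) {
  p_method <- match.arg(p_method)
  n <- length(phases)
  if (n < 5L) stopf("need at least 5 phases, got %d", n)
  V <- kuiper_stat((phases %% period) / period)
  if (p_method == "asymptotic") {
    p <- kuiper_p_asymptotic(V, n)
  } else {
    null_V <- vapply(seq_len(n_mc),
                     function(i) kuiper_stat(stats::runif(n)), 0)
    p <- (1 + sum(null_V >= V)) / (n_mc + 1)
  }
  list(V = V, p = p)
}

kuiper_stat <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  max(i / n - u) + max(u - (i - 1) / n)
}

kuiper_p_asymptotic <- function(V, n) {
  lambda <- V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Phase set enrichment analysis (PSEA)
#'
#' Tests, per gene set, whether the acrophases of its diurnal members are
#' non-uniformly distributed around the clock (i.e. the set is phase
#' synchronized).  Acrophases are rounded to the full hour before testing;
#' sets with fewer than `min_set` diurnal members (after intersection with
#' the phase table) are excluded; BH correction is applied across tested
#' sets.
#'
#' @param phase_table Named numeric vector: acrophase in hours per diurnal
#'   gene (only diurnal genes should be supplied).
#' @param collections Named list of gene sets.
#' @param min_set Minimum diurnal members per set (default 5).
#' @param q_threshold Significance threshold on the BH q-value (default 0.05).
#' @param period Period in hours (default 24).
#' @param p_method Passed to [kuiper_uniform_test()].
#' @return Data.frame: `set_name`, `n_diurnal_members`, `kuiper_V`, `p`,
#'   `q`, `significant`; sorted by `p`.
#' @export
psea <- function(phase_table, collections, min_set = 5, q_threshold = 0.05,
                 period = 24, p_method = "asymptotic") {
  if (length(collections) == 0L) {
    return(data.frame(set_name = character(0), n_diurnal_members = integer(0),
                      kuiper_V = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  if (is.null(names(phase_table))) stopf("phase_table must be named by gene id")
  rounded <- round(phase_table) %% period
  rows <- lapply(names(collections), function(nm) {
    members <- intersect(collections[[nm]], names(phase_table))
    if (length(members) < min_set) return(NULL)
    kt <- kuiper_uniform_test(rounded[members], period, p_method = p_method)
    data.frame(set_name = nm, n_diurnal_members = length(members),
               kuiper_V = kt$V, p = kt$p, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(set_name = character(0), n_diurnal_members = integer(0),
                      kuiper_V = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_threshold
  out[order(out$p), , drop = FALSE]
}
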