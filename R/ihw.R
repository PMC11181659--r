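# Covariate-weighted false discovery rate control.
#
# Hypothesis weights are learned from an informative covariate that is
# independent of the p-value under the null (here: the mean nonDEL CERES
# score). The covariate is split into quantile bins; per-bin weights are
# chosen by cross-fitting (weights used on a fold are learned on the other
# folds only) under the budget constraint sum_b w_b * m_b = m, and the
# adjusted p-values are Benjamini-Hochberg on p_i / w_bin(i).

# Discoveries of weighted BH at level alpha: largest k with q_(k) <= alpha*k/m.
# Only q <= alpha can be discovered, so sorting that subset is exact.
wbh_discoveries <- function(q, m, alpha) {
  qs <- q[q <= alpha]
  if (!length(qs)) return(0L)
  qs <- sort(qs)
  ok <- which(qs <= alpha * seq_along(qs) / m)
  if (!length(ok)) 0L else max(ok)
}

# Candidate per-bin weight vectors: the full grid over `grid` values,
# normalized to the budget for bin counts m_b, deduplicated.
weight_candidates <- function(grid, m_b) {
  n_bins <- length(m_b)
  raw <- as.matrix(expand.grid(rep(list(grid), n_bins)))
  norm <- raw * (sum(m_b) / as.numeric(raw %*% m_b))
  norm <- rbind(rep(1, n_bins), norm) # always offer the unweighted solution
  unique(round(norm, 12))
}

#' Covariate-weighted p-value adjustment
#'
#' Splits the covariate into `n_bins` quantile bins, learns non-negative
#' per-bin hypothesis weights by `n_folds`-fold cross-fitting (for each
#' fold, the weight vector maximizing weighted-BH discoveries at level
#' `alpha` on the remaining folds is selected from a normalized grid,
#' subject to the budget \eqn{\sum_b w_b m_b = m}; ties prefer the most
#' uniform weights), and returns Benjamini-Hochberg adjusted values of
#' \eqn{p_i / w_{bin(i)}} clipped to \[0, 1\]. With a single bin (or fewer
#' hypotheses than bins, which falls back to one bin with a warning) all
#' weights are 1 and the result is exactly the Benjamini-Hochberg
#' adjustment.
#'
#' @param p Numeric vector of raw p-values.
#' @param covariate Numeric vector (same length), finite for every
#'   hypothesis, independent of `p` under the null.
#' @param alpha FDR control level targeted while learning weights
#'   (default 0.1).
#' @param n_bins Number of covariate quantile bins (default 5).
#' @param n_folds Cross-fitting folds (default 5).
#' @param weight_grid Per-bin raw weight grid searched (default
#'   `c(0.5, 1, 2)` before budget normalization).
#' @param seed Optional seed for the fold assignment.
#' @return List of class `"ihw_fit"`: `p_adj`, per-hypothesis `weights`,
#'   `bins` (bin index per hypothesis), `bin_weights` (folds x bins matrix
#'   of learned weights), plus the settings.
#' @export
ihw_adjust <- function(p, covariate, alpha = 0.1, n_bins = 5L, n_folds = 5L,
                       weight_grid = c(0.5, 1, 2), seed = NULL) {
  m <- length(p)
  if (length(covariate) != m)
    stop_data("p and covariate must have equal length")
  if (anyNA(p) || any(p < 0 | p > 1)) stop_data("p must be in [0, 1]")
  if (any(!is.finite(covariate)))
    stop_data("covariate must be finite for every tested hypothesis")
  n_bins <- as.integer(n_bins)
  if (m < n_bins || n_bins < 1L) {
    if (n_bins > 1L)
      warning("fewer hypotheses than bins; falling back to a single bin (plain BH)")
    n_bins <- 1L
  }
  if (n_bins == 1L) {
    return(structure(list(p_adj = stats::p.adjust(p, "BH"),
                          weights = rep(1, m), bins = rep(1L, m),
                          bin_weights = matrix(1, 1L, 1L), alpha = alpha,
                          n_bins = 1L, n_folds = n_folds),
                     class = "ihw_fit"))
  }
  breaks <- unique(stats::quantile(covariate, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < 3L) {
    warning("degenerate covariate; falling back to a single bin (plain BH)")
    return(ihw_adjust(p, covariate, alpha, n_bins = 1L, n_folds = n_folds))
  }
  bins <- as.integer(cut(covariate, breaks, include.lowest = TRUE))
  n_bins <- max(bins)

  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), m)))
  w <- numeric(m)
  bin_weights <- matrix(NA_real_, n_folds, n_bins,
                        dimnames = list(paste0("fold", seq_len(n_folds)),
                                        paste0("bin", seq_len(n_bins))))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    m_b <- tabulate(bins[tr], n_bins)
    if (any(m_b == 0L)) { # a bin absent from training: learn nothing there
      best <- rep(1, n_bins)
    } else {
      cand <- weight_candidates(weight_grid, m_b)
      p_tr <- p[tr]; b_tr <- bins[tr]; m_tr <- sum(tr)
      disc <- apply(cand, 1L, function(wv)
        wbh_discoveries(p_tr / wv[b_tr], m_tr, alpha))
      spread <- apply(cand, 1L, stats::var)
      best <- cand[order(-disc, spread)[1L], ]
    }
    bin_weights[f, ] <- best
    w[folds == f] <- best[bins[folds == f]]
  }
  w <- w * m / sum(w) # enforce the budget exactly on the assembled weights
  q <- pmin(ifelse(w > 0, p / w, 1), 1)
  structure(list(p_adj = pmin(stats::p.adjust(q, "BH"), 1), weights = w,
                 bins = bins, bin_weights = bin_weights, alpha = alpha,
                 n_bins = n_bins, n_folds = n_folds),
            class = "ihw_fit")
}

#' @export
print.ihw_fit <- function(x, ...) {
  cat(sprintf("ihw_fit: %d hypotheses, %d bin(s), %d fold(s), alpha = %s\n",
              length(x$p_adj), x$n_bins, x$n_folds, format(x$alpha)))
  if (x$n_bins > 1L) {
    cat("mean learned bin weights:\n")
    print(round(colMeans(x$bin_weights), 3))
  }
  invisible(x)
}
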