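# Label-free proteomics differential abundance: valid-value filtering,
# quantile normalization, per-sample downshifted imputation of missing
# intensities, and moderated two-group tests with Benjamini-Hochberg
# adjustment. The fixed stage order is filter -> normalize -> impute ->
# test.

#' Valid-value filter for LFQ intensity tables
#'
#' Keeps a protein iff the fraction of valid (non-missing, non-zero)
#' intensities reaches `frac` (inclusive) in at least one condition. Zero
#' intensities are treated as missing, as in MaxQuant/Perseus output.
#'
#' @param x Proteins x samples numeric matrix (raw or log2 intensities).
#' @param condition Factor-like vector over the columns with exactly two
#'   levels.
#' @param frac Required valid fraction per condition (default 0.70).
#' @return The filtered matrix (zero intensities recoded to `NA`).
#' @export
valid_value_filter <- function(x, condition, frac = 0.70) {
  condition <- check_two_conditions(x, condition)
  x[!is.na(x) & x == 0] <- NA_real_
  keep <- rep(FALSE, nrow(x))
  for (lev in levels(condition)) {
    cols <- condition == lev
    keep <- keep | rowSums(!is.na(x[, cols, drop = FALSE])) / sum(cols) >= frac
  }
  x[keep, , drop = FALSE]
}

check_two_conditions <- function(x, condition) {
  condition <- factor(condition)
  if (length(condition) != ncol(x))
    stop_data("'condition' must label every sample column")
  if (nlevels(condition) != 2L)
    stop_data("exactly two conditions are required")
  if (any(table(condition) == 0L)) stop_data("a condition has zero samples")
  condition
}

#' Quantile-normalize a log2 intensity table
#'
#' Classic quantile normalization (each column's ranks mapped to the mean
#' of the column-wise sorted values), ties resolved by averaging, missing
#' entries left missing. Thin wrapper around [limma::normalizeQuantiles()]
#' with an explicit contract check.
#'
#' @param x Proteins x samples numeric matrix on the log2 scale.
#' @return Matrix of the same shape with identical column distributions on
#'   the observed values.
#' @export
quantile_normalize <- function(x) {
  if (any(colSums(!is.na(x)) < 2L))
    stop_data("every sample needs at least 2 observed values to normalize")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Impute missing intensities from a downshifted per-sample distribution
#'
#' Each missing entry of sample \eqn{s} (observed mean \eqn{\mu_s}, SD
#' \eqn{\sigma_s}) is replaced by a draw from
#' \eqn{N(\mu_s - \mathrm{shift}\cdot\sigma_s,
#'       (\mathrm{width}\cdot\sigma_s)^2)},
#' modeling intensities censored at the detection limit. Observed entries
#' are untouched.
#'
#' @param x Proteins x samples log2 intensity matrix.
#' @param shift Downshift in per-sample SD units (default 1.8).
#' @param width Width of the imputation distribution in per-sample SD
#'   units (default 0.3).
#' @param seed Optional seed; the same table and seed reproduce the same
#'   imputed values.
#' @return Complete matrix.
#' @export
downshift_impute <- function(x, shift = 1.8, width = 0.3, seed = NULL) {
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      obs <- x[, j][!is.na(x[, j])]
      mis <- which(is.na(x[, j]))
      if (!length(mis)) next
      if (length(obs) < 2L || stats::sd(obs) == 0)
        stop_data(sprintf("sample %d has zero observed spread; cannot impute",
                          j))
      x[mis, j] <- stats::rnorm(length(mis), mean(obs) - shift * stats::sd(obs),
                                width * stats::sd(obs))
    }
    x
  })
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used when moment-matching the variance prior.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    delta <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + delta
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

#' Moderated two-group differential abundance test
#'
#' Fits the two-group model per protein, shrinks the residual variances
#' towards a common prior (a scaled inverse chi-square fitted by moment
#' matching on \eqn{\log s^2} via digamma/trigamma inversion), and tests
#' the log2 fold change with a moderated t statistic on
#' \eqn{d_0 + d} degrees of freedom:
#' \deqn{\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
#'       t = \frac{\mathrm{log2fc}}{\tilde s\sqrt{1/n_1 + 1/n_2}}.}
#' P-values are Benjamini-Hochberg adjusted, and proteins are classed
#' `up` (log2fc >= `fc_cut` and adjusted p < `alpha`), `down`
#' (log2fc <= -`fc_cut`, same p rule) or `ns`.
#'
#' `d0 = 0` disables moderation (ordinary pooled t); `d0 = NULL` (default)
#' estimates the prior from the data. A degenerate fit with no excess
#' variability collapses to a large finite prior with a warning.
#'
#' @param x Complete proteins x samples log2 matrix (post-imputation).
#' @param condition Two-level condition vector over columns; log2fc is
#'   mean(first level) - mean(second level).
#' @param fc_cut,alpha Calling cuts (defaults 0.6 and 0.05).
#' @param d0 Prior degrees of freedom; `NULL` to estimate.
#' @return `data.frame` with columns `protein`, `log2fc`, `t_mod`, `df`,
#'   `p`, `p_adj`, `class`; prior estimates are attached as attributes
#'   `d0` and `s0_sq`.
#' @export
moderated_test <- function(x, condition, fc_cut = 0.6, alpha = 0.05,
                           d0 = NULL) {
  condition <- check_two_conditions(x, condition)
  if (anyNA(x))
    stop_data("the intensity table must be complete; impute first")
  g1 <- condition == levels(condition)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  d <- n1 + n2 - 2L
  if (d == 0L) stop_data("at least 2 samples in one condition are required")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
    rowSums((x[, !g1, drop = FALSE] - m2)^2)
  s2 <- ss / d
  if (is.null(d0)) {
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(d / 2) + log(d / 2)
    excess <- stats::var(e) - trigamma(d / 2)
    if (!is.finite(excess) || excess <= 0) {
      warning("no excess variance variability; using an effectively infinite prior")
      d0 <- 1e6
    } else {
      d0 <- 2 * trigamma_inverse(excess)
    }
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    s0_sq <- if (d0 > 0) mean(s2) else NA_real_
  }
  s2_post <- if (d0 > 0) (d0 * s0_sq + d * s2) / (d0 + d) else s2
  lfc <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, 0)
  df <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df)
  p_adj <- stats::p.adjust(p, "BH")
  cls <- rep("ns", nrow(x))
  cls[lfc >= fc_cut & p_adj < alpha] <- "up"
  cls[lfc <= -fc_cut & p_adj < alpha] <- "down"
  structure(data.frame(protein = rownames(x) %||% as.character(seq_len(nrow(x))),
                       log2fc = unname(lfc), t_mod = unname(t_mod), df = df,
                       p = unname(p), p_adj = unname(p_adj), class = cls,
                       row.names = NULL),
            d0 = d0, s0_sq = s0_sq)
}

#' Run the full proteomics differential-abundance workflow
#'
#' Fixed stage order: valid-value filter, quantile normalization,
#' downshifted imputation, moderated test.
#'
#' @param x Proteins x samples matrix of raw LFQ intensities
#'   (`log2_transformed = FALSE`, the default, log2-transforms valid
#'   values first) or of already-log2 values.
#' @param condition Two-level condition vector over columns.
#' @param frac,shift,width,fc_cut,alpha Stage parameters (see the
#'   stage functions).
#' @param log2_transformed Set `TRUE` if `x` is already on the log2 scale.
#' @param seed Seed for the imputation draws.
#' @return The [moderated_test()] table, with the processed matrix attached
#'   as attribute `processed`.
#' @export
proteome_diff <- function(x, condition, frac = 0.70, shift = 1.8, width = 0.3,
                          fc_cut = 0.6, alpha = 0.05, log2_transformed = FALSE,
                          seed = NULL) {
  x <- valid_value_filter(x, condition, frac)
  if (!log2_transformed) x <- log2(x)
  x <- quantile_normalize(x)
  x <- downshift_impute(x, shift, width, seed = seed)
  out <- moderated_test(x, condition, fc_cut = fc_cut, alpha = alpha)
  attr(out, "processed") <- x
  out
}

#' Simulate a two-condition LFQ proteome with planted effects
#'
#' Log2-scale intensities with per-protein baselines, a planted log2 fold
#' change on the first `n_planted` proteins (alternating sign), optional
#' intensity-dependent missingness in the low tail (emulating detection
#' censoring), and Gaussian noise.
#'
#' @param n_proteins,n_planted Protein counts.
#' @param lfc Planted absolute log2 fold change.
#' @param n_per_group Samples per condition.
#' @param sigma Per-protein noise SD (log2 units).
#' @param missing_rate Fraction of entries censored from the low intensity
#'   tail (0 = complete).
#' @param seed Seed.
#' @return List: `x` (matrix), `condition`, `planted` (logical),
#'   `planted_sign`.
#' @export
simulate_proteome <- function(n_proteins = 200L, n_planted = 20L, lfc = 1,
                              n_per_group = 3L, sigma = 0.3,
                              missing_rate = 0, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    condition <- rep(c("KO", "CTR"), each = n_per_group)
    base <- stats::rnorm(n_proteins, 25, 2)
    planted <- seq_len(n_proteins) <= n_planted
    sign <- ifelse(seq_len(n_proteins) %% 2L == 0L, -1, 1) * planted
    x <- matrix(base, n_proteins, n) +
      matrix(stats::rnorm(n_proteins * n, 0, sigma), n_proteins, n)
    x[, condition == "KO"] <- x[, condition == "KO"] + sign * lfc
    if (missing_rate > 0) {
      thr <- stats::quantile(x, missing_rate)
      cens <- x < thr & matrix(stats::runif(length(x)) < 0.8, nrow(x))
      x[cens] <- NA_real_
    }
    rownames(x) <- sprintf("P%04d", seq_len(n_proteins))
    colnames(x) <- paste0(condition, rep(seq_len(n_per_group), 2L))
    list(x = x, condition = condition, planted = planted,
         planted_sign = sign)
  })
}
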