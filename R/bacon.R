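# Balanced-correlation prediction of expression-buffering gene pairs.
#
# Buffering predicts a positive Pearson correlation between the partner's
# expression and the buffered gene's fitness score (low partner expression
# <-> more negative score). Raw correlations are also produced in bulk by
# shared structure such as tissue of origin; the balancing step weights
# each pair's correlation down by the fraction of stronger correlations its
# two genes have with other partners, so that only mutually specific pairs
# keep their score.

#' Filter buffering (expression-side) and buffered (fitness-side) candidates
#'
#' A buffering candidate has expression standard deviation strictly above
#' `expr_sd_min` and expression above `expr_level` in at least
#' `expr_level_lines` lines. A buffered candidate has mean log2(TPM+1)
#' strictly above `min_mean_expr` and either absolute mean CERES strictly
#' above `mean_ceres_min` or CERES standard deviation strictly above
#' `sd_ceres_min`.
#'
#' @param expr,fitness [screen_matrix()] objects aligned on the same cell
#'   lines.
#' @param expr_sd_min,expr_level,expr_level_lines Buffering-gene cuts
#'   (defaults 1, 3, 100). When the cohort has fewer than
#'   `expr_level_lines` lines and `desk_scale = TRUE`, the line-count
#'   criterion scales to 20% of lines; otherwise it is applied literally.
#' @param min_mean_expr,mean_ceres_min,sd_ceres_min Buffered-gene cuts
#'   (defaults 2, 0.3, 0.2).
#' @param desk_scale Scale the line-count criterion on small cohorts.
#' @return List of class `"candidate_sets"`: `buffering` and `buffered`
#'   diagnostics data frames (with logical `pass`), plus `buffering_genes`
#'   and `buffered_genes` key vectors.
#' @export
filter_candidates <- function(expr, fitness, expr_sd_min = 1, expr_level = 3,
                              expr_level_lines = 100L, min_mean_expr = 2,
                              mean_ceres_min = 0.3, sd_ceres_min = 0.2,
                              desk_scale = FALSE) {
  if (!identical(colnames(expr), colnames(fitness)))
    stop_data("expression and fitness matrices must be aligned on the same lines")
  n_lines <- ncol(expr)
  level_lines <- expr_level_lines
  if (desk_scale && n_lines < expr_level_lines)
    level_lines <- ceiling(0.2 * n_lines)
  e_sd <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  e_high <- rowSums(expr > expr_level, na.rm = TRUE)
  buffering <- data.frame(gene = rownames(expr), expr_sd = unname(e_sd),
                          n_lines_high = unname(e_high),
                          pass = unname(e_sd > expr_sd_min & e_high >= level_lines),
                          row.names = NULL)
  f_mean <- rowMeans(fitness, na.rm = TRUE)
  f_sd <- apply(fitness, 1L, stats::sd, na.rm = TRUE)
  f_expr <- rowMeans(expr[match(rownames(fitness), rownames(expr)), ,
                          drop = FALSE], na.rm = TRUE)
  buffered <- data.frame(gene = rownames(fitness), mean_expr = unname(f_expr),
                         mean_ceres = unname(f_mean), sd_ceres = unname(f_sd),
                         pass = unname(f_expr > min_mean_expr &
                                         (abs(f_mean) > mean_ceres_min |
                                            f_sd > sd_ceres_min)),
                         row.names = NULL)
  buffered$pass[is.na(buffered$pass)] <- FALSE
  buffering$pass[is.na(buffering$pass)] <- FALSE
  if (!any(buffering$pass))
    stop_data(sprintf(
      "empty buffering candidate set (SD > %s: %d genes; level > %s in >= %d lines: %d genes)",
      format(expr_sd_min), sum(e_sd > expr_sd_min, na.rm = TRUE),
      format(expr_level), level_lines, sum(e_high >= level_lines)))
  if (!any(buffered$pass))
    stop_data(sprintf(
      "empty buffered candidate set (mean expr > %s: %d genes; |mean CERES| > %s or SD > %s: %d genes)",
      format(min_mean_expr), sum(f_expr > min_mean_expr, na.rm = TRUE),
      format(mean_ceres_min), format(sd_ceres_min),
      sum(abs(f_mean) > mean_ceres_min | f_sd > sd_ceres_min, na.rm = TRUE)))
  structure(list(buffering = buffering, buffered = buffered,
                 buffering_genes = buffering$gene[buffering$pass],
                 buffered_genes = buffered$gene[buffered$pass],
                 level_lines = level_lines),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat(sprintf("candidate_sets: %d buffering (expression) x %d buffered (fitness) genes\n",
              length(x$buffering_genes), length(x$buffered_genes)))
  invisible(x)
}

#' All-by-all expression x fitness Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between the expression of each
#' buffering candidate (rows) and the CERES scores of each buffered
#' candidate (columns). Pairs with fewer than `min_obs` complete
#' observations, or with a zero-variance vector, are missing and stay
#' invisible to competition counting and ranking.
#'
#' @param expr,fitness [screen_matrix()] objects aligned on the same lines.
#' @param buffering_genes,buffered_genes Candidate key vectors (e.g. from
#'   [filter_candidates()]).
#' @param min_obs Minimum complete observations per pair (default 3).
#' @return Numeric matrix, rows = buffering/expression genes, columns =
#'   buffered/fitness genes.
#' @export
pcc_matrix <- function(expr, fitness, buffering_genes, buffered_genes,
                       min_obs = 3L) {
  if (!identical(colnames(expr), colnames(fitness)))
    stop_data("expression and fitness matrices must be aligned on the same lines")
  e <- t(unclass(expr)[buffering_genes, , drop = FALSE])
  f <- t(unclass(fitness)[buffered_genes, , drop = FALSE])
  r <- suppressWarnings(stats::cor(e, f, use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(e), !is.na(f))
  r[n_pair < min_obs] <- NA_real_
  r
}

#' All-by-all pair count for candidate sets
#'
#' The number of (buffering, buffered) pairs enumerated by the all-by-all
#' correlation stage; the manifest of [run_pipeline()] checks the computed
#' matrix against this accounting identity.
#'
#' @param n_buffering,n_buffered Candidate set sizes.
#' @return `n_buffering * n_buffered` as a double (the count can exceed the
#'   integer range for genome-scale sets).
#' @export
pair_count <- function(n_buffering, n_buffered) {
  stopifnot(n_buffering >= 0, n_buffered >= 0)
  as.double(n_buffering) * as.double(n_buffered)
}

#' Competition-weighted (balanced) correlation scores
#'
#' For every non-missing correlation \eqn{r_{ij}} the competition counts are
#' the numbers of strictly higher entries in row \eqn{i} and column
#' \eqn{j} (the entry itself excluded; ties and missing entries do not
#' count). The competition fraction is
#' \deqn{w_{ij} = \frac{\#\mathrm{higher\ in\ row} + \#\mathrm{higher\ in\ col}}
#'   {(n_{col}-1) + (n_{row}-1)}}
#' with denominators over non-missing competitors, and the balanced score is
#' `pcc * (1 - w)` (variant `"multiplicative"`, the default, which preserves
#' sign and monotone dominance) or `pcc - w` (variant `"subtractive"`). A
#' pair that is the strict maximum of both its row and column keeps its raw
#' correlation.
#'
#' @param pcc Correlation matrix from [pcc_matrix()] (at least 2 x 2).
#' @param variant `"multiplicative"` or `"subtractive"`.
#' @return List of class `"bacon_scores"` holding matrices `pcc`,
#'   `n_higher_row`, `n_higher_col`, `w`, `score`, and the `variant` label.
#' @export
bacon_scores <- function(pcc, variant = c("multiplicative", "subtractive")) {
  variant <- match.arg(variant)
  if (!is.matrix(pcc) || nrow(pcc) < 2L || ncol(pcc) < 2L)
    stop_data("the correlation matrix must be at least 2 x 2")
  n_row_obs <- rowSums(!is.na(pcc)) # competitors available in each row
  n_col_obs <- colSums(!is.na(pcc))
  higher_than <- function(x) { # per vector: strictly greater non-missing entries
    n <- sum(!is.na(x))
    n - rank(x, ties.method = "max", na.last = "keep")
  }
  n_hi_row <- t(apply(pcc, 1L, higher_than))
  n_hi_col <- apply(pcc, 2L, higher_than)
  denom <- outer(n_row_obs - 1L, n_col_obs - 1L, `+`)
  w <- (n_hi_row + n_hi_col) / ifelse(denom > 0L, denom, 1L)
  score <- if (variant == "multiplicative") pcc * (1 - w) else pcc - w
  dimnames(n_hi_row) <- dimnames(n_hi_col) <- dimnames(w) <- dimnames(pcc)
  structure(list(pcc = pcc, n_higher_row = n_hi_row, n_higher_col = n_hi_col,
                 w = w, score = score, variant = variant),
            class = "bacon_scores")
}

#' @export
print.bacon_scores <- function(x, ...) {
  cat(sprintf("bacon_scores [%s]: %d x %d pairs (%d missing)\n", x$variant,
              nrow(x$pcc), ncol(x$pcc), sum(is.na(x$pcc))))
  invisible(x)
}

#' Rank candidate buffering pairs
#'
#' Converts [bacon_scores()] into a pair table, removes pairs whose
#' fitness-side gene is pan-essential (mean CERES across all lines strictly
#' below `pan_essential_cut`), optionally keeps only pairs whose
#' fitness-side gene belongs to `restrict_to_hits`, and sorts by balanced
#' score (signed, descending) with dense ranks.
#'
#' @param scores A [bacon_scores()] object.
#' @param fitness Fitness [screen_matrix()] used for the pan-essential
#'   means (all lines, not only candidates).
#' @param restrict_to_hits Optional character vector of fitness-side genes
#'   to keep (e.g. the differential-dependency hits); `NULL` or empty means
#'   no restriction.
#' @param pan_essential_cut Mean-CERES cut below which fitness genes are
#'   dropped (default -0.75).
#' @param top_k Optionally truncate the returned table to the best `top_k`
#'   pairs (after ranking).
#' @return `data.frame` with columns `expr_gene`, `fit_gene`, `pcc`,
#'   `n_higher_row`, `n_higher_col`, `w`, `bacon_score`, `rank`
#'   (plus `pcc_rank`, the dense rank by raw correlation over the same
#'   surviving pairs).
#' @export
rank_pairs <- function(scores, fitness, restrict_to_hits = NULL,
                       pan_essential_cut = -0.75, top_k = NULL) {
  stopifnot(inherits(scores, "bacon_scores"))
  keep_cols <- colnames(scores$pcc)
  mean_ceres <- rowMeans(unclass(fitness)[keep_cols, , drop = FALSE], na.rm = TRUE)
  drop_pan <- mean_ceres < pan_essential_cut
  ij <- which(!is.na(scores$pcc), arr.ind = TRUE)
  tab <- data.frame(expr_gene = rownames(scores$pcc)[ij[, 1L]],
                    fit_gene = keep_cols[ij[, 2L]],
                    pcc = scores$pcc[ij],
                    n_higher_row = scores$n_higher_row[ij],
                    n_higher_col = scores$n_higher_col[ij],
                    w = scores$w[ij],
                    bacon_score = scores$score[ij], row.names = NULL)
  tab <- tab[!drop_pan[match(tab$fit_gene, keep_cols)], , drop = FALSE]
  if (!is.null(restrict_to_hits) && length(restrict_to_hits))
    tab <- tab[tab$fit_gene %in% restrict_to_hits, , drop = FALSE]
  tab <- tab[order(-tab$bacon_score), , drop = FALSE]
  tab$rank <- dense_rank_desc(tab$bacon_score)
  tab$pcc_rank <- dense_rank_desc(tab$pcc)
  rownames(tab) <- NULL
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  tab
}
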