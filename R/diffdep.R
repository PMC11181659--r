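# Differential gene dependency between arm-deleted and non-deleted lines:
# expression prefilter, dCERES effect sizes, per-gene Wilcoxon rank-sum
# tests, hit selection, arm enrichment, and the lineage-corrected
# single-gene dependency analysis.

#' Expression prefilter for dependency testing
#'
#' A gene is considered for testing iff its mean log2(TPM+1) is strictly
#' greater than `min_mean` in the DEL group or in the nonDEL group. Genes
#' failing the filter receive no test downstream.
#'
#' @param expr Expression [screen_matrix()] covering the classified lines.
#' @param calls [classify_lines()] output.
#' @param min_mean Strict lower bound on the group mean (default 1).
#' @return Named logical vector over the genes of `expr`.
#' @export
expression_prefilter <- function(expr, calls, min_mean = 1) {
  g <- call_groups(calls, colnames(expr))
  if (!length(g$del) || !length(g$nondel))
    stop_data("both DEL and nonDEL groups must contain classified lines ",
              "present in the expression matrix")
  mean_del <- rowMeans(expr[, g$del, drop = FALSE], na.rm = TRUE)
  mean_nondel <- rowMeans(expr[, g$nondel, drop = FALSE], na.rm = TRUE)
  pass <- (mean_del > min_mean) | (mean_nondel > min_mean)
  pass[is.na(pass)] <- FALSE
  stats::setNames(pass, rownames(expr))
}

#' Differential CERES effect size (dCERES)
#'
#' Per gene: mean CERES in the DEL group minus mean CERES in the nonDEL
#' group, over non-missing values. A negative dCERES marks a gene as more
#' essential in arm-deleted lines.
#'
#' @param fitness Fitness [screen_matrix()].
#' @param calls [classify_lines()] output.
#' @return `data.frame` with columns `gene`, `mean_del`, `mean_nondel`,
#'   `dceres` (`NA` for genes with an empty group after removing missing
#'   values).
#' @export
dceres <- function(fitness, calls) {
  g <- call_groups(calls, colnames(fitness))
  if (!length(g$del) || !length(g$nondel))
    stop_data("both DEL and nonDEL groups must contain classified lines ",
              "present in the fitness matrix")
  n_del <- rowSums(!is.na(fitness[, g$del, drop = FALSE]))
  n_nondel <- rowSums(!is.na(fitness[, g$nondel, drop = FALSE]))
  mean_del <- rowMeans(fitness[, g$del, drop = FALSE], na.rm = TRUE)
  mean_nondel <- rowMeans(fitness[, g$nondel, drop = FALSE], na.rm = TRUE)
  mean_del[n_del == 0L] <- NA_real_
  mean_nondel[n_nondel == 0L] <- NA_real_
  data.frame(gene = rownames(fitness), mean_del = unname(mean_del),
             mean_nondel = unname(mean_nondel),
             dceres = unname(mean_del - mean_nondel), row.names = NULL)
}

# Two-sided rank-sum p for one gene. Exact null enumeration when the
# smaller group has at most `exact_max` values and the data are tie-free;
# otherwise the normal approximation with tie and continuity correction.
ranksum_p <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  pooled <- c(x, y)
  if (all(pooled == pooled[1L])) return(1)
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  if (!is.finite(p)) 1 else min(p, 1)
}

#' Per-gene Wilcoxon rank-sum tests between DEL and nonDEL lines
#'
#' Two-sided p-values comparing each gene's CERES scores between the
#' groups. The exact rank-sum null is enumerated when the smaller group has
#' at most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param fitness Fitness [screen_matrix()].
#' @param calls [classify_lines()] output.
#' @param genes Optional subset of genes to test (e.g. the prefilter
#'   survivors); defaults to all rows.
#' @param exact_max Largest smaller-group size for which the exact null is
#'   enumerated (default 8).
#' @return Named numeric vector of p-values (`NA` for untested genes).
#' @export
wilcoxon_per_gene <- function(fitness, calls, genes = NULL, exact_max = 8L) {
  g <- call_groups(calls, colnames(fitness))
  if (!length(g$del) || !length(g$nondel))
    stop_data("both groups must be non-empty")
  rows <- if (is.null(genes)) seq_len(nrow(fitness)) else
    match(genes, rownames(fitness))
  p <- rep(NA_real_, nrow(fitness))
  for (i in rows[!is.na(rows)]) {
    p[i] <- ranksum_p(fitness[i, g$del], fitness[i, g$nondel], exact_max)
  }
  stats::setNames(p, rownames(fitness))
}

#' Assemble the per-gene dependency table
#'
#' Runs prefilter, dCERES, Wilcoxon tests and covariate-weighted adjustment
#' ([ihw_adjust()] with the mean nonDEL CERES score as covariate) and flags
#' hits with [select_hits()] cuts.
#'
#' @param fitness,expr [screen_matrix()] objects sharing the classified
#'   lines.
#' @param calls [classify_lines()] output.
#' @param min_mean Prefilter bound, see [expression_prefilter()].
#' @param alpha FDR control level handed to [ihw_adjust()].
#' @param n_bins,n_folds [ihw_adjust()] settings.
#' @param p_cut,d_cut,strict_p_cut Hit cuts, see [select_hits()].
#' @param seed Seed for the cross-fitting fold assignment.
#' @return `data.frame` (class `"dependency_table"`) with one row per gene:
#'   `gene`, `mean_del`, `mean_nondel`, `dceres`, `p_value`, `p_adj`,
#'   `ihw_weight`, `passed_prefilter`, `is_hit`, `is_strict_hit`. The
#'   learned per-bin weights are attached as attribute `ihw_fit`.
#' @export
dependency_table <- function(fitness, expr, calls, min_mean = 1, alpha = 0.1,
                             n_bins = 5L, n_folds = 5L, p_cut = 0.25,
                             d_cut = -0.075, strict_p_cut = 0.1, seed = NULL) {
  genes <- intersect(rownames(fitness), rownames(expr))
  fitness <- fitness[genes, , drop = FALSE]
  pass <- expression_prefilter(expr, calls, min_mean)[genes]
  tab <- dceres(fitness, calls)
  tab$p_value <- unname(wilcoxon_per_gene(fitness, calls, genes = genes[pass]))
  tested <- pass & !is.na(tab$p_value) & is.finite(tab$mean_nondel)
  fit <- ihw_adjust(tab$p_value[tested], covariate = tab$mean_nondel[tested],
                    alpha = alpha, n_bins = n_bins, n_folds = n_folds,
                    seed = seed)
  tab$p_adj <- tab$ihw_weight <- NA_real_
  tab$p_adj[tested] <- fit$p_adj
  tab$ihw_weight[tested] <- fit$weights
  tab$passed_prefilter <- unname(pass)
  tab <- select_hits(tab, p_cut = p_cut, d_cut = d_cut,
                     strict_p_cut = strict_p_cut)
  attr(tab, "ihw_fit") <- fit[c("bin_weights", "n_bins", "n_folds", "alpha")]
  class(tab) <- c("dependency_table", "data.frame")
  tab
}

#' Flag differential-dependency hits
#'
#' A hit passes the expression prefilter and has adjusted p strictly below
#' `p_cut` and dCERES strictly below `d_cut`. A stricter tier at
#' `strict_p_cut` is flagged alongside.
#'
#' @param table `data.frame` with columns `p_adj`, `dceres` and
#'   `passed_prefilter` (as built by [dependency_table()]).
#' @param p_cut,d_cut,strict_p_cut Cuts (defaults 0.25, -0.075, 0.1).
#' @return `table` with logical columns `is_hit` and `is_strict_hit`.
#' @export
select_hits <- function(table, p_cut = 0.25, d_cut = -0.075,
                        strict_p_cut = 0.1) {
  ok <- table$passed_prefilter & !is.na(table$p_adj) & !is.na(table$dceres)
  table$is_hit <- ok & table$p_adj < p_cut & table$dceres < d_cut
  table$is_strict_hit <- table$is_hit & table$p_adj < strict_p_cut
  table
}

#' Hypergeometric enrichment of hits on a chromosome arm
#'
#' Upper-tail hypergeometric test of the overlap between the hit set and
#' the arm's genes within the tested universe, with fold enrichment
#' \eqn{(k/n)/(K/N)}.
#'
#' @param hits Character vector of hit gene keys (subset of `universe`).
#' @param annotation Gene annotation table.
#' @param universe Character vector of all tested gene keys.
#' @param chromosome,arm Arm of interest.
#' @return List of class `"enrichment_result"`: `universe_size`,
#'   `on_arm_in_universe`, `n_hits`, `on_arm_hits`, `fold_enrichment`,
#'   `p_value`. `NA` results when the draw or the arm set is empty.
#' @export
arm_enrichment <- function(hits, annotation, universe, chromosome = "8",
                           arm = "p") {
  annotation <- validate_annotation(annotation)
  if (!all(hits %in% universe)) stop_data("hits must be a subset of the universe")
  idx <- match_annotation(universe, annotation)
  on_arm <- !is.na(idx) &
    annotation$chromosome[idx] == as.character(chromosome) &
    annotation$arm[idx] == arm
  N <- length(universe)
  K <- sum(on_arm)
  n <- length(hits)
  k <- sum(universe[on_arm] %in% hits)
  if (n == 0L || K == 0L) {
    fold <- p <- NA_real_
  } else {
    fold <- (k / n) / (K / N)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  }
  structure(list(universe_size = N, on_arm_in_universe = K, n_hits = n,
                 on_arm_hits = k, fold_enrichment = fold, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d hits on arm vs %d/%d in universe; fold = %s, p = %s\n",
              x$on_arm_hits, x$n_hits, x$on_arm_in_universe, x$universe_size,
              format(x$fold_enrichment, digits = 3),
              format(x$p_value, digits = 3)))
  invisible(x)
}

#' Lineage-corrected dependency of a single gene
#'
#' Regresses the lineage effect out of one gene's CERES scores (least
#' squares on lineage indicators, i.e. within-lineage centering), flags the
#' lowest `decile` of residuals as dependent lines, and compares partner
#' expression and copy number between dependent and non-dependent lines
#' (group means plus two-sided rank-sum p).
#'
#' @param scores Named numeric vector: one gene's CERES scores per line.
#' @param lineage Named character vector mapping those lines to lineages.
#' @param partner_expression,partner_cn Optional named numeric vectors for
#'   the partner gene over the same lines.
#' @param decile Fraction of most-negative residuals called dependent
#'   (default 0.10).
#' @return List of class `"lineage_corrected"`: `residuals`,
#'   `dependent` (logical per line), and for each supplied partner vector a
#'   list with `mean_dependent`, `mean_other`, `p_value`.
#' @export
lineage_corrected_dependency <- function(scores, lineage,
                                         partner_expression = NULL,
                                         partner_cn = NULL, decile = 0.10) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  lineage <- lineage[names(scores)]
  if (anyNA(lineage)) stop_data("every scored line needs a lineage label")
  if (length(unique(lineage)) < 2L) {
    warning("single lineage: residuals are grand-mean-centered scores")
    res <- scores - mean(scores)
  } else {
    res <- stats::residuals(stats::lm(scores ~ factor(lineage)))
    names(res) <- names(scores)
  }
  dependent <- res <= stats::quantile(res, decile, names = FALSE)
  cmp <- function(v) {
    if (is.null(v)) return(NULL)
    v <- v[names(res)]
    list(mean_dependent = mean(v[dependent], na.rm = TRUE),
         mean_other = mean(v[!dependent], na.rm = TRUE),
         p_value = ranksum_p(v[dependent], v[!dependent]))
  }
  structure(list(residuals = res, dependent = dependent,
                 expression = cmp(partner_expression), cn = cmp(partner_cn),
                 decile = decile),
            class = "lineage_corrected")
}
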