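# Arm-level deletion scoring and SCNA frequency summaries.

#' Score per-line deletion burden over a chromosome arm
#'
#' The default burden score for line \eqn{l} over the \eqn{N} annotated arm
#' genes with non-missing log2 copy-number ratio \eqn{x_g} is
#' \deqn{S_l = 10 \cdot \frac{1}{N}\sum_g \min(x_g, 0),}
#' which folds deletion depth (how negative the ratios are) and breadth
#' (how much of the arm is affected) into a single non-positive number;
#' gains never offset losses. A whole-arm one-copy loss
#' (\eqn{x \approx -0.7}) scores about -7, a neutral arm about 0, so the
#' default classification threshold of -2.5 separates broad arm loss from
#' focal or shallow events. Alternative scoring functions can be plugged in
#' via `score_fun`.
#'
#' @param cn A copy-number [screen_matrix()] (log2 relative copy number).
#' @param annotation Gene annotation (see [read_annotation()]); arm
#'   membership is decided by the `(chromosome, arm)` labels only.
#' @param chromosome,arm Arm to score, e.g. `"8"` and `"p"`.
#' @param score_fun Function mapping a numeric vector of one line's
#'   non-missing arm-gene ratios to a scalar score. Default: the burden
#'   score above.
#' @return Named numeric vector of per-line scores (`NA` where a line has
#'   no non-missing arm-gene value), with attributes `n_arm_genes` and
#'   `score_fun_label`.
#' @export
arm_deletion_score <- function(cn, annotation, chromosome = "8", arm = "p",
                               score_fun = NULL) {
  annotation <- validate_annotation(annotation)
  label <- if (is.null(score_fun)) "burden_10x_mean_min0" else "custom"
  if (is.null(score_fun)) score_fun <- function(x) 10 * mean(pmin(x, 0))
  idx <- match_annotation(rownames(cn), annotation)
  on_arm <- !is.na(idx) &
    annotation$chromosome[idx] == as.character(chromosome) &
    annotation$arm[idx] == arm
  if (!any(on_arm))
    stop_data(sprintf("no annotated gene on chr%s%s present in the matrix",
                      chromosome, arm))
  sub <- cn[on_arm, , drop = FALSE]
  scores <- apply(sub, 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else score_fun(x)
  })
  if (anyNA(scores))
    warning(sum(is.na(scores)), " line(s) with all-missing arm values; ",
            "their scores are NA and they receive no call")
  structure(scores, n_arm_genes = sum(on_arm), score_fun_label = label)
}

#' Classify cell lines as arm-deleted (DEL) or not (nonDEL)
#'
#' A line is DEL iff its arm score is strictly below `threshold`; scores at
#' the boundary are nonDEL.
#'
#' @param scores Per-line scores from [arm_deletion_score()].
#' @param threshold Classification threshold (default -2.5). `-Inf` is
#'   permitted and calls every line nonDEL.
#' @return A `data.frame` (class `"arm_calls"`) with columns `line`,
#'   `arm_score`, `call`; lines with missing scores are excluded. Attributes
#'   `n_del`, `n_nondel`, `threshold` summarize the split.
#' @export
classify_lines <- function(scores, threshold = -2.5) {
  if (length(threshold) != 1L || is.na(threshold))
    stop_data("threshold must be a single non-missing number")
  if (!length(scores)) stop_data("empty score set")
  keep <- !is.na(scores)
  out <- data.frame(line = names(scores)[keep], arm_score = unname(scores[keep]),
                    call = ifelse(scores[keep] < threshold, "DEL", "nonDEL"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("arm_calls", "data.frame"),
            n_del = sum(out$call == "DEL"), n_nondel = sum(out$call == "nonDEL"),
            threshold = threshold, n_arm_genes = attr(scores, "n_arm_genes"),
            score_fun_label = attr(scores, "score_fun_label"))
}

#' @export
print.arm_calls <- function(x, ...) {
  cat(sprintf("arm_calls: %d DEL / %d nonDEL at threshold %s (score: %s)\n",
              attr(x, "n_del"), attr(x, "n_nondel"),
              format(attr(x, "threshold")), attr(x, "score_fun_label") %||% "?"))
  invisible(x)
}

# Column index helpers for a call table against a matrix.
call_groups <- function(calls, line_ids) {
  del <- calls$line[calls$call == "DEL"]
  nondel <- calls$line[calls$call == "nonDEL"]
  list(del = which(line_ids %in% del), nondel = which(line_ids %in% nondel))
}

#' Per-gene SCNA frequency summary
#'
#' Percentage of samples whose log2 copy-number ratio lies strictly above
#' the gain cutoff (amplified) or strictly below the loss cutoff (deleted),
#' computed over non-missing samples per gene.
#'
#' @param cn Copy-number [screen_matrix()].
#' @param gain_cut,loss_cut Log2-ratio cutoffs (defaults +0.1 / -0.1).
#' @return `data.frame` with columns `gene`, `pct_amplified`, `pct_deleted`,
#'   `n_samples`; genes with no non-missing sample get `NA` percentages.
#' @export
scna_frequency <- function(cn, gain_cut = 0.1, loss_cut = -0.1) {
  n_obs <- rowSums(!is.na(cn))
  amp <- rowSums(cn > gain_cut, na.rm = TRUE)
  del <- rowSums(cn < loss_cut, na.rm = TRUE)
  data.frame(gene = rownames(cn),
             pct_amplified = ifelse(n_obs > 0L, 100 * amp / n_obs, NA_real_),
             pct_deleted = ifelse(n_obs > 0L, 100 * del / n_obs, NA_real_),
             n_samples = n_obs, row.names = NULL)
}
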