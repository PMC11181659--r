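# End-to-end orchestration: one validated configuration object, the staged
# pipeline, and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every numeric threshold of the discovery workflow in one
#' validated structure. Defaults are the reference analysis settings:
#' arm-call threshold -2.5 on the burden score, SCNA cutoffs +/-0.1,
#' expression prefilter 1 (log2(TPM+1)), weighted-FDR level 0.1, hit cuts
#' adjusted p < 0.25 (strict tier 0.1) and dCERES < -0.075, pan-essential
#' cut -0.75, candidate filters (expression SD > 1, level > 3 in >= 100
#' lines; mean expression > 2 with |mean CERES| > 0.3 or CERES SD > 0.2),
#' and the proteomics settings (valid fraction 0.7, downshift 1.8, width
#' 0.3, log2FC cut 0.6, level 0.05).
#'
#' @param chromosome,arm Arm under study.
#' @param cn_threshold,gain_cut,loss_cut Arm-call and SCNA cutoffs.
#' @param prefilter_min_mean Expression prefilter bound.
#' @param ihw_alpha,ihw_bins,ihw_folds Weighted-FDR settings.
#' @param hit_p_cut,strict_p_cut,dceres_cut Hit selection cuts.
#' @param pan_essential_cut Mean-CERES cut for pair ranking.
#' @param buffering_sd_min,buffering_level,buffering_level_lines
#'   Expression-side candidate cuts.
#' @param buffered_min_expr,buffered_mean_ceres,buffered_sd_ceres
#'   Fitness-side candidate cuts.
#' @param bacon_variant Balanced-score variant, see [bacon_scores()].
#' @param proteome_frac,proteome_shift,proteome_width,proteome_fc_cut,proteome_alpha
#'   Proteomics settings.
#' @param seed Seed funneling all pipeline randomness (fold assignment,
#'   imputation).
#' @return List of class `"pipeline_config"` with a stable `hash`
#'   fingerprint.
#' @export
pipeline_config <- function(chromosome = "8", arm = "p", cn_threshold = -2.5,
                            gain_cut = 0.1, loss_cut = -0.1,
                            prefilter_min_mean = 1, ihw_alpha = 0.1,
                            ihw_bins = 5L, ihw_folds = 5L, hit_p_cut = 0.25,
                            strict_p_cut = 0.1, dceres_cut = -0.075,
                            pan_essential_cut = -0.75, buffering_sd_min = 1,
                            buffering_level = 3, buffering_level_lines = 100L,
                            buffered_min_expr = 2, buffered_mean_ceres = 0.3,
                            buffered_sd_ceres = 0.2,
                            bacon_variant = "multiplicative",
                            proteome_frac = 0.7, proteome_shift = 1.8,
                            proteome_width = 0.3, proteome_fc_cut = 0.6,
                            proteome_alpha = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  num <- cfg[vapply(cfg, is.numeric, TRUE)]
  if (!all(vapply(num, function(v) all(is.finite(v)), TRUE)))
    stop_data("every numeric configuration value must be finite")
  if (!bacon_variant %in% c("multiplicative", "subtractive"))
    stop_data("unknown bacon_variant")
  cfg$hash <- config_hash(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";"))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config [%s]: chr%s%s, cn_threshold %s, alpha %s, seed %d\n",
              x$hash, x$chromosome, x$arm, format(x$cn_threshold),
              format(x$ihw_alpha), x$seed))
  invisible(x)
}

#' Run the discovery pipeline end to end
#'
#' Stage order: arm classification, expression prefilter, dCERES plus
#' Wilcoxon testing, covariate-weighted FDR adjustment, hit selection, arm
#' enrichment, candidate filtering, correlation matrix, balanced scoring,
#' pair ranking. A manifest records the configuration hash, seed and row
#' counts at every stage; when `out_dir` is given all tables, the manifest
#' and a verbatim configuration snapshot are written there.
#'
#' @param cohort An [align_cohort()] object with fitness, expression and
#'   copy-number matrices plus annotation (lineage optional).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `"pipeline_result"`: `calls`, `dependency`,
#'   `hits`, `enrichment`, `candidates`, `pairs`, `manifest`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "aligned_cohort"),
            inherits(config, "pipeline_config"))
  if (is.null(cohort$annotation)) stop_data("the cohort carries no annotation")
  stage <- "classify"
  res <- tryCatch({
    scores <- arm_deletion_score(cohort$copy_number, cohort$annotation,
                                 config$chromosome, config$arm)
    calls <- classify_lines(scores, config$cn_threshold)

    stage <- "dependency"
    dep <- dependency_table(cohort$fitness, cohort$expression, calls,
                            min_mean = config$prefilter_min_mean,
                            alpha = config$ihw_alpha, n_bins = config$ihw_bins,
                            n_folds = config$ihw_folds,
                            p_cut = config$hit_p_cut,
                            d_cut = config$dceres_cut,
                            strict_p_cut = config$strict_p_cut,
                            seed = config$seed)
    hits <- dep$gene[dep$is_hit]

    stage <- "enrichment"
    enr <- arm_enrichment(hits, cohort$annotation,
                          universe = dep$gene[dep$passed_prefilter],
                          chromosome = config$chromosome, arm = config$arm)

    stage <- "candidates"
    cand <- filter_candidates(cohort$expression, cohort$fitness,
                              expr_sd_min = config$buffering_sd_min,
                              expr_level = config$buffering_level,
                              expr_level_lines = config$buffering_level_lines,
                              min_mean_expr = config$buffered_min_expr,
                              mean_ceres_min = config$buffered_mean_ceres,
                              sd_ceres_min = config$buffered_sd_ceres)

    stage <- "bacon"
    pcc <- pcc_matrix(cohort$expression, cohort$fitness,
                      cand$buffering_genes, cand$buffered_genes)
    bs <- bacon_scores(pcc, variant = config$bacon_variant)
    pairs <- rank_pairs(bs, cohort$fitness, restrict_to_hits = hits,
                        pan_essential_cut = config$pan_essential_cut)

    manifest <- list(
      config_hash = config$hash, seed = config$seed,
      package_version = as.character(utils::packageVersion("armSL")),
      bacon_variant = config$bacon_variant,
      score_fun = attr(scores, "score_fun_label"),
      counts = list(lines_classified = nrow(calls),
                    n_del = attr(calls, "n_del"),
                    n_nondel = attr(calls, "n_nondel"),
                    genes_prefiltered = sum(dep$passed_prefilter),
                    genes_tested = sum(!is.na(dep$p_value)),
                    n_hits = length(hits),
                    n_strict_hits = sum(dep$is_strict_hit),
                    n_buffering_candidates = length(cand$buffering_genes),
                    n_buffered_candidates = length(cand$buffered_genes),
                    pair_count = sum(!is.na(pcc)),
                    pairs_ranked = nrow(pairs)))
    list(calls = calls, dependency = dep, hits = hits, enrichment = enr,
         candidates = cand, pairs = pairs, manifest = manifest,
         config = config)
  }, error = function(e) {
    stop_data(sprintf("pipeline failed at stage '%s': %s", stage,
                      conditionMessage(e)))
  })
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(paste0("pipeline_result [%s]: %d DEL / %d nonDEL lines, ",
                     "%d hits (%d strict), %d x %d candidates, %d ranked pairs\n"),
              x$manifest$config_hash, cts$n_del, cts$n_nondel, cts$n_hits,
              cts$n_strict_hits, cts$n_buffering_candidates,
              cts$n_buffered_candidates, cts$pairs_ranked))
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(cbind(df, config_hash = res$config$hash),
                       file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(as.data.frame(res$calls), "arm_calls.tsv")
  wt(as.data.frame(res$dependency), "dependency_table.tsv")
  wt(res$pairs, "pair_table.tsv")
  jsonlite::write_json(unclass(res$enrichment),
                       file.path(out_dir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(res$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
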