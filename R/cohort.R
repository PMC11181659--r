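# Synthetic DepMap-like cohorts with planted ground truth.
#
# The generator emulates the statistical structure the discovery pipeline
# relies on: lineage-structured cell lines, an essentiality spectrum of
# CERES-scale fitness scores, log2(TPM+1) expression with lineage effects,
# an arm-level deletion that lowers both copy number and expression of arm
# genes, deletion-specific fitness effects (the dCERES signal), one planted
# expression-buffering pair, and a block of lineage-confounded decoy
# correlations that a raw Pearson ranking mistakes for buffering.

#' Specification of a synthetic cohort
#'
#' Defaults describe the reference cohort used throughout the package's
#' validation: 600 cell lines from 10 lineages, 2,000 genes of which 100 sit
#' on the deleted arm (chr8p in the annotation), a 20% arm-deletion rate at
#' log2-ratio depth -0.7, a buffering effect of `gamma = 0.5` CERES units, a
#' deletion-specific fitness effect of `delta = 0.4`, and strong lineage
#' confounding (`kappa = 1`).
#'
#' @param n_lines,n_genes,n_arm_genes,n_lineages Cohort dimensions.
#' @param p_del Probability that a line carries the arm deletion.
#' @param del_depth Mean log2 copy-number ratio of deleted arm genes.
#' @param cn_noise_sd Copy-number measurement noise (log2-ratio SD).
#' @param expr_noise_sd,lineage_expr_sd Per-gene expression noise and
#'   between-lineage expression spread, log2(TPM+1) units.
#' @param expr_del_shift Expression drop of arm genes in deleted lines
#'   (log2(TPM+1) units); the dosage coupling between copy number and mRNA.
#' @param ceres_noise_sd Per-gene fitness-score noise (CERES units).
#' @param gamma Buffering effect: CERES shift added (negatively) to the
#'   buffered gene in lines whose partner expression is below its cohort
#'   median. `buffering_linear = TRUE` plants a graded dosage effect of
#'   matched covariance instead of the threshold effect.
#' @param delta Deletion-specific fitness effect planted on
#'   `n_dceres_genes` genes (CERES shift in deleted lines).
#' @param kappa Lineage-confounding strength multiplying the decoy loadings;
#'   0 disables confounding.
#' @param n_dceres_genes Genes given the deletion-specific effect; half are
#'   placed on the deleted arm so that arm enrichment of hits is testable.
#' @param n_decoy_expr Lineage-driven decoy expression genes correlated with
#'   the buffered gene through lineage alone.
#' @param n_conf_fitness Lineage-driven, pan-essential fitness genes that
#'   populate the competition landscape of the correlation matrix.
#' @param n_var_expr Additional high-variance (but unstructured) expression
#'   genes, so the buffering-candidate set is not trivially small.
#' @param buffering_linear Plant a linear rather than threshold buffering
#'   effect (see `gamma`).
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_lines = 600L, n_genes = 2000L, n_arm_genes = 100L,
                        n_lineages = 10L, p_del = 0.2, del_depth = -0.7,
                        cn_noise_sd = 0.1, expr_noise_sd = 0.4,
                        lineage_expr_sd = 0.3, expr_del_shift = 1.2,
                        ceres_noise_sd = 0.15, gamma = 0.5, delta = 0.4,
                        kappa = 1, n_dceres_genes = 8L, n_decoy_expr = 30L,
                        n_conf_fitness = 120L, n_var_expr = 40L,
                        buffering_linear = FALSE) {
  spec <- list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
               n_arm_genes = as.integer(n_arm_genes),
               n_lineages = as.integer(n_lineages), p_del = p_del,
               del_depth = del_depth, cn_noise_sd = cn_noise_sd,
               expr_noise_sd = expr_noise_sd, lineage_expr_sd = lineage_expr_sd,
               expr_del_shift = expr_del_shift, ceres_noise_sd = ceres_noise_sd,
               gamma = gamma, delta = delta, kappa = kappa,
               n_dceres_genes = as.integer(n_dceres_genes),
               n_decoy_expr = as.integer(n_decoy_expr),
               n_conf_fitness = as.integer(n_conf_fitness),
               n_var_expr = as.integer(n_var_expr),
               buffering_linear = isTRUE(buffering_linear))
  with(spec, {
    if (any(c(n_lines, n_genes, n_arm_genes, n_lineages) <= 0L))
      stop_data("cohort counts must be positive")
    if (p_del < 0 || p_del > 1) stop_data("p_del must be in [0, 1]")
    if (n_arm_genes > n_genes) stop_data("n_arm_genes must not exceed n_genes")
    if (n_dceres_genes < 2L || n_dceres_genes %% 2L != 0L)
      stop_data("n_dceres_genes must be an even count >= 2")
    n_special_arm <- 1L + n_dceres_genes %/% 2L
    n_special_off <- 1L + n_dceres_genes %/% 2L + n_decoy_expr +
      n_conf_fitness + n_var_expr
    if (n_arm_genes < n_special_arm)
      stop_data("n_arm_genes too small for the planted arm genes")
    if (n_genes - n_arm_genes < n_special_off)
      stop_data("n_genes too small for the planted off-arm genes")
    if (any(c(cn_noise_sd, expr_noise_sd, lineage_expr_sd, ceres_noise_sd) < 0))
      stop_data("noise SDs must be non-negative")
  })
  structure(spec, class = "cohort_spec")
}

# Deterministic gene layout for a spec: keys, annotation and the index sets
# of the planted genes. Arm genes occupy indices 1..n_arm_genes on chr8p.
cohort_layout <- function(spec) {
  n <- spec$n_genes
  keys <- sprintf("G%04d (%d)", seq_len(n), seq_len(n))
  on_arm <- seq_len(spec$n_arm_genes)
  chrom <- rep("8", n)
  arm <- rep("p", n)
  off <- setdiff(seq_len(n), on_arm)
  chrom[off] <- as.character(rep_len(setdiff(1:22, 8), length(off)))
  arm[off] <- "q"
  start <- 1e6 * seq_len(n)
  ann <- data.frame(gene_symbol = sprintf("G%04d", seq_len(n)),
                    entrez_id = seq_len(n), chromosome = chrom, arm = arm,
                    start_bp = start, end_bp = start + 1e4)
  half <- spec$n_dceres_genes %/% 2L
  idx <- list(buffering_expr = 1L,                      # on arm
              dceres_arm = 1L + seq_len(half),          # on arm
              buffered_fit = spec$n_arm_genes + 1L,     # off arm
              dceres_off = spec$n_arm_genes + 1L + seq_len(half))
  nxt <- spec$n_arm_genes + 2L + half
  idx$decoy_expr <- seq(nxt, length.out = spec$n_decoy_expr)
  nxt <- nxt + spec$n_decoy_expr
  idx$conf_fitness <- seq(nxt, length.out = spec$n_conf_fitness)
  nxt <- nxt + spec$n_conf_fitness
  idx$var_expr <- seq(nxt, length.out = spec$n_var_expr)
  idx$dceres <- c(idx$dceres_arm, idx$dceres_off)
  list(keys = keys, annotation = ann, idx = idx)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Model, per line \eqn{l} with lineage \eqn{u(l)} and latent lineage factor
#' \eqn{\lambda_{u}}:
#' \itemize{
#' \item copy number: arm genes of deleted lines ~ N(`del_depth`,
#'   `cn_noise_sd`\eqn{^2}), all other entries ~ N(0, `cn_noise_sd`\eqn{^2});
#' \item expression: gene baseline + per-(gene, lineage) offset + arm-dosage
#'   drop (`expr_del_shift` in deleted lines) + planted variance components
#'   + noise, truncated at 0;
#' \item fitness: gene baseline essentiality + planted effects + noise.
#'   The buffered gene receives `-gamma` where the partner's expression is
#'   below its cohort median; deletion-effect genes receive `-delta` in
#'   deleted lines; decoy expression genes and confounded fitness genes
#'   share the lineage factor scaled by `kappa`, creating correlation with
#'   no causal buffering.
#' }
#' Sub-streams of the RNG are derived deterministically from `seed` per
#' matrix, so the same spec and seed always reproduce the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list with `cohort` (an [align_cohort()] object) and `truth`
#'   (class `"cohort_truth"`: `deleted_lines`, `buffering_pairs`,
#'   `decoy_pairs`, `dceres_positive_genes`, effect sizes and `seed`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  lay <- cohort_layout(spec)
  idx <- lay$idx
  nl <- spec$n_lines; ng <- spec$n_genes
  lines <- sprintf("ACH-%06d", seq_len(nl))

  # stream 1: cohort structure (lineages, deletion status, latent factors)
  st <- with_seed(seed, {
    lineage <- sample.int(spec$n_lineages, nl, replace = TRUE)
    list(lineage = lineage,
         lambda = stats::rnorm(spec$n_lineages),
         deleted = stats::runif(nl) < spec$p_del,
         decoy_load = stats::runif(spec$n_decoy_expr, 1.0, 1.4),
         conf_load = stats::runif(spec$n_conf_fitness, 0.3, 0.5))
  })
  # Latent lineage factor per line, standardized across the cohort so that
  # `kappa` states the realized (not nominal) confounding strength for any
  # draw of the per-lineage values.
  lam_line <- st$lambda[st$lineage]
  if (stats::sd(lam_line) > 0)
    lam_line <- (lam_line - mean(lam_line)) / stats::sd(lam_line)
  del <- st$deleted

  # stream 2: copy number
  cn <- with_seed(seed + 1L, {
    m <- matrix(stats::rnorm(ng * nl, 0, spec$cn_noise_sd), ng, nl)
    m[idx_arm(spec), del] <- m[idx_arm(spec), del] + spec$del_depth
    m
  })

  # stream 3: expression
  expr <- with_seed(seed + 2L, {
    base <- stats::rnorm(ng, 5, 1)
    base[c(idx$buffering_expr, idx$buffered_fit, idx$decoy_expr,
           idx$dceres, idx$conf_fitness)] <- 6
    lin_off <- matrix(stats::rnorm(ng * spec$n_lineages, 0, spec$lineage_expr_sd),
                      ng, spec$n_lineages)
    m <- base + lin_off[, st$lineage] +
      matrix(stats::rnorm(ng * nl, 0, spec$expr_noise_sd), ng, nl)
    m[idx_arm(spec), del] <- m[idx_arm(spec), del] - spec$expr_del_shift
    m[idx$buffering_expr, ] <- m[idx$buffering_expr, ] + stats::rnorm(nl, 0, 1)
    m[idx$decoy_expr, ] <- m[idx$decoy_expr, ] +
      spec$kappa * outer(st$decoy_load, lam_line)
    if (spec$n_var_expr > 0L)
      m[idx$var_expr, ] <- m[idx$var_expr, ] +
        matrix(stats::rnorm(spec$n_var_expr * nl, 0, 1.1), spec$n_var_expr, nl)
    pmax(m, 0)
  })

  buffered_low <- expr[idx$buffering_expr, ] < stats::median(expr[idx$buffering_expr, ])

  # stream 4: fitness
  fit <- with_seed(seed + 3L, {
    base <- stats::rnorm(ng, -0.1, 0.05)
    base[idx$conf_fitness] <- -1.1
    base[idx$buffered_fit] <- -0.35
    base[idx$dceres] <- -0.2
    m <- base + matrix(stats::rnorm(ng * nl, 0, spec$ceres_noise_sd), ng, nl)
    m[idx$conf_fitness, ] <- m[idx$conf_fitness, ] +
      spec$kappa * outer(st$conf_load, lam_line)
    # The buffered gene's own lineage loading is set by moment matching so
    # that the decoy pairs' expected correlation sits at the planted pair's
    # level: this is what makes the decoys effective foils for a raw
    # Pearson ranking.
    m[idx$buffered_fit, ] <- m[idx$buffered_fit, ] + spec$kappa * 0.24 * lam_line
    if (spec$buffering_linear) {
      z <- as.numeric(scale(expr[idx$buffering_expr, ]))
      m[idx$buffered_fit, ] <- m[idx$buffered_fit, ] + spec$gamma * 0.4 * z
    } else {
      m[idx$buffered_fit, buffered_low] <- m[idx$buffered_fit, buffered_low] - spec$gamma
    }
    m[idx$dceres, del] <- m[idx$dceres, del] - spec$delta
    m
  })

  dn <- list(lay$keys, lines)
  dimnames(cn) <- dimnames(expr) <- dimnames(fit) <- dn
  cohort <- align_cohort(
    fitness = screen_matrix(fit, "fitness"),
    expression = screen_matrix(expr, "expression"),
    copy_number = screen_matrix(cn, "copy_number"),
    annotation = lay$annotation,
    lineage = stats::setNames(sprintf("lineage%02d", st$lineage), lines))

  truth <- structure(list(
    deleted_lines = lines[del],
    buffering_pairs = data.frame(expr_gene = lay$keys[idx$buffering_expr],
                                 fit_gene = lay$keys[idx$buffered_fit],
                                 gamma = spec$gamma),
    decoy_pairs = data.frame(expr_gene = lay$keys[idx$decoy_expr],
                             fit_gene = lay$keys[idx$buffered_fit]),
    dceres_positive_genes = data.frame(gene = lay$keys[idx$dceres],
                                       delta = spec$delta,
                                       on_arm = lay$keys[idx$dceres] %in%
                                         lay$keys[idx_arm(spec)]),
    seed = as.integer(seed)), class = "cohort_truth")
  list(cohort = cohort, truth = truth)
}

idx_arm <- function(spec) seq_len(spec$n_arm_genes)

#' Write a synthetic cohort to disk
#'
#' Emits the three matrices in the DepMap CSV dialect, annotation and
#' lineage as TSV, and the ground truth as JSON, so the cohort can be
#' consumed exactly like real data.
#'
#' @param x Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(x$cohort$fitness, file.path(dir, "gene_effect.csv"))
  write_matrix(x$cohort$expression, file.path(dir, "expression.csv"))
  write_matrix(x$cohort$copy_number, file.path(dir, "gene_cn.csv"))
  utils::write.table(x$cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(line_id = names(x$cohort$lineage), lineage = x$cohort$lineage),
    file.path(dir, "lineage.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  write_truth(x$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Serialize / read cohort ground truth
#'
#' @param truth A `"cohort_truth"` object.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   reconstructed `"cohort_truth"`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$deleted_lines <- as.character(unlist(x$deleted_lines))
  x$buffering_pairs <- as.data.frame(x$buffering_pairs)
  x$decoy_pairs <- as.data.frame(x$decoy_pairs)
  x$dceres_positive_genes <- as.data.frame(x$dceres_positive_genes)
  x$seed <- as.integer(x$seed)
  structure(x, class = "cohort_truth")
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A list with `cohort` and `truth`, as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  cohort <- align_cohort(
    fitness = read_matrix(file.path(dir, "gene_effect.csv"), "fitness"),
    expression = read_matrix(file.path(dir, "expression.csv"), "expression"),
    copy_number = read_matrix(file.path(dir, "gene_cn.csv"), "copy_number"),
    annotation = read_annotation(file.path(dir, "annotation.tsv")),
    lineage = read_lineage(file.path(dir, "lineage.tsv")))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) read_truth(truth_path) else NULL
  list(cohort = cohort, truth = truth)
}
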