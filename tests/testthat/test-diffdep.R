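two_group_fixture <- function(vals_del, vals_nondel, genes = NULL) {
  vals <- cbind(vals_del, vals_nondel)
  del <- sprintf("D%02d", seq_len(ncol(as.matrix(vals_del))))
  nondel <- sprintf("N%02d", seq_len(ncol(as.matrix(vals_nondel))))
  m <- tiny_matrix(vals, genes = genes, lines = c(del, nondel))
  list(m = m, calls = calls_from_groups(del, nondel))
}

test_that("the expression prefilter applies a strict OR rule on group means", {
  vals <- rbind(c(1.5, 1.5, 0.2, 0.2),   # DEL mean 1.5, nonDEL 0.2 -> pass
                c(1.0, 1.0, 1.0, 1.0),   # both exactly 1 -> fail (strict)
                c(0.0, 0.0, 0.0, 0.0),   # both 0 -> fail
                c(0.2, 0.2, 1.4, 1.4))   # nonDEL side passes
  m <- tiny_matrix(vals, lines = c("d1", "d2", "n1", "n2"), kind = "expression")
  calls <- calls_from_groups(c("d1", "d2"), c("n1", "n2"))
  expect_identical(unname(expression_prefilter(m, calls)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_error(expression_prefilter(m, calls_from_groups(character(0), c("n1"))),
               "DEL")
})

test_that("dCERES is the DEL minus nonDEL mean and is antisymmetric", {
  fx <- two_group_fixture(rbind(c(-0.6, -0.4)), rbind(c(-0.1, -0.3)))
  tab <- dceres(fx$m, fx$calls)
  expect_equal(tab$mean_del, -0.5)
  expect_equal(tab$mean_nondel, -0.2)
  expect_equal(tab$dceres, -0.3)
  expect_equal(tab$dceres, tab$mean_del - tab$mean_nondel)

  # identical distributions -> 0
  fx0 <- two_group_fixture(rbind(c(-0.2, -0.4)), rbind(c(-0.4, -0.2)))
  expect_equal(dceres(fx0$m, fx0$calls)$dceres, 0)

  # swapping the labels flips the sign
  swapped <- calls_from_groups(c("N01", "N02"), c("D01", "D02"))
  expect_equal(dceres(fx$m, swapped)$dceres, -tab$dceres)

  # a group that is all-missing yields a missing result
  fxna <- two_group_fixture(rbind(c(NA, NA)), rbind(c(-0.1, -0.3)))
  expect_true(is.na(dceres(fxna$m, fxna$calls)$dceres))
})

test_that("rank-sum p-values are exact for small tie-free groups", {
  fx <- two_group_fixture(rbind(c(1, 2, 3)), rbind(c(4, 5, 6)))
  expect_equal(unname(wilcoxon_per_gene(fx$m, fx$calls)), 2 / choose(6, 3))

  # identical multisets in both groups -> p = 1
  fx1 <- two_group_fixture(rbind(c(1, 2)), rbind(c(1, 2)))
  expect_equal(unname(wilcoxon_per_gene(fx1$m, fx1$calls)), 1)

  # constant data -> p = 1
  fxc <- two_group_fixture(rbind(c(2, 2)), rbind(c(2, 2)))
  expect_equal(unname(wilcoxon_per_gene(fxc$m, fxc$calls)), 1)

  # brute-force oracle: full enumeration of all C(10, 5) assignments
  set.seed(5)
  x <- rnorm(5); y <- rnorm(5)
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[1:5])
  combos <- utils::combn(10L, 5L)
  stats <- apply(combos, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- 5 * 11 / 2
  p_oracle <- mean(abs(stats - mu) >= abs(obs - mu))
  fx2 <- two_group_fixture(rbind(x), rbind(y))
  expect_equal(unname(wilcoxon_per_gene(fx2$m, fx2$calls)), p_oracle)
})

test_that("planted DEL-specific effects are recovered by dCERES", {
  # delta = 0.4 planted; mean estimate over seeds within 3 SE of -0.4
  est <- unlist(lapply(1:25, function(s) {
    x <- generate_cohort(small_spec(n_lines = 200L), seed = s)
    calls <- classify_lines(arm_deletion_score(
      x$cohort$copy_number, x$cohort$annotation))
    tab <- dceres(x$cohort$fitness, calls)
    tab$dceres[match(x$truth$dceres_positive_genes$gene, tab$gene)]
  }))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-0.4)), 3 * se + 0.01)
})

test_that("hit selection applies strict cuts on adjusted p and dCERES", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    dceres = c(-0.1, -0.075, -0.1, -0.5, -0.2),
                    p_adj = c(0.2, 0.01, 0.25, 0.05, NA),
                    passed_prefilter = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- select_hits(tab)
  expect_identical(out$is_hit, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$is_strict_hit, c(FALSE, FALSE, FALSE, FALSE, FALSE))
  out2 <- select_hits(transform(tab, p_adj = c(0.05, 0.01, 0.25, 0.05, NA)))
  expect_true(out2$is_strict_hit[1])
})

test_that("arm enrichment matches the closed-form hypergeometric tail", {
  ann <- data.frame(gene_symbol = sprintf("G%03d", 1:100), entrez_id = 1:100,
                    chromosome = c(rep("8", 10), rep("1", 90)),
                    arm = c(rep("p", 10), rep("q", 90)),
                    start_bp = 1:100, end_bp = 2:101)
  universe <- sprintf("G%03d", 1:100)
  # all 10 draws on the arm: p = 1 / C(100, 10)
  enr <- arm_enrichment(sprintf("G%03d", 1:10), ann, universe)
  expect_equal(enr$p_value, 1 / choose(100, 10))
  expect_equal(enr$fold_enrichment, 10)
  # k/n = K/N -> fold exactly 1
  enr2 <- arm_enrichment(sprintf("G%03d", c(1, 11:19)), ann, universe)
  expect_equal(enr2$fold_enrichment, 1)
  expect_error(arm_enrichment("ZZZ", ann, universe), "subset")
})

test_that("null hypergeometric p-values are calibrated (conservative)", {
  set.seed(11)
  N <- 200L; K <- 30L; n <- 20L
  k <- stats::rhyper(10000, K, N - K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  frac <- mean(p <= 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("lineage regression residualizes scores and flags the lowest decile", {
  # two lineages, zero within-lineage variance -> all residuals 0
  sc <- c(a = -0.5, b = -0.5, c = -0.1, d = -0.1)
  lin <- c(a = "L1", b = "L1", c = "L2", d = "L2")
  res <- lineage_corrected_dependency(sc, lin, decile = 0.5)
  expect_equal(unname(res$residuals), rep(0, 4))

  # single lineage: grand-mean centering with a warning
  expect_warning(
    res1 <- lineage_corrected_dependency(sc, c(a = "L", b = "L", c = "L", d = "L")),
    "single lineage")
  expect_equal(unname(res1$residuals), unname(sc - mean(sc)))
})

test_that("dependent lines have lower partner expression when buffering is planted", {
  hit <- vapply(1:30, function(s) {
    x <- generate_cohort(small_spec(n_lines = 200L), seed = s)
    tr <- x$truth$buffering_pairs
    res <- lineage_corrected_dependency(
      unclass(x$cohort$fitness)[tr$fit_gene, ],
      x$cohort$lineage,
      partner_expression = unclass(x$cohort$expression)[tr$expr_gene, ])
    res$expression$mean_dependent < res$expression$mean_other
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})
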