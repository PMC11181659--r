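test_that("candidate filters apply the strict variation and expression rules", {
  set.seed(21)
  n <- 500L
  # gene 1: SD ~1.2, high expression -> buffering candidate
  # gene 2: SD exactly tuned below 1 -> excluded
  # gene 3: high SD but rarely above level 3 -> excluded
  e <- rbind(rnorm(n, 5, 1.2),
             rep(c(4.1, 5.9), length.out = n), # SD ~0.9 -> below the cut
             rnorm(n, 0.5, 1.5),
             rnorm(n, 5, 2))
  e <- pmax(e, 0)
  expr <- tiny_matrix(e, kind = "expression")
  # fitness: gene 1 via |mean| clause, gene 2 via SD clause, gene 3 neither
  f <- rbind(rnorm(n, -0.4, 0.1), rnorm(n, -0.25, 0.25), rnorm(n, -0.1, 0.05))
  fit <- tiny_matrix(f, kind = "fitness")
  cs <- filter_candidates(expr, fit)
  expect_identical(cs$buffering$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(cs$buffered$pass, c(TRUE, TRUE, FALSE))
  # an SD exactly at the cut is excluded: the comparison is strict
  cs_b <- filter_candidates(expr, fit, expr_sd_min = cs$buffering$expr_sd[1])
  expect_false(cs_b$buffering$pass[1])
  expect_error(filter_candidates(expr, tiny_matrix(matrix(-0.1, 1, n))),
               "empty buffered")
})

test_that("small-cohort mode rescales the line-count rule only when asked", {
  set.seed(22)
  n <- 40L
  e <- pmax(rbind(rnorm(n, 5, 1.3), rnorm(n, 5, 1.3)), 0)
  expr <- tiny_matrix(e, kind = "expression")
  fit <- tiny_matrix(rbind(rnorm(n, -0.5, 0.3), rnorm(n, -0.5, 0.3)))
  expect_error(filter_candidates(expr, fit), "empty buffering")
  cs <- filter_candidates(expr, fit, desk_scale = TRUE)
  expect_identical(cs$level_lines, 8)
  expect_true(all(cs$buffering$pass))
})

test_that("the correlation matrix matches a per-pair covariance oracle", {
  set.seed(23)
  nl <- 50L
  e <- matrix(rnorm(30 * nl), 30, nl,
              dimnames = list(sprintf("E%02d (%d)", 1:30, 1:30),
                              sprintf("ACH-%02d", 1:nl)))
  f <- matrix(rnorm(20 * nl), 20, nl,
              dimnames = list(sprintf("F%02d (%d)", 1:20, 101:120),
                              sprintf("ACH-%02d", 1:nl)))
  r <- pcc_matrix(screen_matrix(abs(e), "expression"),
                  screen_matrix(f, "fitness"), rownames(e), rownames(f))
  for (i in sample(30, 8)) for (j in sample(20, 8)) {
    x <- abs(e)[i, ]; y <- f[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(r[i, j] - oracle), 1e-12)
  }
  # perfect correlation and anti-correlation
  v <- abs(rnorm(nl)) + 0.1
  m1 <- tiny_matrix(rbind(v, v * 2), kind = "expression")
  m2 <- tiny_matrix(rbind(v, -v), kind = "fitness")
  r2 <- pcc_matrix(m1, m2, rownames(m1), rownames(m2))
  expect_equal(unname(r2[1, 1]), 1)
  expect_equal(unname(r2[1, 2]), -1)
  # too few complete observations -> missing
  vna <- v; vna[-(1:2)] <- NA
  m3 <- tiny_matrix(rbind(vna), kind = "expression")
  r3 <- pcc_matrix(m3, m2, rownames(m3), rownames(m2))
  expect_true(all(is.na(r3)))
})

test_that("the 2x2 balanced scores match exhaustive enumeration", {
  pcc <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
                dimnames = list(c("e1", "e2"), c("f1", "f2")))
  bs <- bacon_scores(pcc)
  expect_equal(unname(bs$w["e1", "f1"]), 0)
  expect_equal(unname(bs$score["e1", "f1"]), 0.9)
  expect_equal(unname(bs$w["e1", "f2"]), 1)   # both 0.9 and 0.8 beat 0.1
  expect_equal(unname(bs$score["e1", "f2"]), 0)
  expect_equal(unname(bs$w["e2", "f1"]), 1)   # 0.8 (row) and 0.9 (col) beat 0.2
  # 0.8 is the strict maximum of its own row and column: keeps its pcc
  expect_equal(unname(bs$w["e2", "f2"]), 0)
  expect_equal(unname(bs$score["e2", "f2"]), 0.8)
  expect_error(bacon_scores(pcc[1, , drop = FALSE]), "2 x 2")
})

test_that("ties are not competitors: a constant matrix keeps its correlations", {
  pcc <- matrix(0.3, 4, 5, dimnames = list(paste0("e", 1:4), paste0("f", 1:5)))
  bs <- bacon_scores(pcc)
  expect_true(all(bs$w == 0))
  expect_true(all(bs$score == 0.3))
})

test_that("balanced scores match the brute-force counter on random matrices", {
  set.seed(24)
  for (rep in 1:5) {
    nr <- sample(5:40, 1); nc <- sample(5:30, 1)
    pcc <- matrix(runif(nr * nc, -1, 1), nr, nc,
                  dimnames = list(paste0("e", 1:nr), paste0("f", 1:nc)))
    pcc[sample(length(pcc), round(0.05 * length(pcc)))] <- NA
    for (variant in c("multiplicative", "subtractive")) {
      bs <- bacon_scores(pcc, variant)
      oracle <- naive_bacon(pcc, variant)
      expect_equal(unname(bs$n_higher_row), oracle$n_higher_row,
                   ignore_attr = TRUE)
      expect_equal(unname(bs$n_higher_col), oracle$n_higher_col,
                   ignore_attr = TRUE)
      expect_equal(bs$w, oracle$w, ignore_attr = TRUE)
      expect_equal(bs$score, oracle$score, ignore_attr = TRUE)
      expect_true(all(bs$w >= 0 & bs$w <= 1, na.rm = TRUE))
    }
    bm <- bacon_scores(pcc, "multiplicative")
    expect_true(all(abs(bm$score) <= abs(bm$pcc) + 1e-12, na.rm = TRUE))
  }
})

test_that("the global maximum never has competitors and dominance is monotone", {
  set.seed(25)
  pcc <- matrix(runif(12 * 9, -1, 1), 12, 9,
                dimnames = list(paste0("e", 1:12), paste0("f", 1:9)))
  bs <- bacon_scores(pcc)
  top <- which(pcc == max(pcc), arr.ind = TRUE)
  expect_equal(unname(bs$w[top]), 0)
  expect_equal(unname(bs$score[top]), max(pcc))

  # increasing one entry cannot increase its counts or decrease its score
  i <- 5L; j <- 4L
  pcc2 <- pcc; pcc2[i, j] <- pcc2[i, j] + 0.3
  bs2 <- bacon_scores(pcc2)
  expect_lte(bs2$n_higher_row[i, j], bs$n_higher_row[i, j])
  expect_lte(bs2$n_higher_col[i, j], bs$n_higher_col[i, j])
  expect_gte(bs2$score[i, j], bs$score[i, j])

  # ranking is invariant under row/column permutation
  pr <- sample(12); pc <- sample(9)
  bs3 <- bacon_scores(pcc[pr, pc])
  expect_equal(bs3$score, bs$score[pr, pc])
})

test_that("pair ranking removes pan-essentials and respects the hit restriction", {
  set.seed(26)
  nl <- 30L
  expr <- tiny_matrix(matrix(abs(rnorm(3 * nl)) + 3, 3, nl),
                      genes = c("e1", "e2", "e3"), kind = "expression")
  fit_vals <- rbind(rnorm(nl, -0.9, 0.1),  # pan-essential
                    rnorm(nl, -0.3, 0.2),
                    rnorm(nl, -0.1, 0.2))
  fit <- tiny_matrix(fit_vals, genes = c("f1", "f2", "f3"))
  r <- pcc_matrix(expr, fit, c("e1", "e2", "e3"), c("f1", "f2", "f3"))
  bs <- bacon_scores(r)
  tab <- rank_pairs(bs, fit)
  expect_false("f1" %in% tab$fit_gene)     # mean CERES < -0.75 removed
  expect_equal(nrow(tab), 6L)              # empty restriction keeps the rest
  expect_true(all(diff(tab$bacon_score) <= 0))
  expect_identical(tab$rank, dense_rank <- match(-tab$bacon_score,
                                                 sort(unique(-tab$bacon_score))))
  tab2 <- rank_pairs(bs, fit, restrict_to_hits = "f2")
  expect_identical(unique(tab2$fit_gene), "f2")
  expect_identical(nrow(rank_pairs(bs, fit, top_k = 2L)), 2L)
})

test_that("pair-count accounting holds on complete candidate matrices", {
  set.seed(27)
  x <- generate_cohort(small_spec(), seed = 2)
  cs <- filter_candidates(x$cohort$expression, x$cohort$fitness,
                          desk_scale = TRUE)
  r <- pcc_matrix(x$cohort$expression, x$cohort$fitness,
                  cs$buffering_genes, cs$buffered_genes)
  expect_equal(sum(!is.na(r)),
               pair_count(length(cs$buffering_genes), length(cs$buffered_genes)))
})
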