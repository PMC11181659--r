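cond44 <- rep(c("A", "B"), each = 4)

test_that("the valid-value filter keeps proteins observed in 70% of one condition", {
  x <- rbind(p1 = c(1, 2, 3, NA, NA, NA, NA, 0),   # 3/4 in A, 0/4 in B -> kept
             p2 = c(1, 2, NA, NA, 3, 4, NA, NA),   # 2/4 and 2/4 -> dropped
             p3 = c(1, 2, 3, 4, 1, NA, NA, NA))    # 4/4 in A -> kept
  out <- valid_value_filter(x, cond44, frac = 0.70)
  expect_identical(rownames(out), c("p1", "p3"))
  # zero intensities count as missing
  expect_true(is.na(out["p1", 8]))

  # exactly 70% of a condition's samples is kept (inclusive)
  x10 <- matrix(1, 2, 20)
  x10[1, 8:10] <- NA   # 7/10 valid in condition A
  x10[1, 11:20] <- NA  # 0/10 in B
  out10 <- valid_value_filter(x10, rep(c("A", "B"), each = 10))
  expect_identical(nrow(out10), 2L)
  x10[1, 7] <- 0       # 6/10 -> below 70%
  expect_identical(nrow(valid_value_filter(x10, rep(c("A", "B"), each = 10))), 1L)

  expect_error(valid_value_filter(x, rep("A", 8)), "two conditions")
})

test_that("quantile normalization equalizes column distributions", {
  # hand-computed reference: columns (1,2,3) and (4,5,6) -> both (2.5,3.5,4.5)
  x <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(quantile_normalize(x), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)),
               ignore_attr = TRUE)

  # fixed point: columns already sharing a sorted value multiset
  y <- cbind(c(3, 1, 2), c(1, 2, 3))
  expect_equal(quantile_normalize(y), y, ignore_attr = TRUE)

  # defining property on a random complete matrix
  set.seed(31)
  z <- matrix(rnorm(60, 20, 3), 12, 5)
  qz <- quantile_normalize(z)
  ref <- sort(qz[, 1])
  for (j in 2:5) expect_equal(sort(qz[, j]), ref)
  # missing entries stay missing
  z[3, 2] <- NA
  expect_true(is.na(quantile_normalize(z)[3, 2]))
  expect_error(quantile_normalize(matrix(c(1, NA, NA, 1, 2, 3), 3, 2)),
               "at least 2 observed")
})

test_that("downshifted imputation draws from the stated per-sample distribution", {
  set.seed(32)
  x <- matrix(rnorm(12, 25, 2), 3, 4)
  expect_identical(downshift_impute(x, seed = 1), x) # complete -> no-op

  big <- matrix(rnorm(20000, 25, 2), 10000, 2)
  big[seq_len(9000), 2] <- NA
  obs <- big[9001:10000, 2]
  out <- downshift_impute(big, shift = 1.8, width = 0.3, seed = 7)
  expect_identical(downshift_impute(big, shift = 1.8, width = 0.3, seed = 7), out)
  expect_identical(out[9001:10000, 2], obs) # observed entries untouched
  imp <- out[seq_len(9000), 2]
  mu <- mean(obs); s <- sd(obs)
  expect_lt(abs(mean(imp) - (mu - 1.8 * s)), 3 * 0.3 * s / sqrt(9000))
  expect_equal(sd(imp), 0.3 * s, tolerance = 0.05)

  # shift = 0, width = 1 reproduces the sample's own moments
  out2 <- downshift_impute(big, shift = 0, width = 1, seed = 8)
  imp2 <- out2[seq_len(9000), 2]
  expect_equal(mean(imp2), mu, tolerance = 3 * s / sqrt(9000) / mu + 0.01)
  expect_equal(sd(imp2), s, tolerance = 0.05)

  const <- matrix(c(1, 1, 1, NA), 2, 2)
  expect_error(downshift_impute(const), "zero observed spread")
})

test_that("the moderated test reduces to the pooled t when the prior is off", {
  set.seed(33)
  x <- matrix(rnorm(60, 20, 1), 10, 6)
  cond <- rep(c("A", "B"), each = 3)
  out <- moderated_test(x, cond, d0 = 0)
  for (i in 1:10) {
    tt <- t.test(x[i, 1:3], x[i, 4:6], var.equal = TRUE)
    expect_equal(out$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(out$p[i], tt$p.value, tolerance = 1e-10)
  }
  # identical group means -> zero fold change, p = 1
  y <- rbind(c(1, 2, 3, 3, 2, 1))
  out0 <- moderated_test(y, cond, d0 = 0)
  expect_equal(out0$log2fc, 0)
  expect_equal(out0$p, 1)
})

test_that("empirical-Bayes moderation agrees with the limma oracle", {
  set.seed(34)
  # heteroscedastic proteins so the variance prior is finite and informative
  sd_i <- sqrt(1 / stats::rgamma(200, shape = 5, rate = 5))
  x <- matrix(rnorm(200 * 6, 20, rep(sd_i, 6)), 200, 6)
  x[1:20, 1:3] <- x[1:20, 1:3] + 1
  cond <- rep(c("KO", "CTR"), each = 3)
  out <- moderated_test(x, cond)
  design <- cbind(1, cond == "CTR") # second coefficient = CTR - KO = log2fc
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(out, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(out, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(out$t_mod, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(out$p, fit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("classes follow the fold-change and adjusted-p rule exactly", {
  set.seed(35)
  sim <- simulate_proteome(n_proteins = 150, n_planted = 15, lfc = 1.5,
                           sigma = 0.25, seed = 5)
  out <- moderated_test(sim$x, sim$condition)
  expect_identical(out$class == "up", out$log2fc >= 0.6 & out$p_adj < 0.05)
  expect_identical(out$class == "down", out$log2fc <= -0.6 & out$p_adj < 0.05)
})

test_that("the full workflow runs in fixed order and is seed-reproducible", {
  sim <- simulate_proteome(missing_rate = 0.15, seed = 9)
  raw <- 2^sim$x # back to raw intensity scale
  out1 <- proteome_diff(raw, sim$condition, seed = 3)
  out2 <- proteome_diff(raw, sim$condition, seed = 3)
  expect_identical(out1$p, out2$p)
  expect_true(nrow(out1) <= nrow(raw))
  proc <- attr(out1, "processed")
  expect_false(anyNA(proc))
  # planted proteins separate clearly from nulls on the adjusted p scale
  planted <- out1$protein %in% rownames(sim$x)[sim$planted]
  expect_lt(median(out1$p_adj[planted]), median(out1$p_adj[!planted]) / 2)
})
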