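# Naive O(n m (n + m)) competition counter used as the brute-force oracle.
naive_bacon <- function(pcc, variant = "multiplicative") {
  nr <- nrow(pcc); nc <- ncol(pcc)
  hi_r <- hi_c <- w <- s <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(pcc[i, j])) next
    row <- pcc[i, -j]; col <- pcc[-i, j]
    hi_r[i, j] <- sum(row > pcc[i, j], na.rm = TRUE)
    hi_c[i, j] <- sum(col > pcc[i, j], na.rm = TRUE)
    denom <- (sum(!is.na(pcc[i, ])) - 1) + (sum(!is.na(pcc[, j])) - 1)
    w[i, j] <- (hi_r[i, j] + hi_c[i, j]) / max(denom, 1)
    s[i, j] <- if (variant == "multiplicative")
      pcc[i, j] * (1 - w[i, j]) else pcc[i, j] - w[i, j]
  }
  list(n_higher_row = hi_r, n_higher_col = hi_c, w = w, score = s)
}
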