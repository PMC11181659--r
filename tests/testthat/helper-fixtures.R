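# Shared fixtures: tiny matrices and a desk-scale cohort specification.

tiny_matrix <- function(values, genes = NULL, lines = NULL, kind = "fitness") {
  values <- as.matrix(values)
  genes <- genes %||% sprintf("G%04d (%d)", seq_len(nrow(values)), seq_len(nrow(values)))
  lines <- lines %||% sprintf("ACH-%06d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, lines)
  screen_matrix(values, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scaled-down cohort used where the full 600 x 2000 reference cohort would
# be overkill; keeps every planted structure present.
small_spec <- function(n_lines = 150L, ...) {
  cohort_spec(n_lines = n_lines, n_genes = 80L, n_arm_genes = 15L,
              n_lineages = 5L, n_dceres_genes = 4L, n_decoy_expr = 4L,
              n_conf_fitness = 10L, n_var_expr = 5L, ...)
}

# Minimal two-group calls object for direct use of the dependency stages.
calls_from_groups <- function(del, nondel) {
  structure(data.frame(line = c(del, nondel),
                       arm_score = c(rep(-5, length(del)), rep(0, length(nondel))),
                       call = c(rep("DEL", length(del)), rep("nonDEL", length(nondel))),
                       stringsAsFactors = FALSE),
            class = c("arm_calls", "data.frame"),
            n_del = length(del), n_nondel = length(nondel), threshold = -2.5)
}
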