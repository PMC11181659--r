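# Internal helpers shared across modules.

#' Run code with a locally seeded RNG
#'
#' Restores the caller's RNG state on exit so that seeded operations inside
#' the package never perturb the user's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Polynomial rolling hash (mod the Mersenne prime 2^31 - 1) of a character
# scalar, reported as 8 hex digits. Used only to fingerprint configurations
# in run manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

# Dense ranks, largest value first; ties share a rank.
dense_rank_desc <- function(x) {
  u <- sort(unique(x), decreasing = TRUE)
  match(x, u)
}

stop_data <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
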