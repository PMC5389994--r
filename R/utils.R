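# internal helpers shared across modules

clamp01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Population standard deviation
#'
#' Standard deviation with the divisor `n` (not `n - 1`). All spread
#' statistics reported by the package (per-region SDs, across-species SDs,
#' sweep SDs) use this convention, and say so in their output metadata.
#'
#' @param x numeric vector.
#' @return Nonnegative scalar; `NA` for an empty vector.
#' @export
pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is saved and restored).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# derive a reproducible child seed from a master seed; stays below 2^31
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1117) %% 2147483563) + 1L
}
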