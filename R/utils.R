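#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a reproducible per-task seed from a master seed and a counter.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483587 + i * 7919) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
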