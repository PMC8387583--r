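# Internal helpers: seeding substreams and small numeric utilities.

# 32-bit multiply-hash on doubles (exact: all intermediates < 2^53).
mulmod32 <- function(a, b) {
  a <- a %% 4294967296
  b <- b %% 4294967296
  al <- a %% 65536
  ah <- a %/% 65536
  (((ah * b) %% 4294967296) * 65536 + al * b) %% 4294967296
}

#' Derive a reproducible substream seed
#'
#' Chains and generations draw from independent random substreams keyed by
#' `(master_seed, chain, generation)` with a counter-based hash, so that a
#' chain's results depend only on the master seed and its own index, and
#' thinning stored states never perturbs the simulation.
#'
#' @param master_seed Integer master seed for the run.
#' @param chain Chain index (1-based).
#' @param generation Generation index (1-based).
#' @return A single integer in `[0, 2^31)`, suitable for [set.seed()].
#' @export
substream_seed <- function(master_seed, chain = 1L, generation = 1L) {
  h <- mulmod32(master_seed + 2654435769, 2654435761)
  h <- mulmod32(h + chain * 40503 + 97, 2246822519)
  h <- mulmod32(h + generation * 69069 + 31, 3266489917)
  as.integer(h %% 2147483647)
}

# clip a numeric vector to [-lim, lim]
clip <- function(x, lim = 30) pmin(pmax(x, -lim), lim)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
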