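# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based seed derivation: a pure function of the master seed and a few
# small integer coordinates, kept below 2^31 so set.seed() accepts it.
# Adding new coordinates (e.g. extra densities) never perturbs existing seeds.
derive_seed <- function(master, ...) {
  parts <- c(...)
  s <- as.double(master) %% 2147483647
  for (p in parts) {
    s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(s)
}

# Largest-remainder apportionment of k items over positive weights.
# Ties broken by descending weight, then by position in `weights`.
largest_remainder <- function(weights, k) {
  stopifnot(k >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- k * weights / sum(weights)
  base <- floor(quota)
  short <- k - sum(base)
  if (short > 0) {
    rem <- quota - base
    ord <- order(-rem, -weights, seq_along(weights))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(weights)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
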