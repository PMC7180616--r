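# Internal helpers shared across modules.

# Clamp x into [lo, hi] elementwise.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Derive a child seed from a base seed and an index; stays below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 1299709) %% 2147483629)
}

# Recycle two data frames to a common number of rows (lengths 1 or n).
recycle_rows <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
  stop("incompatible numbers of rows: ", na, " vs ", nb)
}

stop_input <- function(...) stop(..., call. = FALSE)
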