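# Internal helpers shared across modules.

# Radix (byte-wise) sorting so that node and symbol order never depends on
# the session locale; collation of symbols containing '-' differs between
# locales and would break deterministic tie-breaking otherwise.
sort_sym <- function(x) sort(x, method = "radix")

order_sym <- function(...) order(..., method = "radix")

# Elementwise byte-wise x < y.  Stable radix order puts x before y on ties,
# so equal strings compare as "less"; callers that care about equality must
# test it separately (canonical edge pairs drop self-loops first).
lt_sym <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0L) return(logical(0))
  pos <- integer(2L * n)
  pos[order(c(x, y), method = "radix")] <- seq_len(2L * n)
  pos[seq_len(n)] < pos[n + seq_len(n)]
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
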