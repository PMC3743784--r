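# Internal helpers: seeded RNG scoping and deterministic seed derivation.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded helpers compose without side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and index path, staying within the
# 32-bit integer range. Deterministic, order-sensitive.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(s %% 2147483587) + 1L
}

stop_mikana <- function(fmt, ..., class = "mikana_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
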