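# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed from a top-level seed plus string labels, so each
# (module, condition) cell gets its own reproducible, order-independent RNG
# stream. Plain 31-multiplier polynomial hash modulo a Mersenne prime; stays
# inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), unlist(list(...))), collapse = "\r")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# Gene identifiers are opaque case-folded strings throughout.
fold_id <- function(x) tolower(trimws(as.character(x)))

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
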