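# Internal helpers: classed conditions, display rounding, seeded evaluation.

vv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "varvote_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Round half away from zero at `digits` decimals; base round() rounds half to
# even, which would turn a printed 0.95 kcal/mol into 0.9 and flip a vote.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 guards against representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
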