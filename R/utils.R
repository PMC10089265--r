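#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation failures.
invanet_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "invanet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derivation from one global seed. Kept well
# below .Machine$integer.max so downstream set.seed() always gets an integer.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1000 + stage_index) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    invanet_error("invanet_invalid_argument", sprintf("`%s` must be a single finite number", name))
  }
}
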