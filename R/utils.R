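# Internal helpers: classed conditions and RNG-state hygiene.

ck_abort <- function(msg, class = "generic") {
  stop(errorCondition(
    msg,
    class = c(sprintf("caprokin_%s_error", class), "caprokin_error")
  ))
}

ck_warn <- function(msg, class = "generic") {
  warning(warningCondition(
    msg,
    class = c(sprintf("caprokin_%s_warning", class), "caprokin_warning")
  ))
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state
# afterwards so simulations are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    ck_abort("`seed` must be a single finite number", "contract")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
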