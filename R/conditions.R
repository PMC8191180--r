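# Classed error conditions shared across the package. Subclass names map onto
# the CLI exit codes: format_error -> 2, invalid parameters/input -> 3,
# incomplete/insufficient data -> 4.

qk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("qamskit_", class), "qamskit_error")))
}

qk_check <- function(ok, msg, class) {
  if (!isTRUE(ok)) qk_stop(msg, class)
  invisible(TRUE)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulations do not disturb the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    qk_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed must be a single finite number", "invalid_parameter")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  code
}
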