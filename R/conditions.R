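# Classed conditions so callers can distinguish bad data from bad configuration.

stop_invalid_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("essnet_invalid_input", "essnet_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("essnet_config_error", "essnet_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("essnet_io_error", "essnet_error")))
}

stop_state <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("essnet_state_error", "essnet_error")))
}

stop_training <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("essnet_training_error", "essnet_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched.
with_local_seed <- function(seed, expr) {
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
  expr
}

# Deterministic fan-out of one global seed into per-stage seeds, so that each
# pipeline stage is independently reproducible from the run's single seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 7919 * h) %% .Machine$integer.max)
}
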