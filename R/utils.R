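# Internal helpers: classed errors and local RNG scope.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("safeguardR_input_error", "safeguardR_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("safeguardR_data_error", "safeguardR_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("safeguardR_config_error", "safeguardR_error")))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. Used by every stochastic operation so that identical (config,
# seed) pairs give bit-identical output regardless of surrounding code.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
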