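# Classed conditions used across the package so callers (and the CLI wrapper)
# can map failures to exit codes: config (2), data/format (3), inconsistency (4).

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fold_config_error", "fold_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fold_data_error", "fold_error")))
}

stop_inconsistency <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fold_inconsistency_error", "fold_error")))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# Guarantees byte-identical output for identical seeds without clobbering
# the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
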