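#' @keywords internal
"_PACKAGE"

## Classed error helpers: configuration errors (bad thresholds, malformed
## specs) are distinguishable from data errors (bad inputs) so callers and
## the command-line front-end can map them to exit codes.

pm_config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("panmetab_config_error", "panmetab_error")))
}

pm_data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("panmetab_data_error", "panmetab_error")))
}

pm_assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    pm_config_error("'%s' must be a single non-missing number", name)
  if (x < min || x > max)
    pm_config_error("'%s' must be in [%s, %s], got %s", name, min, max, x)
  invisible(x)
}

pm_assert_count <- function(x, name) {
  pm_assert_scalar_number(x, name, min = 0)
  if (x != as.integer(x))
    pm_config_error("'%s' must be a non-negative integer", name)
  invisible(as.integer(x))
}

## Deterministic local RNG: evaluates `expr` with the RNG seeded to `seed`
## and restores the caller's RNG state afterwards, so seeded generators do
## not perturb the session stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
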