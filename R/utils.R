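# Internal helpers shared across modules.

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' One pipeline seed is split into independent per-stage seeds so that stages
#' can be re-run in isolation and still reproduce the full-pipeline results.
#' The derivation is a plain polynomial hash, kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the consumer (e.g. `"counts"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483647
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 7919 + h) %% 2147483629 + 1)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# stop() with a consistent condition class so callers can distinguish
# validation failures from stage failures.
abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("stagecluster_validation_error", "error")))
}
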