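# seeded evaluation that restores the caller's RNG state afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a run seed
#'
#' Deterministic expansion of one global seed into per-stage child seeds so
#' that pipeline stages are individually reproducible:
#' `(seed * 7919 + 97 * stage) mod (2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 1).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 97 * as.numeric(stage)) %% 2147483647)
}

# safe logistic log-probability: log(plogis(x)) without underflow
log_plogis <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
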