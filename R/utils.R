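#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw their random numbers from seeds derived
#' deterministically from one global seed, so any stage can be re-run in
#' isolation and reproduce its output. The derivation keeps the result in
#' the 32-bit integer range.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed
#' @export
deriveSeed <- function(seed, stage) {
    v <- as.numeric(utf8ToInt(stage))
    h <- sum(v * seq_along(v) * 2654435) %% 1000003
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

## Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.msg <- function(...) {
    if (isTRUE(getOption("feqtl.verbose", TRUE)))
        message("[feqtl] ", sprintf(...))
}

## Geometric-style interval check used in several validators.
.checkFraction <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop(sprintf("%s must be a single number in [%g, %g]", name, lo, hi),
             call. = FALSE)
    invisible(x)
}
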