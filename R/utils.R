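# Evaluate expr under a local RNG state so generators are pure functions of
# their seed and never disturb the caller's random stream.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Negative-binomial draw that degrades to Poisson at dispersion 0.
rCounts <- function(n, mu, dispersion) {
    stopifnot(dispersion >= 0)
    if (dispersion == 0) rpois(n, lambda = mu)
    else rnbinom(n, mu = mu, size = 1 / dispersion)
}
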