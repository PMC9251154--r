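## Run expr with a private RNG state seeded by `seed`; the caller's
## .Random.seed is restored afterwards so generators never perturb user code.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(seed)
    force(expr)
}

.euclid <- function(p, q) sqrt(sum((p - q)^2))

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
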