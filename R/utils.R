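# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Restores (or removes) `.Random.seed` afterwards so that simulation
#' functions are deterministic given their `seed` argument without
#' perturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Derive a stream-specific seed from a root seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
    as.integer((as.numeric(seed) + as.numeric(k) * 7919) %% 2147483629)
}

#' Largest-remainder apportionment of n items to proportions
#'
#' Returns integer counts summing to `n`; ties in fractional remainder are
#' broken by position so the result is deterministic.
#' @noRd
apportion <- function(n, proportions) {
    stopifnot(abs(sum(proportions) - 1) < 1e-9)
    raw <- n * proportions
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        ord <- order(-(raw - base), seq_along(raw))
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    stats::setNames(as.integer(base), names(proportions))
}

# 1-based index of the bin (width w) containing 0-based base position p.
bin_of <- function(p, w) as.integer(floor(p / w)) + 1L

# md5 of a file, as character.
file_md5 <- function(path) unname(tools::md5sum(path))

stop2 <- function(...) stop(..., call. = FALSE)
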