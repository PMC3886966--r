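#' Unwrap clock hours from a 6AM anchor
#'
#' Clock hours are stored in `[0, 24)`; when a curve is laid out for
#' integration or interpolation it is anchored at 6AM (lights-on), so hours
#' earlier than the anchor are shifted by +24 (the 2AM sample becomes hour
#' 26). The returned vector preserves input order.
#'
#' @param times numeric clock hours in `[0, 24)`.
#' @param anchor anchor hour (default 6).
#' @return numeric hours in `[anchor, anchor + 24)`.
#' @export
#' @examples
#' unwrapTimes(c(6, 10, 14, 18, 22, 2))
unwrapTimes <- function(times, anchor = 6) {
    stopifnot(is.numeric(times), all(times >= 0 & times < 24))
    ((times - anchor) %% 24) + anchor
}

# run `expr` under a locally seeded RNG without disturbing the caller's
# random stream
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# dense periodic sample of a forcing for the compiled integrator:
# values at 0, dt, ..., 24 - dt
.forcingGrid <- function(f, dt = 0.01) {
    tt <- seq(0, 24 - dt, by = dt)
    list(values = forcingValues(f, tt), dt = dt)
}
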