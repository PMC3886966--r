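#' Latin hypercube sample of a parameter box
#'
#' Stratified sample: for each parameter the `n` draws occupy the `n`
#' equal-probability strata of its range exactly once. Deterministic given
#' the seed.
#'
#' @param bounds k x 2 matrix of `[lo, hi]` rows (rownames = parameter
#'   names).
#' @param n sample size.
#' @param seed integer RNG seed.
#' @return n x k matrix with the bounds' rownames as column names.
#' @export
latinHypercube <- function(bounds, n, seed = 1) {
    stopifnot(is.matrix(bounds), ncol(bounds) == 2, all(is.finite(bounds)))
    k <- nrow(bounds)
    u <- .withSeed(seed, lhs::randomLHS(as.integer(n), k))
    out <- sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], `*`),
                 2, bounds[, 1], `+`)
    colnames(out) <- rownames(bounds)
    out
}

#' Partial rank correlation coefficients
#'
#' For each input column j, both column j and the output are rank
#' transformed (average ties) and regressed on the ranks of all other
#' columns; the PRCC is the Pearson correlation of the two residual
#' vectors. The t statistic is `prcc * sqrt((n - 2 - k)/(1 - prcc^2))`
#' with `k` the number of adjusted columns, with a two-sided p-value from
#' the t distribution on `n - 2 - k` degrees of freedom.
#'
#' @param samples n x k numeric matrix of inputs (column names used as
#'   parameter labels; no constant column allowed).
#' @param outputs length-n numeric vector of model outputs.
#' @param timeH optional evaluation-time label stored in the result.
#' @return a [PrccResult-class] with one row per input column.
#' @export
prcc <- function(samples, outputs, timeH = NA_real_) {
    stopifnot(is.matrix(samples), nrow(samples) == length(outputs))
    n <- nrow(samples)
    k <- ncol(samples)
    if (is.null(colnames(samples)))
        colnames(samples) <- paste0("p", seq_len(k))
    cst <- which(apply(samples, 2, function(v) diff(range(v)) == 0))
    if (length(cst) > 0)
        stop("constant input column: ", paste(colnames(samples)[cst],
                                              collapse = ", "))
    if (diff(range(outputs)) == 0) stop("constant output")
    R <- apply(samples, 2, rank, ties.method = "average")
    ry <- rank(outputs, ties.method = "average")
    kAdj <- k - 1L
    df <- n - 2L - kAdj
    if (df < 1) stop("sample size too small for ", k, " parameters")
    rows <- lapply(seq_len(k), function(j) {
        other <- cbind(1, R[, -j, drop = FALSE])
        resJ <- stats::residuals(stats::lm.fit(other, R[, j]))
        resY <- stats::residuals(stats::lm.fit(other, ry))
        r <- stats::cor(resJ, resY)
        r <- max(min(r, 1), -1)
        tt <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
        data.frame(parameter = colnames(samples)[j], time_h = timeH,
                   prcc = r, statistic = tt,
                   p_value = 2 * stats::pt(-abs(tt), df = df), n = n)
    })
    methods::new("PrccResult", table = do.call(rbind, rows))
}

#' Configure the PRCC sensitivity analysis
#'
#' @param nSamples Latin hypercube size (default 1000, the protocol's
#'   sample size).
#' @param evalTimesH clock hours at which the entrained model output is
#'   read (default `c(6, 18)`, the light/dark switch points).
#' @param bounds k x 2 matrix of parameter ranges; parameters with
#'   `lo == hi` are held fixed and excluded from the PRCC.
#' @param seed integer RNG seed.
#' @param includeDummy include an inert `dummy` parameter as a
#'   false-positive control (default TRUE).
#' @return a [PrccConfig-class].
#' @export
prccConfig <- function(nSamples = 1000, evalTimesH = c(6, 18),
                       bounds = NULL, seed = 1, includeDummy = TRUE) {
    if (is.null(bounds)) bounds <- pparSensitivityBounds()
    methods::new("PrccConfig", nSamples = as.integer(nSamples),
                 evalTimesH = evalTimesH, bounds = bounds,
                 seed = as.integer(seed), includeDummy = includeDummy)
}

#' Sensitivity ranges around a parameter point
#'
#' The default PRCC ranges: +/- `span` (fractionally) around each
#' parameter of the centre point, intersected with the admissible domain
#' (`n` kept within `[1, 8]`).
#'
#' @param center a [PparModelParams-class] (default [pparParams()]).
#' @param span fractional half-width (default 0.5, i.e. +/-50%).
#' @return 8 x 2 bounds matrix.
#' @export
pparSensitivityBounds <- function(center = pparParams(), span = 0.5) {
    v <- as.numeric(center)
    b <- cbind(lo = v * (1 - span), hi = v * (1 + span))
    b["n", ] <- pmin(pmax(b["n", ], 1), 8)
    rownames(b) <- .PARAM_NAMES
    b
}

#' Global sensitivity of the entrained model output
#'
#' Latin hypercube draw over the configured ranges (plus an inert dummy
#' parameter when enabled), one entrained periodic solution per draw, the
#' output read at each evaluation clock hour, and a PRCC per (parameter,
#' time). Aborts if more than 1% of the simulations fail.
#'
#' @param center a [PparModelParams-class]: the point the ranges surround
#'   (used for parameters with degenerate `lo == hi` ranges too).
#' @param forcing a [ClockForcing-class].
#' @param cfg a [PrccConfig-class]; its bounds rows must be a subset of
#'   the eight parameter names. The default takes +/-50% ranges around
#'   `center` (via [pparSensitivityBounds()]); note that a cfg built by
#'   `prccConfig()` without explicit bounds is centred on [pparParams()]
#'   instead.
#' @param stepH RK4 step of the integrator (default 0.05).
#' @return a [PrccResult-class].
#' @export
runSensitivity <- function(center, forcing,
                           cfg = prccConfig(bounds = pparSensitivityBounds(center)),
                           stepH = 0.05) {
    stopifnot(methods::is(center, "PparModelParams"))
    b <- cfg@bounds
    if (!all(rownames(b) %in% .PARAM_NAMES))
        stop("bounds rows must be named after the model parameters")
    varying <- rownames(b)[b[, 1] < b[, 2]]
    if (length(varying) == 0) stop("no varying parameter")
    sampB <- b[varying, , drop = FALSE]
    if (cfg@includeDummy)
        sampB <- rbind(sampB, dummy = c(0, 1))
    X <- latinHypercube(sampB, cfg@nSamples, cfg@seed)
    full <- matrix(rep(as.numeric(center), each = cfg@nSamples),
                   nrow = cfg@nSamples, dimnames = list(NULL, .PARAM_NAMES))
    fixedAt <- intersect(rownames(b)[b[, 1] == b[, 2]], .PARAM_NAMES)
    if (length(fixedAt) > 0) full[, fixedAt] <- rep(b[fixedAt, 1],
                                                    each = cfg@nSamples)
    full[, varying] <- X[, varying]
    g <- .forcingGrid(forcing)
    out <- .cppBatchEval(full, g$values, g$dt, cfg@evalTimesH, 6, 1L,
                         stepH, 1e-7, 200L)
    bad <- !stats::complete.cases(out) | apply(out, 1, function(r)
        any(!is.finite(r)))
    if (mean(bad) > 0.01)
        stop(sprintf("sensitivity aborted: %d of %d simulations failed",
                     sum(bad), length(bad)))
    keep <- which(!bad)
    tabs <- lapply(seq_along(cfg@evalTimesH), function(i)
        prccTable(prcc(X[keep, , drop = FALSE], out[keep, i],
                       timeH = cfg@evalTimesH[i])))
    methods::new("PrccResult", table = do.call(rbind, tabs))
}

#' @describeIn prccTable extract the PRCC table.
#' @export
setMethod("prccTable", "PrccResult", function(object) object@table)

#' @export
setMethod("show", "PrccResult", function(object) {
    cat("PrccResult:\n")
    tb <- object@table
    tb$prcc <- signif(tb$prcc, 4)
    tb$statistic <- signif(tb$statistic, 4)
    tb$p_value <- signif(tb$p_value, 3)
    print(tb, row.names = FALSE)
})

#' Write a PRCC table as TSV
#'
#' @param x a [PrccResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePrcc <- function(x, path) {
    utils::write.table(prccTable(x), path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
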