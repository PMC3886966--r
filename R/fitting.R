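#' Default search bounds for the eight model parameters
#'
#' The defaults encode the identifiability structure of a six-timepoint
#' cross-sectional design on the normalized expression scale
#' (lean-control 6AM ~ 1):
#' the clock-driven synthesis rate `vp` spans `[0.05, 2]` per hour while
#' basal synthesis `v0` and the saturable clearance `vd` are bounded at
#' 0.2 (minor mechanisms next to the Hill-driven synthesis and the
#' first-order decay the model is built around); the activation constant
#' `Kp` is confined to `[0.5, 1.5]`, the range actually visited by the
#' normalized BMAL1 drive — outside it the Hill term operates on its flat
#' tails, where no finite timecourse can inform it — and the Hill
#' coefficient to modest cooperativity `[1, 4]`. `deltaP` spans
#' `[0.02, 2]` per hour (mRNA half-lives of ~20 min to ~35 h). Pass a
#' custom matrix to [fitConfig()] to widen any of these.
#'
#' @return 8 x 2 matrix with rows named as in [pparParams()].
#' @export
defaultFitBounds <- function() {
    b <- rbind(v0 = c(1e-3, 0.2), vp = c(0.05, 2), Kp = c(0.5, 1.5),
               n = c(1, 4), vd = c(1e-3, 0.2), Kd = c(0.1, 2),
               deltaP = c(0.02, 2), x0 = c(0.01, 5))
    colnames(b) <- c("lo", "hi")
    b
}

#' Configure the two-stage parameter search
#'
#' Rates (`v0`, `vp`, `vd`, `deltaP`) are sampled log-uniformly by default
#' (they span decades); shape constants (`Kp`, `n`, `Kd`, `x0`) uniformly.
#'
#' @param nMonteCarlo random draws before refinement (default 10000).
#' @param bounds 8 x 2 bounds matrix (default [defaultFitBounds()]).
#' @param logScale named logical vector flagging log-uniform sampling.
#' @param seed integer RNG seed (default 1).
#' @param refineTopK number of best draws refined by conjugate gradient
#'   (default 1).
#' @param weightBySem weight squared residuals by `1/sem^2` (default
#'   FALSE: with 3-5 animals per cell the per-cell SEM estimates carry
#'   ~50% relative error, and weighting by their inverse squares is less
#'   stable than unit weights; set TRUE to restore SEM weighting).
#' @param mode `"initial_value"` (x0 fitted, trajectory started at 6AM) or
#'   `"periodic"` (entrained periodic solution, x0 excluded).
#' @param stepH RK4 step of the fast integrator (default 0.05 h).
#' @return a [FitConfig-class].
#' @export
fitConfig <- function(nMonteCarlo = 10000, bounds = defaultFitBounds(),
                      logScale = NULL, seed = 1, refineTopK = 1,
                      weightBySem = FALSE,
                      mode = c("initial_value", "periodic"), stepH = 0.05) {
    mode <- match.arg(mode)
    if (is.null(logScale))
        logScale <- stats::setNames(
            .PARAM_NAMES %in% c("v0", "vp", "vd", "deltaP"), .PARAM_NAMES)
    methods::new("FitConfig", nMonteCarlo = as.integer(nMonteCarlo),
                 bounds = bounds, logScale = logScale,
                 seed = as.integer(seed), refineTopK = as.integer(refineTopK),
                 weightBySem = weightBySem, mode = mode, stepH = stepH)
}

# observation target shared by objective / search: unwrapped sorted times,
# means and weights
.fitTarget <- function(curve, cfg) {
    if (length(curve@times) < 4) stop("curve needs >= 4 timepoints")
    tu <- unwrapTimes(curve@times)
    o <- order(tu)
    w <- rep(1, length(tu))
    if (cfg@weightBySem) {
        pos <- curve@sems > 0
        w[pos] <- 1 / curve@sems[pos]^2
    }
    list(times = tu[o], means = curve@means[o], weights = w[o])
}

.modeCode <- function(mode) if (mode == "periodic") 1L else 0L

# batch weighted rss for a parameter matrix (n x 8, canonical column order)
.batchRss <- function(parMat, target, fgrid, cfg) {
    vals <- .cppBatchEval(parMat, fgrid$values, fgrid$dt, target$times, 6,
                          .modeCode(cfg@mode), cfg@stepH, 1e-7, 200L)
    res <- sweep(vals, 2, target$means)
    as.numeric(res^2 %*% target$weights)
}

#' Weighted least-squares objective
#'
#' `rss = sum_t w_t (X_model(t) - mean_t)^2` with `w_t = 1/sem_t^2` when
#' SEM weighting is on and `sem_t > 0`, else 1. The model is evaluated at
#' the curve's (unwrapped) clock hours in the configured mode.
#'
#' @param params a [PparModelParams-class].
#' @param curve a [GroupMeanCurve-class] with >= 4 timepoints.
#' @param forcing a [ClockForcing-class].
#' @param cfg a [FitConfig-class].
#' @return non-negative weighted residual sum of squares.
#' @export
fitObjective <- function(params, curve, forcing, cfg = fitConfig()) {
    target <- .fitTarget(curve, cfg)
    g <- .forcingGrid(forcing)
    pv <- matrix(as.numeric(params), nrow = 1)
    .batchRss(pv, target, g, cfg)
}

#' Monte Carlo stage of the search
#'
#' Draws `nMonteCarlo` parameter vectors within the bounds (log-uniform for
#' flagged parameters), evaluates the objective for each and returns them
#' ranked by ascending rss. Deterministic given the configured seed.
#'
#' @inheritParams fitObjective
#' @return list with `draws` (n x 8 matrix, best first), `rss` (ascending)
#'   and `seed`.
#' @export
monteCarloSearch <- function(curve, forcing, cfg = fitConfig()) {
    stopifnot(all(is.finite(cfg@bounds)))
    target <- .fitTarget(curve, cfg)
    g <- .forcingGrid(forcing)
    n <- cfg@nMonteCarlo
    draws <- .withSeed(cfg@seed, {
        m <- matrix(NA_real_, nrow = n, ncol = 8,
                    dimnames = list(NULL, .PARAM_NAMES))
        for (j in seq_len(8)) {
            lo <- cfg@bounds[j, 1]; hi <- cfg@bounds[j, 2]
            m[, j] <- if (cfg@logScale[j])
                10^stats::runif(n, log10(lo), log10(hi))
            else stats::runif(n, lo, hi)
        }
        m
    })
    rss <- .batchRss(draws, target, g, cfg)
    if (all(!is.finite(rss))) stop("all Monte Carlo draws non-finite")
    o <- order(rss)
    list(draws = draws[o, , drop = FALSE], rss = rss[o], seed = cfg@seed)
}

# sine box transform: unbounded z <-> p in [lo, hi]; unlike a logistic
# transform its gradient does not flatten along the whole approach to a
# bound, which keeps the conjugate-gradient line searches alive
.boxFwd <- function(p, lo, hi)
    asin(pmin(pmax(2 * (p - lo) / (hi - lo) - 1, -1), 1))
.boxInv <- function(z, lo, hi) lo + (hi - lo) * (sin(z) + 1) / 2

# Polak-Ribiere conjugate-gradient minimisation of fn over a box, via
# stats::optim(method = "CG", type = 2) on sine-transformed coordinates
# with central-difference numerical gradients
.cgMinimize <- function(fn, start, lower, upper, maxit = 500,
                        reltol = 1e-12) {
    z0 <- .boxFwd(start, lower, upper)
    trace <- new.env()
    trace$log <- list()
    wrapped <- function(z) {
        v <- fn(.boxInv(z, lower, upper))
        if (!is.finite(v)) return(1e12)
        trace$log[[length(trace$log) + 1L]] <- v
        v
    }
    # run in chunks, restarting the conjugate directions from the current
    # point (periodic restarts are standard for nonlinear CG); stop once a
    # whole chunk improves the objective by less than 1e-10 or the total
    # iteration budget is spent
    chunk <- max(50L, maxit %/% 5L)
    z <- z0
    val <- wrapped(z0)
    used <- 0L
    converged <- FALSE
    while (used < maxit) {
        res <- stats::optim(z, wrapped, method = "CG",
                            control = list(type = 2,
                                           maxit = min(chunk, maxit - used),
                                           reltol = reltol,
                                           ndeps = rep(1e-6, length(z0))))
        used <- used + min(chunk, maxit - used)
        z <- res$par
        if (val - res$value < 1e-10) {
            val <- min(val, res$value)
            converged <- TRUE
            break
        }
        val <- res$value
    }
    par <- .boxInv(z, lower, upper)
    val <- fn(par)
    startVal <- fn(start)
    if (!is.finite(val) || val > startVal) {     # never worse than the start
        par <- start
        val <- startVal
    }
    objs <- unlist(trace$log)
    list(par = par, value = val, converged = converged,
         trace = cbind(iteration = seq_along(objs), objective = objs))
}

#' Conjugate-gradient refinement of a parameter start
#'
#' Polak-Ribiere nonlinear conjugate gradient on box-transformed
#' parameters with central-difference numerical gradients; stops when the
#' relative objective change is negligible or after 500 iterations. The
#' refined rss never exceeds the start rss. In `"periodic"` mode `x0` is
#' held fixed (the periodic solution does not depend on it).
#'
#' @param start a [PparModelParams-class] (or named 8-vector) within the
#'   bounds.
#' @param maxit total conjugate-gradient iteration budget (default 500).
#' @inheritParams fitObjective
#' @return a [FitResult-class].
#' @export
refineFit <- function(start, curve, forcing, cfg = fitConfig(), maxit = 500) {
    sv <- if (methods::is(start, "PparModelParams")) as.numeric(start)
          else start[.PARAM_NAMES]
    target <- .fitTarget(curve, cfg)
    g <- .forcingGrid(forcing)
    free <- if (cfg@mode == "periodic") .PARAM_NAMES[1:7] else .PARAM_NAMES
    fixed <- sv
    obj <- function(p) {
        fixed[free] <- p
        .batchRss(matrix(fixed, nrow = 1), target, g, cfg)
    }
    res <- .cgMinimize(obj, sv[free], cfg@bounds[free, 1], cfg@bounds[free, 2],
                       maxit = maxit)
    if (!all(is.finite(res$par))) stop("refinement produced non-finite parameters")
    fitted <- sv
    fitted[free] <- res$par
    params <- .paramsFromVector(fitted)
    methods::new("FitResult", params = params, rss = res$value,
                 nObs = length(target$times), trace = res$trace,
                 converged = res$converged, seed = cfg@seed, mode = cfg@mode,
                 weaklyIdentified = .kpFlat(fitted, res$value, target, g, cfg))
}

# flat-profile identifiability check: rss profile over Kp across its bounds
.kpFlat <- function(fitted, rss, target, fgrid, cfg) {
    kps <- seq(cfg@bounds["Kp", 1], cfg@bounds["Kp", 2], length.out = 15)
    m <- matrix(rep(fitted, each = length(kps)), nrow = length(kps),
                dimnames = list(NULL, .PARAM_NAMES))
    m[, "Kp"] <- kps
    prof <- .batchRss(m, target, fgrid, cfg)
    diff(range(prof)) < 1e-3 * max(rss, 1e-12)
}

#' Full two-stage fit of one experimental group
#'
#' Composes [groupMeans()], [monteCarloSearch()] and [refineFit()] (top-k
#' starts, best kept): the estimation protocol of the study — 10,000
#' Monte Carlo draws followed by conjugate-gradient refinement.
#'
#' @param x a [TimecourseExperiment-class].
#' @param gene gene symbol to fit (e.g. `"PPARA"`).
#' @param maternal,diet group selectors (`lean`/`obese`, `control`/`HFD`).
#' @param forcing a [ClockForcing-class].
#' @param cfg a [FitConfig-class].
#' @return a [FitResult-class].
#' @export
fitGroup <- function(x, gene, maternal, diet, forcing, cfg = fitConfig()) {
    curves <- suppressWarnings(groupMeans(x, gene))
    key <- paste(maternal, diet, sep = ".")
    if (!key %in% names(curves))
        stop(sprintf("group %s has no observations for %s", key, gene))
    fitCurve(curves[[key]], forcing, cfg)
}

#' Two-stage fit of a prepared group-mean curve
#'
#' @param curve a [GroupMeanCurve-class].
#' @inheritParams fitGroup
#' @return a [FitResult-class].
#' @export
fitCurve <- function(curve, forcing, cfg = fitConfig()) {
    mc <- monteCarloSearch(curve, forcing, cfg)
    k <- min(cfg@refineTopK, nrow(mc$draws))
    best <- NULL
    for (i in seq_len(k)) {
        fr <- refineFit(mc$draws[i, ], curve, forcing, cfg)
        if (fr@rss > mc$rss[i]) {           # refinement dominance guard
            fr@params <- .paramsFromVector(mc$draws[i, ])
            fr@rss <- mc$rss[i]
        }
        if (is.null(best) || fr@rss < best@rss) best <- fr
    }
    best
}

#' @describeIn fittedParams extract the best-fit parameters.
#' @export
setMethod("fittedParams", "FitResult", function(object) object@params)

#' @export
setMethod("show", "FitResult", function(object) {
    cat(sprintf(
        "FitResult [%s mode]: rss = %.6g over %d points (seed %d)%s%s\n",
        object@mode, object@rss, object@nObs, object@seed,
        if (object@converged) ", converged" else ", iteration budget reached",
        if (object@weaklyIdentified) " [Kp weakly identified]" else ""))
    print(signif(as.numeric(object@params), 5))
})
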