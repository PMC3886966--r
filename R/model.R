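#' Construct the eight model parameters
#'
#' @param v0 basal synthesis rate (expression/h).
#' @param vp maximum BMAL1-driven synthesis rate (expression/h).
#' @param Kp BMAL1 activation constant.
#' @param n Hill coefficient in `[1, 8]`.
#' @param vd maximum saturable degradation rate (expression/h).
#' @param Kd degradation Michaelis constant.
#' @param deltaP non-specific first-order degradation rate (1/h).
#' @param x0 initial relative expression at the 6AM anchor.
#' @return a validated [PparModelParams-class].
#' @export
#' @examples
#' pparParams(vp = 0.6, deltaP = 0.2)
pparParams <- function(v0 = 0.05, vp = 0.5, Kp = 1, n = 2, vd = 0.05,
                       Kd = 0.3, deltaP = 0.2, x0 = 1) {
    methods::new("PparModelParams", v0 = v0, vp = vp, Kp = Kp, n = n,
                 vd = vd, Kd = Kd, deltaP = deltaP, x0 = x0)
}

#' @export
setMethod("as.numeric", "PparModelParams", function(x, ...) {
    stats::setNames(c(x@v0, x@vp, x@Kp, x@n, x@vd, x@Kd, x@deltaP, x@x0),
                    .PARAM_NAMES)
})

# inverse of as.numeric: named (or canonically ordered) vector -> object
.paramsFromVector <- function(v) {
    if (!is.null(names(v))) v <- v[.PARAM_NAMES]
    stopifnot(length(v) == 8)
    methods::new("PparModelParams", v0 = v[[1]], vp = v[[2]], Kp = v[[3]],
                 n = v[[4]], vd = v[[5]], Kd = v[[6]], deltaP = v[[7]],
                 x0 = v[[8]])
}

#' @export
setMethod("show", "PparModelParams", function(object) {
    v <- as.numeric(object)
    cat("PparModelParams:\n")
    print(signif(v, 5))
})

#' Right-hand side of the clock-forced PPARalpha mRNA equation
#'
#' `dX/dt = v0 + vp * B(t)^n / (Kp^n + B(t)^n) - vd * X/(Kd + X) - deltaP * X`
#'
#' Basal plus BMAL1-activated (Hill) synthesis, saturable plus first-order
#' clearance.
#'
#' @param t time in hours.
#' @param x current relative expression (>= 0).
#' @param params a [PparModelParams-class].
#' @param forcing a [ClockForcing-class] supplying B(t).
#' @return dX/dt (expression/h).
#' @export
pparRhs <- function(t, x, params, forcing) {
    B <- forcingValues(forcing, t)
    bn <- B^params@n
    kn <- params@Kp^params@n
    hill <- ifelse(bn + kn > 0, bn / (kn + bn), 0)
    deg <- ifelse(params@Kd + x > 0, params@vd * x / (params@Kd + x), 0)
    params@v0 + params@vp * hill - deg - params@deltaP * x
}

#' Simulate the model on a time grid
#'
#' Adaptive, stiff-capable integration (lsoda) from `x0` at the 6AM anchor; trajectories stay
#' non-negative because the rhs at X = 0 is non-negative for valid
#' parameters.
#'
#' @param params a [PparModelParams-class].
#' @param forcing a [ClockForcing-class].
#' @param times strictly increasing hours, all `>= t0` (use
#'   [unwrapTimes()] for clock hours crossing midnight).
#' @param t0 integration start (default 6 = 6AM).
#' @param x0 initial state (default `params@x0`).
#' @param atol,rtol absolute/relative integration tolerances (defaults
#'   1e-10 and 1e-8, tight enough that closed-form special cases agree to
#'   1e-6 over a day).
#' @return a [Trajectory-class] on `times`.
#' @export
simulatePpar <- function(params, forcing, times, t0 = 6, x0 = params@x0,
                         atol = 1e-10, rtol = 1e-8) {
    stopifnot(methods::is(params, "PparModelParams"),
              methods::is(forcing, "ClockForcing"))
    methods::validObject(params)
    if (any(times < t0)) stop("all times must be >= t0")
    if (is.unsorted(times, strictly = TRUE))
        stop("times must be strictly increasing")
    solveTimes <- if (times[1] > t0) c(t0, times) else times
    out <- try(deSolve::ode(
        y = c(X = x0), times = solveTimes,
        func = function(t, s, parms) list(pparRhs(t, s[1], params, forcing)),
        parms = NULL, method = "lsoda", atol = atol, rtol = rtol), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(solveTimes)) {
        lastGood <- if (inherits(out, "try-error")) t0 else out[nrow(out), "time"]
        stop(sprintf("integration failed; last good time %.3f h", lastGood))
    }
    vals <- out[match(times, out[, "time"]), "X"]
    methods::new("Trajectory", times = times, values = pmax(vals, 0),
                 params = params, forcingMode = forcing@mode)
}

#' Entrained periodic solution over one 24-h cycle
#'
#' Integrates period after period from the 6AM anchor until the maximum
#' deviation between successive periods falls below `tol` (so in
#' particular `|X(6) - X(30)| < tol`), then returns the final period.
#' Requires dissipation (`deltaP + vd > 0`); in `"periodic"` fitting mode
#' this removes the dependence on the initial condition `x0`.
#'
#' @param params a [PparModelParams-class] with `deltaP + vd > 0`.
#' @param forcing a [ClockForcing-class].
#' @param dt output spacing in hours (default 0.25).
#' @param tol successive-period convergence tolerance (default 1e-6).
#' @param maxPeriods abort after this many periods (default 200).
#' @param stepH RK4 step of the integrator (default 0.05).
#' @return a [Trajectory-class] on `seq(6, 30, by = dt)`.
#' @export
periodicSolution <- function(params, forcing, dt = 0.25, tol = 1e-6,
                             maxPeriods = 200, stepH = 0.05) {
    stopifnot(methods::is(params, "PparModelParams"))
    methods::validObject(params)
    if (params@deltaP + params@vd <= 0)
        stop("periodic solution requires dissipation (deltaP + vd > 0)")
    g <- .forcingGrid(forcing)
    rec <- seq(6, 30 - dt, by = dt)
    res <- .cppPeriodicSolution(as.numeric(params), g$values, g$dt,
                                6, stepH, tol, as.integer(maxPeriods),
                                rec, max(params@x0, 1e-6))
    if (!res$converged)
        stop(sprintf(
            "periodic solution did not converge in %d periods (deviation %.3g)",
            maxPeriods, res$deviation))
    methods::new("Trajectory",
                 times = c(rec, 30),
                 values = pmax(c(res$values, res$endState), 0),
                 params = params, forcingMode = forcing@mode)
}

#' @export
setMethod("show", "Trajectory", function(object) {
    cat(sprintf(
        "Trajectory (%s forcing): %d points on [%.2f, %.2f] h, range [%.4f, %.4f]\n",
        object@forcingMode, length(object@times), min(object@times),
        max(object@times), min(object@values), max(object@values)))
})

#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
    data.frame(time_h = x@times, value = x@values)
})
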