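#' Analytic cosinor clock drive
#'
#' `B(t) = mesor + amplitude * cos(2*pi*(t - acrophase)/24)`, the standard
#' rhythmometric waveform. Used as generating truth by the synthetic-data
#' module and convenient as a smooth stand-in drive.
#'
#' @param mesor rhythm-adjusted mean (> 0).
#' @param amplitude half peak-to-trough range (0 <= amplitude <= mesor so
#'   the drive stays non-negative).
#' @param acrophase clock hour of the peak (default 10, the observed
#'   CLOCK/BMAL1 peak).
#' @return a [ClockForcing-class] with mode `"cosinor"`.
#' @export
cosinorForcing <- function(mesor = 1, amplitude = 0.5, acrophase = 10) {
    stopifnot(mesor > 0, amplitude >= 0, amplitude <= mesor,
              acrophase >= 0, acrophase < 24)
    fun <- function(t) mesor + amplitude * cos(2 * pi * (t - acrophase) / 24)
    methods::new("ClockForcing", mode = "cosinor", periodH = 24, fun = fun,
                 info = list(mesor = mesor, amplitude = amplitude,
                             acrophase = acrophase))
}

#' Empirical clock drive from measured BMAL1 means
#'
#' Periodic cubic-spline interpolation through the per-time group means of
#' the clock gene, with period 24 h (the first knot is re-appended at
#' +24 h). The interpolant is exact at the knots and clipped at zero
#' (expression cannot be negative; clipping is recorded in `info`).
#'
#' @param curve a [GroupMeanCurve-class] with >= 4 distinct times
#'   (typically the BMAL1 curve of one group).
#' @return a [ClockForcing-class] with mode `"empirical"`.
#' @export
empiricalForcing <- function(curve) {
    stopifnot(methods::is(curve, "GroupMeanCurve"))
    tt <- curve@times
    yy <- curve@means
    if (length(unique(tt)) < 4)
        stop("empirical forcing needs >= 4 distinct times")
    t0 <- tt[1]
    sp <- stats::splinefun(c(tt, tt[1] + 24), c(yy, yy[1]),
                           method = "periodic")
    # clipping check on a fine grid
    grid <- seq(t0, t0 + 24, by = 0.01)
    clipped <- any(sp(grid) < 0)
    fun <- function(t) {
        u <- ((t - t0) %% 24) + t0
        pmax(sp(u), 0)
    }
    methods::new("ClockForcing", mode = "empirical", periodH = 24, fun = fun,
                 info = list(knots = data.frame(time_h = tt, mean = yy),
                             gene = curve@gene, maternal = curve@maternal,
                             diet = curve@diet, clipped = clipped))
}

#' Construct oscillator parameters
#'
#' Defaults give a three-variable Goodwin-type loop with an intrinsic
#' free-running period near (but not equal to) 24 h that entrains to a
#' 12:12 light-dark cycle; see [OscillatorParams-class] for the meaning of
#' each rate.
#'
#' @param v1,K,hill,k1,k2,k3,k4,k5 kinetic parameters (> 0).
#' @param lightAmp additive transcription drive during lights-on.
#' @param lightsOnHour clock hour of lights-on (default 6).
#' @param photoperiodH hours of light per cycle (default 12).
#' @return an [OscillatorParams-class].
#' @export
oscillatorParams <- function(v1 = 3, K = 1, hill = 10,
                             k1 = 0.16, k2 = 0.16, k3 = 0.16, k4 = 0.16,
                             k5 = 0.16, lightAmp = 0.3, lightsOnHour = 6,
                             photoperiodH = 12) {
    methods::new("OscillatorParams", v1 = v1, K = K, hill = hill,
                 k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 lightAmp = lightAmp, lightsOnHour = lightsOnHour,
                 photoperiodH = photoperiodH)
}

# square-wave light input: lightAmp during the photoperiod, 0 otherwise
.lightInput <- function(t, p) {
    u <- (t - p@lightsOnHour) %% 24
    ifelse(u < p@photoperiodH, p@lightAmp, 0)
}

.oscillatorRhs <- function(t, state, p) {
    x <- state[1]; y <- state[2]; z <- state[3]
    dx <- p@v1 / (1 + (z / p@K)^p@hill) + .lightInput(t, p) - p@k1 * x
    dy <- p@k2 * x - p@k3 * y
    dz <- p@k4 * y - p@k5 * z
    list(c(dx, dy, dz))
}

# integrate the oscillator and return a dense tail trajectory of the first
# variable (the clock transcript read out as the drive)
.oscillatorRun <- function(p, nPeriods = 60, dt = 0.05) {
    times <- seq(0, nPeriods * 24, by = dt)
    out <- deSolve::ode(y = c(x = 0.5, y = 0.5, z = 0.5), times = times,
                        func = function(t, s, parms) .oscillatorRhs(t, s, p),
                        parms = NULL, method = "lsoda",
                        atol = 1e-9, rtol = 1e-8, hmax = 0.25)
    data.frame(time = out[, "time"], x = out[, "x"])
}

# period from mean intervals between upward mean-crossings in the tail
.measurePeriod <- function(tr, tailH = 24 * 10) {
    tail <- tr[tr$time >= max(tr$time) - tailH, ]
    m <- mean(tail$x)
    s <- tail$x - m
    up <- which(s[-length(s)] < 0 & s[-1] >= 0)
    if (length(up) < 3) return(NA_real_)
    # linear interpolation of each crossing time
    tc <- tail$time[up] - s[up] * (tail$time[up + 1] - tail$time[up]) /
        (s[up + 1] - s[up])
    mean(diff(tc))
}

#' Mechanistic clock drive from an entrained oscillator
#'
#' Integrates the Goodwin-type oscillator under its light schedule for
#' `nPeriods` cycles, discards the transient, verifies entrainment (period
#' within 24 +/- 0.1 h, otherwise a warning carrying the measured period),
#' and returns the final cycle rescaled to the requested mean and
#' amplitude as a periodic interpolant.
#'
#' @param p an [OscillatorParams-class].
#' @param targetMean,targetAmplitude scale of the returned drive, matching
#'   the measured clock-gene mean and half-range (defaults 1 and 0.5).
#' @param nPeriods cycles to integrate (>= 10; default 60).
#' @return a [ClockForcing-class] with mode `"mechanistic"`; `info` carries
#'   the measured period and the raw final cycle.
#' @export
mechanisticForcing <- function(p = oscillatorParams(), targetMean = 1,
                               targetAmplitude = 0.5, nPeriods = 60) {
    stopifnot(methods::is(p, "OscillatorParams"), nPeriods >= 10)
    methods::validObject(p)
    tr <- .oscillatorRun(p, nPeriods = nPeriods)
    period <- .measurePeriod(tr)
    if (is.na(period) || abs(period - 24) > 0.1)
        warning(sprintf(
            "oscillator failed to entrain: measured period %.3f h", period))
    # final complete cycle, phase-aligned to clock time
    tEnd <- max(tr$time)
    anchor <- floor((tEnd - 24) / 24) * 24   # multiple of 24 => clock phase 0
    cyc <- tr[tr$time >= anchor & tr$time <= anchor + 24, ]
    xs <- cyc$x
    half <- (max(xs) - min(xs)) / 2
    scaled <- if (half > 0)
        targetMean + (xs - mean(xs)) / half * targetAmplitude
    else rep(targetMean, length(xs))
    clockT <- cyc$time - anchor             # in [0, 24]
    scaled[length(scaled)] <- scaled[1]     # enforce exact periodic closure
    sp <- stats::splinefun(clockT, scaled, method = "periodic")
    fun <- function(t) pmax(sp(t %% 24), 0)
    methods::new("ClockForcing", mode = "mechanistic", periodH = 24,
                 fun = fun,
                 info = list(measuredPeriod = period, params = p,
                             rawCycle = data.frame(time_h = clockT, x = xs)))
}

#' Free-running period of the oscillator
#'
#' Runs the oscillator with the light input switched off and measures the
#' interval between successive upward mean-crossings of the tail
#' trajectory — the intrinsic period, which need not equal 24 h.
#'
#' @param p an [OscillatorParams-class].
#' @param nPeriods cycles to integrate (default 60).
#' @return intrinsic period in hours.
#' @export
freeRunPeriod <- function(p = oscillatorParams(), nPeriods = 60) {
    pf <- p
    pf@lightAmp <- 0
    tr <- .oscillatorRun(pf, nPeriods = nPeriods)
    .measurePeriod(tr)
}

#' @describeIn forcingValues evaluate the drive (vectorised, periodic,
#'   clipped at zero).
#' @export
setMethod("forcingValues", "ClockForcing", function(object, times) {
    v <- object@fun(times)
    pmax(v, 0)
})

#' @export
setMethod("show", "ClockForcing", function(object) {
    g <- forcingValues(object, seq(0, 23.75, by = 0.25))
    cat(sprintf("ClockForcing [%s], period %g h, range [%.3f, %.3f]\n",
                object@mode, object@periodH, min(g), max(g)))
    if (object@mode == "mechanistic")
        cat(sprintf("  measured period: %.3f h\n", object@info$measuredPeriod))
})
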