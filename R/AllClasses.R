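#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib pparClock, .registration = TRUE
NULL

.MATERNAL_LEVELS <- c("lean", "obese")
.DIET_LEVELS <- c("control", "HFD")
.PARAM_NAMES <- c("v0", "vp", "Kp", "n", "vd", "Kd", "deltaP", "x0")

#' Cross-sectional circadian timecourse container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding relative expression
#' values (genes x animals) for a factorial circadian study: each animal
#' carries a maternal phenotype (`lean`/`obese`), a post-weaning diet
#' (`control`/`HFD`) and the clock hour at which it was sampled
#' (hours after midnight, in `[0, 24)`). Sampling is cross-sectional: each
#' animal contributes one timepoint.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`; the assay is
#'   named `"relexpr"` and `colData` carries `animal_id`, `maternal`,
#'   `diet`, `time_h`.
#' @export
setClass("TimecourseExperiment",
         contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("animal_id", "maternal", "diet", "time_h")
    miss <- setdiff(need, colnames(cd))
    if (length(miss) > 0)
        return(sprintf("colData lacks column(s): %s", paste(miss, collapse = ", ")))
    if (!all(as.character(cd$maternal) %in% .MATERNAL_LEVELS))
        return("maternal must be one of: lean, obese")
    if (!all(as.character(cd$diet) %in% .DIET_LEVELS))
        return("diet must be one of: control, HFD")
    tt <- cd$time_h
    if (!is.numeric(tt) || anyNA(tt) || any(tt < 0 | tt >= 24))
        return("time_h must be numeric in [0, 24)")
    if (!"relexpr" %in% SummarizedExperiment::assayNames(object))
        return("assay 'relexpr' is required")
    v <- SummarizedExperiment::assay(object, "relexpr")
    if (any(v < 0, na.rm = TRUE))
        return("relative expression values must be non-negative")
    TRUE
})

#' Per-group mean expression curve
#'
#' Mean +/- SEM relative expression of one gene in one
#' (maternal, diet) group across the sampled clock hours.
#'
#' @slot gene gene symbol.
#' @slot maternal,diet group factors (`lean`/`obese`, `control`/`HFD`).
#' @slot times clock hours in `[0, 24)`, strictly increasing.
#' @slot means per-time arithmetic means.
#' @slot sems per-time standard errors (sample SD / sqrt(n); 0 when n = 1).
#' @slot ns per-time replicate counts.
#' @export
setClass("GroupMeanCurve",
         representation(gene = "character", maternal = "character",
                        diet = "character", times = "numeric",
                        means = "numeric", sems = "numeric", ns = "integer"))

setValidity("GroupMeanCurve", function(object) {
    k <- length(object@times)
    if (length(object@means) != k || length(object@sems) != k ||
        length(object@ns) != k)
        return("times, means, sems, ns must have equal length")
    if (k > 1 && any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    if (any(object@times < 0 | object@times >= 24))
        return("times must lie in [0, 24)")
    if (any(object@sems < 0)) return("sems must be non-negative")
    TRUE
})

#' qPCR standard curve
#'
#' Log-linear calibration `Ct = intercept + slope * log10(quantity)` fitted
#' by ordinary least squares. The slope is negative for an amplifying
#' reaction; `efficiency()` returns `10^(-1/slope) - 1` (1 = perfect
#' doubling per cycle).
#'
#' @slot gene gene or amplicon label.
#' @slot intercept Ct at unit quantity.
#' @slot slope Ct change per decade of template (negative).
#' @slot r2 coefficient of determination of the fit.
#' @export
setClass("StandardCurve",
         representation(gene = "character", intercept = "numeric",
                        slope = "numeric", r2 = "numeric"))

setValidity("StandardCurve", function(object) {
    if (object@slope >= 0) return("slope must be negative")
    eff <- 10^(-1 / object@slope) - 1
    if (!(eff > 0 && eff <= 1.2))
        return(sprintf("implied amplification efficiency %.3f outside (0, 1.2]", eff))
    if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
    TRUE
})

#' 24-h periodic clock drive B(t)
#'
#' The BMAL1 forcing that drives PPARalpha synthesis: a non-negative,
#' 24-h periodic function of clock time. Built empirically (periodic spline
#' through measured group means), mechanistically (entrained oscillator) or
#' as an analytic cosinor.
#'
#' @slot mode `"empirical"`, `"mechanistic"` or `"cosinor"`.
#' @slot periodH the period in hours (24).
#' @slot fun vectorised function of clock time (any real hours).
#' @slot info provenance list (knots, measured period, clipping, ...).
#' @export
setClass("ClockForcing",
         representation(mode = "character", periodH = "numeric",
                        fun = "function", info = "list"))

setValidity("ClockForcing", function(object) {
    if (!object@mode %in% c("empirical", "mechanistic", "cosinor"))
        return("mode must be empirical, mechanistic or cosinor")
    if (object@periodH != 24) return("periodH must be 24")
    TRUE
})

#' Parameters of a minimal entrainable clock oscillator
#'
#' A three-variable Goodwin-type negative-feedback loop (transcript,
#' cytosolic protein, nuclear repressor) with square-wave light input on the
#' transcription term. Serves as the mechanistic source of the BMAL1 drive.
#'
#' @slot v1 maximal transcription rate (conc/h).
#' @slot K repression threshold (conc).
#' @slot hill repression Hill coefficient (>= 8 for sustained oscillation).
#' @slot k1,k3,k5 first-order degradation rates of the three species (1/h).
#' @slot k2,k4 production rates of the downstream species (1/h).
#' @slot lightAmp additive transcription drive during the light phase.
#' @slot lightsOnHour clock hour of lights-on (default 6).
#' @slot photoperiodH light-phase length in hours (default 12).
#' @export
setClass("OscillatorParams",
         representation(v1 = "numeric", K = "numeric", hill = "numeric",
                        k1 = "numeric", k2 = "numeric", k3 = "numeric",
                        k4 = "numeric", k5 = "numeric",
                        lightAmp = "numeric", lightsOnHour = "numeric",
                        photoperiodH = "numeric"))

setValidity("OscillatorParams", function(object) {
    rates <- c(object@v1, object@K, object@hill, object@k1, object@k2,
               object@k3, object@k4, object@k5)
    if (any(rates <= 0)) return("all kinetic parameters must be > 0")
    if (object@lightAmp < 0) return("lightAmp must be >= 0")
    if (object@photoperiodH <= 0 || object@photoperiodH >= 24)
        return("photoperiodH must lie in (0, 24)")
    TRUE
})

#' The eight parameters of the clock-forced PPARalpha mRNA equation
#'
#' `dX/dt = v0 + vp * B(t)^n / (Kp^n + B(t)^n) - vd * X / (Kd + X) - deltaP * X`
#'
#' @slot v0 basal synthesis rate (expression/h).
#' @slot vp maximum BMAL1-driven synthesis rate (expression/h).
#' @slot Kp BMAL1 activation constant (expression units).
#' @slot n Hill coefficient, continuous in `[1, 8]`.
#' @slot vd maximum saturable (specific) degradation rate (expression/h).
#' @slot Kd degradation Michaelis constant (expression units).
#' @slot deltaP non-specific first-order degradation rate (1/h).
#' @slot x0 initial condition at the 6AM anchor (expression units).
#' @export
setClass("PparModelParams",
         representation(v0 = "numeric", vp = "numeric", Kp = "numeric",
                        n = "numeric", vd = "numeric", Kd = "numeric",
                        deltaP = "numeric", x0 = "numeric"))

setValidity("PparModelParams", function(object) {
    v <- as.numeric(object)
    if (length(v) != 8 || anyNA(v)) return("all 8 parameters must be finite")
    if (any(v < 0)) return("all parameters must be non-negative")
    if (object@n < 1 || object@n > 8) return("n must lie in [1, 8]")
    TRUE
})

#' Simulated model trajectory
#'
#' @slot times hours (possibly unwrapped beyond 24), strictly increasing.
#' @slot values modelled relative expression, non-negative.
#' @slot params the [PparModelParams-class] used.
#' @slot forcingMode which forcing produced it.
#' @export
setClass("Trajectory",
         representation(times = "numeric", values = "numeric",
                        params = "PparModelParams", forcingMode = "character"))

setValidity("Trajectory", function(object) {
    if (length(object@times) != length(object@values))
        return("times and values must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    if (any(object@values < -1e-12)) return("values must be non-negative")
    TRUE
})

#' Configuration of the two-stage parameter search
#'
#' @slot nMonteCarlo number of random draws (10,000 in the reference
#'   protocol).
#' @slot bounds 8 x 2 matrix of `[lo, hi]` per parameter (rows named as in
#'   [pparParams()]).
#' @slot logScale named logical: sample that parameter log-uniformly.
#' @slot seed integer RNG seed; every stage is deterministic given it.
#' @slot refineTopK how many best draws to refine by conjugate gradient.
#' @slot weightBySem weight residuals by 1/sem^2 where sem > 0.
#' @slot mode `"initial_value"` (x0 fitted) or `"periodic"` (entrained
#'   periodic solution; x0 excluded from fitting).
#' @slot stepH RK4 step (h) of the fast integrator used during search.
#' @export
setClass("FitConfig",
         representation(nMonteCarlo = "integer", bounds = "matrix",
                        logScale = "logical", seed = "integer",
                        refineTopK = "integer", weightBySem = "logical",
                        mode = "character", stepH = "numeric"))

setValidity("FitConfig", function(object) {
    if (object@nMonteCarlo < 1L) return("nMonteCarlo must be >= 1")
    b <- object@bounds
    if (!identical(rownames(b), .PARAM_NAMES) || ncol(b) != 2)
        return("bounds must be an 8 x 2 matrix with the canonical row names")
    if (any(b[, 1] >= b[, 2])) return("each lower bound must be < upper bound")
    if (!identical(names(object@logScale), .PARAM_NAMES))
        return("logScale must be named with the canonical parameter names")
    if (!object@mode %in% c("initial_value", "periodic"))
        return("mode must be 'initial_value' or 'periodic'")
    TRUE
})

#' Result of a model fit
#'
#' @slot params best-fit [PparModelParams-class].
#' @slot rss (weighted) residual sum of squares at the optimum.
#' @slot nObs number of fitted points.
#' @slot trace matrix of (iteration, objective) across the refinement.
#' @slot converged logical: refinement met its stopping rule.
#' @slot seed the seed used.
#' @slot mode fitting mode.
#' @slot weaklyIdentified logical: rss profile over Kp is flat across the
#'   bounds (range < 1e-3 * rss), signalling poor identifiability.
#' @export
setClass("FitResult",
         representation(params = "PparModelParams", rss = "numeric",
                        nObs = "integer", trace = "matrix",
                        converged = "logical", seed = "integer",
                        mode = "character", weaklyIdentified = "logical"))

setValidity("FitResult", function(object) {
    if (object@rss < 0) return("rss must be non-negative")
    TRUE
})

#' Configuration of the PRCC sensitivity analysis
#'
#' @slot nSamples Latin hypercube size (1000 in the reference protocol).
#' @slot evalTimesH clock hours at which the model output is read
#'   (defaults 6 and 18, the light/dark switch points).
#' @slot bounds k x 2 matrix of parameter ranges (rows named).
#' @slot seed integer RNG seed.
#' @slot includeDummy add an inert parameter as a false-positive control.
#' @export
setClass("PrccConfig",
         representation(nSamples = "integer", evalTimesH = "numeric",
                        bounds = "matrix", seed = "integer",
                        includeDummy = "logical"))

setValidity("PrccConfig", function(object) {
    k <- nrow(object@bounds) + as.integer(object@includeDummy)
    if (object@nSamples <= k + 2L)
        return("nSamples must exceed number of parameters + 2")
    if (any(object@bounds[, 1] > object@bounds[, 2]))
        return("lower bounds must not exceed upper bounds")
    if (all(object@bounds[, 1] == object@bounds[, 2]))
        return("at least one parameter range must be non-degenerate")
    TRUE
})

#' Partial rank correlation results
#'
#' One row per (parameter, evaluation time): the PRCC, its t statistic,
#' two-sided p-value and the sample size.
#'
#' @slot table data.frame with columns `parameter`, `time_h`, `prcc`,
#'   `statistic`, `p_value`, `n`.
#' @export
setClass("PrccResult", representation(table = "data.frame"))

setValidity("PrccResult", function(object) {
    tb <- object@table
    need <- c("parameter", "time_h", "prcc", "statistic", "p_value", "n")
    if (!all(need %in% colnames(tb)))
        return("table lacks required columns")
    if (any(abs(tb$prcc) > 1 + 1e-12)) return("|prcc| must be <= 1")
    if (any(tb$p_value < 0 | tb$p_value > 1)) return("p_value must be in [0, 1]")
    TRUE
})

#' Cosinor specification of a synthetic gene timecourse
#'
#' Per-(maternal, diet) mesor M, amplitude A and acrophase phi (clock hour
#' of peak); cell means follow `M + A * cos(2*pi*(t - phi)/24)` and animals
#' get multiplicative lognormal noise of the given coefficient of variation.
#'
#' @slot gene gene symbol.
#' @slot groups data.frame with columns `maternal`, `diet`, `mesor`,
#'   `amplitude`, `acrophase`.
#' @slot noiseCv lognormal coefficient of variation (e.g. 0.10).
#' @slot nPerCell animals per group per timepoint (3-5 in the emulated
#'   design).
#' @export
setClass("CosinorSpec",
         representation(gene = "character", groups = "data.frame",
                        noiseCv = "numeric", nPerCell = "integer"))

setValidity("CosinorSpec", function(object) {
    g <- object@groups
    need <- c("maternal", "diet", "mesor", "amplitude", "acrophase")
    if (!all(need %in% colnames(g))) return("groups lacks required columns")
    if (any(g$mesor <= 0)) return("mesor must be > 0")
    if (any(g$amplitude < 0)) return("amplitude must be >= 0")
    if (any(g$amplitude > g$mesor))
        return("amplitude must not exceed mesor (means must stay positive)")
    if (any(g$acrophase < 0 | g$acrophase >= 24))
        return("acrophase must lie in [0, 24)")
    if (object@noiseCv < 0) return("noiseCv must be >= 0")
    TRUE
})
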