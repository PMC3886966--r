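#' Evaluate a clock forcing at arbitrary times
#'
#' @param object a [ClockForcing-class].
#' @param times numeric hours (any real; the drive is 24-h periodic).
#' @return numeric vector of non-negative drive values.
#' @export
setGeneric("forcingValues", function(object, times) standardGeneric("forcingValues"))

#' Per-group mean +/- SEM curves for one gene
#'
#' @param x a [TimecourseExperiment-class].
#' @param gene gene symbol present in `x`.
#' @param ... unused.
#' @return named list of [GroupMeanCurve-class], one per observed
#'   (maternal, diet) combination, named `"maternal.diet"`.
#' @export
setGeneric("groupMeans", function(x, gene, ...) standardGeneric("groupMeans"))

#' Replicate counts of the factorial circadian design
#'
#' @param x a [TimecourseExperiment-class].
#' @param gene optional gene symbol; when given, counts non-missing
#'   observations of that gene, otherwise counts animals.
#' @return data.frame with columns `maternal`, `diet`, `time_h`, `n`.
#' @export
setGeneric("designTable", function(x, gene = NULL) standardGeneric("designTable"))

#' Amplification efficiency implied by a standard curve
#'
#' @param object a [StandardCurve-class].
#' @return `10^(-1/slope) - 1`; 1 means perfect doubling per cycle.
#' @export
setGeneric("efficiency", function(object) standardGeneric("efficiency"))

#' Best-fit parameters of a model fit
#'
#' @param object a [FitResult-class].
#' @return the fitted [PparModelParams-class].
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))

#' PRCC table of a sensitivity analysis
#'
#' @param object a [PrccResult-class].
#' @return data.frame with columns `parameter`, `time_h`, `prcc`,
#'   `statistic`, `p_value`, `n`.
#' @export
setGeneric("prccTable", function(object) standardGeneric("prccTable"))
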