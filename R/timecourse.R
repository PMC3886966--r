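#' Build a TimecourseExperiment from long-format observations
#'
#' @param observations data.frame with columns `animal_id`, `maternal`,
#'   `diet`, `time_h`, `gene`, `value` (one row per animal x gene
#'   measurement; each animal is sampled at a single clock hour).
#' @return a validated [TimecourseExperiment-class].
#' @export
#' @examples
#' obs <- data.frame(animal_id = c("a1", "a2"), maternal = "lean",
#'                   diet = "control", time_h = c(6, 10),
#'                   gene = "PPARA", value = c(1.0, 1.4))
#' TimecourseExperiment(obs)
TimecourseExperiment <- function(observations) {
    obs <- .checkObservations(observations)
    animals <- unique(obs[, c("animal_id", "maternal", "diet", "time_h")])
    if (anyDuplicated(animals$animal_id))
        stop("animal_id maps to more than one (maternal, diet, time_h) combination")
    genes <- sort(unique(obs$gene))
    mat <- matrix(NA_real_, nrow = length(genes), ncol = nrow(animals),
                  dimnames = list(genes, animals$animal_id))
    idx <- cbind(match(obs$gene, genes), match(obs$animal_id, animals$animal_id))
    if (anyDuplicated(idx))
        stop("duplicate (animal_id, gene) observation")
    mat[idx] <- obs$value
    cd <- S4Vectors::DataFrame(
        animal_id = animals$animal_id,
        maternal = factor(animals$maternal, levels = .MATERNAL_LEVELS),
        diet = factor(animals$diet, levels = .DIET_LEVELS),
        time_h = animals$time_h,
        row.names = animals$animal_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(relexpr = mat), colData = cd)
    methods::new("TimecourseExperiment", se)
}

.checkObservations <- function(obs) {
    need <- c("animal_id", "maternal", "diet", "time_h", "gene", "value")
    miss <- setdiff(need, colnames(obs))
    if (length(miss) > 0)
        stop("missing column(s): ", paste(miss, collapse = ", "))
    obs <- as.data.frame(obs)[, need]
    obs$animal_id <- as.character(obs$animal_id)
    obs$gene <- as.character(obs$gene)
    tt <- suppressWarnings(as.numeric(obs$time_h))
    bad <- which(is.na(tt) | tt < 0 | tt >= 24)
    if (length(bad) > 0)
        stop(sprintf("row %d: time_h '%s' is not a clock hour in [0, 24)",
                     bad[1], as.character(obs$time_h)[bad[1]]))
    obs$time_h <- tt
    vv <- suppressWarnings(as.numeric(obs$value))
    bad <- which(is.na(vv) | vv < 0)
    if (length(bad) > 0)
        stop(sprintf("row %d: value '%s' is not a non-negative number",
                     bad[1], as.character(obs$value)[bad[1]]))
    obs$value <- vv
    badm <- which(!obs$maternal %in% .MATERNAL_LEVELS)
    if (length(badm) > 0)
        stop(sprintf("row %d: maternal '%s' not in {lean, obese}",
                     badm[1], obs$maternal[badm[1]]))
    badd <- which(!obs$diet %in% .DIET_LEVELS)
    if (length(badd) > 0)
        stop(sprintf("row %d: diet '%s' not in {control, HFD}",
                     badd[1], obs$diet[badd[1]]))
    obs
}

#' Read a circadian timecourse table
#'
#' Expects a UTF-8 delimited file with header columns `animal_id`,
#' `maternal`, `diet`, `time_h`, `gene`, `value`. Negative values and
#' malformed clock times are rejected with the offending row number.
#'
#' @param path file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a [TimecourseExperiment-class].
#' @export
readTimecourse <- function(path, dialect = c("csv", "tsv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (dialect == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, colClasses = "character",
                            fileEncoding = "UTF-8")
    TimecourseExperiment(df)
}

#' Write a timecourse back to its long tabular form
#'
#' Round-trips with [readTimecourse()] record-for-record (missing gene x
#' animal cells are omitted).
#'
#' @param x a [TimecourseExperiment-class].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeTimecourse <- function(x, path, dialect = c("csv", "tsv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "csv") "," else "\t"
    df <- asObservations(x)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Long-format view of a TimecourseExperiment
#'
#' @param x a [TimecourseExperiment-class].
#' @return data.frame with one row per observed (animal, gene) value.
#' @export
asObservations <- function(x) {
    stopifnot(methods::is(x, "TimecourseExperiment"))
    m <- SummarizedExperiment::assay(x, "relexpr")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    idx <- which(!is.na(m), arr.ind = TRUE)
    df <- data.frame(
        animal_id = cd$animal_id[idx[, 2]],
        maternal = as.character(cd$maternal)[idx[, 2]],
        diet = as.character(cd$diet)[idx[, 2]],
        time_h = cd$time_h[idx[, 2]],
        gene = rownames(m)[idx[, 1]],
        value = m[idx],
        stringsAsFactors = FALSE)
    df <- df[order(df$gene, df$maternal, df$diet, df$time_h, df$animal_id), ]
    rownames(df) <- NULL
    df
}

#' @describeIn designTable counts per factorial cell; with `gene`,
#'   non-missing observations of that gene.
#' @export
setMethod("designTable", "TimecourseExperiment", function(x, gene = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- rep(TRUE, nrow(cd))
    if (!is.null(gene)) {
        if (!gene %in% rownames(x)) stop("gene not present: ", gene)
        keep <- !is.na(SummarizedExperiment::assay(x, "relexpr")[gene, ])
    }
    cd <- cd[keep, , drop = FALSE]
    agg <- stats::aggregate(list(n = rep(1L, nrow(cd))),
                            by = list(maternal = as.character(cd$maternal),
                                      diet = as.character(cd$diet),
                                      time_h = cd$time_h),
                            FUN = sum)
    agg <- agg[order(agg$maternal, agg$diet, agg$time_h), ]
    rownames(agg) <- NULL
    agg
})

#' @describeIn groupMeans arithmetic mean and sample-SD/sqrt(n) SEM per
#'   clock hour within each (maternal, diet) group; times sorted ascending
#'   in `[0, 24)`. Cells with a single animal get SEM 0 and a warning.
#' @export
setMethod("groupMeans", "TimecourseExperiment", function(x, gene, ...) {
    if (!gene %in% rownames(x)) stop("gene not present: ", gene)
    vals <- SummarizedExperiment::assay(x, "relexpr")[gene, ]
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- !is.na(vals)
    cd <- cd[keep, , drop = FALSE]
    v <- vals[keep]
    out <- list()
    for (mm in .MATERNAL_LEVELS) for (dd in .DIET_LEVELS) {
        sel <- cd$maternal == mm & cd$diet == dd
        if (!any(sel)) next
        tt <- sort(unique(cd$time_h[sel]))
        means <- sems <- numeric(length(tt))
        ns <- integer(length(tt))
        for (i in seq_along(tt)) {
            xi <- v[sel & cd$time_h == tt[i]]
            ns[i] <- length(xi)
            means[i] <- mean(xi)
            sems[i] <- if (ns[i] > 1) stats::sd(xi) / sqrt(ns[i]) else 0
        }
        if (any(ns == 1))
            warning(sprintf("%s/%s/%s: %d cell(s) with n = 1 (SEM reported as 0)",
                            gene, mm, dd, sum(ns == 1)))
        out[[paste(mm, dd, sep = ".")]] <-
            methods::new("GroupMeanCurve", gene = gene, maternal = mm,
                         diet = dd, times = tt, means = means, sems = sems,
                         ns = ns)
    }
    out
})

#' @export
setMethod("show", "TimecourseExperiment", function(object) {
    methods::callNextMethod()
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("clock hours: %s\n",
                paste(sort(unique(cd$time_h)), collapse = ", ")))
    cat(sprintf("groups: %s\n",
                paste(sort(unique(paste(cd$maternal, cd$diet, sep = "."))),
                      collapse = ", ")))
})

#' @export
setMethod("show", "GroupMeanCurve", function(object) {
    cat(sprintf("GroupMeanCurve: %s [%s, %s], %d timepoints\n",
                object@gene, object@maternal, object@diet,
                length(object@times)))
    print(data.frame(time_h = object@times, mean = object@means,
                     sem = object@sems, n = object@ns))
})

#' Write group-mean curves as a delimited table
#'
#' @param curves list of [GroupMeanCurve-class] (as from [groupMeans()]).
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeGroupMeans <- function(curves, path, dialect = c("csv", "tsv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "csv") "," else "\t"
    rows <- lapply(curves, function(cv)
        data.frame(gene = cv@gene, maternal = cv@maternal, diet = cv@diet,
                   time_h = cv@times, mean = cv@means, sem = cv@sems,
                   n = cv@ns))
    utils::write.table(do.call(rbind, rows), path, sep = sep,
                       row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
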