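#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template quantity:
#' `Ct = intercept + slope * log10(quantity)`. A slope of -3.32 corresponds
#' to an amplification efficiency of ~1 (doubling per cycle).
#'
#' @param log10Quantity numeric log10 template quantities (>= 3 distinct).
#' @param ct observed cycle thresholds, same length.
#' @param gene amplicon label.
#' @return a [StandardCurve-class].
#' @export
#' @examples
#' fitStandardCurve(c(0, 1, 2), c(30, 26.68, 23.36))
fitStandardCurve <- function(log10Quantity, ct, gene = "unknown") {
    stopifnot(length(log10Quantity) == length(ct))
    if (length(unique(log10Quantity)) < 3)
        stop("standard curve needs >= 3 distinct quantities")
    if (stats::var(log10Quantity) == 0)
        stop("zero variance in log10 quantity")
    fit <- stats::lm(ct ~ log10Quantity)
    co <- stats::coef(fit)
    # direct r2 (summary.lm warns on exactly collinear standards)
    sst <- sum((ct - mean(ct))^2)
    r2 <- if (sst == 0) 1 else
        min(max(1 - sum(stats::residuals(fit)^2) / sst, 0), 1)
    methods::new("StandardCurve", gene = gene,
                 intercept = unname(co[1]), slope = unname(co[2]),
                 r2 = r2)
}

#' @describeIn efficiency efficiency from the fitted slope.
#' @export
setMethod("efficiency", "StandardCurve", function(object)
    10^(-1 / object@slope) - 1)

#' @export
setMethod("show", "StandardCurve", function(object) {
    cat(sprintf(
        "StandardCurve: %s  Ct = %.3f %+.3f * log10(q)  (r2 = %.4f, E = %.1f%%)\n",
        object@gene, object@intercept, object@slope, object@r2,
        100 * efficiency(object)))
})

#' Interpolate template quantity from a Ct value
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept)/slope)`;
#' strictly decreasing in Ct for an amplifying (negative-slope) curve.
#'
#' @param ct cycle threshold(s).
#' @param curve a [StandardCurve-class].
#' @return relative template quantity (unit quantity at `ct == intercept`).
#' @export
relativeQuantity <- function(ct, curve) {
    stopifnot(methods::is(curve, "StandardCurve"))
    methods::validObject(curve)
    10^((ct - curve@intercept) / curve@slope)
}

#' Normalize target quantity to a reference gene
#'
#' Relative expression is the target quantity divided element-wise by the
#' reference-gene quantity of the same sample (SRP14 in the emulated assay).
#'
#' @param targetQ target-gene quantities.
#' @param refQ reference-gene quantities (> 0), recycled if scalar.
#' @return relative expression `targetQ / refQ`.
#' @export
normalizeToReference <- function(targetQ, refQ) {
    if (any(refQ <= 0)) stop("reference quantity must be > 0")
    targetQ / refQ
}

#' ChIP-qPCR enrichment as percent of input
#'
#' The input Ct is first adjusted for the input dilution
#' (`ct_input - log2(input_fraction)` = Ct the full input would have given),
#' then enrichment is `100 * 2^(ct_input_adjusted - ct_ip)`. Adding a
#' constant to both Ct values leaves the result unchanged.
#'
#' @param ctIp IP cycle threshold(s), in (0, 45).
#' @param ctInput input cycle threshold(s), in (0, 45).
#' @param inputFraction fraction of chromatin used as input, in (0, 1];
#'   default 0.01 (1% input).
#' @return enrichment in percent of input (non-negative).
#' @export
#' @examples
#' percentInput(25, 25, inputFraction = 1)   # 100
#' percentInput(26, 25, inputFraction = 1)   # 50
percentInput <- function(ctIp, ctInput, inputFraction = 0.01) {
    if (any(inputFraction <= 0 | inputFraction > 1))
        stop("inputFraction must lie in (0, 1]")
    if (any(c(ctIp, ctInput) <= 0) || any(c(ctIp, ctInput) >= 45))
        stop("Ct values must lie in (0, 45)")
    ctInputAdj <- ctInput - log2(inputFraction)
    100 * 2^(ctInputAdj - ctIp)
}

#' Fold enrichment of a specific antibody over matched IgG
#'
#' Secondary ChIP statistic: ratio of percent-input enrichments.
#'
#' @param percentSpecific percent-input of the specific antibody.
#' @param percentIgG percent-input of the matched IgG control (> 0).
#' @return fold enrichment over IgG.
#' @export
foldOverIgG <- function(percentSpecific, percentIgG) {
    if (any(percentIgG <= 0)) stop("IgG enrichment must be > 0")
    percentSpecific / percentIgG
}

#' Read a raw Ct table
#'
#' CSV with columns `sample_id`, `target` (gene or region), `role` (one of
#' `target`, `reference`, `standard`, `ip`, `input`, `igg`), `ct`, and
#' optionally `log10_quantity` (standards) and `input_fraction` (ChIP rows).
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
readCtTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "target", "role", "ct")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0)
        stop("missing column(s): ", paste(miss, collapse = ", "))
    ok <- c("target", "reference", "standard", "ip", "input", "igg")
    bad <- which(!df$role %in% ok)
    if (length(bad) > 0)
        stop(sprintf("row %d: unknown role '%s'", bad[1], df$role[bad[1]]))
    df$ct <- as.numeric(df$ct)
    if (anyNA(df$ct)) stop("non-numeric ct value")
    df
}

#' Quantify a Ct table against its standards
#'
#' Fits one standard curve per target from the `standard` rows, converts
#' `target`/`reference` rows to quantities, and normalizes each sample's
#' targets to its reference-gene quantity.
#'
#' @param ct data.frame as returned by [readCtTable()].
#' @param referenceGene the reference gene symbol (default `"SRP14"`).
#' @return data.frame with columns `sample_id`, `target`, `quantity`,
#'   `rel_expr`.
#' @export
quantifyCtTable <- function(ct, referenceGene = "SRP14") {
    std <- ct[ct$role == "standard", , drop = FALSE]
    if (nrow(std) == 0) stop("no standard rows")
    if (!"log10_quantity" %in% colnames(std))
        stop("standards need a log10_quantity column")
    curves <- lapply(split(std, std$target), function(s)
        fitStandardCurve(as.numeric(s$log10_quantity), s$ct, gene = s$target[1]))
    meas <- ct[ct$role %in% c("target", "reference"), , drop = FALSE]
    unk <- setdiff(unique(meas$target), names(curves))
    if (length(unk) > 0)
        stop("no standard curve for: ", paste(unk, collapse = ", "))
    meas$quantity <- vapply(seq_len(nrow(meas)), function(i)
        relativeQuantity(meas$ct[i], curves[[meas$target[i]]]), numeric(1))
    refs <- meas[meas$target == referenceGene, c("sample_id", "quantity")]
    if (nrow(refs) == 0) stop("reference gene absent: ", referenceGene)
    out <- meas[meas$role == "target", , drop = FALSE]
    refQ <- refs$quantity[match(out$sample_id, refs$sample_id)]
    if (anyNA(refQ)) stop("sample(s) lack a reference-gene measurement")
    out$rel_expr <- normalizeToReference(out$quantity, refQ)
    rownames(out) <- NULL
    out[, c("sample_id", "target", "quantity", "rel_expr")]
}
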