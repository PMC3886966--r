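#' Trapezoidal area under a 24-h expression curve
#'
#' Clock hours are unwrapped from the 6AM anchor (so a 2AM sample becomes
#' hour 26) and must be distinct. With `closure = "periodic"` the first
#' point is re-appended one period later so the integral spans a full
#' 24 h; `"open"` integrates only the observed span.
#'
#' @param times clock hours in `[0, 24)` (any order; duplicates are an
#'   error), or already-unwrapped hours if `unwrap = FALSE`.
#' @param values expression values matching `times`.
#' @param closure `"periodic"` (default) or `"open"`.
#' @param unwrap unwrap from the 6AM anchor first (default TRUE).
#' @return area in expression x hours.
#' @export
#' @examples
#' trapezoidAuc(c(6, 10, 14, 18, 22, 2), c(1, 2, 3, 2, 1, 0.5))  # 38
trapezoidAuc <- function(times, values, closure = c("periodic", "open"),
                         unwrap = TRUE) {
    closure <- match.arg(closure)
    stopifnot(length(times) == length(values), length(times) >= 2)
    tu <- if (unwrap) unwrapTimes(times) else times
    if (anyDuplicated(tu)) stop("duplicate times")
    o <- order(tu)
    tu <- tu[o]; vv <- values[o]
    if (closure == "periodic") {
        tu <- c(tu, tu[1] + 24)
        vv <- c(vv, vv[1])
    }
    sum(diff(tu) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

# trapezoid weight of each (sorted, unwrapped) timepoint
.trapWeights <- function(tu, closure) {
    k <- length(tu)
    if (closure == "periodic") {
        tt <- c(tu, tu[1] + 24)
        w <- numeric(k)
        for (i in seq_len(k)) {
            left <- if (i == 1) tt[k + 1] - tt[k] else tt[i] - tt[i - 1]
            right <- tt[i + 1] - tt[i]
            w[i] <- (left + right) / 2
        }
        w
    } else {
        w <- numeric(k)
        w[1] <- (tu[2] - tu[1]) / 2
        w[k] <- (tu[k] - tu[k - 1]) / 2
        if (k > 2)
            w[2:(k - 1)] <- (tu[3:k] - tu[1:(k - 2)]) / 2
        w
    }
}

#' AUC of a group-mean curve with a delta-method standard error
#'
#' The AUC is computed on the per-time means; because sampling is
#' cross-sectional the timepoint means are independent, so
#' `se_auc = sqrt(sum(w_i^2 * sem_i^2))` with `w_i` the trapezoid weight
#' of timepoint i (the first point carries the closure segment's weight
#' under periodic closure). Curves with fewer than 4 distinct times are
#' refused; cells with n = 1 make the SE unavailable (NA).
#'
#' @param curve a [GroupMeanCurve-class].
#' @param closure `"periodic"` (default) or `"open"`.
#' @return one-row data.frame: `gene`, `maternal`, `diet`, `auc`,
#'   `se_auc`, `closure`.
#' @export
aucWithError <- function(curve, closure = c("periodic", "open")) {
    closure <- match.arg(closure)
    stopifnot(methods::is(curve, "GroupMeanCurve"))
    if (length(unique(curve@times)) < 4)
        stop("AUC refused: fewer than 4 distinct times")
    tu <- unwrapTimes(curve@times)
    o <- order(tu)
    w <- .trapWeights(tu[o], closure)
    auc <- sum(w * curve@means[o])
    se <- if (any(curve@ns == 1)) NA_real_
          else sqrt(sum(w^2 * curve@sems[o]^2))
    data.frame(gene = curve@gene, maternal = curve@maternal,
               diet = curve@diet, auc = auc, se_auc = se, closure = closure,
               stringsAsFactors = FALSE)
}

#' Lean-vs-obese t-test at one clock hour
#'
#' Two-sample, two-tailed Student's t with pooled variance comparing
#' offspring of lean vs obese dams on the same post-weaning diet at one
#' timepoint.
#'
#' @param x a [TimecourseExperiment-class].
#' @param gene gene symbol.
#' @param timeH clock hour.
#' @param diet `"control"` or `"HFD"`.
#' @return data.frame with `t`, `df`, `p_value`, `significant`
#'   (p < 0.05), and the group means.
#' @export
timepointTTest <- function(x, gene, timeH, diet = c("control", "HFD")) {
    diet <- match.arg(diet)
    if (!gene %in% rownames(x)) stop("gene not present: ", gene)
    v <- SummarizedExperiment::assay(x, "relexpr")[gene, ]
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    pick <- function(mm) {
        vi <- v[cd$maternal == mm & cd$diet == diet & cd$time_h == timeH]
        vi[!is.na(vi)]
    }
    a <- pick("lean"); b <- pick("obese")
    if (length(a) < 2 || length(b) < 2)
        stop("both cells need n >= 2")
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(gene = gene, time_h = timeH, diet = diet,
               mean_lean = mean(a), mean_obese = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, significant = tt$p.value < 0.05)
}

#' Two-way factorial ANOVA with SNK follow-up
#'
#' Fixed-effects 2 x 2 ANOVA of maternal phenotype x post-weaning diet
#' (Type II sums of squares, robust to unbalanced cells). When the
#' interaction is significant (p < 0.05), a one-way ANOVA across the four
#' groups is followed by all pairwise Student-Newman-Keuls comparisons
#' and letter groupings (groups sharing a letter do not differ at
#' alpha = 0.05).
#'
#' @param value numeric response.
#' @param maternal,diet factors of matching length (levels `lean`/`obese`
#'   and `control`/`HFD`).
#' @return list with `effects` (data.frame: effect, df, F, p_value) and
#'   `posthoc` (data.frame: group, mean, n, letters; NULL when the
#'   interaction is not significant).
#' @export
twoWayAnova <- function(value, maternal, diet) {
    maternal <- factor(as.character(maternal), levels = .MATERNAL_LEVELS)
    diet <- factor(as.character(diet), levels = .DIET_LEVELS)
    stopifnot(length(value) == length(maternal),
              length(value) == length(diet))
    cellN <- table(maternal, diet)
    if (any(cellN == 0)) stop("empty design cell")
    if (any(cellN < 2)) stop("each cell needs >= 2 replicates")
    dat <- data.frame(value = value, maternal = maternal, diet = diet)
    fit <- stats::lm(value ~ maternal * diet, data = dat)
    a2 <- car::Anova(fit, type = 2)
    rows <- c("maternal", "diet", "maternal:diet")
    eff <- data.frame(
        effect = c("maternal", "diet", "interaction"),
        df = a2[rows, "Df"],
        F = a2[rows, "F value"],
        p_value = a2[rows, "Pr(>F)"])
    posthoc <- NULL
    if (eff$p_value[eff$effect == "interaction"] < 0.05) {
        dat$group <- interaction(dat$maternal, dat$diet, sep = ".")
        ow <- stats::aov(value ~ group, data = dat)
        ms <- stats::anova(ow)
        mse <- ms["Residuals", "Mean Sq"]
        dfe <- ms["Residuals", "Df"]
        means <- tapply(dat$value, dat$group, mean)
        ns <- tapply(dat$value, dat$group, length)
        posthoc <- snkPosthoc(means, mse, dfe, ns)
    }
    list(effects = eff, posthoc = posthoc)
}

#' Student-Newman-Keuls letter groupings
#'
#' Means are ordered and ranges tested sequentially against studentized
#' range critical values whose span matches the number of means in the
#' range (`qtukey(1 - alpha, r, df)`): a non-significant range declares
#' all means inside it homogeneous and is not subdivided; a significant
#' range is subdivided from both ends. Groups sharing a letter are not
#' significantly different. Unequal n is handled with the harmonic mean
#' of the pair being compared.
#'
#' @param means named vector of group means.
#' @param mse error mean square of the one-way context.
#' @param df error degrees of freedom (> 0).
#' @param ns per-group replicate counts (recycled if scalar).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `group`, `mean`, `n`, `letters`, sorted by
#'   descending mean.
#' @export
snkPosthoc <- function(means, mse, df, ns, alpha = 0.05) {
    if (df <= 0) stop("df must be > 0")
    k <- length(means)
    if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
    ns <- rep(ns, length.out = k)
    o <- order(means)
    m <- means[o]; nn <- ns[o]
    sig <- function(i, j) {       # is the range i..j significant?
        r <- j - i + 1
        nh <- 2 / (1 / nn[i] + 1 / nn[j])
        q <- (m[j] - m[i]) / sqrt(mse / nh)
        q > stats::qtukey(1 - alpha, r, df)
    }
    # SNK stepdown: collect maximal homogeneous (non-subdivided) ranges
    homog <- list()
    covered <- function(i, j) any(vapply(homog, function(h)
        h[1] <= i && j <= h[2], logical(1)))
    for (span in (if (k >= 2) seq(k, 2) else integer(0))) {
        for (i in seq_len(k - span + 1)) {
            j <- i + span - 1
            if (covered(i, j)) next
            if (!sig(i, j)) homog[[length(homog) + 1]] <- c(i, j)
        }
    }
    letters <- rep("", k)
    li <- 0
    for (h in homog) {
        li <- li + 1
        idx <- h[1]:h[2]
        letters[idx] <- paste0(letters[idx], base::letters[li])
    }
    for (i in seq_len(k)) if (letters[i] == "") {
        li <- li + 1
        letters[i] <- base::letters[li]
    }
    out <- data.frame(group = names(m), mean = unname(m), n = nn,
                      letters = letters, stringsAsFactors = FALSE)
    out <- out[order(-out$mean), ]
    rownames(out) <- NULL
    out
}

#' Z-contrasts between group AUCs
#'
#' Replicate-level AUCs do not exist in a cross-sectional design, so
#' group AUC comparisons use normal-theory contrasts on the
#' delta-method (auc, se) pairs: the two main effects and the
#' interaction contrast `(HFD effect in obese) - (HFD effect in lean)`.
#'
#' @param aucs data.frame from rbind-ing [aucWithError()] rows for the
#'   four groups of one gene.
#' @return data.frame: `effect`, `estimate`, `se`, `z`, `p_value`.
#' @export
aucContrasts <- function(aucs) {
    need <- expand.grid(maternal = .MATERNAL_LEVELS, diet = .DIET_LEVELS,
                        stringsAsFactors = FALSE)
    key <- paste(aucs$maternal, aucs$diet, sep = ".")
    rownames(aucs) <- key
    missing <- setdiff(paste(need$maternal, need$diet, sep = "."), key)
    if (length(missing) > 0)
        stop("missing group(s): ", paste(missing, collapse = ", "))
    if (anyNA(aucs$se_auc)) stop("SE unavailable for some group")
    contrast <- function(effect, w) {
        est <- sum(w * aucs[names(w), "auc"])
        se <- sqrt(sum(w^2 * aucs[names(w), "se_auc"]^2))
        z <- est / se
        data.frame(effect = effect, estimate = est, se = se, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
    }
    g <- c("lean.control", "lean.HFD", "obese.control", "obese.HFD")
    rbind(
        contrast("maternal", stats::setNames(c(-0.5, -0.5, 0.5, 0.5), g)),
        contrast("diet", stats::setNames(c(-0.5, 0.5, -0.5, 0.5), g)),
        contrast("interaction", stats::setNames(c(1, -1, -1, 1), g)))
}

#' Per-gene AUC summary table
#'
#' One row per gene x group with the 24-h AUC +/- delta-method SE, plus
#' the Z-contrast p-values for the maternal, diet and interaction
#' effects.
#'
#' @param x a [TimecourseExperiment-class].
#' @param genes gene symbols (default: all genes).
#' @param closure `"periodic"` or `"open"`.
#' @return data.frame with columns `gene`, `maternal`, `diet`, `auc`,
#'   `se_auc`, `p_maternal`, `p_diet`, `p_interaction`.
#' @export
aucTable <- function(x, genes = rownames(x), closure = c("periodic", "open")) {
    closure <- match.arg(closure)
    out <- list()
    for (gene in genes) {
        curves <- suppressWarnings(groupMeans(x, gene))
        recs <- do.call(rbind, lapply(curves, aucWithError, closure = closure))
        ps <- if (nrow(recs) == 4 && !anyNA(recs$se_auc))
            aucContrasts(recs) else NULL
        recs$p_maternal <- if (is.null(ps)) NA_real_ else
            ps$p_value[ps$effect == "maternal"]
        recs$p_diet <- if (is.null(ps)) NA_real_ else
            ps$p_value[ps$effect == "diet"]
        recs$p_interaction <- if (is.null(ps)) NA_real_ else
            ps$p_value[ps$effect == "interaction"]
        out[[gene]] <- recs
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
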