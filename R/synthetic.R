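#' Build a cosinor generating specification
#'
#' @param gene gene symbol.
#' @param groups data.frame with columns `maternal`, `diet`, `mesor`,
#'   `amplitude`, `acrophase` (one row per group); default
#'   [cosinorGroups()] under the `"null"` scenario.
#' @param noiseCv multiplicative lognormal coefficient of variation
#'   (default 0.10, typical qPCR replicate scatter).
#' @param nPerCell animals per group per timepoint (default 4; the
#'   emulated design uses 3-5).
#' @return a [CosinorSpec-class].
#' @export
cosinorSpec <- function(gene = "BMAL1", groups = cosinorGroups("null"),
                        noiseCv = 0.10, nPerCell = 4) {
    methods::new("CosinorSpec", gene = gene, groups = groups,
                 noiseCv = noiseCv, nPerCell = as.integer(nPerCell))
}

#' Group-level cosinor parameters for the named effect scenarios
#'
#' * `null` — all four groups identical (mesor 1.5, amplitude 0.75,
#'   acrophase per gene class).
#' * `hfd_amplitude_loss` — both HFD groups lose half their amplitude.
#' * `interaction_obese_hfd` — only the obese-HFD group is affected
#'   (amplitude 0.75 -> 0.05, a near-arrhythmic deficit), the synthetic
#'   analogue of an interaction-driven amplitude loss; the effect size is
#'   calibrated so the 2x2 ANOVA at the peak hour has >= 80% power at
#'   n = 4/cell.
#'
#' @param scenario scenario name.
#' @param acrophase peak clock hour (default 10, the CLOCK/BMAL1 peak;
#'   use 18 for the antiphasic Per/Cry class).
#' @return data.frame usable as the `groups` slot of a
#'   [CosinorSpec-class].
#' @export
cosinorGroups <- function(scenario = c("null", "hfd_amplitude_loss",
                                       "interaction_obese_hfd"),
                          acrophase = 10) {
    scenario <- match.arg(scenario)
    g <- expand.grid(maternal = .MATERNAL_LEVELS, diet = .DIET_LEVELS,
                     stringsAsFactors = FALSE)
    g$mesor <- 1.5
    g$amplitude <- 0.75
    g$acrophase <- acrophase
    if (scenario == "hfd_amplitude_loss")
        g$amplitude[g$diet == "HFD"] <- 0.375
    if (scenario == "interaction_obese_hfd")
        g$amplitude[g$maternal == "obese" & g$diet == "HFD"] <- 0.05
    g
}

# lognormal factors with mean exactly 1 at the given CV
.lnNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cross-sectional timecourse
#'
#' Per (maternal, diet, time) cell, draws `nPerCell` animals with values
#' `cosinor_mean(t) * lognormal(cv)` (mean-one multiplicative noise).
#' Deterministic given the seed.
#'
#' @param spec a [CosinorSpec-class].
#' @param times sampled clock hours (default `c(6, 10, 14, 18, 22, 2)`:
#'   every 4 h across 24 h).
#' @param seed integer RNG seed.
#' @return a [TimecourseExperiment-class].
#' @export
synthDataset <- function(spec, times = c(6, 10, 14, 18, 22, 2), seed = 1) {
    stopifnot(methods::is(spec, "CosinorSpec"))
    methods::validObject(spec)
    g <- spec@groups
    rows <- .withSeed(seed, {
        out <- list()
        aid <- 0L
        for (r in seq_len(nrow(g))) for (tt in times) {
            mu <- g$mesor[r] +
                g$amplitude[r] * cos(2 * pi * (tt - g$acrophase[r]) / 24)
            vals <- mu * .lnNoise(spec@nPerCell, spec@noiseCv)
            ids <- sprintf("%s_%s_t%02d_%d", substr(g$maternal[r], 1, 1),
                           substr(g$diet[r], 1, 1), as.integer(tt),
                           aid + seq_len(spec@nPerCell))
            aid <- aid + spec@nPerCell
            out[[length(out) + 1]] <- data.frame(
                animal_id = ids, maternal = g$maternal[r], diet = g$diet[r],
                time_h = tt, gene = spec@gene, value = vals,
                stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
    TimecourseExperiment(rows)
}

#' Ground-truth model parameters for the named model scenarios
#'
#' * `stepwise_degradation` — the four groups share `v0 = 0.05`,
#'   `Kp = 1`, `n = 2`, `vd = 0.05`, `Kd = 0.3`; `vp` is 0.6 in lean and
#'   0.42 in obese groups (reduced maximum synthesis under maternal
#'   obesity) and `deltaP` ascends 0.15 < 0.20 < 0.25 < 0.35 across
#'   lean-control < lean-HFD < obese-control < obese-HFD (stepwise
#'   increase of non-specific degradation). The truth was chosen for
#'   identifiability: small basal synthesis and a minor saturable
#'   clearance term keep `deltaP` the dominant state-dependent loss.
#' * `identical_groups` — all four groups share [pparParams()] defaults
#'   (exchangeability control).
#'
#' @param scenario scenario name.
#' @return named list of [PparModelParams-class], one per group
#'   (`lean.control`, `lean.HFD`, `obese.control`, `obese.HFD`).
#' @export
pparScenario <- function(scenario = c("stepwise_degradation",
                                      "identical_groups")) {
    scenario <- match.arg(scenario)
    keys <- c("lean.control", "lean.HFD", "obese.control", "obese.HFD")
    if (scenario == "identical_groups") {
        out <- rep(list(pparParams()), 4)
        names(out) <- keys
        return(out)
    }
    vp <- c(0.6, 0.6, 0.42, 0.42)
    dp <- c(0.15, 0.20, 0.25, 0.35)
    out <- lapply(seq_len(4), function(i)
        pparParams(v0 = 0.05, vp = vp[i], Kp = 1, n = 2, vd = 0.05,
                   Kd = 0.3, deltaP = dp[i], x0 = 1))
    names(out) <- keys
    out
}

#' Generate model-driven group timecourses with known truth
#'
#' Simulates each group's entrained periodic solution under the given
#' forcing, samples it at the six clock hours with mean-one lognormal
#' noise on each animal, and returns both the dataset and the generating
#' parameter table for closed-loop recovery tests.
#'
#' @param scenario scenario name passed to [pparScenario()], or a named
#'   list of [PparModelParams-class] (names `maternal.diet`).
#' @param forcing a [ClockForcing-class] (default [cosinorForcing()]).
#' @param times sampled clock hours.
#' @param noiseCv lognormal CV per animal (default 0.05).
#' @param nPerCell animals per cell (default 4).
#' @param seed integer RNG seed.
#' @return list with `experiment` (a [TimecourseExperiment-class], gene
#'   `PPARA`) and `truth` (data.frame of the generating parameters).
#' @export
synthPparGroups <- function(scenario = "stepwise_degradation",
                            forcing = cosinorForcing(),
                            times = c(6, 10, 14, 18, 22, 2),
                            noiseCv = 0.05, nPerCell = 4, seed = 1) {
    pars <- if (is.character(scenario)) pparScenario(scenario) else scenario
    stopifnot(is.list(pars), !is.null(names(pars)))
    tu <- unwrapTimes(times)
    rows <- list()
    truth <- list()
    k <- 0L
    draws <- .withSeed(seed, {
        lapply(pars, function(p) .lnNoise(nPerCell * length(times), noiseCv))
    })
    for (key in names(pars)) {
        p <- pars[[key]]
        md <- strsplit(key, ".", fixed = TRUE)[[1]]
        tr <- periodicSolution(p, forcing, dt = 0.25)
        mu <- stats::approx(tr@times, tr@values, xout = tu)$y
        noise <- draws[[key]]
        for (i in seq_along(times)) {
            vals <- mu[i] * noise[(i - 1) * nPerCell + seq_len(nPerCell)]
            k <- k + nPerCell
            rows[[length(rows) + 1]] <- data.frame(
                animal_id = sprintf("%s_t%02d_%d", key,
                                    as.integer(times[i]),
                                    k - nPerCell + seq_len(nPerCell)),
                maternal = md[1], diet = md[2], time_h = times[i],
                gene = "PPARA", value = vals, stringsAsFactors = FALSE)
        }
        truth[[key]] <- cbind(data.frame(maternal = md[1], diet = md[2]),
                              as.data.frame(t(as.numeric(p))))
    }
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    list(experiment = TimecourseExperiment(do.call(rbind, rows)),
         truth = truthDf)
}

#' Default ChIP-qPCR generating targets
#'
#' Percent-input targets per (maternal, diet, antibody, region, time)
#' emulating the assayed pattern: the activating mark high at 6AM and low
#' at 6PM in control-fed groups but flattened under HFD; the repressive
#' mark elevated in the obese-HFD group at 6PM (an interaction); IgG flat
#' and far below both specific marks.
#'
#' @return data.frame with columns `maternal`, `diet`, `antibody`,
#'   `region`, `time_h`, `percent_input`.
#' @export
defaultChipSpec <- function() {
    g <- expand.grid(maternal = .MATERNAL_LEVELS, diet = .DIET_LEVELS,
                     antibody = c("H3K4me3", "H3K27me3", "IgG"),
                     region = c("upstream_500", "downstream_500"),
                     time_h = c(6, 18), stringsAsFactors = FALSE)
    pct <- numeric(nrow(g))
    for (i in seq_len(nrow(g))) {
        if (g$antibody[i] == "IgG") { pct[i] <- 0.05; next }
        if (g$antibody[i] == "H3K4me3") {
            pct[i] <- if (g$diet[i] == "control")
                (if (g$time_h[i] == 6) 2.0 else 0.8) else 1.2
        } else {  # H3K27me3
            base <- if (g$time_h[i] == 6) 1.5 else 1.0
            pct[i] <- base
            if (g$diet[i] == "control") pct[i] <- 0.8
            if (g$maternal[i] == "obese" && g$diet[i] == "HFD" &&
                g$time_h[i] == 18) pct[i] <- 3.0
        }
    }
    g$percent_input <- pct
    g
}

#' Generate a synthetic ChIP-qPCR Ct table
#'
#' Inverts the percent-input formula: for each target enrichment, an
#' input Ct is drawn around `ctInputCenter` and the IP Ct is set to
#' `ct_input - log2(input_fraction) - log2(percent/100)`, then both Ct
#' values get independent Gaussian noise of `sdCt` cycles.
#' [percentInput()] applied to the output recovers the targets up to
#' that noise.
#'
#' @param spec data.frame as from [defaultChipSpec()] (`percent_input`
#'   > 0 required).
#' @param nRep technical replicates per row (default 3, run-in-triplicate
#'   convention).
#' @param inputFraction chromatin input fraction (default 0.01).
#' @param sdCt Gaussian Ct noise in cycles (default 0.15).
#' @param ctInputCenter centre of the input Ct distribution (default 24,
#'   leaving IgG IP wells below the 45-cycle detection ceiling).
#' @param seed integer RNG seed.
#' @return data.frame with columns of `spec` plus `rep`, `ct_ip`,
#'   `ct_input`, `input_fraction`.
#' @export
synthChip <- function(spec = defaultChipSpec(), nRep = 3,
                      inputFraction = 0.01, sdCt = 0.15,
                      ctInputCenter = 24, seed = 1) {
    stopifnot(all(spec$percent_input > 0))
    igg <- spec$percent_input[spec$antibody == "IgG"]
    specific <- spec$percent_input[spec$antibody != "IgG"]
    if (length(igg) > 0 && length(specific) > 0 &&
        max(igg) >= min(specific))
        stop("IgG targets must lie below all specific-antibody targets")
    .withSeed(seed, {
        out <- spec[rep(seq_len(nrow(spec)), each = nRep), , drop = FALSE]
        out$rep <- rep(seq_len(nRep), nrow(spec))
        ctIn <- ctInputCenter + stats::rnorm(nrow(out), 0, sdCt)
        ctIpExact <- ctIn - log2(inputFraction) -
            log2(out$percent_input / 100)
        out$ct_ip <- ctIpExact + stats::rnorm(nrow(out), 0, sdCt)
        out$ct_input <- ctIn
        out$input_fraction <- inputFraction
        rownames(out) <- NULL
        out
    })
}
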