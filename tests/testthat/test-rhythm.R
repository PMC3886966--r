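# independent SNK recursion: tests every sub-range reachable through
# significant parents and collects homogeneous blocks
snkOracle <- function(means, mse, df, ns, alpha = 0.05) {
    o <- order(means)
    m <- means[o]; nn <- rep(ns, length.out = length(means))[o]
    k <- length(m)
    blocks <- list()
    recurse <- function(i, j) {
        if (j <= i) return()
        nh <- 2 / (1 / nn[i] + 1 / nn[j])
        q <- (m[j] - m[i]) / sqrt(mse / nh)
        if (q <= stats::qtukey(1 - alpha, j - i + 1, df)) {
            blocks[[length(blocks) + 1]] <<- c(i, j)
        } else {
            recurse(i, j - 1)
            recurse(i + 1, j)
        }
    }
    recurse(1, k)
    # maximal blocks only
    keep <- Filter(function(b) !any(vapply(blocks, function(h)
        (h[1] < b[1] && b[2] <= h[2]) || (h[1] <= b[1] && b[2] < h[2]),
        logical(1))), blocks)
    keep <- unique(keep)
    # pair i<j homogeneous iff inside some kept block
    same <- matrix(FALSE, k, k)
    for (b in keep) same[b[1]:b[2], b[1]:b[2]] <- TRUE
    diag(same) <- TRUE
    dimnames(same) <- list(names(m), names(m))
    same
}

sameFromLetters <- function(ph) {
    k <- nrow(ph)
    same <- matrix(FALSE, k, k, dimnames = list(ph$group, ph$group))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        li <- strsplit(ph$letters[i], "")[[1]]
        lj <- strsplit(ph$letters[j], "")[[1]]
        same[i, j] <- length(intersect(li, lj)) > 0
    }
    diag(same) <- TRUE
    same
}

test_that("trapezoid AUC handles closure, anchors and hand-checked values", {
    # constant curve over a closed day is a rectangle
    expect_equal(trapezoidAuc(c(6, 10, 14, 18, 22, 2), rep(1, 6),
                              "periodic"), 24)
    # open triangle
    expect_equal(trapezoidAuc(c(0, 4), c(0, 2), "open", unwrap = FALSE), 4)
    # six-point curve: interior trapezoids 6+10+10+6+3 plus closure 3
    got <- trapezoidAuc(c(6, 10, 14, 18, 22, 2), c(1, 2, 3, 2, 1, 0.5),
                        "periodic")
    yy <- c(1, 2, 3, 2, 1, 0.5, 1)      # closure re-appends the first value
    handSum <- sum(4 * (yy[-7] + yy[-1]) / 2)
    expect_equal(handSum, 38)
    expect_equal(got, handSum, tolerance = 1e-12)
    # cross-check the open part against an established quadrature
    expect_equal(trapezoidAuc(c(6, 10, 14, 18, 22, 2), c(1, 2, 3, 2, 1, 0.5),
                              "open"),
                 pracma::trapz(c(6, 10, 14, 18, 22, 26),
                               c(1, 2, 3, 2, 1, 0.5)), tolerance = 1e-12)
    expect_error(trapezoidAuc(c(6, 6, 10), c(1, 1, 2)), "duplicate")
})

test_that("trapezoid AUC is exact, additive and scales linearly", {
    set.seed(21)
    tt <- sort(runif(7, 0, 23))
    yy <- runif(7, 0, 3)
    a <- trapezoidAuc(tt, yy, "open", unwrap = FALSE)
    # additivity over adjacent intervals
    a1 <- trapezoidAuc(tt[1:4], yy[1:4], "open", unwrap = FALSE)
    a2 <- trapezoidAuc(tt[4:7], yy[4:7], "open", unwrap = FALSE)
    expect_equal(a, a1 + a2, tolerance = 1e-12)
    # linear scaling
    expect_equal(trapezoidAuc(tt, 3.7 * yy, "open", unwrap = FALSE),
                 3.7 * a, tolerance = 1e-12)
    # exact on a piecewise-linear function densely resampled
    dense <- sort(c(tt, runif(40, min(tt), max(tt))))
    yd <- stats::approx(tt, yy, xout = dense)$y
    expect_equal(trapezoidAuc(dense, yd, "open", unwrap = FALSE), a,
                 tolerance = 1e-10)
})

test_that("AUC standard errors follow the delta method", {
    cv <- makeCurve(times = c(6, 10, 14, 18, 22, 2),
                    means = c(1, 2, 3, 2, 1, 0.5), sems = rep(0, 6))
    rec <- aucWithError(cv, "periodic")
    expect_equal(rec$auc, 38)
    expect_equal(rec$se_auc, 0)
    # a single nonzero sem at an interior 4-h-spaced point weighs in at 4
    cv2 <- makeCurve(times = c(6, 10, 14, 18, 22, 2),
                     means = rep(1, 6), sems = c(0, 0, 0.3, 0, 0, 0))
    expect_equal(aucWithError(cv2, "periodic")$se_auc, 4 * 0.3,
                 tolerance = 1e-12)
    # refusal cases
    cv3 <- makeCurve(times = c(6, 12, 18), means = rep(1, 3),
                     sems = rep(0.1, 3), ns = rep(4L, 3))
    expect_error(aucWithError(cv3), "fewer than 4")
    cv4 <- makeCurve(ns = c(4L, 1L, 4L, 4L, 4L, 4L))
    expect_true(is.na(aucWithError(cv4)$se_auc))
})

test_that("delta-method AUC error matches a resampling experiment", {
    mesor <- 1.5; amp <- 0.75; phi <- 10; cv <- 0.10; n <- 4
    tt <- c(6, 10, 14, 18, 22, 2)
    mu <- mesor + amp * cos(2 * pi * (tt - phi) / 24)
    trueSem <- mu * cv / sqrt(n)
    curve <- makeCurve(times = tt, means = mu, sems = trueSem)
    se <- aucWithError(curve, "periodic")$se_auc
    set.seed(4)
    s2 <- log(1 + cv^2)
    aucs <- replicate(1000, {
        mhat <- vapply(mu, function(m)
            mean(m * stats::rlnorm(n, -s2 / 2, sqrt(s2))), numeric(1))
        trapezoidAuc(tt, mhat, "periodic")
    })
    expect_lt(abs(stats::sd(aucs) - se) / se, 0.10)
})

test_that("pooled t on {1,2,3} vs {4,5,6} reproduces the textbook value", {
    obs <- data.frame(
        animal_id = paste0("a", 1:6),
        maternal = rep(c("lean", "obese"), each = 3),
        diet = "HFD", time_h = 14, gene = "G",
        value = c(1, 2, 3, 4, 5, 6))
    te <- TimecourseExperiment(obs)
    tt <- timepointTTest(te, "G", 14, "HFD")
    # hand computation: pooled s^2 = 1, se = sqrt(2/3), t = -3/se
    expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
    expect_equal(tt$df, 4)
    expect_equal(tt$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4),
                 tolerance = 1e-10)
    expect_true(tt$significant)
    # identical cells
    obs$value <- rep(c(1, 2, 3), 2)
    te2 <- TimecourseExperiment(obs)
    t2 <- timepointTTest(te2, "G", 14, "HFD")
    expect_equal(t2$t, 0)
    expect_equal(t2$p_value, 1)
    # insufficient replication
    expect_error(timepointTTest(te[, 1:4], "G", 14, "HFD"), "n >= 2")
})

test_that("two-way ANOVA agrees with hand-computed sums of squares", {
    set.seed(31)
    n <- 3
    g <- expand.grid(maternal = c("lean", "obese"), diet = c("control", "HFD"))
    mu <- c(1, 1.5, 2, 3.2)
    value <- unlist(lapply(seq_len(4), function(i) mu[i] + rnorm(n, 0, 0.3)))
    maternal <- rep(g$maternal, each = n)
    diet <- rep(g$diet, each = n)
    got <- twoWayAnova(value, maternal, diet)
    # balanced closed-form decomposition
    gm <- mean(value)
    mm <- tapply(value, maternal, mean)
    dm <- tapply(value, diet, mean)
    cm <- tapply(value, interaction(maternal, diet), mean)
    ssA <- 2 * n * sum((mm - gm)^2)
    ssB <- 2 * n * sum((dm - gm)^2)
    cellOf <- interaction(maternal, diet)
    ssE <- sum((value - cm[cellOf])^2)
    ssAB <- sum(n * (cm - rep(mm, 2) - rep(dm, each = 2) + gm)^2)
    dfe <- 4 * (n - 1)
    eff <- got$effects
    expect_equal(eff$F[eff$effect == "maternal"], (ssA / 1) / (ssE / dfe),
                 tolerance = 1e-10)
    expect_equal(eff$F[eff$effect == "diet"], (ssB / 1) / (ssE / dfe),
                 tolerance = 1e-10)
    expect_equal(eff$F[eff$effect == "interaction"], (ssAB / 1) / (ssE / dfe),
                 tolerance = 1e-10)
    expect_equal(eff$p_value,
                 stats::pf(eff$F, 1, dfe, lower.tail = FALSE),
                 tolerance = 1e-10)
})

test_that("purely additive cell means carry no interaction sum of squares", {
    n <- 3
    maternal <- rep(rep(c("lean", "obese"), each = n), 2)
    diet <- rep(c("control", "HFD"), each = 2 * n)
    # additive means + replicate offsets identical in every cell: the
    # interaction contrast is exactly zero
    base <- ifelse(maternal == "obese", 0.5, 0) + ifelse(diet == "HFD", 1, 0)
    value <- base + rep(c(-0.1, 0, 0.1), 4)
    fit <- stats::lm(value ~ factor(maternal) * factor(diet))
    ss <- stats::anova(fit)
    expect_lt(ss["factor(maternal):factor(diet)", "Sum Sq"], 1e-20)
})

test_that("ANOVA design errors are raised", {
    expect_error(twoWayAnova(1:6, rep("lean", 6),
                             rep(c("control", "HFD"), 3)), "empty design cell")
    expect_error(twoWayAnova(1:5,
                             c("lean", "lean", "obese", "obese", "lean"),
                             c("control", "HFD", "control", "HFD", "HFD")),
                 ">= 2 replicates")
})

test_that("type-I error of the timepoint test is calibrated", {
    set.seed(61)
    reps <- 2000
    rej <- 0L
    for (r in seq_len(reps)) {
        a <- rnorm(4); b <- rnorm(4)
        p <- stats::t.test(a, b, var.equal = TRUE)$p.value
        if (p < 0.05) rej <- rej + 1L
    }
    expect_lt(abs(rej / reps - 0.05), 0.015)
})

test_that("SNK letters match the brute-force recursion oracle", {
    cases <- list(
        list(means = c(g1 = 10, g2 = 10.1, g3 = 15, g4 = 20), mse = 1,
             df = 12, ns = 4),
        list(means = c(a = 1, b = 1.05, c = 1.1, d = 1.12), mse = 0.01,
             df = 12, ns = 4),
        list(means = c(a = 5, b = 5, c = 5, d = 5), mse = 1, df = 12, ns = 4),
        list(means = c(a = 0, b = 3, c = 6, d = 9), mse = 0.5, df = 8,
             ns = c(3, 4, 5, 4)))
    for (cs in cases) {
        ph <- snkPosthoc(cs$means, cs$mse, cs$df, cs$ns)
        sm <- sameFromLetters(ph)
        orc <- snkOracle(cs$means, cs$mse, cs$df, cs$ns)
        orc <- orc[rownames(sm), colnames(sm)]
        expect_identical(sm, orc)
    }
    # trivial outcomes
    allEq <- snkPosthoc(c(a = 2, b = 2, c = 2), 1, 10, 5)
    expect_true(all(allEq$letters == "a"))
    sep <- snkPosthoc(c(lo = 0, hi = 50), 1, 30, 10)
    expect_setequal(sep$letters, c("a", "b"))
    expect_error(snkPosthoc(c(a = 1, b = 2), 1, 0, 3), "df")
})

test_that("SNK letters are order-consistent on random instances", {
    set.seed(17)
    for (r in 1:25) {
        k <- sample(3:5, 1)
        means <- stats::setNames(sort(runif(k, 0, 5)), paste0("g", 1:k))
        ph <- snkPosthoc(means, mse = runif(1, 0.05, 2),
                         df = sample(6:20, 1), ns = sample(3:5, 1))
        ph <- ph[order(ph$mean), ]
        for (L in unique(unlist(strsplit(ph$letters, "")))) {
            idx <- grep(L, ph$letters)
            expect_equal(idx, seq(min(idx), max(idx)))  # contiguous block
        }
    }
})

test_that("AUC contrasts expose the factorial effects of Table-style output", {
    sim <- synthDataset(cosinorSpec(gene = "CLOCK",
                                    groups = cosinorGroups("interaction_obese_hfd")),
                        seed = 12)
    tab <- aucTable(sim, "CLOCK", closure = "periodic")
    expect_equal(nrow(tab), 4)
    expect_true(all(c("auc", "se_auc", "p_interaction") %in% colnames(tab)))
    # the amplitude deficit does not move the 24-h AUC (cosine integrates
    # out), so the interaction Z-contrast on AUCs should stay quiet
    expect_gt(min(tab$auc), 30)
    # a mesor deficit does move it
    g <- cosinorGroups("null")
    g$mesor[g$maternal == "obese" & g$diet == "HFD"] <- 0.9
    sim2 <- synthDataset(cosinorSpec(gene = "CLOCK", groups = g), seed = 12)
    tab2 <- aucTable(sim2, "CLOCK", closure = "periodic")
    expect_lt(tab2$p_interaction[1], 0.01)
})
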