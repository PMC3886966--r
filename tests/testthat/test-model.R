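test_that("rhs reproduces its closed-form pieces", {
    f <- cosinorForcing()
    # pure linear decay
    p <- pparParams(v0 = 0, vp = 0, vd = 0, deltaP = 0.1)
    expect_equal(pparRhs(12, 2, p, f), -0.2, tolerance = 1e-14)
    # half-saturation: B(t) == Kp gives vp/2
    fConst <- cosinorForcing(mesor = 1.7, amplitude = 0)
    p2 <- pparParams(v0 = 0, vp = 0.8, Kp = 1.7, vd = 0, deltaP = 0)
    expect_equal(pparRhs(3, 5, p2, fConst), 0.4, tolerance = 1e-14)
})

test_that("rhs matches an independently coded formula on a grid", {
    f <- cosinorForcing(mesor = 1.2, amplitude = 0.7, acrophase = 9)
    p <- pparParams(v0 = 0.07, vp = 0.9, Kp = 1.4, n = 3.2, vd = 0.25,
                    Kd = 0.6, deltaP = 0.31, x0 = 1)
    for (t in seq(0, 24, by = 1.7)) for (x in c(0, 0.3, 1.1, 4)) {
        B <- 1.2 + 0.7 * cos(2 * pi * (t - 9) / 24)
        expected <- 0.07 + 0.9 * B^3.2 / (1.4^3.2 + B^3.2) -
            0.25 * x / (0.6 + x) - 0.31 * x
        expect_equal(pparRhs(t, x, p, f), expected, tolerance = 1e-14)
    }
})

test_that("with synthesis off the trajectory is exponential decay", {
    f <- cosinorForcing()
    lam <- 0.23
    p <- pparParams(v0 = 0, vp = 0, vd = 0, deltaP = lam, x0 = 1.8)
    tt <- seq(6, 30, by = 0.5)
    tr <- simulatePpar(p, f, tt)
    expect_lt(max(abs(tr@values - 1.8 * exp(-lam * (tt - 6)))), 1e-6)
})

test_that("constant forcing converges to the bisection steady state", {
    b <- 1.4
    f <- cosinorForcing(mesor = b, amplitude = 0)
    p <- pparParams(v0 = 0.06, vp = 0.7, Kp = 1.1, n = 2.5, vd = 0.3,
                    Kd = 0.5, deltaP = 0.12, x0 = 0.2)
    # independent root-finder on the algebraic balance
    synth <- 0.06 + 0.7 * b^2.5 / (1.1^2.5 + b^2.5)
    g <- function(x) synth - 0.3 * x / (0.5 + x) - 0.12 * x
    lo <- 0; hi <- 50
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) lo <- mid else hi <- mid
    }
    xStar <- (lo + hi) / 2
    tr <- simulatePpar(p, f, times = c(200, 300))
    expect_lt(abs(tr@values[2] - xStar), 1e-6)
})

test_that("periodic forcing settles onto a repeating cycle", {
    f <- cosinorForcing()
    p <- pparParams()
    tt <- seq(6, 6 + 24 * 12, by = 0.5)
    tr <- simulatePpar(p, f, tt)
    lastTwo <- tr@values[tt >= 6 + 24 * 10]
    n <- length(lastTwo) %/% 2
    expect_lt(max(abs(lastTwo[seq_len(n)] - lastTwo[n + seq_len(n)])), 1e-5)
})

test_that("periodicSolution meets its stopping criterion and linear limits", {
    f <- cosinorForcing()
    p <- pparParams()
    tr <- periodicSolution(p, f, dt = 0.25)
    expect_lt(abs(tr@values[1] - tr@values[length(tr@values)]), 1e-6)
    # constant solution v0/deltaP when all forcing-driven terms vanish
    p2 <- pparParams(v0 = 0.4, vp = 0, vd = 0, deltaP = 0.2)
    tr2 <- periodicSolution(p2, f)
    expect_equal(tr2@values, rep(2, length(tr2@values)), tolerance = 1e-6)
    # dissipation precondition
    expect_error(periodicSolution(pparParams(vd = 0, deltaP = 0), f),
                 "dissipation")
})

test_that("sinusoidal synthesis with linear clearance matches the convolution solution", {
    # choose a drive whose Hill transform is exactly sinusoidal:
    # s(t) = 0.5 + 0.25 cos(w (t - 10)), B = Kp * s / (1 - s), n = 1
    Kp <- 1.3; dp <- 0.22; v0 <- 0.05; vp <- 0.6
    w <- 2 * pi / 24
    sfun <- function(t) 0.5 + 0.25 * cos(w * (t - 10))
    fCustom <- methods::new("ClockForcing", mode = "cosinor", periodH = 24,
                            fun = function(t) Kp * sfun(t) / (1 - sfun(t)),
                            info = list())
    p <- pparParams(v0 = v0, vp = vp, Kp = Kp, n = 1, vd = 0,
                    deltaP = dp, x0 = 1)
    tr <- periodicSolution(p, fCustom, dt = 0.25, tol = 1e-8)
    # analytic periodic solution of dX/dt = a + b cos(w(t-phi)) - dp X
    a <- v0 + vp * 0.5; b <- vp * 0.25
    expected <- a / dp + b / (dp^2 + w^2) *
        (dp * cos(w * (tr@times - 10)) + w * sin(w * (tr@times - 10)))
    expect_lt(max(abs(tr@values - expected)), 1e-5)
})

test_that("trajectories stay non-negative across random parameter draws", {
    f <- cosinorForcing()
    set.seed(99)
    for (i in 1:20) {
        p <- pparParams(v0 = runif(1, 0, 1), vp = runif(1, 0, 2),
                        Kp = runif(1, 0.1, 3), n = runif(1, 1, 8),
                        vd = runif(1, 0, 2), Kd = runif(1, 0.1, 3),
                        deltaP = runif(1, 0.01, 2), x0 = runif(1, 0, 3))
        tr <- periodicSolution(p, f)
        expect_true(all(tr@values >= 0))
        tr2 <- simulatePpar(p, f, seq(6, 54, by = 2))
        expect_true(all(tr2@values >= 0))
    }
})

test_that("raising deltaP never raises the periodic mean", {
    f <- cosinorForcing()
    set.seed(7)
    for (i in 1:10) {
        base <- list(v0 = runif(1, 0, 0.5), vp = runif(1, 0.1, 1.5),
                     Kp = runif(1, 0.3, 2), n = runif(1, 1, 5),
                     vd = runif(1, 0, 0.5), Kd = runif(1, 0.2, 2))
        d1 <- runif(1, 0.05, 0.5)
        d2 <- d1 + runif(1, 0.05, 0.5)
        m1 <- mean(periodicSolution(do.call(pparParams, c(base, deltaP = d1)),
                                    f)@values)
        m2 <- mean(periodicSolution(do.call(pparParams, c(base, deltaP = d2)),
                                    f)@values)
        expect_lte(m2, m1 + 1e-9)
    }
})

test_that("the linearized model scales exactly with its synthesis rates", {
    f <- cosinorForcing()
    p1 <- pparParams(v0 = 0.1, vp = 0.5, vd = 0, deltaP = 0.3)
    p3 <- pparParams(v0 = 0.3, vp = 1.5, vd = 0, deltaP = 0.3)
    t1 <- periodicSolution(p1, f, tol = 1e-9)
    t3 <- periodicSolution(p3, f, tol = 1e-9)
    expect_equal(t3@values, 3 * t1@values, tolerance = 1e-6)
})

test_that("integration input contracts are enforced", {
    f <- cosinorForcing()
    p <- pparParams()
    expect_error(simulatePpar(p, f, c(4, 8)), ">= t0")
    expect_error(simulatePpar(p, f, c(8, 8)), "strictly increasing")
})
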