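ringSC <- function(n = 5, w = 0.2) {
    m <- matrix(0, n, n)
    for (j in seq_len(n)) {
        k <- j %% n + 1
        m[j, k] <- w; m[k, j] <- w
    }
    scMatrix(m)
}

test_that("noise-free uncoupled dynamics follow the radial closed form", {
    sc <- ringSC()
    # a < 0: damped spiral, amplitude decays to zero
    spec <- hopfModelSpec(a = -0.5, omega = 2 * pi * 0.05, g = 0, C = sc,
                          beta = 0)
    sim <- simulateHopf(spec, duration = 40, tr = 0.5, seed = 1,
                        transient = 0, z0 = rep(0.5 + 0i, 5))
    late <- signalValues(sim$bold)[, 60:80]
    expect_lt(max(abs(late)), 1e-3)

    # a > 0: limit cycle of amplitude sqrt(a)
    ampAt <- function(a, dt) {
        spec <- hopfModelSpec(a = a, omega = 2 * pi * 0.05, g = 0, C = sc,
                              beta = 0, dt = dt)
        sim <- simulateHopf(spec, duration = 300, tr = 0.5, seed = 1,
                            transient = 100, z0 = rep(0.1 + 0i, 5))
        x <- signalValues(sim$bold)[1, ]
        sqrt(2 * mean(x^2))
    }
    for (a in c(0.09, 0.25))
        expect_equal(ampAt(a, dt = 0.025), sqrt(a), tolerance = 0.02)
    # step-halving convergence towards the closed form
    errs <- abs(vapply(c(0.1, 0.05, 0.025), ampAt, numeric(1),
                       a = 0.09) - 0.3)
    expect_true(all(diff(errs) < 0))
})

test_that("limit-cycle oscillation peaks at its intrinsic frequency", {
    sc <- ringSC()
    spec <- hopfModelSpec(a = 0.25, omega = 2 * pi * 0.05, g = 0, C = sc,
                          beta = 0)
    sim <- simulateHopf(spec, duration = 1100, tr = 2, seed = 1,
                        transient = 60, z0 = rep(0.1 + 0i, 5))
    x <- signalValues(sim$bold)[1, ]
    sp <- Mod(stats::fft(x - mean(x)))^2
    nf <- floor(length(x) / 2)
    freqs <- (seq_len(nf) - 1) / (length(x) * 2)
    expect_equal(freqs[which.max(sp[seq_len(nf)])], 0.05,
                 tolerance = 1 / (length(x) * 2) + 1e-9)
})

test_that("diffusive coupling vanishes on a fully synchronized network", {
    sc <- ringSC()
    z0 <- rep(0.3 + 0.1i, 5)
    base <- hopfModelSpec(a = 0.1, omega = 2 * pi * 0.05, g = 0, C = sc,
                          beta = 0)
    coupled <- hopfModelSpec(a = 0.1, omega = 2 * pi * 0.05, g = 2, C = sc,
                             beta = 0)
    s0 <- simulateHopf(base, 100, 1, seed = 1, transient = 0, z0 = z0)
    s2 <- simulateHopf(coupled, 100, 1, seed = 1, transient = 0, z0 = z0)
    expect_equal(signalValues(s0$bold), signalValues(s2$bold),
                 tolerance = 1e-10)
})

test_that("bare and effective parameterizations are the same flow", {
    sc <- fixtureSC()
    a <- rep(0, 40)
    g <- 1.5
    bare <- hopfModelSpec(a = a, omega = 2 * pi * 0.05, g = g, C = sc)
    eff <- hopfModelSpec(a = effectiveParameters(a, g, sc),
                         omega = 2 * pi * 0.05, g = g, C = sc,
                         effectiveMode = TRUE)
    s1 <- simulateHopf(bare, 200, 2, seed = 3)
    s2 <- simulateHopf(eff, 200, 2, seed = 3)
    expect_identical(signalValues(s1$bold), signalValues(s2$bold))
})

test_that("trajectories are deterministic and stationary after transient", {
    sc <- fixtureSC()
    spec <- hopfModelSpec(a = 0, omega = 2 * pi * 0.05, g = 1, C = sc)
    s1 <- simulateHopf(spec, 400, 2, seed = 5)
    s2 <- simulateHopf(spec, 400, 2, seed = 5)
    expect_identical(signalValues(s1$bold), signalValues(s2$bold))

    long <- simulateHopf(spec, 1260, 2, seed = 6)
    x <- signalValues(long$bold)
    half <- ncol(x) %/% 2
    m1 <- mean(abs(x[, seq_len(half)]))
    m2 <- mean(abs(x[, (half + 1):(2 * half)]))
    expect_lt(abs(m1 - m2) / m1, 0.1)

    expect_error(simulateHopf(spec, 400, tr = 0.35, seed = 1), "multiple")
    expect_error(simulateHopf(spec, 30, tr = 2, seed = 1), "transient")
})

test_that("intrinsic frequency estimation recovers tones and averages", {
    one <- sinusoidBold(3, freq = 0.05, nVol = 300)
    est <- estimateIntrinsicFrequencies(list(one))
    # spectral resolution = one Welch bin (fs / segment length)
    expect_lt(max(abs(est$freqHz - 0.05)), 0.5 / 75 + 1e-9)
    expect_equal(est$omega, 2 * pi * est$freqHz)

    a <- sinusoidBold(2, freq = 0.04, nVol = 300)
    b <- sinusoidBold(2, freq = 0.06, nVol = 300)
    est2 <- estimateIntrinsicFrequencies(list(a, b))
    expect_lt(max(abs(est2$freqHz - 0.05)), 0.5 / 75 + 1e-9)
    expect_true(all(est2$freqHz >= 0.04 & est2$freqHz <= 0.07))
})

test_that("power proportion separates narrowband from broadband signals", {
    slow <- sinusoidBold(1, freq = 0.05, nVol = 1000)
    expect_gt(powerProportion(slow)[1], 0.95)

    fast <- sinusoidBold(1, freq = 0.15, nVol = 1000)
    expect_lt(powerProportion(fast)[1], 0.05)

    set.seed(131)
    wn <- boldMatrix(matrix(rnorm(8 * 2000), 8), 2)
    p <- mean(powerProportion(wn))
    expect_lt(abs(p - (0.07 - 0.04) / (0.25 - 0.04)), 0.03)
})
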