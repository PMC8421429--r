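trim <- function(x, k = 20) x[(k + 1):(length(x) - k)]

test_that("band-pass keeps in-band tones and rejects out-of-band power", {
    inband <- sinusoidBold(1, freq = 0.055, nVol = 300)
    out <- bandpassFilter(inband, 0.04, 0.07)
    rin <- sqrt(mean(trim(signalValues(inband)[1, ])^2))
    rout <- sqrt(mean(trim(signalValues(out)[1, ])^2))
    expect_gt(rout / rin, 0.95)

    fast <- sinusoidBold(1, freq = 0.2, nVol = 300)
    outf <- bandpassFilter(fast, 0.04, 0.07)
    att <- mean(trim(signalValues(outf)[1, ])^2) /
        mean(trim(signalValues(fast)[1, ])^2)
    expect_lt(att, 0.1)

    const <- boldMatrix(matrix(5, 1, 300), 2)
    expect_lt(max(abs(signalValues(bandpassFilter(const, .04, .07)))),
              1e-8)

    expect_error(bandpassFilter(inband, 0.04, 0.3), "Nyquist")
    expect_error(bandpassFilter(boldMatrix(matrix(1:10, 1), 2), .04, .07),
                 "short")
})

test_that("instantaneous phases track a tone and wrap to (-pi, pi]", {
    b <- sinusoidBold(2, freq = 0.05, nVol = 300,
                      phaseOffsets = c(0, -pi / 2))   # cos and sin
    ph <- instantaneousPhases(bandpassFilter(b, 0.04, 0.07))
    p <- signalValues(ph)
    expect_true(all(p > -pi & p <= pi))

    # unwrapped phase advances at 2*pi*f rad/s
    keep <- 30:270
    unw <- cumsum(c(p[1, keep[1]],
        ((diff(p[1, keep]) + pi) %% (2 * pi)) - pi))
    slope <- stats::coef(stats::lm(unw ~ I(2 * keep)))[2]
    expect_equal(unname(slope), 2 * pi * 0.05, tolerance = 0.02)

    # cos vs sin: constant quarter-cycle offset
    d <- abs(((p[1, keep] - p[2, keep] + pi) %% (2 * pi)) - pi)
    expect_equal(mean(d), pi / 2, tolerance = 0.05)

    zero <- boldMatrix(matrix(0, 2, 100), 2)
    expect_error(instantaneousPhases(zero), "undefined phase")
})

test_that("phase-interaction values hit 1, 0 and -1 at the canonical offsets", {
    ph <- phaseFixture(rbind(rep(0.3, 50),
                             rep(0.3, 50),
                             rep(0.3 + pi / 2, 50),
                             rep(0.3 - pi, 50)))
    series <- phaseInteractions(ph, settle = 0L)
    P <- series@tensor[, , 25]
    expect_equal(P[1, 2], 1)
    expect_equal(P[1, 3], 0, tolerance = 1e-12)
    expect_equal(P[1, 4], -1)
})

test_that("every phase-interaction slice is symmetric with unit diagonal", {
    set.seed(11)
    for (rep in 1:5) {
        n <- sample(3:8, 1)
        ph <- phaseFixture(matrix(stats::runif(n * 40, -pi, pi), n))
        tens <- phaseInteractions(ph, settle = 0L)@tensor
        for (t in c(1, 20, 40)) {
            sl <- tens[, , t]
            expect_identical(sl, t(sl))
            expect_identical(diag(sl), rep(1, n))
            expect_true(all(abs(sl) <= 1 + 1e-12))
        }
    }
})

test_that("global synchrony: coherent networks give r = 1, m = 0", {
    ph <- phaseFixture(matrix(rep(stats::runif(60, -pi, pi), each = 5), 5,
                              byrow = FALSE))
    gs <- globalSynchrony(phaseInteractions(ph, settle = 0L))
    expect_equal(gs$r, rep(1, 60))
    expect_identical(gs$m, 0)

    # two nodes at a fixed third-of-cycle offset: r = cos(pi/3) = 1/2
    ph2 <- phaseFixture(rbind(rep(0.1, 30), rep(0.1 + pi / 3, 30)))
    gs2 <- globalSynchrony(phaseInteractions(ph2, settle = 0L))
    expect_equal(gs2$r, rep(0.5, 30), tolerance = 1e-12)
    expect_equal(gs2$m, 0, tolerance = 1e-12)

    # independent phases: r near zero but fluctuating
    set.seed(21)
    ph3 <- phaseFixture(matrix(stats::runif(100 * 80, -pi, pi), 100))
    gs3 <- globalSynchrony(phaseInteractions(ph3, settle = 0L))
    expect_lt(abs(mean(gs3$r)), 0.05)
    expect_gt(gs3$m, 0)

    one <- phaseFixture(matrix(0.2, 1, 30))
    expect_error(globalSynchrony(phaseInteractions(one, settle = 0L)),
                 "2 regions")
})

test_that("surrogates preserve the power spectrum and autocorrelation", {
    set.seed(31)
    b <- boldMatrix(matrix(rnorm(5 * 201), 5), 2)  # odd and even T both hit
    for (bold in list(b, boldMatrix(matrix(rnorm(4 * 200), 4), 2))) {
        surr <- phaseRandomizedSurrogate(bold, seed = 8)
        x <- signalValues(bold); y <- signalValues(surr)
        expect_true(is.numeric(y))
        for (j in seq_len(nrow(x))) {
            a1 <- Mod(stats::fft(x[j, ])); a2 <- Mod(stats::fft(y[j, ]))
            expect_lt(max(abs(a1 - a2)) / max(a1), 1e-10)
            # Wiener-Khinchin: equal spectra imply equal autocorrelations
            ac1 <- Re(stats::fft(a1^2, inverse = TRUE))
            ac2 <- Re(stats::fft(a2^2, inverse = TRUE))
            expect_equal(ac1, ac2, tolerance = 1e-9)
        }
        # same seed reproduces, different seed does not
        expect_identical(y,
            signalValues(phaseRandomizedSurrogate(bold, seed = 8)))
        expect_false(identical(y,
            signalValues(phaseRandomizedSurrogate(bold, seed = 9))))
    }
})

test_that("surrogate bias correction zeroes its own null and keeps signal", {
    set.seed(41)
    b <- boldMatrix(matrix(rnorm(6 * 300), 6), 2)

    # a surrogate's own mean interaction, corrected by an ensemble, ~ 0
    surr <- phaseRandomizedSurrogate(b, seed = 55)
    mp <- meanPhaseInteraction(surr)
    corr <- biasCorrectMeanInteraction(mp, surr, nSurrogates = 19,
                                       seed = 77)
    # the systematic bias is removed; per-pair sampling noise remains
    expect_lt(abs(mean(corr[upper.tri(corr)])), 0.05)
    expect_lt(mean(abs(corr[upper.tri(corr)])),
              mean(abs(mp[upper.tri(mp)])) + 0.05)

    # single-surrogate self-subtraction is exactly zero
    s1 <- phaseRandomizedSurrogate(b, seed = hopfbrain:::subSeed(3, 1))
    mp1 <- meanPhaseInteraction(s1)
    z <- biasCorrectMeanInteraction(mp1, b, nSurrogates = 1, seed = 3)
    expect_equal(max(abs(z)), 0, tolerance = 1e-12)

    # perfectly synchronized signals survive the correction
    sync <- sinusoidBold(6, freq = 0.05)
    mps <- meanPhaseInteraction(sync)
    cs <- biasCorrectMeanInteraction(mps, sync, nSurrogates = 19, seed = 5)
    # a pure tone's surrogates are phase-shifted tones, so individual
    # corrections scatter, but the synchrony survives clearly on average
    expect_gt(mean(cs[upper.tri(cs)]), 0.8)
    expect_gt(min(cs[upper.tri(cs)]), 0.5)
})

test_that("the analysis chain is deterministic in (input, seed)", {
    sc <- generateCorePeripherySC(10, 2, 3, 0.5, seed = 6)
    gt <- makeGroundTruthDataset(sc, 1, list(mode = "homogeneous",
        value = 0), nVolumes = 120L, seed = 13)
    s1 <- dynamicsSummary(gt$bold, nSurrogates = 100, seed = 2)
    s2 <- dynamicsSummary(gt$bold, nSurrogates = 100, seed = 2)
    expect_identical(s1, s2)
})
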