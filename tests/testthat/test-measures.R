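test_that("integration matches closed forms on canonical graphs", {
    n <- 10
    full <- matrix(1, n, n); diag(full) <- 0
    expect_equal(integration(full), 1)

    empty <- matrix(0, n, n)
    expect_equal(integration(empty), 1 / n)

    two <- cliqueMatrix(2, 5)
    expect_equal(integration(two), 0.5)

    expect_error(integration(matrix(0, 2, 3)), "square")
})

test_that("integration agrees with a BFS largest-component oracle", {
    set.seed(51)
    for (rep in 1:5) {
        n <- 8
        m <- matrix(stats::runif(n * n), n)
        m <- (m + t(m)) / 2; diag(m) <- 0
        step <- 0.05
        thr <- seq(0, 1 - step, by = step)
        oracle <- mean(vapply(thr, function(th)
            bfsLargestComponent(m > th) / n, numeric(1)))
        expect_equal(integration(m, step), oracle)
    }
})

test_that("integration is monotone under pointwise increase", {
    set.seed(61)
    for (rep in 1:5) {
        m <- matrix(stats::runif(49, 0, 0.8), 7)
        m <- (m + t(m)) / 2; diag(m) <- 0
        bump <- matrix(stats::runif(49, 0, 0.2), 7)
        bump <- (bump + t(bump)) / 2; diag(bump) <- 0
        expect_gte(integration(pmin(m + bump, 1)), integration(m))
    }
})

test_that("Louvain modularity equals brute-force enumeration on small graphs", {
    # hand-derivable clique graphs
    expect_equal(modularityQ(cliqueMatrix(2, 5), seed = 1), 0.5)
    expect_equal(modularityQ(cliqueMatrix(4, 3), seed = 1), 0.75)
    full <- matrix(1, 6, 6); diag(full) <- 0
    expect_equal(modularityQ(full, seed = 1), 0)

    # exhaustive partition search on random 7-node graphs
    set.seed(71)
    for (rep in 1:3) {
        adj <- matrix(stats::runif(49) < 0.4, 7, 7)
        adj <- adj | t(adj); diag(adj) <- FALSE
        if (!any(adj)) next
        expect_equal(modularityQ(adj, seed = rep),
                     bruteForceModularity(adj), tolerance = 1e-12)
    }

    expect_warning(q0 <- modularityQ(matrix(0, 4, 4)), "no edges")
    expect_identical(q0, 0)
})

test_that("segregation binarizes against the surrogate null", {
    # two independent frequency blocks -> two modules survive binarization
    b <- sinusoidBold(8, freq = 0.05)
    v <- signalValues(b)
    set.seed(81)
    v[5:8, ] <- t(sapply(1:4, function(i) {
        tt <- seq(0, by = 2, length.out = ncol(v))
        cos(2 * pi * 0.062 * tt + runif(1, 0, 2 * pi))
    }))
    v <- v + matrix(rnorm(length(v), 0, 0.05), nrow(v))
    b2 <- boldMatrix(v, 2)
    mp <- meanPhaseInteraction(b2)
    q <- segregation(mp, b2, nSurrogates = 100, alpha = 0.01, seed = 4)
    expect_gte(q, 0)
    expect_error(segregation(mp, b2, nSurrogates = 10, alpha = 0.01),
                 "surrogates")
})

test_that("FCD hits the exact cosine values for constructed patterns", {
    # stationary pattern: all similarities 1
    ph <- phaseFixture(matrix(rep(c(0, 1, 2), 50), 3, 50))
    f <- fcd(phaseInteractions(ph, settle = 0L), window = 10L)
    expect_true(all(abs(f@similarity - 1) < 1e-9))
    expect_equal(meanFCD(f), 1, tolerance = 1e-9)

    expect_error(fcd(phaseInteractions(ph, settle = 0L), window = 100L),
                 "short")
})

test_that("FCD is symmetric with unit diagonal on random inputs", {
    set.seed(91)
    ph <- phaseFixture(matrix(stats::runif(6 * 80, -pi, pi), 6))
    f <- fcd(phaseInteractions(ph, settle = 0L), window = 15L, step = 2L)
    s <- f@similarity
    expect_identical(s, t(s))
    expect_identical(diag(s), rep(1, nrow(s)))
    expect_true(all(abs(s) <= 1))
    expect_identical(nrow(s), length(seq(1, 80 - 15 + 1, by = 2)))
})

test_that("meanFCD averages the upper triangle, with overlap exclusion", {
    m <- matrix(c(1, 0.4, 0.4, 1), 2)
    f <- methods::new("FCDMatrix", similarity = m, window = 30L, step = 1L)
    expect_equal(meanFCD(f), 0.4)
    # two windows one step apart always overlap
    expect_error(meanFCD(f, excludeOverlap = TRUE), "non-overlapping")

    set.seed(101)
    ph <- phaseFixture(matrix(stats::runif(5 * 120, -pi, pi), 5))
    f2 <- fcd(phaseInteractions(ph, settle = 0L), window = 20L)
    all_ <- meanFCD(f2)
    nonov <- meanFCD(f2, excludeOverlap = TRUE)
    s <- f2@similarity
    lag <- abs(outer(seq_len(nrow(s)), seq_len(nrow(s)), "-"))
    expect_equal(nonov, mean(s[upper.tri(s) & lag >= 20]))
    expect_false(identical(all_, nonov))
})

test_that("white-noise FCD has near-zero mean similarity", {
    set.seed(111)
    b <- boldMatrix(matrix(rnorm(40 * 300), 40), 2)
    ser <- phaseInteractions(instantaneousPhases(
        bandpassFilter(b, 0.04, 0.07)))
    f <- fcd(ser)
    # non-overlapping windows are genuinely unrelated; the all-pairs mean
    # retains a small positive offset from windows sharing samples
    expect_lt(abs(meanFCD(f, excludeOverlap = TRUE)), 0.05)
    expect_lt(abs(meanFCD(f)), 0.2)
})

test_that("Fisher-z functional connectivity behaves at the boundaries", {
    set.seed(121)
    x <- rnorm(400)
    b <- boldMatrix(rbind(x, x, -x + rnorm(400, 0, 1e-3), rnorm(400)), 2)
    z <- pearsonFC(b)
    expect_true(all(is.na(diag(z))))
    expect_true(is.finite(z[1, 2]))          # r = 1 capped, not Inf
    expect_gt(z[1, 2], 5)
    expect_lt(z[1, 3], -5)                   # anti-correlated pair
    expect_lt(abs(z[1, 4]), 0.2)             # independent noise ~ 0

    bz <- boldMatrix(rbind(x, rep(1, 400)), 2)
    expect_warning(z2 <- pearsonFC(bz), "zero-variance")
    expect_true(all(is.na(z2[2, ])))
})

test_that("stronger coupling raises integration and FCD recurrence", {
    sc <- generateCorePeripherySC(20, 3, 4, 0.3, seed = 2)
    stat <- function(g, seed) {
        gt <- makeGroundTruthDataset(sc, g, list(mode = "homogeneous",
            value = 0), nVolumes = 150L, seed = seed)
        ser <- phaseInteractions(instantaneousPhases(
            bandpassFilter(gt$bold, 0.04, 0.07)))
        mp <- meanPhaseInteraction(gt$bold)
        mpc <- biasCorrectMeanInteraction(mp, gt$bold, nSurrogates = 5,
                                          seed = seed)
        c(fcd = meanFCD(fcd(ser)), int = integration(mpc))
    }
    lo <- rowMeans(sapply(1:10, function(s) stat(0.3, s)))
    hi <- rowMeans(sapply(1:10, function(s) stat(2.0, s)))
    expect_gt(hi["fcd"], lo["fcd"])
    expect_gt(hi["int"], lo["int"])
})
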