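#' Two-sample Kolmogorov-Smirnov distance
#'
#' Maximal absolute difference between the empirical cumulative
#' distribution functions of two samples, evaluated at all breakpoints.
#'
#' @param sampleA,sampleB non-empty numeric vectors.
#' @return scalar in [0, 1].
#' @examples
#' ksDistance(c(0, 1), c(0, 0, 1, 1))   # 0
#' @export
ksDistance <- function(sampleA, sampleB) {
    if (!length(sampleA) || !length(sampleB))
        stop("both samples must be non-empty")
    br <- sort(unique(c(sampleA, sampleB)))
    Fa <- stats::ecdf(sampleA)(br)
    Fb <- stats::ecdf(sampleB)(br)
    max(abs(Fa - Fb))
}

# Simulate at one g and return the FCD upper-triangle values, using the
# same analysis chain as the empirical side.
simulatedFcdValues <- function(spec, duration, tr, seed, low, high,
                               settle, window, step, transient) {
    sim <- simulateHopf(spec, duration, tr, seed, transient = transient)
    ph <- instantaneousPhases(bandpassFilter(sim$bold, low, high))
    series <- phaseInteractions(ph, settle)
    upperTriValues(fcd(series, window, step)@similarity)
}

#' Fit the global coupling g by FCD distribution matching
#'
#' Scans a grid of candidate couplings; at each, runs \code{trials}
#' simulations of the homogeneous model (distinct deterministic sub-seeds),
#' computes the distribution of FCD similarities through the same analysis
#' chain used for the data, and records the Kolmogorov-Smirnov distance to
#' the empirical FCD distribution. The optimum is the grid value minimizing
#' the mean KS distance (ties broken towards the smallest g).
#'
#' @param empiricalFcdValues numeric vector of empirical FCD upper-triangle
#'   similarities.
#' @param template a [HopfModelSpec-class] providing a, omega, C, beta, dt;
#'   its \code{g} is overridden by each grid candidate.
#' @param gGrid sorted non-negative candidate couplings
#'   (default \code{seq(0, 3, by = 0.1)}).
#' @param trials simulations per candidate (default 10).
#' @param duration simulated seconds per trial, including transient
#'   (default 660: a 10-minute scan plus 60 s transient).
#' @param tr sampling interval (default 2 s).
#' @param seed master seed.
#' @param low,high,settle,window,step analysis-chain parameters (defaults
#'   0.04, 0.07, 10, 30, 1).
#' @param transient simulation transient in seconds (default 60).
#' @return a [GlobalFitResult-class].
#' @export
fitGlobalCoupling <- function(empiricalFcdValues, template,
                              gGrid = seq(0, 3, by = 0.1), trials = 10L,
                              duration = 660, tr = 2, seed = 1L,
                              low = 0.04, high = 0.07, settle = 10L,
                              window = 30L, step = 1L, transient = 60) {
    stopifnot(is(template, "HopfModelSpec"), trials >= 1)
    if (is.unsorted(gGrid) || any(gGrid < 0))
        stop("'gGrid' must be sorted and non-negative")
    ksMean <- ksSE <- rep(NA_real_, length(gGrid))
    for (i in seq_along(gGrid)) {
        spec <- template
        spec@g <- gGrid[i]
        ks <- rep(NA_real_, trials)
        for (t in seq_len(trials)) {
            ks[t] <- tryCatch(
                ksDistance(empiricalFcdValues,
                           simulatedFcdValues(spec, duration, tr,
                               seed = subSeed(seed, i * 1000L + t),
                               low, high, settle, window, step, transient)),
                error = function(e) {
                    warning("simulation failed at g = ", gGrid[i], ": ",
                            conditionMessage(e))
                    NA_real_
                })
        }
        if (any(!is.na(ks))) {
            ksMean[i] <- mean(ks, na.rm = TRUE)
            ksSE[i] <- stats::sd(ks, na.rm = TRUE) /
                sqrt(sum(!is.na(ks)))
        }
    }
    if (all(is.na(ksMean))) stop("all candidate couplings failed")
    gOpt <- gGrid[which.min(ksMean)]    # first minimum = smallest g on ties
    new("GlobalFitResult", gGrid = as.numeric(gGrid), ksMean = ksMean,
        ksSE = ksSE, gOpt = gOpt, trials = as.integer(trials),
        seed = as.integer(seed))
}

# Shared driver for the two local-parameter fits.
localFitEngine <- function(pEmp, spec, eta, maxIter, tol, seed,
                           duration, tr, transient, narrowBand, wideBand) {
    a <- spec@a
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        spec@a <- a
        sim <- simulateHopf(spec, duration, tr, seed = subSeed(seed, iter),
                            transient = transient)
        pSim <- powerProportion(sim$bold, narrowBand = narrowBand,
                                wideBand = wideBand)
        delta <- pEmp - pSim
        trace[iter] <- max(abs(delta))
        if (trace[iter] < tol) { converged <- TRUE; break }
        a <- a + eta * delta          # parallel update of all nodes
    }
    new("LocalFitResult", aHat = a, iterations = iter, trace = trace,
        converged = converged, eta = eta,
        effectiveMode = spec@effectiveMode)
}

#' Fit node-wise bifurcation parameters from spectral power proportions
#'
#' Iterative fit of the heterogeneous model: with g fixed (from the
#' homogeneous fit), each iteration simulates the network with the current
#' a_j, measures every node's proportion of power in the narrow band, and
#' moves each parameter in parallel along the mismatch,
#' \code{a_j <- a_j + eta * (p_emp_j - p_sim_j)}, until the maximal
#' node-wise mismatch drops below \code{tol} or \code{maxIter} is reached.
#' Each iteration uses a fresh deterministic sub-seed so the fit does not
#' lock onto one noise path.
#'
#' @param pEmp length-N vector of empirical power proportions in [0, 1].
#' @param spec a [HopfModelSpec-class] with \code{effectiveMode = FALSE};
#'   its \code{a} is the starting point (typically all zero) and \code{g}
#'   stays fixed.
#' @param eta learning rate (default 0.1).
#' @param maxIter iteration cap (default 100).
#' @param tol convergence tolerance on max |p_emp - p_sim| (default 0.01).
#' @param seed master seed.
#' @param duration,tr,transient simulation settings per iteration (defaults
#'   660 s, 2 s, 60 s).
#' @param narrowBand,wideBand spectral bands in Hz (defaults c(0.04, 0.07)
#'   and c(0.04, 0.25)); forced identical for the empirical and simulated
#'   sides by using the same estimator.
#' @return a [LocalFitResult-class] (returned even without convergence,
#'   with \code{converged = FALSE}).
#' @export
fitLocalBifurcation <- function(pEmp, spec, eta = 0.1, maxIter = 100L,
                                tol = 0.01, seed = 1L, duration = 660,
                                tr = 2, transient = 60,
                                narrowBand = c(0.04, 0.07),
                                wideBand = c(0.04, 0.25)) {
    stopifnot(is(spec, "HopfModelSpec"), all(pEmp >= 0 & pEmp <= 1),
              length(pEmp) == spec@n, eta > 0)
    spec@effectiveMode <- FALSE
    localFitEngine(pEmp, spec, eta, maxIter, tol, seed, duration, tr,
                   transient, narrowBand, wideBand)
}

#' Fit effective bifurcation parameters directly
#'
#' Identical procedure to [fitLocalBifurcation()] but the simulator runs in
#' effective parameterization: growth term a_eff + i w and coupling
#' g * sum_k C_jk z_k (no diffusive leak). The fitted vector estimates
#' a_eff = a - g*S directly, so in a homogeneous-a network it is linearly
#' (negatively) related to node strength.
#'
#' @inheritParams fitLocalBifurcation
#' @param spec a [HopfModelSpec-class]; \code{a} is the starting a_eff
#'   (a sensible start is \code{-g * rowSums(scWeights(C))}).
#' @return a [LocalFitResult-class] with \code{effectiveMode = TRUE}.
#' @export
fitEffectiveParameters <- function(pEmp, spec, eta = 0.1, maxIter = 100L,
                                   tol = 0.01, seed = 1L, duration = 660,
                                   tr = 2, transient = 60,
                                   narrowBand = c(0.04, 0.07),
                                   wideBand = c(0.04, 0.25)) {
    stopifnot(is(spec, "HopfModelSpec"), all(pEmp >= 0 & pEmp <= 1),
              length(pEmp) == spec@n, eta > 0)
    spec@effectiveMode <- TRUE
    localFitEngine(pEmp, spec, eta, maxIter, tol, seed, duration, tr,
                   transient, narrowBand, wideBand)
}

#' Effective bifurcation parameters from bare parameters
#'
#' The identity a_eff_j = a_j - g * S_j, with S_j the structural strength.
#'
#' @param a length-N bare bifurcation parameters.
#' @param g global coupling.
#' @param sc an [SCMatrix-class].
#' @return length-N numeric vector.
#' @export
effectiveParameters <- function(a, g, sc) {
    stopifnot(is(sc, "SCMatrix"))
    a - g * rowSums(sc@weights)
}

#' Linear relation between effective parameters and node strength
#'
#' Ordinary least squares of a_eff on strength. In a homogeneous network
#' a_eff = a - g*S lies exactly on a line, so the node-wise absolute
#' residuals measure how heterogeneous the local dynamics are beyond what
#' the structure dictates.
#'
#' @param aEff length-N effective parameters.
#' @param strengths length-N node strengths (non-constant).
#' @return list with \code{slope}, \code{intercept}, \code{residuals}
#'   (signed), \code{absResiduals} and \code{medianAbsResidual}.
#' @export
strengthResidualAnalysis <- function(aEff, strengths) {
    if (length(aEff) != length(strengths) || length(aEff) < 3)
        stop("'aEff' and 'strengths' must have equal length >= 3")
    if (stats::sd(strengths) == 0)
        stop("undefined slope: strengths are constant")
    fit <- stats::lm(aEff ~ strengths)
    res <- stats::residuals(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residuals = unname(res),
         absResiduals = abs(unname(res)),
         medianAbsResidual = stats::median(abs(res)))
}

#' Random permutation of fitted local parameters
#'
#' Control analysis: shuffling the fitted a_j across regions preserves
#' their distribution but destroys the region-to-parameter assignment; a
#' model run with shuffled parameters should fit the data worse.
#'
#' @param aHat numeric vector.
#' @param seed integer seed.
#' @return permuted vector (same multiset).
#' @export
shuffleLocalParameters <- function(aHat, seed) {
    if (!length(aHat)) stop("'aHat' must be non-empty")
    withSeed(seed, sample(aHat))
}
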