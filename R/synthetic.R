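#' Generate a core-periphery structural connectome
#'
#' Weighted stochastic-block construction with a designated hub core:
#' link weights are drawn log-normally; links incident to a hub are always
#' present (hubs connect broadly) and scaled by \code{hubFactor}, hub-hub
#' links by \code{hubFactor^2}, while periphery-periphery links exist with
#' probability \code{density}. The matrix is symmetrized, the diagonal
#' zeroed, and the result linearly rescaled so the maximum entry is exactly
#' 0.2 (the model scaling that prevents full synchronization). The
#' construction yields a long-tailed strength distribution and a rich club:
#' for \code{hubFactor >= 2} hub strengths clearly exceed every non-hub
#' strength and hub-hub links are on average the strongest.
#'
#' @param nNodes number of regions.
#' @param nHubs number of hub (core) regions, \code{1 <= nHubs < nNodes}.
#' @param hubFactor multiplicative boost of hub-incident weights (> 0;
#'   1 disables the core structure).
#' @param density probability of a periphery-periphery link, in (0, 1].
#' @param seed integer seed.
#' @param baseSdLog log-scale standard deviation of the base log-normal
#'   weight distribution (default 1.2, giving the long-tailed weight and
#'   strength distributions typical of tractography connectomes; smaller
#'   values give more homogeneous graphs).
#' @return an [SCMatrix-class] with \code{hubIndices} set to the designated
#'   core (the first \code{nHubs} node indices).
#' @examples
#' sc <- generateCorePeripherySC(40, 6, hubFactor = 3, density = .3, seed = 1)
#' max(scWeights(sc))   # 0.2
#' @export
generateCorePeripherySC <- function(nNodes, nHubs, hubFactor, density,
                                    seed, baseSdLog = 1.2) {
    if (nHubs < 1 || nHubs >= nNodes)
        stop("'nHubs' must satisfy 1 <= nHubs < nNodes")
    if (density <= 0)
        stop("degenerate graph: 'density' must be positive")
    if (density > 1) stop("'density' must be at most 1")
    if (hubFactor <= 0) stop("'hubFactor' must be positive")
    hubs <- seq_len(nHubs)
    w <- withSeed(seed, {
        m <- matrix(0, nNodes, nNodes)
        for (j in seq_len(nNodes - 1)) {
            for (k in (j + 1):nNodes) {
                nh <- (j %in% hubs) + (k %in% hubs)
                present <- nh > 0 || stats::runif(1) < density
                if (present)
                    m[j, k] <- stats::rlnorm(1, 0, baseSdLog) * hubFactor^nh
            }
        }
        m + t(m)
    })
    if (max(w) == 0) stop("degenerate graph: no links generated")
    w <- w * 0.2 / max(w)
    scMatrix(w, hubIndices = hubs)
}

#' Attenuate hub-incident links (lesion model)
#'
#' Emulates hub damage: every link incident to a node whose strength
#' exceeds \code{hubThreshold} is multiplied by \code{1 - reduction}. The
#' node count is kept constant (attenuation, not deletion) so lesioned and
#' intact connectomes share a parcellation. Symmetry is preserved; by
#' default the output keeps the raw attenuated scale.
#'
#' @param sc an [SCMatrix-class].
#' @param reduction attenuation fraction in [0, 1]; 0 returns the input
#'   unchanged, 1 removes all hub-incident links.
#' @param hubThreshold strength threshold on the scale of \code{sc} (nodes
#'   with strength strictly above it are treated as hubs).
#' @param rescale if \code{TRUE}, rescale the result so the maximum entry
#'   is 0.2 again (default \code{FALSE}).
#' @return an [SCMatrix-class]; \code{hubIndices} are preserved from the
#'   input for bookkeeping.
#' @export
degradeHubs <- function(sc, reduction, hubThreshold, rescale = FALSE) {
    stopifnot(is(sc, "SCMatrix"))
    if (reduction < 0 || reduction > 1)
        stop("'reduction' must lie in [0, 1]")
    w <- sc@weights
    S <- rowSums(w)
    hub <- S > hubThreshold
    mask <- outer(hub, hub, "|")
    w[mask] <- w[mask] * (1 - reduction)
    if (rescale && max(w) > 0) w <- w * 0.2 / max(w)
    scMatrix(w, regionLabels = sc@regionLabels, hubIndices = sc@hubIndices)
}

#' Ground-truth dataset: connectome, parameters and simulated BOLD
#'
#' Draws node frequencies uniformly in \code{band}, sets the bifurcation
#' parameters homogeneously or heterogeneously, and simulates BOLD from the
#' coupled Hopf model, returning both the generating parameters and the
#' signal so that every downstream estimator can be validated against known
#' truth. Identical inputs and seed give bit-identical output.
#'
#' @param sc an [SCMatrix-class] (model-scaled).
#' @param g global coupling.
#' @param aSpec either \code{list(mode = "homogeneous", value = v)} or
#'   \code{list(mode = "heterogeneous", min = lo, max = hi)} (values drawn
#'   uniformly).
#' @param band frequency band in Hz (default c(0.04, 0.07)); must lie below
#'   Nyquist.
#' @param nVolumes number of volumes (default 300).
#' @param tr repetition time in seconds (default 2).
#' @param seed integer seed.
#' @param beta noise standard deviation (default 0.02).
#' @param dt integration step (default 0.1 s).
#' @param transient seconds discarded before sampling (default 60).
#' @return list with \code{groundTruth} (list: \code{g}, \code{a},
#'   \code{omega}, \code{hubIndices}, \code{seed}) and \code{bold}
#'   (a [BoldMatrix-class] of shape N x nVolumes).
#' @export
makeGroundTruthDataset <- function(sc, g, aSpec, band = c(0.04, 0.07),
                                   nVolumes = 300L, tr = 2, seed = 1L,
                                   beta = 0.02, dt = 0.1, transient = 60) {
    stopifnot(is(sc, "SCMatrix"))
    nyq <- 1 / (2 * tr)
    if (band[2] >= nyq)
        stop("band upper edge must lie below Nyquist = ", nyq, " Hz")
    n <- nRegions(sc)
    pars <- withSeed(seed, {
        omega <- 2 * pi * stats::runif(n, band[1], band[2])
        a <- switch(aSpec$mode,
            homogeneous = rep(aSpec$value, n),
            heterogeneous = stats::runif(n, aSpec$min, aSpec$max),
            stop("unknown aSpec mode: ", aSpec$mode))
        list(a = a, omega = omega)
    })
    spec <- hopfModelSpec(pars$a, pars$omega, g, sc, beta = beta, dt = dt)
    sim <- simulateHopf(spec, duration = transient + nVolumes * tr,
                        tr = tr, seed = subSeed(seed, 1L),
                        transient = transient)
    list(
        groundTruth = list(g = g, a = pars$a, omega = pars$omega,
                           hubIndices = sc@hubIndices,
                           seed = as.integer(seed)),
        bold = sim$bold
    )
}
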