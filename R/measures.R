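#' Integration of a mean phase-interaction matrix
#'
#' Scans binarization thresholds over the threshold grid
#' \code{seq(0, 1 - thresholdStep, by = thresholdStep)}; at each threshold
#' the matrix is binarized (entry strictly greater than the threshold) and
#' the size of the largest connected component, as a fraction of N, is
#' recorded. Integration is the mean of that curve — the normalized integral
#' of largest-component size over thresholds, in [1/N, 1].
#'
#' A fully coherent matrix (all off-diagonal entries 1) gives integration 1;
#' a fully incoherent one (all 0) gives 1/N; two disconnected equal cliques
#' give 1/2.
#'
#' @param meanP symmetric N x N matrix (typically the bias-corrected
#'   time-averaged phase-interaction matrix).
#' @param thresholdStep grid resolution (default 0.01).
#' @return scalar integration value in [0, 1].
#' @export
integration <- function(meanP, thresholdStep = 0.01) {
    meanP <- as.matrix(meanP)
    if (nrow(meanP) != ncol(meanP)) stop("'meanP' must be square")
    n <- nrow(meanP)
    thr <- seq(0, 1 - thresholdStep, by = thresholdStep)
    sizes <- vapply(thr, function(th) {
        adj <- (meanP > th)
        diag(adj) <- FALSE
        gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        max(igraph::components(gr)$csize) / n
    }, numeric(1))
    mean(sizes)
}

#' Newman modularity of a binary graph via Louvain detection
#'
#' Runs Louvain community detection \code{restarts} times under a fixed seed
#' stream and returns the Newman modularity Q of the best partition found.
#'
#' @param adjacency symmetric binary (or logical) adjacency matrix.
#' @param seed integer seed controlling the Louvain restarts.
#' @param restarts best-of-k restarts (default 10).
#' @return scalar Q in [-0.5, 1].
#' @export
modularityQ <- function(adjacency, seed = 1L, restarts = 10L) {
    adj <- as.matrix(adjacency) != 0
    diag(adj) <- FALSE
    if (!any(adj)) {
        warning("graph has no edges; Q = 0")
        return(0)
    }
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    best <- -Inf
    for (k in seq_len(restarts)) {
        q <- withSeed(subSeed(seed, k), {
            cl <- igraph::cluster_louvain(gr)
            igraph::modularity(gr, igraph::membership(cl))
        })
        if (q > best) best <- q
    }
    best
}

#' Segregation: modularity of the significance-binarized mean interaction
#'
#' Pairs whose time-averaged phase interaction exceeds the (1 - alpha)
#' quantile of their own phase-randomized surrogate distribution are kept as
#' edges; Louvain community detection is then run on the binarized graph and
#' the Newman modularity Q of the best partition is returned. A large Q
#' means the phase interactions split into well-separated functional
#' modules.
#'
#' @param meanP raw (uncorrected) time-averaged phase-interaction matrix.
#' @param bold the [BoldMatrix-class] the matrix was computed from.
#' @param nSurrogates surrogate ensemble size; must be at least
#'   \code{1/alpha} so that the alpha quantile is resolvable (default 100).
#' @param alpha per-pair significance level (default 0.01).
#' @param seed integer seed (surrogates and Louvain restarts).
#' @param low,high,settle analysis-chain parameters, as in
#'   [meanPhaseInteraction()].
#' @param restarts Louvain best-of-k restarts (default 10).
#' @return scalar modularity Q; 0 (with a warning) if no pair survives.
#' @export
segregation <- function(meanP, bold, nSurrogates = 100L, alpha = 0.01,
                        seed = 1L, low = 0.04, high = 0.07, settle = 10L,
                        restarts = 10L) {
    if (nSurrogates < ceiling(1 / alpha))
        stop("need at least 1/alpha = ", ceiling(1 / alpha),
             " surrogates to resolve alpha = ", alpha)
    surr <- surrogateMeanInteractions(bold, nSurrogates, seed,
                                      low, high, settle)
    crit <- apply(surr, c(2L, 3L), stats::quantile, probs = 1 - alpha,
                  names = FALSE)
    adj <- meanP > crit
    diag(adj) <- FALSE
    adj <- adj & t(adj)
    modularityQ(adj, seed = seed, restarts = restarts)
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Divides the phase-interaction series into sliding windows of
#' \code{window} volumes shifted by \code{step}; for each window the
#' window-mean interaction matrix is vectorized (strict upper triangle) and
#' all window pairs are compared by cosine similarity, giving a symmetric
#' M x M matrix with unit diagonal. Large off-diagonal values mean the
#' synchronization pattern recurs in time.
#'
#' @param series a [PhaseInteractionSeries-class].
#' @param window window length in TRs (default 30).
#' @param step window shift in TRs (default 1, i.e. one TR).
#' @return an [FCDMatrix-class].
#' @export
fcd <- function(series, window = 30L, step = 1L) {
    stopifnot(is(series, "PhaseInteractionSeries"))
    tens <- series@tensor
    T <- dim(tens)[3]
    window <- as.integer(window); step <- as.integer(step)
    if (T < window)
        stop("series too short: ", T, " volumes < window of ", window)
    n <- dim(tens)[1]
    ut <- upper.tri(matrix(0, n, n))
    starts <- seq.int(1L, T - window + 1L, by = step)
    V <- vapply(starts, function(s) {
        m <- rowMeans(tens[, , s:(s + window - 1L), drop = FALSE], dims = 2L)
        m[ut]
    }, numeric(sum(ut)))
    V <- t(V)                              # windows x pairs
    norms <- sqrt(rowSums(V^2))
    if (any(norms == 0)) stop("degenerate all-zero window pattern")
    V <- V / norms
    sim <- tcrossprod(V)
    sim <- (sim + t(sim)) / 2
    sim[sim > 1] <- 1; sim[sim < -1] <- -1
    diag(sim) <- 1
    new("FCDMatrix", similarity = sim, window = window, step = step)
}

#' Mean FCD
#'
#' Mean of the strict upper triangle of the FCD matrix — the average
#' similarity between synchronization patterns at different times.
#'
#' @param fcdm an [FCDMatrix-class].
#' @param excludeOverlap if \code{TRUE}, drop window pairs that share
#'   samples (centres closer than one window length); default \code{FALSE},
#'   i.e. all off-diagonal pairs are included.
#' @return scalar mean similarity in [-1, 1].
#' @export
meanFCD <- function(fcdm, excludeOverlap = FALSE) {
    stopifnot(is(fcdm, "FCDMatrix"))
    s <- fcdm@similarity
    keep <- upper.tri(s)
    if (excludeOverlap) {
        M <- nrow(s)
        lag <- abs(outer(seq_len(M), seq_len(M), "-")) * fcdm@step
        keep <- keep & (lag >= fcdm@window)
        if (!any(keep))
            stop("no non-overlapping window pairs available")
    }
    mean(s[keep])
}

#' Grand-average Pearson functional connectivity
#'
#' Pairwise Pearson correlations between all region pairs, Fisher
#' z-transformed (atanh). The diagonal is masked with NA; correlations at
#' the +/-1 boundary are capped before the transform so the result stays
#' finite. Regions with zero variance yield NA rows/columns with a warning.
#'
#' @param bold a [BoldMatrix-class].
#' @return N x N numeric matrix of z-values with NA diagonal.
#' @export
pearsonFC <- function(bold) {
    stopifnot(is(bold, "BoldMatrix"))
    x <- bold@values
    v <- apply(x, 1L, stats::var)
    bad <- which(v == 0)
    r <- suppressWarnings(stats::cor(t(x)))
    if (length(bad)) {
        warning("zero-variance region(s): ", paste(bad, collapse = ", "),
                "; correlations undefined (NA)")
        r[bad, ] <- NA_real_
        r[, bad] <- NA_real_
    }
    cap <- 1 - 1e-7
    r[r > cap] <- cap
    r[r < -cap] <- -cap
    z <- atanh(r)
    diag(z) <- NA_real_
    z
}

#' Summary of the four global phase-dynamics statistics
#'
#' Convenience wrapper computing, for one subject's BOLD matrix:
#' integration (on the bias-corrected mean interaction), segregation,
#' phase-interaction fluctuations m, and mean FCD.
#'
#' @param bold a [BoldMatrix-class].
#' @param low,high narrowband edges in Hz (defaults 0.04, 0.07).
#' @param settle edge margin in volumes (default 10).
#' @param window,step FCD window length and shift in TRs (defaults 30, 1).
#' @param nSurrogates surrogates for bias correction and significance
#'   binarization (default 100).
#' @param alpha significance level for segregation (default 0.01).
#' @param seed integer seed.
#' @return list with components \code{integration}, \code{segregation},
#'   \code{fluctuations}, \code{meanFCD}.
#' @export
dynamicsSummary <- function(bold, low = 0.04, high = 0.07, settle = 10L,
                            window = 30L, step = 1L, nSurrogates = 100L,
                            alpha = 0.01, seed = 1L) {
    mp <- meanPhaseInteraction(bold, low, high, settle)
    mpc <- biasCorrectMeanInteraction(mp, bold, nSurrogates, seed,
                                      low, high, settle)
    series <- phaseInteractions(
        instantaneousPhases(bandpassFilter(bold, low, high)), settle)
    gs <- globalSynchrony(series)
    fc <- fcd(series, window, step)
    list(
        integration = integration(mpc),
        segregation = segregation(mp, bold, nSurrogates, alpha, seed,
                                  low, high, settle),
        fluctuations = gs$m,
        meanFCD = meanFCD(fc)
    )
}
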