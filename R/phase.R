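#' Zero-phase band-pass filtering of BOLD signals
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (\code{signal::filtfilt}; effective fourth order, zero phase lag) to each
#' region's time series. Zero-phase filtering matters here because the
#' downstream statistics are built from instantaneous phases.
#'
#' @param bold a [BoldMatrix-class].
#' @param low,high band edges in Hz; must satisfy
#'   \code{0 < low < high < 1/(2*tr)}.
#' @return a [BoldMatrix-class] of the same shape, each row band-passed and
#'   (as a consequence) approximately zero-mean.
#' @examples
#' tt <- seq(0, 598, by = 2)
#' b <- boldMatrix(rbind(sin(2 * pi * 0.055 * tt)), tr = 2)
#' f <- bandpassFilter(b, 0.04, 0.07)
#' @export
bandpassFilter <- function(bold, low, high) {
    stopifnot(is(bold, "BoldMatrix"))
    nyq <- 1 / (2 * bold@tr)
    if (!(low > 0 && low < high && high < nyq))
        stop("band edges must satisfy 0 < low < high < Nyquist (",
             format(nyq), " Hz)")
    x <- bold@values
    if (ncol(x) < 24L)
        stop("time series too short for stable band-pass filtering (",
             ncol(x), " volumes)")
    bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
    out <- t(apply(x, 1L, function(r)
        signal::filtfilt(bf, r - mean(r))))
    boldMatrix(out, bold@tr)
}

#' Instantaneous phases via the Hilbert transform
#'
#' Computes, per region, the argument of the analytic signal
#' z(t) = s(t) + i H[s(t)] of the (already band-passed) series s(t). Phases
#' are wrapped to (-pi, pi].
#'
#' @param filtered a band-passed [BoldMatrix-class].
#' @return a [PhaseMatrix-class].
#' @examples
#' tt <- seq(0, 598, by = 2)
#' b <- boldMatrix(rbind(cos(2 * pi * 0.05 * tt)), tr = 2)
#' ph <- instantaneousPhases(bandpassFilter(b, 0.04, 0.07))
#' @export
instantaneousPhases <- function(filtered) {
    stopifnot(is(filtered, "BoldMatrix"))
    x <- filtered@values
    rms <- sqrt(rowMeans(x^2))
    if (any(rms < .Machine$double.eps * 1e3))
        stop("undefined phase: region(s) ",
             paste(which(rms < .Machine$double.eps * 1e3), collapse = ", "),
             " have (near-)zero signal")
    ph <- t(apply(x, 1L, function(r) Arg(analyticSignal(r))))
    # Arg returns [-pi, pi]; fold -pi onto +pi to match the open interval
    ph[ph <= -pi] <- pi
    new("PhaseMatrix", phases = ph, tr = filtered@tr)
}

#' Phase-interaction matrices P(t)
#'
#' For every time point t builds the N x N matrix
#' P_jk(t) = cos(|phi_j(t) - phi_k(t)|): 1 for in-phase pairs, 0 for
#' orthogonal pairs, -1 for anti-phase pairs. Since cosine is even this
#' equals cos(phi_j - phi_k); the absolute difference is used so symmetry is
#' exact in floating point.
#'
#' @param phases a [PhaseMatrix-class].
#' @param settle number of volumes to discard at each end before building
#'   the series (default 10), protecting the statistics from filter/Hilbert
#'   edge transients. Use 0 to keep all samples.
#' @return a [PhaseInteractionSeries-class].
#' @export
phaseInteractions <- function(phases, settle = 10L) {
    stopifnot(is(phases, "PhaseMatrix"))
    p <- phases@phases
    T <- ncol(p)
    settle <- as.integer(settle)
    if (T - 2L * settle < 2L)
        stop("too few volumes (", T, ") for settle margin ", settle)
    keep <- seq.int(settle + 1L, T - settle)
    n <- nrow(p)
    out <- array(0, dim = c(n, n, length(keep)))
    for (i in seq_along(keep)) {
        d <- abs(outer(p[, keep[i]], p[, keep[i]], "-"))
        out[, , i] <- cos(d)
    }
    new("PhaseInteractionSeries", tensor = out, tr = phases@tr)
}

#' Global synchrony r(t) and its fluctuations m
#'
#' r(t) is the mean of the strict upper triangle of P(t) — the average
#' pairwise phase interaction at each volume. Its temporal standard
#' deviation m (population convention, divide by T) quantifies
#' phase-interaction fluctuations: a fully synchronized network has
#' r(t) = 1 at every t and m = 0.
#'
#' @param series a [PhaseInteractionSeries-class] with at least 2 regions.
#' @return a list with components \code{r} (length-T numeric) and \code{m}
#'   (non-negative scalar, \code{m = sd_pop(r)}).
#' @export
globalSynchrony <- function(series) {
    stopifnot(is(series, "PhaseInteractionSeries"))
    n <- dim(series@tensor)[1]
    if (n < 2) stop("at least 2 regions are required")
    ut <- upper.tri(matrix(0, n, n))
    r <- apply(series@tensor, 3L, function(m) mean(m[ut]))
    m <- sqrt(mean((r - mean(r))^2))
    list(r = r, m = m)
}

#' Phase-randomized surrogate signals
#'
#' Replaces the phases of each region's Fourier coefficients with i.i.d.
#' uniform random phases while preserving the amplitude spectrum exactly,
#' destroying phase relationships but keeping each series' power spectrum
#' (and hence autocorrelation). Random phases are assigned on the half
#' spectrum and mirrored conjugate-symmetrically, with the DC and (for even
#' T) Nyquist bins left untouched, so the surrogate is exactly real-valued.
#'
#' @param bold a [BoldMatrix-class].
#' @param seed integer seed; the surrogate is a pure function of
#'   (\code{bold}, \code{seed}).
#' @return a [BoldMatrix-class] of the same shape.
#' @export
phaseRandomizedSurrogate <- function(bold, seed) {
    stopifnot(is(bold, "BoldMatrix"))
    x <- bold@values
    T <- ncol(x)
    nHalf <- if (T %% 2 == 0) T / 2 - 1 else (T - 1) / 2
    out <- withSeed(seed, {
        o <- x
        for (j in seq_len(nrow(x))) {
            X <- stats::fft(x[j, ])
            if (nHalf > 0) {
                phi <- stats::runif(nHalf, -pi, pi)
                idx <- 2:(nHalf + 1)
                X[idx] <- Mod(X[idx]) * exp(1i * phi)
                X[T + 2 - idx] <- Conj(X[idx])
            }
            o[j, ] <- Re(stats::fft(X, inverse = TRUE) / T)
        }
        o
    })
    boldMatrix(out, bold@tr)
}

#' Time-averaged phase-interaction matrix of a BOLD matrix
#'
#' Runs the full chain band-pass -> Hilbert phases -> P(t) -> time average.
#' The average is computed through the identity
#' mean_t cos(phi_j - phi_k) = Re(E E^H)/T with E = exp(i phi), which avoids
#' materializing the full tensor.
#'
#' @param bold a [BoldMatrix-class] (raw, unfiltered).
#' @param low,high band edges in Hz (defaults 0.04 and 0.07).
#' @param settle edge margin in volumes discarded before averaging
#'   (default 10).
#' @return symmetric N x N numeric matrix with unit diagonal.
#' @export
meanPhaseInteraction <- function(bold, low = 0.04, high = 0.07,
                                 settle = 10L) {
    ph <- instantaneousPhases(bandpassFilter(bold, low, high))
    p <- ph@phases
    T <- ncol(p)
    keep <- seq.int(settle + 1L, T - settle)
    E <- exp(1i * p[, keep, drop = FALSE])
    m <- Re(E %*% Conj(t(E))) / length(keep)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
}

#' Surrogate bias correction of the mean phase-interaction matrix
#'
#' Time-averaged phase interactions are positively biased at finite T even
#' for unrelated signals. The correction subtracts the expected interaction
#' under the phase-randomized null: the full analysis chain is applied to
#' each of \code{nSurrogates} surrogate datasets and the ensemble mean of
#' their time-averaged P matrices is subtracted from \code{meanP}.
#'
#' @param meanP N x N time-averaged phase-interaction matrix (as returned by
#'   [meanPhaseInteraction()]).
#' @param bold the [BoldMatrix-class] the matrix was computed from.
#' @param nSurrogates ensemble size (>= 1; default 19).
#' @param seed integer master seed for the surrogate ensemble.
#' @param low,high,settle analysis-chain parameters; keep identical to those
#'   used for \code{meanP}.
#' @return bias-corrected symmetric N x N matrix (diagonal zeroed: the
#'   self-interaction carries no information after correction).
#' @export
biasCorrectMeanInteraction <- function(meanP, bold, nSurrogates = 19L,
                                       seed = 1L, low = 0.04, high = 0.07,
                                       settle = 10L) {
    stopifnot(nSurrogates >= 1)
    n <- nrow(meanP)
    acc <- matrix(0, n, n)
    for (s in seq_len(nSurrogates)) {
        surr <- phaseRandomizedSurrogate(bold, seed = subSeed(seed, s))
        acc <- acc + meanPhaseInteraction(surr, low, high, settle)
    }
    out <- meanP - acc / nSurrogates
    out <- (out + t(out)) / 2
    diag(out) <- 0
    out
}

#' Per-pair surrogate distribution of time-averaged phase interactions
#'
#' Returns the nSurrogates x N x N stack of time-averaged P matrices of
#' phase-randomized surrogates; used for significance binarization in
#' [segregation()].
#'
#' @inheritParams biasCorrectMeanInteraction
#' @return array of dimension \code{c(nSurrogates, N, N)}.
#' @keywords internal
surrogateMeanInteractions <- function(bold, nSurrogates, seed,
                                      low = 0.04, high = 0.07,
                                      settle = 10L) {
    n <- nrow(bold@values)
    out <- array(0, dim = c(nSurrogates, n, n))
    for (s in seq_len(nSurrogates)) {
        surr <- phaseRandomizedSurrogate(bold, seed = subSeed(seed, s))
        out[s, , ] <- meanPhaseInteraction(surr, low, high, settle)
    }
    out
}
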