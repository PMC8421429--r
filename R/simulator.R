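#' Simulate the coupled Stuart-Landau (Hopf) network
#'
#' Integrates the complex stochastic system
#' \deqn{dz_j = [z_j((a_j + i w_j) - |z_j|^2) +
#'   g \sum_k C_{jk} (z_k - z_j)] dt + \beta dW_j}
#' with the Euler-Maruyama scheme (noise increments scaled by sqrt(dt),
#' independent Gaussian components on the real and imaginary parts, each
#' with standard deviation \code{beta}). Internally the drift uses the
#' strength-absorbed form (a - gS + iw) z + g C z, which is algebraically
#' identical; in \code{effectiveMode} the slot \code{a} already holds
#' a_eff = a - gS and the leak term is skipped. BOLD is modelled as the real
#' part of z, sampled every \code{tr} seconds after discarding the initial
#' transient.
#'
#' @param spec a [HopfModelSpec-class].
#' @param duration total simulated time in seconds (including the
#'   transient).
#' @param tr sampling interval of the returned BOLD (seconds); must be a
#'   multiple of \code{spec@dt}.
#' @param seed integer seed; the trajectory is a pure function of
#'   (\code{spec}, \code{duration}, \code{tr}, \code{seed}, \code{z0}).
#' @param transient initial seconds discarded (default 60).
#' @param z0 optional complex initial state (length N); by default drawn
#'   from the seed as small complex Gaussian values (sd 0.1).
#' @return list with components \code{bold} (a [BoldMatrix-class]),
#'   \code{seed}, and \code{transient} (seconds discarded).
#' @examples
#' sc <- generateCorePeripherySC(10, 2, hubFactor = 3, density = .5, seed = 1)
#' spec <- hopfModelSpec(a = 0, omega = 2 * pi * 0.05, g = 1.5, C = sc)
#' sim <- simulateHopf(spec, duration = 360, tr = 2, seed = 1)
#' @export
simulateHopf <- function(spec, duration, tr, seed, transient = 60,
                         z0 = NULL) {
    stopifnot(is(spec, "HopfModelSpec"))
    dt <- spec@dt
    stepsPerTr <- tr / dt
    if (abs(stepsPerTr - round(stepsPerTr)) > 1e-9)
        stop("'tr' must be a multiple of the integration step dt = ", dt)
    stepsPerTr <- as.integer(round(stepsPerTr))
    nVol <- floor((duration - transient) / tr)
    if (nVol < 1) stop("duration must exceed the transient by at least one TR")
    n <- spec@n
    S <- rowSums(spec@connectivity@weights)
    growth <- if (spec@effectiveMode) spec@a else spec@a - spec@g * S
    lam <- growth + 1i * spec@omega
    C <- spec@connectivity@weights
    g <- spec@g
    beta <- spec@beta
    sq <- sqrt(dt)
    nTransSteps <- as.integer(round(transient / dt))
    nSteps <- nTransSteps + nVol * stepsPerTr
    withSeed(seed, {
        z <- if (is.null(z0))
            complex(real = stats::rnorm(n, 0, 0.1),
                    imaginary = stats::rnorm(n, 0, 0.1))
        else as.complex(z0)
        out <- matrix(0, n, nVol)
        col <- 0L
        for (s in seq_len(nSteps)) {
            dz <- z * (lam - Mod(z)^2) + g * (C %*% z)[, 1]
            z <- z + dt * dz +
                beta * sq * complex(real = stats::rnorm(n),
                                    imaginary = stats::rnorm(n))
            if (any(Mod(z) > 1e3))
                stop("simulation diverged (|z| > 1e3); reduce dt = ", dt,
                     " or check the bifurcation parameters")
            if (s > nTransSteps && (s - nTransSteps) %% stepsPerTr == 0L) {
                col <- col + 1L
                out[, col] <- Re(z)
            }
        }
        list(bold = boldMatrix(out, tr), seed = as.integer(seed),
             transient = transient)
    })
}

#' Intrinsic node frequencies from narrowband BOLD
#'
#' For each region, band-passes every subject's series to \code{band},
#' locates the power-spectral peak (Welch estimate) inside the band and
#' averages the peak frequency across subjects — the model's omega_j.
#'
#' @param boldList list of [BoldMatrix-class] objects sharing N and tr.
#' @param band numeric length-2 Hz interval (default c(0.04, 0.07)).
#' @return list with \code{freqHz} (length-N vector, Hz) and \code{omega}
#'   (rad/s).
#' @export
estimateIntrinsicFrequencies <- function(boldList, band = c(0.04, 0.07)) {
    stopifnot(length(boldList) >= 1)
    n <- nRegions(boldList[[1]])
    fs <- 1 / boldList[[1]]@tr
    peaks <- matrix(NA_real_, length(boldList), n)
    for (s in seq_along(boldList)) {
        filt <- bandpassFilter(boldList[[s]], band[1], band[2])
        for (j in seq_len(n)) {
            psd <- welchPsd(filt@values[j, ], fs)
            keep <- psd$freq >= band[1] & psd$freq <= band[2]
            if (!any(keep) || all(psd$power[keep] == 0)) {
                warning("flat in-band spectrum for region ", j,
                        "; using band centre")
                peaks[s, j] <- mean(band)
            } else {
                f <- psd$freq[keep]
                peaks[s, j] <- f[which.max(psd$power[keep])]
            }
        }
    }
    freqHz <- colMeans(peaks)
    list(freqHz = freqHz, omega = 2 * pi * freqHz)
}

#' Proportion of spectral power in the narrow band
#'
#' p_j = (power in \code{narrowBand}) / (power in \code{wideBand}), with
#' band edges clipped to Nyquist. Each series is mean-removed and its power
#' spectrum estimated by Welch's method (Hann taper, 50\% overlap, segment
#' length \code{min(128, T/4)}); the two band powers are integrals of that
#' one spectrum, so no band-edge filter shaping enters the ratio (a flat
#' spectrum gives exactly the bandwidth ratio in expectation).
#'
#' @param bold a [BoldMatrix-class].
#' @param nodes regions to evaluate (default all).
#' @param narrowBand numerator band in Hz (default c(0.04, 0.07)).
#' @param wideBand denominator band in Hz (default c(0.04, 0.25)).
#' @return numeric vector of fractions in [0, 1], one per requested node.
#' @export
powerProportion <- function(bold, nodes = NULL,
                            narrowBand = c(0.04, 0.07),
                            wideBand = c(0.04, 0.25)) {
    stopifnot(is(bold, "BoldMatrix"))
    nyq <- 1 / (2 * bold@tr)
    wideBand[2] <- min(wideBand[2], nyq)
    narrowBand[2] <- min(narrowBand[2], nyq)
    if (is.null(nodes)) nodes <- seq_len(nRegions(bold))
    fs <- 1 / bold@tr
    vapply(nodes, function(j) {
        x <- bold@values[j, ]
        psd <- welchPsd(x - mean(x), fs)
        tot <- bandPower(psd, wideBand)
        if (tot <= 0) stop("zero wide-band power for region ", j,
                           "; power proportion undefined")
        bandPower(psd, narrowBand) / tot
    }, numeric(1))
}
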