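# Internal helpers: seeded evaluation, analytic signal, Welch PSD.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic sub-seed stream; stays inside 32-bit integer range.
subSeed <- function(master, i) {
    as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %%
        2147483647)
}

# Analytic signal z(t) = s(t) + i H[s(t)] via the FFT half-spectrum method:
# double the positive-frequency coefficients, keep DC (and Nyquist for even
# T) untouched, zero the negative frequencies.
analyticSignal <- function(x) {
    n <- length(x)
    X <- stats::fft(x)
    h <- numeric(n)
    if (n %% 2 == 0) {
        h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
    } else {
        h[1] <- 1; h[2:((n + 1) / 2)] <- 2
    }
    stats::fft(X * h, inverse = TRUE) / n
}

# Strict upper-triangle values of a square matrix.
upperTriValues <- function(m) m[upper.tri(m)]

# Welch averaged-periodogram PSD: Hann-tapered segments, 50% overlap.
# Returns freq (Hz) and power (arbitrary units; only ratios are used).
welchPsd <- function(x, fs, segLength = NULL) {
    n <- length(x)
    if (is.null(segLength)) segLength <- min(128L, floor(n / 4))
    segLength <- max(8L, min(as.integer(segLength), n))
    step <- max(1L, segLength %/% 2L)
    starts <- seq(1L, n - segLength + 1L, by = step)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))
    nf <- segLength %/% 2L + 1L
    acc <- numeric(nf)
    for (s in starts) {
        seg <- x[s:(s + segLength - 1L)]
        seg <- (seg - mean(seg)) * win
        P <- Mod(stats::fft(seg))^2
        acc <- acc + P[seq_len(nf)]
    }
    list(freq = (seq_len(nf) - 1L) * fs / segLength,
         power = acc / length(starts))
}

# Band-limited power from a Welch PSD (trapezoidal sum over bins in band).
bandPower <- function(psd, band) {
    keep <- psd$freq >= band[1] & psd$freq <= band[2]
    sum(psd$power[keep])
}
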