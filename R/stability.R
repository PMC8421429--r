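#' Jacobian of the coupled Hopf system at z = 0
#'
#' A = diag(a - gS + iw) + gC: each diagonal entry combines the node's
#' growth rate, the diffusive leak through its strength S_j and its
#' intrinsic frequency; off-diagonal entries are the scaled structural
#' couplings. In effective parameterization the leak is already inside a,
#' so the diagonal is a_eff + iw. Row sums of the real parts recover a_j
#' exactly (the strength cancels against the couplings).
#'
#' @param spec a [HopfModelSpec-class].
#' @return N x N complex matrix.
#' @export
buildJacobian <- function(spec) {
    stopifnot(is(spec, "HopfModelSpec"))
    S <- rowSums(spec@connectivity@weights)
    diagPart <- if (spec@effectiveMode) spec@a else spec@a - spec@g * S
    A <- spec@g * spec@connectivity@weights + 0i
    diag(A) <- diagPart + 1i * spec@omega
    A
}

#' Sorted eigen-decomposition of a Jacobian
#'
#' Eigenvalues and eigenvectors sorted ascending by real part (most stable
#' mode first). Eigenvectors are normalized to unit Euclidean norm and
#' phase-fixed so that the largest-magnitude component is real and
#' positive, making the reported vectors reproducible. The system is stable
#' iff every eigenvalue has negative real part.
#'
#' @param A square complex (or real) matrix.
#' @return a [StabilityResult-class].
#' @export
eigendecomposeSorted <- function(A) {
    A <- as.matrix(A)
    if (nrow(A) != ncol(A)) stop("'A' must be square")
    e <- eigen(A)
    ord <- order(Re(e$values))
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
    for (k in seq_len(ncol(vecs))) {
        v <- vecs[, k]
        v <- v / sqrt(sum(Mod(v)^2))
        imax <- which.max(Mod(v))
        rot <- Conj(v[imax]) / Mod(v[imax])
        vecs[, k] <- v * rot
    }
    res <- A %*% vecs - vecs %*% diag(vals, nrow = length(vals))
    if (max(Mod(res)) > 1e-8)
        stop("eigen-decomposition residual exceeds 1e-8 (max ",
             format(max(Mod(res))), ")")
    new("StabilityResult",
        eigenvalues = as.complex(vals),
        vectors = vecs,
        eigenvectorMagnitudes = Mod(vecs),
        stable = max(Re(vals)) < 0)
}

#' Hub contribution to the most stable eigenvectors
#'
#' For the k most stable modes (lowest real parts) computes the Pearson
#' correlation between eigenvector component magnitudes and node strengths:
#' a positive correlation means the structural hubs dominate the most
#' stable directions of the linearized dynamics. Also reports the stability
#' depth min Re(lambda).
#'
#' @param result a [StabilityResult-class].
#' @param strengths length-N node strengths (non-constant).
#' @param kDominant number of most-stable eigenvectors to summarize
#'   (default 5, capped at N).
#' @return list with \code{correlations} (length-k vector, most stable
#'   first), \code{minReal} (stability depth) and \code{kDominant}.
#' @export
hubStabilitySummary <- function(result, strengths, kDominant = 5L) {
    stopifnot(is(result, "StabilityResult"))
    n <- length(result@eigenvalues)
    if (length(strengths) != n)
        stop("'strengths' must have length ", n)
    if (stats::sd(strengths) == 0)
        stop("correlation undefined: strengths are constant")
    kDominant <- min(as.integer(kDominant), n)
    cors <- vapply(seq_len(kDominant), function(k)
        stats::cor(result@eigenvectorMagnitudes[, k], strengths),
        numeric(1))
    list(correlations = cors,
         minReal = min(Re(result@eigenvalues)),
         kDominant = kDominant)
}
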