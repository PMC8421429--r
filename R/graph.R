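#' Node strengths of a structural connectome
#'
#' S_j = sum_k C_jk, the total weight of the links a node makes.
#'
#' @param sc an [SCMatrix-class] (or a plain symmetric matrix).
#' @return numeric length-N vector.
#' @export
nodeStrengths <- function(sc) {
    w <- if (is(sc, "SCMatrix")) sc@weights else as.matrix(sc)
    rowSums(w)
}

#' Detect hub regions by strength threshold
#'
#' Hubs are nodes whose strength strictly exceeds the threshold. The
#' default 4.5 is meaningful on the normalization scale of empirical
#' fibre-density connectomes; for synthetic matrices pass a threshold on
#' their own strength scale.
#'
#' @param strengths numeric vector of node strengths.
#' @param threshold strength cutoff (default 4.5).
#' @return integer vector of hub indices (possibly empty).
#' @export
detectHubs <- function(strengths, threshold = 4.5) {
    which(strengths > threshold)
}

#' Weighted k-density (rich-club) curve
#'
#' For each threshold S' on the grid \code{seq(0, sMax, by = step)}, keeps
#' the nodes whose full-matrix strength exceeds S' (strengths are computed
#' once and not re-pruned) and records rho(S') — the average off-diagonal
#' weight among the surviving nodes. A curve that rises with S' signals a
#' rich club: the stronger nodes are also more densely interconnected. The
#' curve is cut off once fewer than 2 nodes survive.
#'
#' @param sc an [SCMatrix-class].
#' @param sMax upper end of the strength grid (default 10).
#' @param step grid increment (default 0.2).
#' @param existingOnly if \code{TRUE}, average only over non-zero weights
#'   rather than all surviving pairs (default \code{FALSE}).
#' @return data.frame with columns \code{sPrime} and \code{rho} (rho is NA
#'   beyond the cutoff); the attribute \code{"cutoff"} holds the first
#'   threshold with fewer than 2 survivors (or NA if none).
#' @export
kDensity <- function(sc, sMax = 10, step = 0.2, existingOnly = FALSE) {
    stopifnot(is(sc, "SCMatrix"), step > 0)
    w <- sc@weights
    S <- rowSums(w)
    grid <- seq(0, sMax, by = step)
    rho <- rep(NA_real_, length(grid))
    cutoff <- NA_real_
    for (i in seq_along(grid)) {
        # the scan starts from the full network; pruning is strict above 0
        keep <- if (grid[i] == 0) seq_along(S) else which(S > grid[i])
        if (length(keep) < 2) { cutoff <- grid[i]; break }
        sub <- w[keep, keep, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        if (existingOnly) vals <- vals[vals > 0]
        rho[i] <- if (length(vals)) mean(vals) else 0
    }
    out <- data.frame(sPrime = grid, rho = rho)
    attr(out, "cutoff") <- cutoff
    out
}

#' Mean link weight within hubs and within non-hubs
#'
#' @param sc an [SCMatrix-class].
#' @param hubIndices integer vector of hub nodes; both the hub and non-hub
#'   class must have at least 2 members for their mean to be defined
#'   (otherwise NA with a warning).
#' @return named numeric vector \code{c(hub = ..., nonhub = ...)} of mean
#'   off-diagonal weights within each class.
#' @export
hubVsNonhubWeights <- function(sc, hubIndices) {
    stopifnot(is(sc, "SCMatrix"))
    w <- sc@weights
    n <- nrow(w)
    hubIndices <- as.integer(hubIndices)
    non <- setdiff(seq_len(n), hubIndices)
    classMean <- function(idx, label) {
        if (length(idx) < 2) {
            warning("fewer than 2 ", label,
                    " nodes; within-class weight undefined")
            return(NA_real_)
        }
        sub <- w[idx, idx, drop = FALSE]
        mean(sub[upper.tri(sub)])
    }
    c(hub = classMean(hubIndices, "hub"),
      nonhub = classMean(non, "non-hub"))
}

#' Symmetrize and normalize a raw connectivity matrix
#'
#' Averages the matrix with its transpose, zeroes the diagonal, and divides
#' by the total link weight so entries represent link densities. With
#' \code{modelScale = TRUE} the result is additionally rescaled linearly so
#' its maximum entry is exactly 0.2, the scale used by the network model.
#'
#' @param cRaw square non-negative numeric matrix (possibly asymmetric,
#'   e.g. probabilistic tractography counts).
#' @param modelScale rescale the maximum to 0.2 (default \code{FALSE}).
#' @return an [SCMatrix-class].
#' @export
symmetrizeAndNormalize <- function(cRaw, modelScale = FALSE) {
    cRaw <- as.matrix(cRaw)
    if (nrow(cRaw) != ncol(cRaw)) stop("'cRaw' must be square")
    if (any(cRaw < 0)) stop("'cRaw' must be non-negative")
    w <- (cRaw + t(cRaw)) / 2
    diag(w) <- 0
    tot <- sum(w)
    if (tot == 0) stop("degenerate input: all-zero connectivity")
    w <- w / tot
    if (modelScale) w <- w * 0.2 / max(w)
    scMatrix(w)
}

#' Structural graph summary
#'
#' Bundles the graph-level descriptors used for the rich-club analysis:
#' strengths, hub set, k-density curve, and within-class mean weights.
#'
#' @param sc an [SCMatrix-class].
#' @param hubThreshold strength cutoff for hub detection (default 4.5).
#' @param sMax,step k-density grid (defaults 10 and 0.2).
#' @return list with \code{strengths}, \code{hubIndices},
#'   \code{kDensityCurve}, \code{hubMeanWeight}, \code{nonhubMeanWeight}.
#' @export
graphSummary <- function(sc, hubThreshold = 4.5, sMax = 10, step = 0.2) {
    S <- nodeStrengths(sc)
    hubs <- detectHubs(S, hubThreshold)
    kd <- kDensity(sc, sMax, step)
    hv <- if (length(hubs) >= 2 && length(S) - length(hubs) >= 2)
        hubVsNonhubWeights(sc, hubs)
    else c(hub = NA_real_, nonhub = NA_real_)
    list(strengths = S, hubIndices = hubs, kDensityCurve = kd,
         hubMeanWeight = unname(hv["hub"]),
         nonhubMeanWeight = unname(hv["nonhub"]))
}
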