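#' @import methods
NULL

#' Weighted structural connectome
#'
#' An \code{SCMatrix} holds a square, symmetric, non-negative weight matrix
#' describing the density of anatomical links between brain regions, with a
#' zero diagonal. When built for the network model the matrix is linearly
#' rescaled so that its maximum entry equals 0.2, which prevents full
#' synchronization of the coupled oscillators.
#'
#' @slot weights square numeric matrix of link weights (dimensionless).
#' @slot regionLabels character vector of region identifiers, one per node.
#' @slot hubIndices integer vector of designated hub nodes (may be empty;
#'   populated by the synthetic generator so that recovery tests have ground
#'   truth available).
#'
#' @seealso [scMatrix()], [generateCorePeripherySC()], [symmetrizeAndNormalize()]
#' @export
setClass("SCMatrix",
    slots = c(
        weights = "matrix",
        regionLabels = "character",
        hubIndices = "integer"
    )
)

setValidity("SCMatrix", function(object) {
    w <- object@weights
    msg <- character(0)
    if (!is.numeric(w) || nrow(w) != ncol(w))
        msg <- c(msg, "'weights' must be a square numeric matrix")
    else {
        if (any(!is.finite(w)))
            msg <- c(msg, "'weights' must be finite")
        else {
            if (any(w < 0)) msg <- c(msg, "'weights' must be non-negative")
            if (max(abs(w - t(w))) > 1e-12)
                msg <- c(msg, "'weights' must be symmetric")
            if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
        }
        if (length(object@regionLabels) != nrow(w))
            msg <- c(msg, "'regionLabels' length must match matrix dimension")
    }
    if (length(object@hubIndices) &&
        (any(object@hubIndices < 1) || any(object@hubIndices > nrow(w))))
        msg <- c(msg, "'hubIndices' out of range")
    if (length(msg)) msg else TRUE
})

#' Construct an SCMatrix
#'
#' @param weights square symmetric non-negative numeric matrix with zero
#'   diagonal.
#' @param regionLabels optional character labels (default \code{"R1"..."RN"}).
#' @param hubIndices optional integer vector of designated hubs.
#' @return an [SCMatrix-class] object.
#' @examples
#' w <- matrix(c(0, .1, .1, 0), 2)
#' scMatrix(w)
#' @export
scMatrix <- function(weights, regionLabels = NULL, hubIndices = integer(0)) {
    weights <- as.matrix(weights)
    storage.mode(weights) <- "double"
    if (is.null(regionLabels))
        regionLabels <- paste0("R", seq_len(nrow(weights)))
    new("SCMatrix", weights = weights, regionLabels = regionLabels,
        hubIndices = as.integer(hubIndices))
}

#' Region-by-time BOLD signal matrix
#'
#' Rows are brain regions, columns are volumes sampled every \code{tr}
#' seconds.
#'
#' @slot values numeric N x T matrix (arbitrary BOLD units).
#' @slot tr repetition time in seconds.
#' @seealso [boldMatrix()], [bandpassFilter()]
#' @export
setClass("BoldMatrix",
    slots = c(values = "matrix", tr = "numeric")
)

setValidity("BoldMatrix", function(object) {
    msg <- character(0)
    if (any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (length(object@tr) != 1 || object@tr <= 0)
        msg <- c(msg, "'tr' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct a BoldMatrix
#'
#' @param values numeric N x T matrix, regions in rows.
#' @param tr repetition time (seconds).
#' @return a [BoldMatrix-class] object.
#' @export
boldMatrix <- function(values, tr) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("BoldMatrix", values = values, tr = as.numeric(tr))
}

#' Instantaneous phase matrix
#'
#' Phases (radians, wrapped to (-pi, pi]) of the analytic signal of each
#' region's band-passed BOLD series.
#'
#' @slot phases numeric N x T matrix of radians.
#' @slot tr repetition time in seconds.
#' @seealso [instantaneousPhases()]
#' @export
setClass("PhaseMatrix",
    slots = c(phases = "matrix", tr = "numeric")
)

setValidity("PhaseMatrix", function(object) {
    p <- object@phases
    if (any(!is.finite(p))) return("'phases' must be finite")
    if (any(p <= -pi | p > pi)) return("'phases' must lie in (-pi, pi]")
    TRUE
})

#' Per-timepoint phase-interaction tensor
#'
#' Stacks, for every volume t, the N x N matrix P(t) whose (j,k) entry is the
#' cosine of the instantaneous phase difference between regions j and k.
#' Every slice is symmetric with unit diagonal and entries in [-1, 1].
#'
#' @slot tensor numeric N x N x T array.
#' @slot tr repetition time in seconds.
#' @seealso [phaseInteractions()], [globalSynchrony()], [fcd()]
#' @export
setClass("PhaseInteractionSeries",
    slots = c(tensor = "array", tr = "numeric")
)

setValidity("PhaseInteractionSeries", function(object) {
    d <- dim(object@tensor)
    if (length(d) != 3 || d[1] != d[2])
        return("'tensor' must be an N x N x T array")
    if (any(!is.finite(object@tensor)))
        return("'tensor' must be finite")
    if (max(abs(object@tensor)) > 1 + 1e-9)
        return("entries must lie in [-1, 1]")
    TRUE
})

#' Functional connectivity dynamics matrix
#'
#' Window-by-window cosine similarities between time-window-averaged
#' phase-interaction patterns. Symmetric with unit diagonal.
#'
#' @slot similarity numeric M x M matrix, M = number of sliding windows.
#' @slot window window length in TRs.
#' @slot step window shift in TRs.
#' @seealso [fcd()], [meanFCD()]
#' @export
setClass("FCDMatrix",
    slots = c(similarity = "matrix", window = "integer", step = "integer")
)

setValidity("FCDMatrix", function(object) {
    s <- object@similarity
    if (nrow(s) != ncol(s)) return("'similarity' must be square")
    if (max(abs(s)) > 1 + 1e-9) return("entries must lie in [-1, 1]")
    if (any(abs(diag(s) - 1) > 1e-9)) return("diagonal must equal 1")
    TRUE
})

#' Parameterization of the coupled Stuart-Landau network
#'
#' Full specification of the whole-brain Hopf model: node-wise bifurcation
#' parameters \code{a} (1/s), intrinsic angular frequencies \code{omega}
#' (rad/s), global coupling \code{g}, structural coupling matrix \code{C}
#' (max-scaled to 0.2), noise standard deviation \code{beta} and integration
#' step \code{dt}. When \code{effectiveMode} is \code{TRUE}, \code{a} is
#' interpreted as the effective parameter a_eff = a - g*S (the diffusive
#' leak -g*S_j*z_j already absorbed) and the coupling term is g*sum_k C_jk z_k;
#' otherwise \code{a} is the bare parameter and the coupling is diffusive,
#' g*sum_k C_jk (z_k - z_j). The two parameterizations are algebraically
#' identical when a_eff = a - g*S.
#'
#' @slot n number of nodes.
#' @slot a numeric length-N bifurcation parameters (1/s).
#' @slot omega numeric length-N intrinsic frequencies (rad/s).
#' @slot g non-negative global coupling.
#' @slot connectivity an [SCMatrix-class] (model-scaled; max entry 0.2).
#' @slot beta noise standard deviation (default 0.02).
#' @slot dt Euler-Maruyama integration step (seconds, default 0.1).
#' @slot effectiveMode logical; see description.
#' @seealso [hopfModelSpec()], [simulateHopf()], [buildJacobian()]
#' @export
setClass("HopfModelSpec",
    slots = c(
        n = "integer", a = "numeric", omega = "numeric", g = "numeric",
        connectivity = "SCMatrix", beta = "numeric", dt = "numeric",
        effectiveMode = "logical"
    )
)

setValidity("HopfModelSpec", function(object) {
    msg <- character(0)
    n <- object@n
    if (length(object@a) != n) msg <- c(msg, "'a' must have length n")
    if (length(object@omega) != n) msg <- c(msg, "'omega' must have length n")
    if (nrow(object@connectivity@weights) != n) msg <- c(msg, "dim(C) must equal n")
    if (object@g < 0) msg <- c(msg, "'g' must be non-negative")
    if (object@beta < 0) msg <- c(msg, "'beta' must be non-negative")
    if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a HopfModelSpec
#'
#' @param a bifurcation parameters: scalar (recycled) or length-N vector.
#' @param omega intrinsic angular frequencies (rad/s): scalar or length-N.
#' @param g global coupling (non-negative scalar).
#' @param C an [SCMatrix-class] coupling matrix.
#' @param beta noise standard deviation (default 0.02).
#' @param dt integration step in seconds (default 0.1).
#' @param effectiveMode interpret \code{a} as effective parameters
#'   (default \code{FALSE}).
#' @return a [HopfModelSpec-class] object.
#' @examples
#' sc <- generateCorePeripherySC(10, 2, hubFactor = 3, density = .5, seed = 1)
#' spec <- hopfModelSpec(a = 0, omega = 2 * pi * 0.05, g = 1.5, C = sc)
#' @export
hopfModelSpec <- function(a, omega, g, C, beta = 0.02, dt = 0.1,
                          effectiveMode = FALSE) {
    n <- nrow(C@weights)
    if (length(a) == 1) a <- rep(a, n)
    if (length(omega) == 1) omega <- rep(omega, n)
    new("HopfModelSpec", n = as.integer(n), a = as.numeric(a),
        omega = as.numeric(omega), g = as.numeric(g), connectivity = C,
        beta = as.numeric(beta), dt = as.numeric(dt),
        effectiveMode = isTRUE(effectiveMode))
}

#' Linear stability analysis result
#'
#' Eigen-decomposition of the Jacobian of the coupled system at the silent
#' fixed point z = 0, sorted ascending by the real part of the eigenvalues
#' (most stable first).
#'
#' @slot eigenvalues complex length-N vector, ascending by real part.
#' @slot vectors complex N x N matrix of unit-norm eigenvectors (columns),
#'   phase-fixed so the largest-magnitude component is real-positive.
#' @slot eigenvectorMagnitudes numeric N x N matrix of component magnitudes.
#' @slot stable logical; \code{TRUE} iff all real parts are negative.
#' @seealso [eigendecomposeSorted()], [hubStabilitySummary()]
#' @export
setClass("StabilityResult",
    slots = c(
        eigenvalues = "complex", vectors = "matrix",
        eigenvectorMagnitudes = "matrix", stable = "logical"
    )
)

setValidity("StabilityResult", function(object) {
    ev <- object@eigenvalues
    if (is.unsorted(Re(ev))) return("eigenvalues must be sorted by real part")
    if (!identical(object@stable, max(Re(ev)) < 0))
        return("'stable' inconsistent with eigenvalues")
    TRUE
})

#' Global-coupling fit result
#'
#' Grid scan of the global coupling g: for each candidate, simulated FCD
#' value distributions are compared with the empirical distribution by the
#' two-sample Kolmogorov-Smirnov distance, averaged over simulation trials.
#'
#' @slot gGrid candidate couplings.
#' @slot ksMean mean KS distance per candidate.
#' @slot ksSE standard error of the KS distance over trials.
#' @slot gOpt the candidate minimizing \code{ksMean} (ties: smallest g).
#' @slot trials number of simulation trials per candidate.
#' @slot seed master seed of the scan.
#' @seealso [fitGlobalCoupling()]
#' @export
setClass("GlobalFitResult",
    slots = c(
        gGrid = "numeric", ksMean = "numeric", ksSE = "numeric",
        gOpt = "numeric", trials = "integer", seed = "integer"
    )
)

setValidity("GlobalFitResult", function(object) {
    msg <- character(0)
    ok <- is.finite(object@ksMean)
    if (any(object@ksMean[ok] < 0 | object@ksMean[ok] > 1))
        msg <- c(msg, "KS values must lie in [0, 1]")
    if (!object@gOpt %in% object@gGrid)
        msg <- c(msg, "'gOpt' must belong to 'gGrid'")
    if (length(msg)) msg else TRUE
})

#' Node-wise bifurcation-parameter fit result
#'
#' Outcome of the iterative spectral fit of local parameters (bare a_j or
#' effective a_eff_j): final estimates, the per-iteration trace of the
#' maximum node-wise power-proportion mismatch, and a convergence flag.
#'
#' @slot aHat fitted length-N parameter vector.
#' @slot iterations iterations performed.
#' @slot trace numeric vector, max_j |p_emp_j - p_sim_j| per iteration.
#' @slot converged logical.
#' @slot eta learning rate used (default 0.1).
#' @slot effectiveMode whether a_eff (TRUE) or bare a (FALSE) was fitted.
#' @seealso [fitLocalBifurcation()], [fitEffectiveParameters()]
#' @export
setClass("LocalFitResult",
    slots = c(
        aHat = "numeric", iterations = "integer", trace = "numeric",
        converged = "logical", eta = "numeric", effectiveMode = "logical"
    )
)
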