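#' @describeIn SCMatrix-class number of regions
#' @param x an SCMatrix
#' @export
setMethod("nRegions", "SCMatrix", function(x) nrow(x@weights))

#' @describeIn BoldMatrix-class number of regions
#' @export
setMethod("nRegions", "BoldMatrix", function(x) nrow(x@values))

#' @describeIn PhaseMatrix-class number of regions
#' @export
setMethod("nRegions", "PhaseMatrix", function(x) nrow(x@phases))

#' @describeIn PhaseInteractionSeries-class number of regions
#' @export
setMethod("nRegions", "PhaseInteractionSeries", function(x) dim(x@tensor)[1])

#' @describeIn SCMatrix-class weight matrix accessor
#' @export
setMethod("scWeights", "SCMatrix", function(x) x@weights)

#' @describeIn BoldMatrix-class value matrix accessor
#' @export
setMethod("signalValues", "BoldMatrix", function(x) x@values)

#' @describeIn PhaseMatrix-class phase matrix accessor
#' @export
setMethod("signalValues", "PhaseMatrix", function(x) x@phases)

#' @describeIn BoldMatrix-class repetition time accessor
#' @export
setMethod("repetitionTime", "BoldMatrix", function(x) x@tr)

#' @describeIn PhaseMatrix-class repetition time accessor
#' @export
setMethod("repetitionTime", "PhaseMatrix", function(x) x@tr)

#' @describeIn PhaseInteractionSeries-class repetition time accessor
#' @export
setMethod("repetitionTime", "PhaseInteractionSeries", function(x) x@tr)

setMethod("show", "SCMatrix", function(object) {
    w <- object@weights
    cat("SCMatrix with", nrow(w), "regions\n")
    cat("  max weight:", format(max(w), digits = 4),
        " mean strength:", format(mean(rowSums(w)), digits = 4), "\n")
    if (length(object@hubIndices))
        cat("  designated hubs:", paste(object@hubIndices, collapse = ", "), "\n")
})

setMethod("show", "BoldMatrix", function(object) {
    cat("BoldMatrix:", nrow(object@values), "regions x",
        ncol(object@values), "volumes (TR =", object@tr, "s)\n")
})

setMethod("show", "PhaseMatrix", function(object) {
    cat("PhaseMatrix:", nrow(object@phases), "regions x",
        ncol(object@phases), "volumes (TR =", object@tr, "s)\n")
})

setMethod("show", "PhaseInteractionSeries", function(object) {
    d <- dim(object@tensor)
    cat("PhaseInteractionSeries:", d[1], "x", d[2], "x", d[3],
        "(regions x regions x volumes)\n")
})

setMethod("show", "FCDMatrix", function(object) {
    cat("FCDMatrix:", nrow(object@similarity), "windows (window =",
        object@window, "TRs, step =", object@step, "TRs)\n")
    cat("  mean off-diagonal similarity:",
        format(meanFCD(object), digits = 4), "\n")
})

setMethod("show", "HopfModelSpec", function(object) {
    cat("HopfModelSpec with", object@n, "nodes\n")
    cat("  g =", object@g, " beta =", object@beta, " dt =", object@dt, "s\n")
    cat("  a in [", format(min(object@a), digits = 3), ",",
        format(max(object@a), digits = 3), "]  f in [",
        format(min(object@omega) / (2 * pi), digits = 3), ",",
        format(max(object@omega) / (2 * pi), digits = 3), "] Hz\n")
    if (object@effectiveMode)
        cat("  parameterized by effective a_eff (coupling g*C*z)\n")
})

setMethod("show", "StabilityResult", function(object) {
    ev <- object@eigenvalues
    cat("StabilityResult:", length(ev), "eigenvalues;",
        if (object@stable) "stable" else "UNSTABLE", "\n")
    cat("  Re(lambda) in [", format(min(Re(ev)), digits = 4), ",",
        format(max(Re(ev)), digits = 4), "]\n")
})

setMethod("show", "GlobalFitResult", function(object) {
    cat("GlobalFitResult: g_opt =", object@gOpt, "over grid [",
        min(object@gGrid), ",", max(object@gGrid), "] (",
        length(object@gGrid), "values,", object@trials, "trials )\n")
    cat("  min mean KS =", format(min(object@ksMean, na.rm = TRUE),
        digits = 4), "\n")
})

setMethod("show", "LocalFitResult", function(object) {
    cat("LocalFitResult (", if (object@effectiveMode) "a_eff" else "a",
        "): ", object@iterations, " iterations, ",
        if (object@converged) "converged" else "not converged", "\n", sep = "")
    cat("  final max |p_emp - p_sim| =",
        format(utils::tail(object@trace, 1), digits = 4), "\n")
})
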