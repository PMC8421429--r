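#' Number of nodes / regions of an object
#'
#' @param x an object with a notion of region count.
#' @return integer number of regions.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Extract the underlying weight matrix
#'
#' @param x an [SCMatrix-class].
#' @return numeric matrix.
#' @export
setGeneric("scWeights", function(x) standardGeneric("scWeights"))

#' Extract the signal value matrix
#'
#' @param x a [BoldMatrix-class] or [PhaseMatrix-class].
#' @return numeric matrix (regions x time).
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' Repetition time accessor
#'
#' @param x an object carrying a sampling interval.
#' @return repetition time in seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
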