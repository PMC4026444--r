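#' Number of cells in the modelled row
#'
#' @param x a \linkS4class{ModelParameters}, \linkS4class{ExpressionProfiles},
#'   \linkS4class{PhosphoState} or \linkS4class{RunConfig} object.
#' @return integer scalar.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Per-cell Fj kinase activity profile
#' @param x an object carrying expression profiles.
#' @return numeric vector, one value per cell, proximal to distal.
#' @export
setGeneric("fjProfile", function(x) standardGeneric("fjProfile"))

#' Per-cell total Ds profile
#' @param x an object carrying expression profiles.
#' @return numeric vector, one value per cell.
#' @export
setGeneric("dsTotal", function(x) standardGeneric("dsTotal"))

#' Per-cell total Ft profile
#' @param x an object carrying expression profiles.
#' @return numeric vector, one value per cell.
#' @export
setGeneric("ftTotal", function(x) standardGeneric("ftTotal"))

#' Phosphorylated Ft levels
#' @param x a \linkS4class{PhosphoState} or an object containing one.
#' @return numeric vector, one value per cell.
#' @export
setGeneric("ftPhos", function(x) standardGeneric("ftPhos"))

#' Phosphorylated Ds levels
#' @param x a \linkS4class{PhosphoState} or an object containing one.
#' @return numeric vector, one value per cell.
#' @export
setGeneric("dsPhos", function(x) standardGeneric("dsPhos"))

#' Total heterodimer concentration per interior edge
#' @param x an \linkS4class{EdgeState} or an object containing one.
#' @return numeric vector of length \code{nCells - 1}.
#' @export
setGeneric("edgeTotals", function(x) standardGeneric("edgeTotals"))

#' Steady-state heterodimer asymmetry per interior cell
#' @param x a \linkS4class{PolarityResult} or an object containing one.
#' @return numeric vector for interior cells (cells with two neighbours).
#' @export
setGeneric("deltaC", function(x) standardGeneric("deltaC"))

#' Polarity classification labels
#' @param x a \linkS4class{PolarityResult} or an object containing one.
#' @return character vector with values \code{"distal"}, \code{"proximal"}
#'   or \code{"unpolarized"}, one per interior cell.
#' @export
setGeneric("polarityLabels", function(x) standardGeneric("polarityLabels"))

#' Convergence flag of a simulation
#' @param x a \linkS4class{Trajectory} or \linkS4class{ExperimentResult}.
#' @return logical scalar.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Time at which the steady-state criterion was first met
#' @param x a \linkS4class{Trajectory} or \linkS4class{ExperimentResult}.
#' @return numeric scalar, or \code{NA} if the run did not converge.
#' @export
setGeneric("convergenceTime", function(x) standardGeneric("convergenceTime"))
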