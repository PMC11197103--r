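#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal t crossprod
#' @importFrom stats fft lm coef optim runif rnorm sd median setNames
#' @importFrom utils read.delim write.table modifyList head tail
#' @useDynLib fluorspin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Number of spins
#'
#' @param object a \linkS4class{SpinSystem} or basis object.
#' @return integer scalar.
#' @export
setGeneric("nSpins", function(object) standardGeneric("nSpins"))

#' Isotope labels
#'
#' @param object a \linkS4class{SpinSystem}.
#' @return character vector of isotope labels, one per spin.
#' @export
setGeneric("isotopes", function(object) standardGeneric("isotopes"))

#' Chemical shifts in ppm
#'
#' @param object a \linkS4class{SpinSystem} or \linkS4class{FitParameters}.
#' @return numeric vector (ppm), one value per spin.
#' @export
setGeneric("chemicalShifts", function(object) standardGeneric("chemicalShifts"))

#' Scalar coupling matrix in Hz
#'
#' @param object a \linkS4class{SpinSystem} or \linkS4class{FitParameters}.
#' @return symmetric numeric matrix (Hz) with zero diagonal.
#' @export
setGeneric("jCouplings", function(object) standardGeneric("jCouplings"))

#' State-space dimension
#'
#' @param object a basis or operator object.
#' @return integer scalar: number of retained states.
#' @export
setGeneric("dimension", function(object) standardGeneric("dimension"))

#' Reduction provenance
#'
#' Records which state-space reduction stages were applied and the dimension
#' after each one.
#'
#' @param object a \linkS4class{ProductBasis} or \linkS4class{SymmetrizedBasis}.
#' @return data.frame with columns \code{stage} and \code{dimension}.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Conformer populations
#'
#' @param object a \linkS4class{PopulationResult}.
#' @return numeric vector of populations (sums to one).
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))
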