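#' Uncleaved-linker fraction of a circuit
#'
#' Fraction of a linker population not yet fully cleaved (a linker counts as
#' cleaved only once both of its trigger sites have been displaced), normalized
#' to the initial linker concentration.
#'
#' @param x a trajectory object.
#' @param label circuit label.
#' @param ... further arguments passed to methods.
#' @return numeric vector of w(t), one value per sample time.
#' @export
setGeneric("uncleavedFraction", function(x, label, ...)
  standardGeneric("uncleavedFraction"))

#' Concentration trace of a single species
#'
#' @param x a trajectory object.
#' @param name species name, e.g. \code{"T.AB.1"}.
#' @return numeric vector of concentrations at the trajectory's sample times.
#' @export
setGeneric("speciesTrace", function(x, name) standardGeneric("speciesTrace"))

#' Time at which a division-ratio trace crosses a level
#'
#' First upward crossing of \code{level}, linearly interpolated between
#' samples. Later re-crossings are ignored. If the trace never attains the
#' level the outcome is "undivided": the returned value is \code{NA} and its
#' \code{"status"} attribute says so.
#'
#' @param trace a \linkS4class{DivisionTrace}, or a numeric vector of division
#'   ratios (then \code{times} must be given).
#' @param level crossing level, default 0.5.
#' @param ... further arguments passed to methods.
#' @return length-one numeric (NA when undivided) with attribute
#'   \code{status} equal to \code{"divided"} or \code{"undivided"}.
#' @export
setGeneric("divisionTime", function(trace, level = 0.5, ...)
  standardGeneric("divisionTime"))

#' Sample times of a trajectory or trace
#' @param x object with a time axis.
#' @return numeric vector of times.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
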