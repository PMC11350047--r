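#' Cooperative division switch
#'
#' Hill-type sigmoidal function of the uncleaved-linker fraction,
#' \eqn{H(w) = K^n / (K^n + w^n)}. H is strictly decreasing in w: once most
#' linkers are cleaved (w below the threshold K) the droplet components can
#' demix. Evaluated on the log scale so that large cooperativities (n = 16 and
#' beyond) neither overflow nor underflow near w = K.
#'
#' @param w uncleaved-linker fraction(s), >= 0 (normalized to the initial
#'   total).
#' @param K threshold on the same scale as w, > 0.
#' @param n cooperativity coefficient, > 0.
#' @return H(w) in (0, 1]; H(0) = 1, H(K) = 0.5.
#' @examples
#' hillH(c(0, 0.05, 0.1), K = 0.05, n = 16)
#' @export
hillH <- function(w, K, n) {
  if (any(w < 0)) stop("w must be non-negative")
  if (!(K > 0) || !(n > 0)) stop("K and n must be positive")
  out <- numeric(length(w))
  pos <- w > 0
  ## H = 1 / (1 + (w/K)^n), computed as an inverse logit of n*log(w/K)
  out[pos] <- 1 / (1 + exp(n * (log(w[pos]) - log(K))))
  out[!pos] <- 1
  out
}

#' Division ratio from an uncleaved-linker trace
#'
#' Maps an uncleaved-linker fraction time course w(t) to the division ratio
#' \eqn{r_{div} = (H(w) - H_{min}) / (H_{max} - H_{min})} with
#' \eqn{H_{max} = H(0)} and \eqn{H_{min} = H(w_0)}, where w0 is the initial
#' (maximal) uncleaved total. r_div is 0 while no linker has been cleaved and
#' reaches exactly 1 when all linkers are cleaved.
#'
#' @param w numeric vector of uncleaved fractions; its first element is taken
#'   as w0 and must be the maximum of the trace.
#' @param K,n Hill parameters (see \code{\link{hillH}}).
#' @return numeric vector of division ratios in [0, 1].
#' @export
divisionRatio <- function(w, K, n) {
  if (!length(w)) stop("empty trace")
  w0 <- w[1]
  if (w0 <= 0) stop("initial uncleaved total w0 must be positive (nothing to cleave)")
  if (max(w) > w0 + 1e-9)
    stop("trace must start at its maximum w0")
  hMax <- 1                       # H(0)
  hMin <- hillH(w0, K, n)
  (hillH(w, K, n) - hMin) / (hMax - hMin)
}

#' Construct a division trace
#'
#' Bundles a time grid, an uncleaved-linker trace and its Hill-mapped division
#' ratio for one droplet component.
#'
#' @param times sample times.
#' @param w uncleaved-linker fractions (first element = w0).
#' @param K,n Hill parameters.
#' @param component component label, e.g. "B" or "C".
#' @return a \linkS4class{DivisionTrace}.
#' @export
divisionTrace <- function(times, w, K, n, component = "B") {
  r <- divisionRatio(w, K, n)
  new("DivisionTrace", times = times, w = w, rDiv = pmin(pmax(r, 0), 1),
      component = component, K = K, n = n)
}

#' Division trace from an image-derived r_div series
#'
#' @param times frame times.
#' @param rDiv division ratios in [0, 1].
#' @param component component label.
#' @return a \linkS4class{DivisionTrace} with an empty w slot.
#' @export
divisionTraceFromRatios <- function(times, rDiv, component = "B") {
  new("DivisionTrace", times = times, rDiv = pmin(pmax(rDiv, 0), 1),
      component = component)
}

#' @rdname sampleTimes
setMethod("sampleTimes", "DivisionTrace", function(x) x@times)

setMethod("show", "DivisionTrace", function(object) {
  tau <- divisionTime(object)
  cat(sprintf("DivisionTrace (component %s): %d samples over [%g, %g];%s\n",
              object@component, length(object@times), min(object@times),
              max(object@times),
              if (is.na(tau)) " undivided within horizon"
              else sprintf(" tau_div = %.4g", tau)))
})

.crossingTime <- function(times, r, level) {
  hit <- which(r >= level)
  if (!length(hit)) {
    out <- NA_real_; attr(out, "status") <- "undivided"; return(out)
  }
  k <- hit[1]
  if (k == 1L || r[k] == level) {
    out <- times[k]
  } else {
    ## linear interpolation over the first upward crossing
    out <- times[k - 1] + (level - r[k - 1]) / (r[k] - r[k - 1]) *
      (times[k] - times[k - 1])
  }
  attr(out, "status") <- "divided"
  out
}

#' @rdname divisionTime
setMethod("divisionTime", "DivisionTrace", function(trace, level = 0.5, ...) {
  .crossingTime(trace@times, trace@rDiv, level)
})

#' @rdname divisionTime
#' @param times sample times, required for the numeric method.
setMethod("divisionTime", "numeric", function(trace, level = 0.5, times, ...) {
  if (missing(times) || length(times) != length(trace))
    stop("times must accompany a numeric r_div trace")
  .crossingTime(times, trace, level)
})

#' Division-time difference and pathway label
#'
#' Computes the signed difference \eqn{\Delta\tau = \tau_{div,B} -
#' \tau_{div,C}} and the resulting division pathway: positive differences mean
#' the C droplet divides first (Pathway 1), negative ones that the B droplet
#' divides first (Pathway 2).
#'
#' @param tauB,tauC division times of the B and C components (possibly with
#'   the status attribute set by \code{\link{divisionTime}}).
#' @return list with \code{deltaTau}, \code{pathway} ("Pathway 1",
#'   "Pathway 2", "tie" or "undefined") and, when undefined, \code{reason}.
#' @examples
#' deltaTau(60, 10)   # Pathway 1
#' @export
deltaTau <- function(tauB, tauC) {
  if (is.na(tauB) || is.na(tauC)) {
    und <- c(if (is.na(tauB)) "B", if (is.na(tauC)) "C")
    return(list(deltaTau = NA_real_, pathway = "undefined",
                reason = paste("component(s) undivided:",
                               paste(und, collapse = ", "))))
  }
  d <- as.numeric(tauB) - as.numeric(tauC)
  list(deltaTau = d,
       pathway = if (d > 0) "Pathway 1" else if (d < 0) "Pathway 2" else "tie")
}

#' Offset concentration of the comparator
#'
#' Given per-condition input differences (delta c-tilde) and the corresponding
#' division-time differences (delta tau), locates the single sign change of
#' delta tau along the dose axis and reports the offset sigma as the
#' arithmetic mean of the two adjacent doses bracketing it. Sigma is the input
#' difference at which the comparator's output pathway switches; an ideal
#' comparator has sigma = 0.
#'
#' @param deltaC numeric vector of input differences, sorted (ascending or
#'   descending).
#' @param deltaTauValues numeric vector of division-time differences (only
#'   their signs are used), same length.
#' @return list with \code{sigma} (NA when no sign change), \code{status}
#'   ("ok" or "outside range") and \code{bracket} (the two doses around the
#'   switch).
#' @examples
#' estimateOffset(c(1.25, 0.5, -0.5, -1.0, -1.25), c(30, 18, 7, -4, -11))
#' @export
estimateOffset <- function(deltaC, deltaTauValues) {
  if (length(deltaC) != length(deltaTauValues) || length(deltaC) < 2L)
    stop("need matching deltaC and deltaTau vectors of length >= 2")
  if (anyNA(deltaTauValues))
    stop("all conditions must have a defined deltaTau")
  o <- order(deltaC, decreasing = TRUE)
  if (!identical(o, seq_along(deltaC)) &&
      !identical(o, rev(seq_along(deltaC))))
    stop("conditions must be sorted by deltaC")
  dc <- deltaC[o]; s <- sign(deltaTauValues[o])
  flips <- which(s[-1] != s[-length(s)])
  if (!length(flips))
    return(list(sigma = NA_real_, status = "outside range",
                bracket = c(NA_real_, NA_real_)))
  if (length(flips) > 1L)
    stop("multiple sign changes; brackets: ",
         paste(sprintf("(%g, %g)", dc[flips], dc[flips + 1]), collapse = ", "))
  k <- flips
  list(sigma = mean(dc[c(k, k + 1)]), status = "ok",
       bracket = dc[c(k, k + 1)])
}
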