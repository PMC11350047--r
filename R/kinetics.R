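#' Construct a linker circuit
#'
#' @param label alphanumeric circuit label.
#' @param linkerTotal total linker concentration (uM).
#' @param triggerTotal total concentration of each of the two trigger species
#'   (uM).
#' @param cTilde normalized inhibitor-RNA dose (total inhibitor RNA over total
#'   trigger); only meaningful for delayed circuits.
#' @param delayed logical; delayed circuits start with their triggers
#'   partitioned between free and inhibited forms according to \code{cTilde}.
#' @param kOn trigger-toehold hybridization rate (1/(uM s)).
#' @param kDisp strand-displacement rate (1/s).
#' @param weight share of this linker in the total linker DNA (for combined
#'   uncleaved fractions); NA when not used.
#' @return a \linkS4class{LinkerCircuit}.
#' @examples
#' linkerCircuit("AB", linkerTotal = 0.6, triggerTotal = 1, cTilde = 1.25,
#'               delayed = TRUE)
#' @export
linkerCircuit <- function(label, linkerTotal, triggerTotal, cTilde = 0,
                          delayed = cTilde > 0, kOn = 0.1, kDisp = 0.05,
                          weight = NA_real_) {
  new("LinkerCircuit", label = label, delayed = delayed,
      linkerTotal = linkerTotal, triggerTotal = triggerTotal, cTilde = cTilde,
      kOn = kOn, kDisp = kDisp, weight = weight)
}

#' Construct a circuit model
#'
#' @param circuits list of \linkS4class{LinkerCircuit} objects (or a single
#'   one).
#' @param enzyme RNase H level (U/uL).
#' @param kCat Michaelis-Menten turnover, uM/s per (U/uL).
#' @param Km Michaelis constant (uM).
#' @param kHybRNA trigger/inhibitor-RNA hybridization rate (1/(uM s)).
#' @param competition "independent" or "shared" (one enzyme pool shared by all
#'   inhibited-trigger substrates, summed in the Michaelis-Menten denominator).
#' @param sdMode "two-step" or "single-step" strand-displacement scheme.
#' @return a \linkS4class{CircuitModel}.
#' @examples
#' m <- circuitModel(linkerCircuit("AB", 0.6, 1, cTilde = 1.5, delayed = TRUE),
#'                   enzyme = 0.25)
#' @export
circuitModel <- function(circuits, enzyme = 0.25, kCat = 2e-3, Km = 0.5,
                         kHybRNA = 0.05, competition = "independent",
                         sdMode = "two-step") {
  if (is(circuits, "LinkerCircuit")) circuits <- list(circuits)
  new("CircuitModel", circuits = circuits, enzyme = enzyme, kCat = kCat,
      Km = Km, kHybRNA = kHybRNA, competition = competition, sdMode = sdMode)
}

## species bookkeeping ------------------------------------------------------

.speciesKinds <- c("T", "iT", "R", "Sf", "Sb", "Sd")

#' Species names of a circuit model
#'
#' Each circuit contributes, per site i = 1, 2: free trigger \code{T}, inhibited
#' trigger \code{iT}, free inhibitor RNA \code{R}, and the linker site in its
#' free (\code{Sf}), toehold-bound (\code{Sb}) and displaced (\code{Sd})
#' states. Names are \code{<kind>.<label>.<site>}.
#'
#' @param model a \linkS4class{CircuitModel}.
#' @return character vector of species names.
#' @export
speciesNames <- function(model) {
  unlist(lapply(model@circuits, function(circ)
    as.vector(outer(.speciesKinds, 1:2,
                    function(k, i) paste(k, circ@label, i, sep = ".")))))
}

.sp <- function(kind, label, site) paste(kind, label, site, sep = ".")

#' Initial well-mixed state of a circuit model
#'
#' For a delayed circuit with dose \code{cTilde}, total inhibitor RNA is
#' \code{cTilde * triggerTotal}; trigger and RNA hybridize to completion during
#' annealing, so the inhibited trigger starts at \code{min(triggerTotal,
#' RNAtotal)}, the free trigger at the trigger excess, and the free inhibitor
#' RNA at the RNA excess. Non-delayed circuits start with all trigger free.
#' All linker sites start uncleaved.
#'
#' @param model a \linkS4class{CircuitModel}.
#' @return named numeric vector of concentrations (uM).
#' @export
initialState <- function(model) {
  state <- numeric(0)
  for (circ in model@circuits) {
    rTot <- if (circ@delayed) circ@cTilde * circ@triggerTotal else 0
    iT0 <- min(circ@triggerTotal, rTot)
    for (i in 1:2) {
      v <- c(circ@triggerTotal - iT0, iT0, rTot - iT0, circ@linkerTotal, 0, 0)
      names(v) <- .sp(.speciesKinds, circ@label, i)
      state <- c(state, v)
    }
  }
  state[speciesNames(model)]
}

## elementary rate laws -----------------------------------------------------

#' Michaelis-Menten release rate of an inhibited trigger
#'
#' Rate at which RNase H degrades the RNA strand of an inhibited trigger,
#' releasing free trigger: \code{kCat * cE * uIT / (Km + uITTotal)}. Under
#' shared-enzyme competition, \code{uITTotal} is the sum of all
#' inhibited-trigger substrates competing for the same enzyme pool; in
#' independent mode it equals \code{uIT}.
#'
#' @param uIT concentration of the inhibited trigger being released (uM).
#' @param kCat turnover (uM/s per U/uL).
#' @param Km Michaelis constant (uM).
#' @param cE enzyme level (U/uL).
#' @param uITTotal total competing substrate in the denominator (uM).
#' @return release rate (uM/s).
#' @examples
#' mmReleaseRate(0.5, kCat = 2e-3, Km = 0.5, cE = 0.25)   # half-saturation
#' @export
mmReleaseRate <- function(uIT, kCat, Km, cE, uITTotal = uIT) {
  if (any(uIT < 0) || any(cE < 0) || any(uITTotal < 0))
    stop("concentrations and enzyme level must be non-negative")
  kCat * cE * uIT / (Km + uITTotal)
}

#' Mass-action inhibition rate
#'
#' Bilinear hybridization rate of a free trigger with a free inhibitor RNA,
#' \code{kHybRNA * uT * uR}.
#'
#' @param uT free trigger concentration (uM).
#' @param uR free inhibitor RNA concentration (uM).
#' @param kHybRNA hybridization rate constant (1/(uM s)).
#' @return inhibition rate (uM/s).
#' @export
inhibitionRate <- function(uT, uR, kHybRNA) {
  if (any(uT < 0) || any(uR < 0))
    stop("concentrations must be non-negative")
  kHybRNA * uT * uR
}

## assembled rate terms; u is a named list whose elements are scalars (well
## mixed) or matrices (one value per grid cell) -- all arithmetic elementwise.
.circuitRates <- function(u, model) {
  du <- lapply(u, function(x) x * 0)
  sharedIT <- NULL
  if (model@competition == "shared") {
    sharedIT <- 0
    for (circ in model@circuits) for (i in 1:2)
      sharedIT <- sharedIT + u[[.sp("iT", circ@label, i)]]
  }
  for (circ in model@circuits) {
    for (i in 1:2) {
      nT <- .sp("T", circ@label, i); nIT <- .sp("iT", circ@label, i)
      nR <- .sp("R", circ@label, i); nSf <- .sp("Sf", circ@label, i)
      nSb <- .sp("Sb", circ@label, i); nSd <- .sp("Sd", circ@label, i)
      denomTot <- if (is.null(sharedIT)) u[[nIT]] else sharedIT
      rel <- model@kCat * model@enzyme * u[[nIT]] / (model@Km + denomTot)
      inh <- model@kHybRNA * u[[nT]] * u[[nR]]
      du[[nIT]] <- du[[nIT]] + inh - rel
      du[[nR]] <- du[[nR]] - inh
      if (model@sdMode == "two-step") {
        bind <- circ@kOn * u[[nT]] * u[[nSf]]
        disp <- circ@kDisp * u[[nSb]]
        du[[nT]] <- du[[nT]] + rel - inh - bind
        du[[nSf]] <- du[[nSf]] - bind
        du[[nSb]] <- du[[nSb]] + bind - disp
        du[[nSd]] <- du[[nSd]] + disp
      } else {
        clv <- circ@kOn * u[[nT]] * u[[nSf]]
        du[[nT]] <- du[[nT]] + rel - inh - clv
        du[[nSf]] <- du[[nSf]] - clv
        du[[nSd]] <- du[[nSd]] + clv
      }
    }
  }
  du
}

.stateToList <- function(state) as.list(state)
.listToState <- function(u) unlist(u)

#' Time-delay circuit net rate per trigger
#'
#' Net generation rate of each free trigger by the time-delay circuit:
#' Michaelis-Menten release from the inhibited form minus mass-action
#' re-inhibition by free inhibitor RNA.
#'
#' @param state named numeric state vector (see \code{\link{initialState}}).
#' @param model a \linkS4class{CircuitModel}.
#' @return named numeric vector, one net rate (uM/s) per trigger species.
#' @export
gTD <- function(state, model) {
  .checkState(state, model)
  out <- numeric(0)
  sharedIT <- if (model@competition == "shared")
    sum(state[grep("^iT\\.", names(state))]) else NULL
  for (circ in model@circuits) for (i in 1:2) {
    uIT <- state[[.sp("iT", circ@label, i)]]
    rel <- mmReleaseRate(uIT, model@kCat, model@Km, model@enzyme,
                         if (is.null(sharedIT)) uIT else sharedIT)
    inh <- inhibitionRate(state[[.sp("T", circ@label, i)]],
                          state[[.sp("R", circ@label, i)]], model@kHybRNA)
    out[.sp("T", circ@label, i)] <- rel - inh
  }
  out
}

#' Trigger consumption by linker hybridization and strand displacement
#'
#' Rates of the linker-cleavage arm: consumption of each free trigger by
#' toehold binding to its linker site, and the site-state transition rates. In
#' the two-step scheme a site passes through a toehold-bound intermediate
#' before displacement; in the single-step scheme binding and displacement are
#' lumped into one effective bimolecular reaction.
#'
#' @param state named numeric state vector.
#' @param model a \linkS4class{CircuitModel}.
#' @return list with components \code{triggerConsumption} (named vector, uM/s)
#'   and \code{siteRates} (named vector of d/dt for every Sf/Sb/Sd species).
#' @export
fHSD <- function(state, model) {
  .checkState(state, model)
  cons <- numeric(0); site <- numeric(0)
  for (circ in model@circuits) for (i in 1:2) {
    uT <- state[[.sp("T", circ@label, i)]]
    uSf <- state[[.sp("Sf", circ@label, i)]]
    uSb <- state[[.sp("Sb", circ@label, i)]]
    if (any(c(uT, uSf, uSb) < 0)) stop("concentrations must be non-negative")
    if (model@sdMode == "two-step") {
      bind <- circ@kOn * uT * uSf
      disp <- circ@kDisp * uSb
      cons[.sp("T", circ@label, i)] <- bind
      site[.sp("Sf", circ@label, i)] <- -bind
      site[.sp("Sb", circ@label, i)] <- bind - disp
      site[.sp("Sd", circ@label, i)] <- disp
    } else {
      clv <- circ@kOn * uT * uSf
      cons[.sp("T", circ@label, i)] <- clv
      site[.sp("Sf", circ@label, i)] <- -clv
      site[.sp("Sb", circ@label, i)] <- 0
      site[.sp("Sd", circ@label, i)] <- clv
    }
  }
  list(triggerConsumption = cons, siteRates = site)
}

.checkState <- function(state, model) {
  need <- speciesNames(model)
  if (!all(need %in% names(state)))
    stop("state is missing species: ",
         paste(setdiff(need, names(state)), collapse = ", "))
  invisible(TRUE)
}

#' Well-mixed right-hand side
#'
#' Full time derivative of the well-mixed state: time-delay circuit generation
#' and inhibition of triggers, trigger consumption by linker cleavage, and the
#' linker site bookkeeping.
#'
#' @param state named numeric state vector.
#' @param model a \linkS4class{CircuitModel}.
#' @return named numeric derivative vector, same names as \code{state}.
#' @export
rhsWellMixed <- function(state, model) {
  .checkState(state, model)
  if (any(state < 0))
    stop("concentrations must be non-negative")
  du <- .circuitRates(as.list(state[speciesNames(model)]), model)
  out <- unlist(du)
  out[names(state)]
}

#' Integrate the well-mixed circuit kinetics
#'
#' Adaptive stiff-capable integration (\code{deSolve::lsoda}) of the circuit
#' rate equations.
#'
#' @param model a \linkS4class{CircuitModel}.
#' @param times strictly increasing sample times (s).
#' @param init optional initial state (defaults to \code{initialState(model)}).
#' @param rtol,atol integrator tolerances.
#' @return a \linkS4class{WellMixedTrajectory}.
#' @examples
#' m <- circuitModel(linkerCircuit("AB", 0.6, 1, cTilde = 1.5, delayed = TRUE))
#' traj <- simulateWellMixed(m, seq(0, 600, by = 10))
#' head(uncleavedFraction(traj, "AB"))
#' @export
simulateWellMixed <- function(model, times, init = NULL,
                              rtol = 1e-6, atol = 1e-9) {
  validObject(model)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two samples")
  if (is.null(init)) init <- initialState(model)
  .checkState(init, model)
  if (any(init < 0)) stop("initial concentrations must be non-negative")
  init <- init[speciesNames(model)]
  deriv <- function(t, y, parms) {
    list(unlist(.circuitRates(as.list(pmax(y, 0)), model)))
  }
  sol <- deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failed (istate = ", attr(sol, "istate")[1],
         "); consider loosening tolerances or shortening the horizon")
  states <- unclass(sol)[, -1, drop = FALSE]
  neg <- states < 0
  if (any(states < -100 * atol))
    warning("integration produced negative concentrations beyond tolerance")
  states[neg] <- 0
  new("WellMixedTrajectory", times = times, states = states, model = model)
}

## accessors ----------------------------------------------------------------

#' @rdname sampleTimes
setMethod("sampleTimes", "WellMixedTrajectory", function(x) x@times)

#' @rdname speciesTrace
setMethod("speciesTrace", "WellMixedTrajectory", function(x, name) {
  if (!name %in% colnames(x@states)) stop("unknown species: ", name)
  x@states[, name]
})

.wFromStates <- function(states, circ) {
  p1 <- states[, .sp("Sd", circ@label, 1)] / circ@linkerTotal
  p2 <- states[, .sp("Sd", circ@label, 2)] / circ@linkerTotal
  ## guard against integrator round-off pushing p marginally past 1
  pmin(pmax(1 - p1 * p2, 0), 1)
}

.findCircuit <- function(model, label) {
  for (circ in model@circuits) if (circ@label == label) return(circ)
  stop("no circuit with label '", label, "'")
}

#' @rdname uncleavedFraction
setMethod("uncleavedFraction", "WellMixedTrajectory", function(x, label, ...) {
  .wFromStates(x@states, .findCircuit(x@model, label))
})

#' Combined uncleaved fraction over several linkers
#'
#' Weighted combination of per-linker uncleaved fractions, with weights equal
#' to each linker's share of the total linker DNA (the circuits' \code{weight}
#' slots, or an explicit vector).
#'
#' @param traj a \linkS4class{WellMixedTrajectory}.
#' @param labels circuit labels to combine (default: all).
#' @param weights weights summing to 1 (default: circuit \code{weight} slots).
#' @return numeric vector of the combined w(t).
#' @export
combinedUncleaved <- function(traj, labels = NULL, weights = NULL) {
  circs <- traj@model@circuits
  if (is.null(labels)) labels <- vapply(circs, function(c) c@label, character(1))
  if (is.null(weights)) {
    weights <- vapply(labels, function(l) .findCircuit(traj@model, l)@weight,
                      numeric(1))
    if (anyNA(weights)) stop("weights missing; set circuit weights or pass them")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  ws <- vapply(labels, function(l) uncleavedFraction(traj, l),
               numeric(length(traj@times)))
  drop(ws %*% weights)
}

#' Tidy data.frame of a well-mixed trajectory
#'
#' @param x a \linkS4class{WellMixedTrajectory}.
#' @param ... unused.
#' @return data.frame with columns \code{time}, \code{species},
#'   \code{concentration}.
#' @export
setMethod("as.data.frame", "WellMixedTrajectory", function(x, ...) {
  data.frame(
    time = rep(x@times, times = ncol(x@states)),
    species = rep(colnames(x@states), each = length(x@times)),
    concentration = as.vector(x@states),
    row.names = NULL
  )
})

setMethod("show", "WellMixedTrajectory", function(object) {
  cat("WellMixedTrajectory:", length(object@times), "samples over [",
      min(object@times), ",", max(object@times), "] s;",
      ncol(object@states), "species;",
      length(object@model@circuits), "circuit(s)\n")
})

setMethod("show", "CircuitModel", function(object) {
  cat("CircuitModel with", length(object@circuits), "circuit(s):\n")
  for (circ in object@circuits)
    cat(sprintf("  %-5s %s linker %.3g uM, trigger %.3g uM, cTilde %.3g, kOn %.3g, kDisp %.3g\n",
                circ@label, if (circ@delayed) "delayed," else "plain,  ",
                circ@linkerTotal, circ@triggerTotal, circ@cTilde,
                circ@kOn, circ@kDisp))
  cat(sprintf("  enzyme %.3g U/uL, kCat %.3g, Km %.3g uM, kHybRNA %.3g, %s enzyme, %s displacement\n",
              object@enzyme, object@kCat, object@Km, object@kHybRNA,
              object@competition, object@sdMode))
})
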