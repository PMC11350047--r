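#' Comparator circuit model
#'
#' Ternary-droplet model of the miRNA concentration comparator: two delayed
#' linker circuits (AB and AC) in one solution, sharing a single RNase H pool
#' (shared-enzyme Michaelis-Menten competition). In the asymmetric preset the
#' trigger-linker hybridization and strand-displacement rates of the AB circuit
#' are \code{handicap}-fold lower than those of the AC circuit, modelling
#' sequence-dependent kinetics of the two linker nanostructures.
#'
#' @param cTildeAB,cTildeAC normalized inhibitor-RNA doses of the two inputs.
#' @param handicap factor by which AB hybridization/displacement rates are
#'   slower than AC rates (1 = symmetric kinetics).
#' @param enzyme RNase H level (U/uL).
#' @param kOn,kDisp AC-circuit hybridization and displacement rates.
#' @param linkerTotal,triggerTotal per-circuit linker and per-trigger totals
#'   (uM).
#' @param kCat,Km,kHybRNA,sdMode circuit parameters, see
#'   \code{\link{circuitModel}}.
#' @param competition enzyme competition mode; the comparator default is
#'   \code{"shared"} because both circuits draw on one RNase H pool.
#' @return a \linkS4class{CircuitModel} with circuits labelled "AB" and "AC".
#' @export
comparatorModel <- function(cTildeAB, cTildeAC, handicap = 10, enzyme = 0.25,
                            kOn = 0.1, kDisp = 0.05, linkerTotal = 0.6,
                            triggerTotal = 1.0, kCat = 2e-3, Km = 0.5,
                            kHybRNA = 0.05, competition = "shared",
                            sdMode = "two-step") {
  if (handicap <= 0) stop("handicap must be positive")
  circuitModel(
    list(
      linkerCircuit("AB", linkerTotal, triggerTotal, cTilde = cTildeAB,
                    delayed = TRUE, kOn = kOn / handicap,
                    kDisp = kDisp / handicap),
      linkerCircuit("AC", linkerTotal, triggerTotal, cTilde = cTildeAC,
                    delayed = TRUE, kOn = kOn, kDisp = kDisp)
    ),
    enzyme = enzyme, kCat = kCat, Km = Km, kHybRNA = kHybRNA,
    competition = competition, sdMode = sdMode
  )
}

#' Five-point comparator dose preset
#'
#' The five (cTildeAB, cTildeAC) condition pairs of the comparator experiment,
#' spanning input differences delta c-tilde of 1.25, 0.50, -0.50, -1.00 and
#' -1.25.
#'
#' @return data.frame with columns \code{cTildeAB}, \code{cTildeAC},
#'   \code{deltaC}.
#' @export
comparatorPresetConditions <- function() {
  d <- data.frame(
    cTildeAB = c(1.25, 1.25, 0.75, 0.25, 0),
    cTildeAC = c(0, 0.75, 1.25, 1.25, 1.25)
  )
  d$deltaC <- d$cTildeAB - d$cTildeAC
  d
}

#' Run one comparator condition
#'
#' Simulates both circuits under one dose pair, maps each linker's uncleaved
#' fraction through its component's Hill threshold (B through K_AB on the AB
#' linker, C through K_AC on the AC linker), and extracts division times and
#' the pathway label.
#'
#' @param cTildeAB,cTildeAC input doses.
#' @param KAB,KAC per-component Hill thresholds on the normalized w scale.
#' @param n Hill cooperativity.
#' @param engine \code{"well-mixed"} or \code{"reaction-diffusion"}.
#' @param times sample times (s).
#' @param grid,dmap grid and diffusion map for the reaction-diffusion engine.
#' @param rdLayout initial layout for the reaction-diffusion engine (see
#'   \code{\link{initialFields}}).
#' @param ... further arguments passed to \code{\link{comparatorModel}}.
#' @return a \linkS4class{PathwayResult}.
#' @examples
#' res <- runComparatorCondition(1.25, 0, times = seq(0, 8000, by = 20))
#' res@pathway
#' @export
runComparatorCondition <- function(cTildeAB, cTildeAC, KAB = 0.1, KAC = 0.9,
                                   n = 16, engine = c("well-mixed",
                                                      "reaction-diffusion"),
                                   times = seq(0, 20000, by = 20),
                                   grid = NULL, dmap = NULL,
                                   rdLayout = "droplet", ...) {
  engine <- match.arg(engine)
  model <- comparatorModel(cTildeAB, cTildeAC, ...)
  if (engine == "well-mixed") {
    traj <- simulateWellMixed(model, times)
    wAB <- uncleavedFraction(traj, "AB")
    wAC <- uncleavedFraction(traj, "AC")
  } else {
    if (is.null(grid)) grid <- gridSpec(64, 64, spacing = 2.5, radius = 50)
    if (is.null(dmap)) dmap <- diffusionMap()
    traj <- simulateRD(model, grid, dmap, times, layout = rdLayout)
    wAB <- uncleavedFraction(traj, "AB")
    wAC <- uncleavedFraction(traj, "AC")
  }
  trB <- divisionTrace(times, wAB, KAB, n, component = "B")
  trC <- divisionTrace(times, wAC, KAC, n, component = "C")
  tauB <- divisionTime(trB); tauC <- divisionTime(trC)
  dt <- deltaTau(tauB, tauC)
  new("PathwayResult", tauB = as.numeric(tauB), tauC = as.numeric(tauC),
      deltaTau = dt$deltaTau, pathway = dt$pathway,
      traces = list(B = trB, C = trC))
}

setMethod("show", "PathwayResult", function(object) {
  cat(sprintf("PathwayResult: tauB = %.4g, tauC = %.4g, deltaTau = %.4g -> %s\n",
              object@tauB, object@tauC, object@deltaTau, object@pathway))
})

#' Run a comparator dose sweep
#'
#' Runs every condition of a dose table, assembles the per-condition
#' division-time table, and estimates the comparator offset sigma from the
#' sign change of delta tau along the dose axis.
#'
#' @param conditions data.frame with columns \code{cTildeAB} and
#'   \code{cTildeAC}, sorted by their difference; default the five-point
#'   preset.
#' @param symmetric logical; TRUE runs identical kinetics for both circuits
#'   (handicap 1) with equal thresholds \code{KAB = KAC}, as for an ideal
#'   comparator.
#' @param handicap AB-rate handicap; default 10 for the asymmetric preset,
#'   forced to 1 when \code{symmetric}.
#' @param KAB,KAC,n Hill parameters (in the symmetric case KAC is forced to
#'   KAB).
#' @param refine logical; if TRUE, additionally refine sigma by bisection on
#'   the dose axis (extra simulation runs).
#' @param refineIter bisection iterations.
#' @param ... passed to \code{\link{runComparatorCondition}} (engine, times,
#'   kinetic overrides).
#' @return a \linkS4class{ComparatorResult}.
#' @examples
#' \donttest{
#' sweep <- runComparatorSweep(symmetric = TRUE,
#'                             times = seq(0, 20000, by = 20))
#' sweep@sigma
#' }
#' @export
runComparatorSweep <- function(conditions = comparatorPresetConditions(),
                               symmetric = FALSE, handicap = 10, KAB = 0.1,
                               KAC = 0.9, n = 16, refine = FALSE,
                               refineIter = 5, ...) {
  if (nrow(conditions) < 2L) stop("need at least two conditions")
  if (symmetric) { KAC <- KAB; handicap <- 1 }
  runOne <- function(cab, cac)
    runComparatorCondition(cab, cac, KAB = KAB, KAC = KAC, n = n,
                           handicap = handicap, ...)
  results <- Map(runOne, conditions$cTildeAB, conditions$cTildeAC)
  tab <- data.frame(
    cTildeAB = conditions$cTildeAB,
    cTildeAC = conditions$cTildeAC,
    deltaC = conditions$cTildeAB - conditions$cTildeAC,
    tauB = vapply(results, function(r) r@tauB, numeric(1)),
    tauC = vapply(results, function(r) r@tauC, numeric(1)),
    deltaTau = vapply(results, function(r) r@deltaTau, numeric(1)),
    pathway = vapply(results, function(r) r@pathway, character(1))
  )
  if (anyNA(tab$deltaTau))
    stop("undivided component(s) in condition(s) ",
         paste(which(is.na(tab$deltaTau)), collapse = ", "),
         "; extend the simulation horizon")
  off <- estimateOffset(tab$deltaC, tab$deltaTau)
  sigmaRefined <- NA_real_
  if (refine && off$status == "ok") {
    ## bisect delta-c between the bracketing conditions at fixed total dose
    lo <- min(off$bracket); hi <- max(off$bracket)
    iLo <- which(tab$deltaC == lo)[1]; iHi <- which(tab$deltaC == hi)[1]
    totLo <- tab$cTildeAB[iLo] + tab$cTildeAC[iLo]
    totHi <- tab$cTildeAB[iHi] + tab$cTildeAC[iHi]
    sgn <- function(dc) {
      frac <- (dc - lo) / (hi - lo)
      tot <- totLo + frac * (totHi - totLo)
      r <- runOne((tot + dc) / 2, (tot - dc) / 2)
      sign(r@deltaTau)
    }
    sLo <- sign(tab$deltaTau[iLo])
    for (it in seq_len(refineIter)) {
      mid <- (lo + hi) / 2
      if (sgn(mid) == sLo) lo <- mid else hi <- mid
    }
    sigmaRefined <- (lo + hi) / 2
  }
  new("ComparatorResult", table = tab, sigma = off$sigma,
      sigmaStatus = off$status, sigmaRefined = sigmaRefined,
      results = results)
}

setMethod("show", "ComparatorResult", function(object) {
  cat("ComparatorResult over", nrow(object@table), "conditions\n")
  print(object@table, row.names = FALSE)
  if (object@sigmaStatus == "ok")
    cat(sprintf("offset sigma = %g%s\n", object@sigma,
                if (!is.na(object@sigmaRefined))
                  sprintf(" (refined: %.4g)", object@sigmaRefined) else ""))
  else cat("offset outside tested range\n")
})

#' Effect of the total RNA dose under enzyme competition
#'
#' Runs the comparator at several total doses c-tilde_t at a fixed input
#' difference and reports whether both division times are non-decreasing in
#' the total dose, the signature of substrate competition for the shared
#' RNase H pool. Refuses to run in independent-enzyme mode, where the result
#' would be vacuous.
#'
#' @param cTildeT numeric vector of total doses (cTildeAB + cTildeAC),
#'   increasing.
#' @param deltaC fixed input difference.
#' @param ... passed to \code{\link{runComparatorCondition}}.
#' @return list with the per-dose table and logicals \code{tauBMonotone},
#'   \code{tauCMonotone}.
#' @export
totalDoseEffect <- function(cTildeT, deltaC = 0.5, ...) {
  args <- list(...)
  if (!is.null(args$competition) && args$competition == "independent")
    stop("total-dose competition effect requires shared-enzyme mode")
  if (any(diff(cTildeT) <= 0)) stop("cTildeT must be increasing")
  cab <- (cTildeT + deltaC) / 2; cac <- (cTildeT - deltaC) / 2
  if (any(cab < 0) || any(cac < 0))
    stop("doses must be non-negative; reduce |deltaC| or raise cTildeT")
  res <- Map(function(a, c) runComparatorCondition(a, c, ...), cab, cac)
  tab <- data.frame(
    cTildeT = cTildeT, cTildeAB = cab, cTildeAC = cac,
    tauB = vapply(res, function(r) r@tauB, numeric(1)),
    tauC = vapply(res, function(r) r@tauC, numeric(1))
  )
  list(table = tab,
       tauBMonotone = !is.unsorted(tab$tauB),
       tauCMonotone = !is.unsorted(tab$tauC))
}
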