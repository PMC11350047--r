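#' @import methods
NULL

#' Linker circuit description
#'
#' One crosslinking-linker population together with the division-trigger pool
#' that cleaves it. A linker carries two trigger-binding sites (i = 1, 2); each
#' site is cleaved by its own single-stranded trigger species via
#' toehold-mediated strand displacement. For a delayed circuit the triggers are
#' initially sequestered in DNA:RNA hybrids (inhibited triggers) according to
#' the normalized inhibitor dose \code{cTilde}; an RNase H pool releases them
#' over time.
#'
#' @slot label single alphanumeric string identifying the circuit (e.g. "AB").
#' @slot delayed logical; if \code{TRUE} the trigger pool starts partitioned
#'   between free and inhibited forms according to \code{cTilde}, otherwise all
#'   trigger is free at t = 0 and \code{cTilde} is ignored.
#' @slot linkerTotal total linker concentration (uM); equals the total of each
#'   of the two site populations.
#' @slot triggerTotal total concentration of each trigger species (uM),
#'   i.e. \eqn{u^{tot}_{T,i}} for i = 1, 2.
#' @slot cTilde normalized initial total inhibitor-RNA dose, the ratio of total
#'   inhibitor RNA to total trigger (dimensionless).
#' @slot kOn trigger-toehold hybridization rate (1/(uM s)).
#' @slot kDisp strand-displacement (branch-migration) rate (1/s); used only in
#'   the two-step scheme.
#' @slot weight weight of this linker in a combined uncleaved fraction (its
#'   share of the total linker DNA); \code{NA} when not applicable.
#'
#' @exportClass LinkerCircuit
setClass("LinkerCircuit",
  representation(
    label = "character",
    delayed = "logical",
    linkerTotal = "numeric",
    triggerTotal = "numeric",
    cTilde = "numeric",
    kOn = "numeric",
    kDisp = "numeric",
    weight = "numeric"
  ),
  prototype(weight = NA_real_, delayed = FALSE, cTilde = 0)
)

setValidity("LinkerCircuit", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L || !grepl("^[A-Za-z0-9]+$", object@label))
    msg <- c(msg, "label must be a single alphanumeric string")
  for (s in c("linkerTotal", "triggerTotal", "cTilde", "kOn", "kDisp")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Well-mixed circuit model
#'
#' A collection of linker circuits sharing one RNase H pool and one set of
#' Michaelis-Menten / hybridization parameters. The enzyme level is expressed
#' in the units the bench protocol uses (U/uL); \code{kCat} carries the unit
#' conversion so that printed enzyme doses are usable verbatim.
#'
#' @slot circuits list of \linkS4class{LinkerCircuit} objects with unique
#'   labels.
#' @slot enzyme RNase H level (U/uL).
#' @slot kCat Michaelis-Menten turnover, uM/s per (U/uL) of enzyme.
#' @slot Km Michaelis constant of the RNase H reaction (uM).
#' @slot kHybRNA hybridization rate of free triggers with inhibitor RNAs
#'   (1/(uM s)).
#' @slot competition \code{"independent"} (each inhibited-trigger substrate has
#'   its own Michaelis-Menten denominator) or \code{"shared"} (one enzyme pool;
#'   the denominator contains the sum of all inhibited-trigger substrates).
#' @slot sdMode \code{"two-step"} (bimolecular toehold binding followed by a
#'   first-order displacement step) or \code{"single-step"} (effective
#'   bimolecular cleavage).
#'
#' @exportClass CircuitModel
setClass("CircuitModel",
  representation(
    circuits = "list",
    enzyme = "numeric",
    kCat = "numeric",
    Km = "numeric",
    kHybRNA = "numeric",
    competition = "character",
    sdMode = "character"
  ),
  prototype(competition = "independent", sdMode = "two-step")
)

setValidity("CircuitModel", function(object) {
  msg <- character(0)
  if (!length(object@circuits) ||
      !all(vapply(object@circuits, is, logical(1), "LinkerCircuit")))
    msg <- c(msg, "circuits must be a non-empty list of LinkerCircuit objects")
  labs <- vapply(object@circuits, function(x) x@label, character(1))
  if (anyDuplicated(labs)) msg <- c(msg, "circuit labels must be unique")
  if (object@enzyme < 0) msg <- c(msg, "enzyme must be >= 0")
  if (object@kCat < 0 || object@kHybRNA < 0) msg <- c(msg, "rates must be >= 0")
  if (!(object@Km > 0)) msg <- c(msg, "Km must be > 0")
  if (!object@competition %in% c("independent", "shared"))
    msg <- c(msg, "competition must be 'independent' or 'shared'")
  if (!object@sdMode %in% c("two-step", "single-step"))
    msg <- c(msg, "sdMode must be 'two-step' or 'single-step'")
  if (length(msg)) msg else TRUE
})

#' Well-mixed trajectory
#'
#' Result of integrating the well-mixed circuit kinetics: concentrations of
#' every species at every requested time.
#'
#' @slot times numeric vector of sample times (s).
#' @slot states matrix, one row per time, one column per species.
#' @slot model the \linkS4class{CircuitModel} that was integrated.
#'
#' @exportClass WellMixedTrajectory
setClass("WellMixedTrajectory",
  representation(times = "numeric", states = "matrix", model = "CircuitModel")
)

#' Simulation grid for the reaction-diffusion engine
#'
#' A square-cell 2D lattice holding one circular droplet. The droplet mask is
#' the set of cells whose centres lie within \code{radius} of \code{center}.
#'
#' @slot nx,ny number of cells along x and y.
#' @slot spacing cell edge length (um).
#' @slot center droplet centre, length-2 numeric (um).
#' @slot radius droplet radius (um).
#'
#' @exportClass GridSpec
setClass("GridSpec",
  representation(nx = "integer", ny = "integer", spacing = "numeric",
                 center = "numeric", radius = "numeric")
)

setValidity("GridSpec", function(object) {
  msg <- character(0)
  if (object@nx < 3L || object@ny < 3L) msg <- c(msg, "grid must be at least 3x3")
  if (!(object@spacing > 0)) msg <- c(msg, "spacing must be > 0")
  if (length(object@center) != 2L) msg <- c(msg, "center must have length 2")
  if (!(object@radius > 0)) msg <- c(msg, "radius must be > 0")
  if (!length(msg)) {
    m <- dropletMask(object)
    if (!any(m)) msg <- c(msg, "droplet mask is empty")
    if (any(m[1, ]) || any(m[object@ny, ]) || any(m[, 1]) || any(m[, object@nx]))
      msg <- c(msg, "droplet must lie strictly inside the domain")
  }
  if (length(msg)) msg else TRUE
})

#' Position-dependent diffusion coefficients
#'
#' Diffusion coefficients (um^2/s) inside and outside the droplet, one per
#' species class. Classes: \code{"trigger"} (free triggers), \code{"inhibited"}
#' (trigger:RNA hybrids), \code{"rna"} (free inhibitor RNA), \code{"linker"}
#' (linker sites in any state). The droplet is a condensed phase of the
#' nanostructures, so by default linkers are immobile and small species are
#' slowed inside.
#'
#' @slot dInside named numeric, one entry per class (um^2/s).
#' @slot dOutside named numeric, one entry per class (um^2/s).
#'
#' @exportClass DiffusionMap
setClass("DiffusionMap",
  representation(dInside = "numeric", dOutside = "numeric")
)

setValidity("DiffusionMap", function(object) {
  cls <- c("trigger", "inhibited", "rna", "linker")
  msg <- character(0)
  for (s in c("dInside", "dOutside")) {
    v <- slot(object, s)
    if (!all(cls %in% names(v)))
      msg <- c(msg, sprintf("%s must be named with classes %s", s,
                            paste(cls, collapse = ", ")))
    if (any(v < 0)) msg <- c(msg, sprintf("%s must be >= 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Reaction-diffusion trajectory
#'
#' Output of the 2D reaction-diffusion engine: droplet- and domain-averaged
#' species traces, per-linker uncleaved-fraction statistics, optional full-field
#' snapshots, and the per-cell time at which the local uncleaved fraction of
#' each linker first dropped below one half.
#'
#' @slot times sample times (s).
#' @slot dropletMeans matrix time x species, means over the droplet mask.
#' @slot domainMeans matrix time x species, means over the full domain.
#' @slot linkerStats data.frame with columns \code{time}, \code{label},
#'   \code{w} (droplet-mean uncleaved fraction) and \code{cv} (spatial
#'   coefficient of variation of the uncleaved-linker field over the droplet).
#' @slot snapshots named list: for each snapshot time (name = time), a named
#'   list of 2D fields.
#' @slot crossingTimes named list of matrices, per linker label: first time the
#'   local uncleaved fraction fell to 0.5 (NA where it never did).
#' @slot grid the \linkS4class{GridSpec} used.
#' @slot model the \linkS4class{CircuitModel} used.
#' @slot clampCount number of cell-updates clamped at zero to preserve
#'   non-negativity.
#'
#' @exportClass RDTrajectory
setClass("RDTrajectory",
  representation(times = "numeric", dropletMeans = "matrix",
                 domainMeans = "matrix", linkerStats = "data.frame",
                 snapshots = "list", crossingTimes = "list",
                 grid = "GridSpec", model = "CircuitModel",
                 clampCount = "numeric")
)

#' Division-ratio trace
#'
#' Time series of the uncleaved-linker fraction w and the division ratio
#' r_div of one droplet component, under the cooperative (Hill-type)
#' phase-separation threshold model. For image-derived traces w is unknown and
#' left empty.
#'
#' @slot times sample times.
#' @slot w uncleaved-linker fraction, normalized to its initial value
#'   (empty for image-derived traces).
#' @slot rDiv division ratio in [0, 1].
#' @slot component component label ("B", "C", ...).
#' @slot K Hill threshold on the w scale (NA for image-derived traces).
#' @slot n Hill cooperativity (NA for image-derived traces).
#'
#' @exportClass DivisionTrace
setClass("DivisionTrace",
  representation(times = "numeric", w = "numeric", rDiv = "numeric",
                 component = "character", K = "numeric", n = "numeric"),
  prototype(w = numeric(0), K = NA_real_, n = NA_real_)
)

setValidity("DivisionTrace", function(object) {
  msg <- character(0)
  if (length(object@rDiv) != length(object@times))
    msg <- c(msg, "rDiv and times must have equal length")
  if (length(object@w) && length(object@w) != length(object@times))
    msg <- c(msg, "w, when present, must match times in length")
  finite <- object@rDiv[!is.na(object@rDiv)]
  if (length(finite) && (min(finite) < -1e-9 || max(finite) > 1 + 1e-9))
    msg <- c(msg, "rDiv must lie within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Division-pathway result for one condition
#'
#' Division times of the B and C components, their signed difference, and the
#' resulting pathway label. Pathway 1 means the C droplet divides first
#' (delta tau > 0); Pathway 2 means the B droplet divides first.
#'
#' @slot tauB,tauC division times (time at which r_div crosses 0.5); NA when
#'   the component never divides within the simulated horizon.
#' @slot deltaTau tauB - tauC, NA if either is undefined.
#' @slot pathway "Pathway 1", "Pathway 2", "tie" or "undefined".
#' @slot traces named list of \linkS4class{DivisionTrace} objects ("B", "C").
#'
#' @exportClass PathwayResult
setClass("PathwayResult",
  representation(tauB = "numeric", tauC = "numeric", deltaTau = "numeric",
                 pathway = "character", traces = "list")
)

#' Comparator sweep result
#'
#' Per-condition division-time differences of the molecular concentration
#' comparator, together with the estimated offset concentration sigma (the
#' input difference at which the output pathway switches).
#'
#' @slot table data.frame with columns \code{cTildeAB}, \code{cTildeAC},
#'   \code{deltaC}, \code{tauB}, \code{tauC}, \code{deltaTau}, \code{pathway}.
#' @slot sigma offset concentration (bracket midpoint); NA when the sign of
#'   delta tau does not change over the tested range.
#' @slot sigmaStatus "ok", "outside range".
#' @slot sigmaRefined optional bisection refinement of sigma (NA if not
#'   requested).
#' @slot results list of \linkS4class{PathwayResult}, one per condition.
#'
#' @exportClass ComparatorResult
setClass("ComparatorResult",
  representation(table = "data.frame", sigma = "numeric",
                 sigmaStatus = "character", sigmaRefined = "numeric",
                 results = "list"),
  prototype(sigmaRefined = NA_real_)
)

#' Multi-channel fluorescence image stack
#'
#' Time-ordered frames of 2 or 3 channels sharing one geometry, as produced by
#' the synthetic movie generator or read from a multi-page TIFF.
#'
#' @slot data 4D numeric array, dimensions (row, column, channel, frame).
#' @slot channels channel labels, e.g. c("A", "B") or c("A", "B", "C").
#' @slot pixelSize pixel edge length (um); NA when unknown.
#' @slot times frame times; defaults to the frame index.
#'
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", channels = "character",
                 pixelSize = "numeric", times = "numeric"),
  prototype(pixelSize = NA_real_)
)

setValidity("ImageStack", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array (y, x, channel, frame)")
  else {
    if (d[3] != length(object@channels))
      msg <- c(msg, "number of channels must match the channel labels")
    if (d[4] < 1L) msg <- c(msg, "stack must contain at least one frame")
    if (length(object@times) != d[4])
      msg <- c(msg, "times must have one entry per frame")
  }
  if (anyDuplicated(object@channels)) msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})
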