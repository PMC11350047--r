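#' Binary mixed-droplet model with a time-delay circuit
#'
#' The A:B droplet carries two linker populations: the plain linker (90% of
#' the linker DNA), cleaved immediately by its free division triggers, and the
#' delayed linker (10%), whose triggers pass through the inhibitor-RNA /
#' RNase H time-delay circuit. Defaults follow the bench protocol: linker
#' totals after dilution (0.36 and 0.04 uM), 2.5 uM of each plain trigger and
#' 1.0 uM total of each delayed trigger.
#'
#' @param cTilde normalized inhibitor-RNA dose of the delayed circuit.
#' @param enzyme RNase H level (U/uL).
#' @param linkerTotal total linker DNA (uM), split 90/10 between the plain and
#'   delayed linkers.
#' @param plainTrigger free plain-trigger concentration (uM, per trigger).
#' @param delayedTrigger total delayed-trigger concentration (uM, per
#'   trigger).
#' @param kOn,kDisp trigger-linker rates shared by both linkers.
#' @param ... further arguments passed to \code{\link{circuitModel}}.
#' @return a \linkS4class{CircuitModel} with circuits "AB" (plain, weight 0.9)
#'   and "ABd" (delayed, weight 0.1).
#' @examples
#' m <- abDropletModel(cTilde = 1.5, enzyme = 2.5e-2)
#' @export
abDropletModel <- function(cTilde = 1.5, enzyme = 2.5e-2, linkerTotal = 0.4,
                           plainTrigger = 2.5, delayedTrigger = 1.0,
                           kOn = 0.1, kDisp = 0.05, ...) {
  circuitModel(
    list(
      linkerCircuit("AB", 0.9 * linkerTotal, plainTrigger, delayed = FALSE,
                    kOn = kOn, kDisp = kDisp, weight = 0.9),
      linkerCircuit("ABd", 0.1 * linkerTotal, delayedTrigger, cTilde = cTilde,
                    delayed = TRUE, kOn = kOn, kDisp = kDisp, weight = 0.1)
    ),
    enzyme = enzyme, ...
  )
}

#' Default spatial configuration for the mixed-droplet simulation
#'
#' One circular droplet of radius 50 um centred in a 160 x 160 um domain on a
#' 64 x 64 grid; linker nanostructures immobile, small species slowed
#' 10-fold inside the condensed phase. The default enzyme dose (0.1 U/uL)
#' keeps the delayed-linker cleavage reaction-limited, i.e. slower than
#' trigger diffusion across the droplet - the regime in which the delayed
#' linker degrades spatially uniformly while the plain linker is cleaved
#' outside-in by the trigger front - yet still completes within a desk-scale
#' horizon (a few thousand seconds).
#'
#' @param cTilde inhibitor dose of the delayed circuit.
#' @param enzyme RNase H level (U/uL).
#' @param nx,ny grid size.
#' @param spacing cell size (um).
#' @param radius droplet radius (um).
#' @return list with elements \code{model}, \code{grid}, \code{dmap}.
#' @export
spatialDropletConfig <- function(cTilde = 1.5, enzyme = 0.1, nx = 64,
                                 ny = 64, spacing = 2.5, radius = 50) {
  list(model = abDropletModel(cTilde = cTilde, enzyme = enzyme),
       grid = gridSpec(nx, ny, spacing, radius),
       dmap = diffusionMap())
}
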