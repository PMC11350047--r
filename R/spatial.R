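#' Construct a grid specification
#'
#' @param nx,ny grid size in cells.
#' @param spacing cell edge length (um).
#' @param radius droplet radius (um).
#' @param center droplet centre (um); defaults to the domain centre.
#' @return a \linkS4class{GridSpec}.
#' @examples
#' gridSpec(64, 64, spacing = 2.5, radius = 50)
#' @export
gridSpec <- function(nx, ny, spacing, radius, center = NULL) {
  if (is.null(center)) center <- c(nx, ny) * spacing / 2
  new("GridSpec", nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
      center = center, radius = radius)
}

#' Cell-centre coordinates of a grid
#' @param grid a \linkS4class{GridSpec}.
#' @return list with matrices \code{x}, \code{y} (um) and \code{r} (distance
#'   from the droplet centre).
#' @export
cellCoordinates <- function(grid) {
  xs <- (seq_len(grid@nx) - 0.5) * grid@spacing
  ys <- (seq_len(grid@ny) - 0.5) * grid@spacing
  x <- matrix(xs, grid@ny, grid@nx, byrow = TRUE)
  y <- matrix(ys, grid@ny, grid@nx)
  list(x = x, y = y,
       r = sqrt((x - grid@center[1])^2 + (y - grid@center[2])^2))
}

#' Droplet mask of a grid
#' @param grid a \linkS4class{GridSpec}.
#' @return logical matrix, TRUE inside the droplet.
#' @export
dropletMask <- function(grid) cellCoordinates(grid)$r <= grid@radius

#' Construct a diffusion map
#'
#' @param dInside,dOutside named numeric vectors of diffusion coefficients
#'   (um^2/s) for classes \code{trigger}, \code{inhibited}, \code{rna},
#'   \code{linker}. Defaults: small species slowed 10-fold inside the condensed
#'   droplet phase; linker nanostructures immobile.
#' @return a \linkS4class{DiffusionMap}.
#' @export
diffusionMap <- function(
    dInside = c(trigger = 1, inhibited = 1, rna = 1, linker = 0),
    dOutside = c(trigger = 10, inhibited = 10, rna = 10, linker = 0)) {
  new("DiffusionMap", dInside = dInside, dOutside = dOutside)
}

.speciesClass <- function(name) {
  kind <- sub("\\..*$", "", name)
  switch(kind, T = "trigger", iT = "inhibited", R = "rna",
         Sf = , Sb = , Sd = "linker",
         stop("unknown species kind in '", name, "'"))
}

.dFields <- function(model, grid, dmap) {
  inside <- dropletMask(grid)
  lapply(structure(speciesNames(model), names = speciesNames(model)),
         function(nm) {
           cl <- .speciesClass(nm)
           ifelse(inside, dmap@dInside[[cl]], dmap@dOutside[[cl]])
         })
}

#' Five-point Laplacian with no-flux boundaries
#'
#' Discrete Laplacian on a regular grid using the 5-point stencil with
#' reflecting (zero-flux) boundaries. The stencil is conservative: the output
#' sums to zero exactly.
#'
#' @param field 2D numeric matrix.
#' @param spacing cell edge length.
#' @return matrix of the same shape.
#' @export
laplacianNoFlux <- function(field, spacing) {
  if (!is.matrix(field)) stop("field must be a matrix")
  nr <- nrow(field); nc <- ncol(field)
  if (nr < 2L || nc < 2L) stop("field must be at least 2x2")
  up <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (up + down + left + right - 4 * field) / spacing^2
}

## divergence of D grad u with spatially varying D; interface coefficients are
## harmonic means (conservative treatment of the piecewise-constant D jump at
## the droplet surface); no-flux domain boundaries.
.diffuseVarD <- function(field, dfield, spacing) {
  nr <- nrow(field); nc <- ncol(field)
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  ## vertical faces (between rows)
  dv <- harm(dfield[-nr, , drop = FALSE], dfield[-1L, , drop = FALSE])
  fv <- dv * (field[-1L, , drop = FALSE] - field[-nr, , drop = FALSE])
  ## horizontal faces (between columns)
  dh <- harm(dfield[, -nc, drop = FALSE], dfield[, -1L, drop = FALSE])
  fh <- dh * (field[, -1L, drop = FALSE] - field[, -nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  out[-nr, ] <- out[-nr, ] + fv
  out[-1L, ] <- out[-1L, ] - fv
  out[, -nc] <- out[, -nc] + fh
  out[, -1L] <- out[, -1L] - fh
  out / spacing^2
}

#' Initial concentration fields
#'
#' Lays out the model's initial concentrations on the grid. In the
#' \code{"droplet"} layout (the experimental geometry) the linker sites sit
#' inside the droplet at their nominal concentrations and the trigger mixture
#' (free/inhibited triggers and inhibitor RNAs) is added to the bulk outside.
#' In the \code{"uniform"} layout every species is spread homogeneously at its
#' nominal value.
#'
#' @param model a \linkS4class{CircuitModel}.
#' @param grid a \linkS4class{GridSpec}.
#' @param layout "droplet" or "uniform".
#' @return named list of 2D matrices (uM).
#' @export
initialFields <- function(model, grid, layout = c("droplet", "uniform")) {
  layout <- match.arg(layout)
  inside <- dropletMask(grid)
  init <- initialState(model)
  lapply(structure(names(init), names = names(init)), function(nm) {
    v <- init[[nm]]
    if (layout == "uniform") return(matrix(v, grid@ny, grid@nx))
    if (.speciesClass(nm) == "linker") ifelse(inside, v, 0)
    else ifelse(inside, 0, v)
  })
}

#' One operator-splitting step of the reaction-diffusion system
#'
#' Advances all fields by \code{dt}: a second-order (Heun) local reaction
#' update followed by an explicit conservative diffusion update with
#' harmonic-mean interface coefficients and no-flux boundaries. Negative
#' excursions are clamped at zero and counted.
#'
#' @param fields named list of 2D matrices.
#' @param dt time step (s); must satisfy the explicit diffusion stability
#'   bound \code{dt <= spacing^2 / (4 max D)}.
#' @param grid a \linkS4class{GridSpec}.
#' @param dmap a \linkS4class{DiffusionMap}.
#' @param model a \linkS4class{CircuitModel}.
#' @param dfields precomputed per-species diffusion-coefficient fields
#'   (internal use; recomputed when NULL).
#' @return list with \code{fields} (updated) and \code{clamped} (number of
#'   clamped cell-updates).
#' @export
stepRD <- function(fields, dt, grid, dmap, model, dfields = NULL) {
  if (is.null(dfields)) dfields <- .dFields(model, grid, dmap)
  dmax <- max(c(dmap@dInside, dmap@dOutside))
  if (dmax > 0 && dt > grid@spacing^2 / (4 * dmax) + 1e-12)
    stop(sprintf(
      "dt = %g violates the explicit diffusion stability bound; use dt <= %g",
      dt, grid@spacing^2 / (4 * dmax)))
  ## reaction half: Heun (RK2)
  k1 <- .circuitRates(fields, model)
  mid <- mapply(function(f, d) f + dt * d, fields, k1, SIMPLIFY = FALSE)
  k2 <- .circuitRates(lapply(mid, function(m) pmax(m, 0)), model)
  fields <- mapply(function(f, d1, d2) f + dt * (d1 + d2) / 2,
                   fields, k1, k2, SIMPLIFY = FALSE)
  ## diffusion half: explicit conservative update
  for (nm in names(fields)) {
    if (max(dfields[[nm]]) > 0)
      fields[[nm]] <- fields[[nm]] +
        dt * .diffuseVarD(fields[[nm]], dfields[[nm]], grid@spacing)
  }
  clamped <- 0L
  for (nm in names(fields)) {
    neg <- fields[[nm]] < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg)
      fields[[nm]][neg] <- 0
    }
  }
  list(fields = fields, clamped = clamped)
}

.linkerFieldStats <- function(fields, circ, region) {
  L <- circ@linkerTotal
  p1 <- fields[[.sp("Sd", circ@label, 1)]] / L
  p2 <- fields[[.sp("Sd", circ@label, 2)]] / L
  wLocal <- 1 - p1 * p2
  unc <- L * wLocal
  vals <- unc[region]
  list(w = mean(wLocal[region]),
       cv = if (mean(vals) > 0) stats::sd(vals) / mean(vals) else 0,
       wField = wLocal)
}

## column indices (0-based) of the per-(circuit, site) species for the
## compiled stepper
.siteIndexTable <- function(model, nms) {
  rows <- list(); rates <- list()
  for (circ in model@circuits) for (i in 1:2) {
    rows[[length(rows) + 1L]] <-
      match(.sp(c("T", "iT", "R", "Sf", "Sb", "Sd"), circ@label, i), nms) - 1L
    rates[[length(rates) + 1L]] <- c(circ@kOn, circ@kDisp)
  }
  list(idx = do.call(rbind, rows), rate = do.call(rbind, rates))
}

#' Simulate the reaction-diffusion system
#'
#' Integrates the spatial circuit kinetics on a 2D grid (compiled inner loop;
#' the exported \code{\link{stepRD}} is the equivalent R reference stepper)
#' and records droplet-averaged and domain-averaged species traces, per-linker
#' uncleaved-fraction statistics, optional full-field snapshots, and per-cell
#' half-cleavage crossing times (tracked at the recording resolution).
#'
#' @param model a \linkS4class{CircuitModel}.
#' @param grid a \linkS4class{GridSpec}.
#' @param dmap a \linkS4class{DiffusionMap}.
#' @param times strictly increasing recording times (s), starting at 0.
#' @param dt step size; default 0.2 times the explicit stability bound.
#' @param snapshotTimes recording times at which full fields are stored;
#'   default none.
#' @param snapshotSpecies species to store at snapshot times; default the
#'   uncleaved-linker fraction field per circuit (named \code{w.<label>}).
#' @param init optional initial fields (default
#'   \code{initialFields(model, grid)}).
#' @param layout initial layout when \code{init} is NULL.
#' @return an \linkS4class{RDTrajectory}.
#' @export
simulateRD <- function(model, grid, dmap, times, dt = NULL,
                       snapshotTimes = numeric(0), snapshotSpecies = NULL,
                       init = NULL, layout = "droplet") {
  validObject(model); validObject(grid); validObject(dmap)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  dmax <- max(c(dmap@dInside, dmap@dOutside))
  stabBound <- grid@spacing^2 / (4 * max(dmax, 1e-300))
  if (is.null(dt))
    dt <- if (dmax > 0) 0.2 * stabBound else min(diff(times)) / 20
  if (dmax > 0 && dt > stabBound + 1e-12)
    stop(sprintf(
      "dt = %g violates the explicit diffusion stability bound; use dt <= %g",
      dt, stabBound))
  fields <- if (is.null(init)) initialFields(model, grid, layout) else init
  dfields <- .dFields(model, grid, dmap)
  inside <- dropletMask(grid)
  nms <- speciesNames(model)
  if (!all(nms %in% names(fields)))
    stop("init fields are missing species")
  ncell <- grid@ny * grid@nx
  U <- vapply(nms, function(nm) as.vector(fields[[nm]]), numeric(ncell))
  D <- vapply(nms, function(nm) as.vector(dfields[[nm]]), numeric(ncell))
  st <- .siteIndexTable(model, nms)
  mobile <- apply(D, 2, max) > 0
  recTimes <- times
  nRec <- length(recTimes)
  dropletMeans <- matrix(NA_real_, nRec, length(nms),
                         dimnames = list(NULL, nms))
  domainMeans <- dropletMeans
  circs <- model@circuits
  labs <- vapply(circs, function(c) c@label, character(1))
  statRows <- vector("list", nRec * length(circs))
  snapshots <- list()
  crossing <- lapply(labs, function(l) matrix(NA_real_, grid@ny, grid@nx))
  names(crossing) <- labs
  clampCount <- 0
  fieldsFromU <- function() {
    out <- lapply(seq_along(nms), function(p) matrix(U[, p], grid@ny, grid@nx))
    names(out) <- nms
    out
  }
  record <- function(k, tNow) {
    fl <- fieldsFromU()
    for (nm in nms) {
      dropletMeans[k, nm] <<- mean(fl[[nm]][inside])
      domainMeans[k, nm] <<- mean(fl[[nm]])
    }
    for (j in seq_along(circs)) {
      stats <- .linkerFieldStats(fl, circs[[j]], inside)
      statRows[[(k - 1) * length(circs) + j]] <<-
        data.frame(time = tNow, label = labs[j], w = stats$w, cv = stats$cv)
      hit <- is.na(crossing[[j]]) & stats$wField <= 0.5
      if (any(hit)) crossing[[j]][hit] <<- tNow
    }
    if (length(snapshotTimes) && any(abs(snapshotTimes - tNow) < 1e-9 +
                                       min(diff(recTimes)) / 2)) {
      snap <- if (is.null(snapshotSpecies)) {
        out <- lapply(circs, function(c) .linkerFieldStats(fl, c, inside)$wField)
        names(out) <- paste0("w.", labs)
        out
      } else fl[snapshotSpecies]
      snapshots[[sprintf("%g", tNow)]] <<- snap
    }
  }
  tNow <- recTimes[1]
  if (abs(tNow) > 1e-12) stop("times must start at 0")
  record(1L, tNow)
  for (k in 2:nRec) {
    target <- recTimes[k]
    nSteps <- max(1L, round((target - tNow) / dt))
    h <- (target - tNow) / nSteps
    res <- .rdStepCpp(U, D, grid@ny, grid@nx, grid@spacing, h, nSteps,
                      st$idx, st$rate, model@kCat, model@Km, model@kHybRNA,
                      model@enzyme, model@competition == "shared",
                      model@sdMode == "two-step", mobile)
    U <- res$U
    clampCount <- clampCount + res$clamped
    tNow <- target
    record(k, target)
  }
  if (clampCount > 0)
    warning(clampCount, " cell-updates clamped at zero")
  new("RDTrajectory", times = recTimes, dropletMeans = dropletMeans,
      domainMeans = domainMeans, linkerStats = do.call(rbind, statRows),
      snapshots = snapshots, crossingTimes = crossing, grid = grid,
      model = model, clampCount = clampCount)
}

#' @rdname uncleavedFraction
#' @param region for spatial trajectories, \code{"droplet"} uses the
#'   droplet-mask mean of the local uncleaved fraction; \code{"domain"}
#'   computes w from domain-mean displaced-site concentrations (appropriate
#'   for well-mixed comparisons).
setMethod("uncleavedFraction", "RDTrajectory",
          function(x, label, region = c("droplet", "domain"), ...) {
  region <- match.arg(region)
  if (region == "droplet") {
    rows <- x@linkerStats$label == label
    if (!any(rows)) stop("no circuit with label '", label, "'")
    x@linkerStats$w[rows]
  } else {
    .wFromStates(x@domainMeans, .findCircuit(x@model, label))
  }
})

#' @rdname sampleTimes
setMethod("sampleTimes", "RDTrajectory", function(x) x@times)

setMethod("show", "RDTrajectory", function(object) {
  cat(sprintf("RDTrajectory: %dx%d grid, %d samples over [%g, %g] s, %d snapshot(s)\n",
              object@grid@ny, object@grid@nx, length(object@times),
              min(object@times), max(object@times), length(object@snapshots)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %dx%d cells, spacing %g um; droplet radius %g um at (%g, %g)\n",
              object@nx, object@ny, object@spacing, object@radius,
              object@center[1], object@center[2]))
})

#' Radial concentration profile
#'
#' Mean concentration in concentric annuli around the droplet centre. Empty
#' annuli are reported as NA, not zero. The annulus-count-weighted mean of the
#' profile over the droplet equals the droplet mean of the field.
#'
#' @param field 2D matrix aligned to \code{grid}.
#' @param grid a \linkS4class{GridSpec}.
#' @param nBins number of equal-width annuli between 0 and the droplet radius.
#' @param maxRadius outer radius of the profile (default: droplet radius).
#' @return data.frame with columns \code{rMid} (annulus mid-radius),
#'   \code{mean} and \code{n} (cells in the annulus).
#' @export
radialProfile <- function(field, grid, nBins = 8, maxRadius = grid@radius) {
  if (!identical(dim(field), c(grid@ny, grid@nx)))
    stop("field shape does not match the grid")
  r <- cellCoordinates(grid)$r
  edges <- seq(0, maxRadius, length.out = nBins + 1)
  bin <- cut(r, edges, include.lowest = TRUE, labels = FALSE)
  means <- rep(NA_real_, nBins); ns <- integer(nBins)
  for (b in seq_len(nBins)) {
    sel <- !is.na(bin) & bin == b
    ns[b] <- sum(sel)
    if (ns[b]) means[b] <- mean(field[sel])
  }
  data.frame(rMid = (edges[-1] + edges[-(nBins + 1)]) / 2,
             mean = means, n = ns)
}
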