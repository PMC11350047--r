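#' Read a simulation configuration
#'
#' Parses a YAML configuration describing a circuit model and, optionally, the
#' spatial grid and diffusion map. Concentrations are in uM, the enzyme level
#' in U/uL, lengths in um, rates in 1/s or 1/(uM s). See
#' \code{system.file("extdata", "ab-droplet.yaml", package = "DropletTimer")}
#' for a complete example.
#'
#' @param path path to the YAML file.
#' @return list with elements \code{model} (a \linkS4class{CircuitModel}),
#'   \code{grid} (\linkS4class{GridSpec} or NULL), \code{dmap}
#'   (\linkS4class{DiffusionMap} or NULL) and \code{times} (numeric or NULL).
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$circuits)) stop("config must contain a 'circuits' section")
  circuits <- lapply(cfg$circuits, function(cc) {
    linkerCircuit(
      label = cc$label,
      linkerTotal = cc$linkerTotal,
      triggerTotal = cc$triggerTotal,
      cTilde = cc$cTilde %||% 0,
      delayed = cc$delayed %||% ((cc$cTilde %||% 0) > 0),
      kOn = cc$kOn %||% 0.1,
      kDisp = cc$kDisp %||% 0.05,
      weight = cc$weight %||% NA_real_
    )
  })
  p <- cfg$params %||% list()
  model <- circuitModel(
    circuits,
    enzyme = cfg$enzyme %||% 0.25,
    kCat = p$kCat %||% 2e-3,
    Km = p$Km %||% 0.5,
    kHybRNA = p$kHybRNA %||% 0.05,
    competition = p$competition %||% "independent",
    sdMode = p$sdMode %||% "two-step"
  )
  grid <- NULL
  if (!is.null(cfg$grid))
    grid <- gridSpec(cfg$grid$nx, cfg$grid$ny, cfg$grid$spacing,
                     cfg$grid$radius,
                     center = unlist(cfg$grid$center) %||% NULL)
  dmap <- NULL
  if (!is.null(cfg$diffusion)) {
    toVec <- function(x) unlist(x)[c("trigger", "inhibited", "rna", "linker")]
    dmap <- diffusionMap(dInside = toVec(cfg$diffusion$inside),
                         dOutside = toVec(cfg$diffusion$outside))
  }
  times <- NULL
  if (!is.null(cfg$times))
    times <- seq(cfg$times$from %||% 0, cfg$times$to, by = cfg$times$by)
  list(model = model, grid = grid, dmap = dmap, times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as tidy CSV
#'
#' One row per (time, species) pair, columns \code{time}, \code{species},
#' \code{concentration}.
#'
#' @param traj a \linkS4class{WellMixedTrajectory}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTraceCSV <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write division traces as CSV
#'
#' Columns \code{time}, \code{component}, \code{w}, \code{rDiv}; the schema is
#' shared between simulation-derived and image-derived traces (w is NA for the
#' latter).
#'
#' @param traces a \linkS4class{DivisionTrace} or a list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDivisionCSV <- function(traces, path) {
  if (is(traces, "DivisionTrace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time = tr@times, component = tr@component,
               w = if (length(tr@w)) tr@w else NA_real_, rDiv = tr@rDiv)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written channel-major: all frames of channel 1, then channel 2,
#' etc. Pixel values are stored as 32-bit floats after division by
#' \code{scale} (TIFF float samples live in [0, 1]); pass the same scale to
#' \code{\link{readStackTIFF}} to restore the original intensities.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output file.
#' @param scale intensity divisor; the default maps the stack maximum to 1.
#' @return the scale used, invisibly.
#' @export
writeStackTIFF <- function(stack, path, scale = max(stack@data, 1)) {
  d <- dim(stack@data)
  lo <- min(stack@data)
  if (lo < 0) stop("negative intensities cannot be stored; shift the stack")
  if (max(stack@data) / scale > 1 + 1e-7)
    stop("scale too small: values above 1 do not fit a float TIFF sample")
  pages <- list()
  for (k in seq_len(d[3])) for (f in seq_len(d[4]))
    pages[[length(pages) + 1L]] <- pmin(stack@data[, , k, f] / scale, 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file with \code{length(channels) * nFrames} pages.
#' @param channels channel labels.
#' @param order \code{"channel-major"} (all frames of channel 1 first) or
#'   \code{"interleaved"} (channels cycle within each frame).
#' @param times optional frame times.
#' @param scale intensity multiplier undoing the divisor used by
#'   \code{\link{writeStackTIFF}}.
#' @return an \linkS4class{ImageStack}.
#' @export
readStackTIFF <- function(path, channels, order = c("channel-major",
                                                    "interleaved"),
                          times = NULL, scale = 1) {
  order <- match.arg(order)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("page count is not a multiple of the channel count")
  nF <- length(pages) %/% nc
  d <- dim(pages[[1]])[1:2]
  dat <- array(0, c(d, nc, nF))
  for (p in seq_along(pages)) {
    if (order == "channel-major") {
      k <- (p - 1L) %/% nF + 1L; f <- (p - 1L) %% nF + 1L
    } else {
      f <- (p - 1L) %/% nc + 1L; k <- (p - 1L) %% nc + 1L
    }
    pg <- pages[[p]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    dat[, , k, f] <- pg * scale
  }
  imageStack(dat, channels, times = times)
}

#' Write reaction-diffusion snapshots to a multi-page TIFF
#'
#' One page per (snapshot time, field), each normalized to [0, 1] by the
#' global maximum of its field across snapshots.
#'
#' @param traj an \linkS4class{RDTrajectory} with snapshots.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSnapshotTIFF <- function(traj, path) {
  if (!length(traj@snapshots)) stop("trajectory has no snapshots")
  fieldNames <- names(traj@snapshots[[1]])
  tops <- vapply(fieldNames, function(fn)
    max(vapply(traj@snapshots, function(s) max(s[[fn]]), numeric(1)), 1e-12),
    numeric(1))
  pages <- list()
  for (s in traj@snapshots) for (fn in fieldNames)
    pages[[length(pages) + 1L]] <- pmin(pmax(s[[fn]] / tops[[fn]], 0), 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
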