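#' Construct an image stack
#'
#' @param data 4D numeric array with dimensions (row, column, channel, frame),
#'   or a 3D array (row, column, frame) for a single channel.
#' @param channels channel labels.
#' @param pixelSize pixel edge length (um), NA if unknown.
#' @param times frame times; default the frame index.
#' @return an \linkS4class{ImageStack}.
#' @export
imageStack <- function(data, channels, pixelSize = NA_real_, times = NULL) {
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (is.null(times)) times <- seq_len(dim(data)[4])
  new("ImageStack", data = data, channels = channels, pixelSize = pixelSize,
      times = times)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d px, channels [%s], %d frame(s)\n",
              d[1], d[2], paste(object@channels, collapse = ", "), d[4]))
})

#' @rdname sampleTimes
setMethod("sampleTimes", "ImageStack", function(x) x@times)

#' Extract one channel frame
#' @param stack an \linkS4class{ImageStack}.
#' @param channel channel label.
#' @param frame frame index.
#' @return 2D numeric matrix.
#' @export
getFrame <- function(stack, channel, frame) {
  k <- match(channel, stack@channels)
  if (is.na(k)) stop("unknown channel label '", channel, "'")
  stack@data[, , k, frame]
}

#' Binarize a fluorescence frame
#'
#' Thresholds one channel frame into a foreground mask. The default automatic
#' method rescales the frame to [0, 1] and applies Otsu's threshold
#' (\code{EBImage::otsu}), which makes the segmentation invariant to constant
#' intensity offsets and gain. A manual absolute threshold can be supplied
#' instead. An optional 3x3 median filter suppresses shot noise before
#' thresholding.
#'
#' @param frame 2D numeric matrix.
#' @param method "otsu" or "manual".
#' @param threshold absolute threshold for the manual method.
#' @param medianFilter logical; apply a radius-1 median filter first.
#' @return logical matrix; all-FALSE (with a warning) for a blank frame.
#' @export
binarizeFrame <- function(frame, method = c("otsu", "manual"),
                          threshold = NULL, medianFilter = FALSE) {
  method <- match.arg(method)
  if (!is.matrix(frame)) stop("frame must be a single-channel 2D matrix")
  if (medianFilter)
    frame <- EBImage::imageData(EBImage::medianFilter(
      EBImage::Image(frame / max(frame, 1e-12)), size = 1)) *
      max(frame, 1e-12)
  if (method == "manual") {
    if (is.null(threshold)) stop("manual method needs a threshold")
    return(frame > threshold)
  }
  rng <- range(frame)
  if (diff(rng) <= 0) {
    warning("blank frame: no foreground found")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > th
}

#' Division ratio from a pair of binary masks
#'
#' Overlap-based division ratio of two fluorescent components:
#' \eqn{r_{div} = 1 - |X \cap Y| / \min(|X|, |Y|)}. Identical masks (fully
#' mixed components) give 0; disjoint masks (completely divided droplets)
#' give 1. The estimator is symmetric in its arguments and invariant under a
#' common translation of both masks.
#'
#' @param maskX,maskY logical matrices of equal shape.
#' @return division ratio in [0, 1]; NA (with a warning) when either mask is
#'   empty.
#' @examples
#' m <- matrix(FALSE, 8, 8); a <- b <- m
#' a[2:5, 2:5] <- TRUE; b[2:5, 4:7] <- TRUE
#' maskDivisionRatio(a, b)
#' @export
maskDivisionRatio <- function(maskX, maskY) {
  if (!identical(dim(maskX), dim(maskY)))
    stop("masks must have the same shape")
  nx <- sum(maskX); ny <- sum(maskY)
  if (nx == 0 && ny == 0) {
    warning("both masks empty: division ratio undefined")
    return(NA_real_)
  }
  if (nx == 0 || ny == 0) {
    warning("one mask empty: division ratio undefined")
    return(NA_real_)
  }
  1 - sum(maskX & maskY) / min(nx, ny)
}

#' Division-ratio traces from an image stack
#'
#' Binarizes the requested channels frame by frame and computes the
#' overlap-based division ratio for each component pair. For a ternary stack
#' the default pairing reads the B component from channels (A, B) and the C
#' component from (A, C); a two-channel stack yields a single trace.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param pairing named list of channel pairs, e.g.
#'   \code{list(B = c("A", "B"), C = c("A", "C"))}; default derived from the
#'   stack's channels.
#' @param ... passed to \code{\link{binarizeFrame}}.
#' @return named list of \linkS4class{DivisionTrace} objects.
#' @export
divisionTraceFromStack <- function(stack, pairing = NULL, ...) {
  ch <- stack@channels
  if (is.null(pairing)) {
    if (length(ch) == 2L) {
      pairing <- stats::setNames(list(ch), ch[2])
    } else if (all(c("A", "B", "C") %in% ch)) {
      pairing <- list(B = c("A", "B"), C = c("A", "C"))
    } else stop("cannot derive a default pairing; pass one explicitly")
  }
  for (p in pairing)
    if (!all(p %in% ch)) stop("unknown channel label in pairing: ",
                              paste(setdiff(p, ch), collapse = ", "))
  nF <- dim(stack@data)[4]
  masks <- lapply(unique(unlist(pairing)), function(cc)
    lapply(seq_len(nF), function(f) binarizeFrame(getFrame(stack, cc, f), ...)))
  names(masks) <- unique(unlist(pairing))
  lapply(stats::setNames(names(pairing), names(pairing)), function(comp) {
    p <- pairing[[comp]]
    r <- vapply(seq_len(nF), function(f)
      maskDivisionRatio(masks[[p[1]]][[f]], masks[[p[2]]][[f]]), numeric(1))
    divisionTraceFromRatios(stack@times, r, component = comp)
  })
}
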