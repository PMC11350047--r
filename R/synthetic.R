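#' Overlap area of two equal circles
#'
#' Closed-form lens area of two circles of radius \code{r} whose centres are a
#' distance \code{d} apart.
#'
#' @param d centre-to-centre distance(s).
#' @param r circle radius.
#' @return overlap area(s); \code{pi r^2} at d = 0, 0 at d >= 2r.
#' @export
circleOverlapArea <- function(d, r) {
  d <- pmin(pmax(d, 0), 2 * r)
  2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(pmax(4 * r^2 - d^2, 0))
}

#' Ground-truth division ratio of a separation schedule
#'
#' Analytic division ratio of two rigid equal disks at the scheduled
#' centre-to-centre separations: \code{1 - overlap / (pi r^2)}.
#'
#' @param separation numeric vector of separations (px).
#' @param radius disk radius (px).
#' @return division ratios in [0, 1].
#' @export
scheduleDivisionRatio <- function(separation, radius) {
  1 - circleOverlapArea(separation, radius) / (pi * radius^2)
}

.diskMatrix <- function(dim, center, radius) {
  x <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  y <- matrix(seq_len(dim[1]), dim[1], dim[2])
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Default linear separation schedule
#'
#' Separation stays at 0 until \code{startFrame}, ramps linearly to
#' \code{finalSep} at \code{endFrame}, and stays there.
#'
#' @param nFrames number of frames.
#' @param startFrame,endFrame ramp limits (frame indices).
#' @param finalSep final centre-to-centre separation (px).
#' @return numeric vector of length \code{nFrames}.
#' @export
separationSchedule <- function(nFrames, startFrame, endFrame, finalSep) {
  stopifnot(startFrame >= 1, endFrame > startFrame, endFrame <= nFrames)
  f <- seq_len(nFrames)
  pmin(pmax((f - startFrame) / (endFrame - startFrame), 0), 1) * finalSep
}

#' Synthetic two-channel droplet-division movie
#'
#' Generates a movie of a dividing binary droplet: two initially colocalized
#' fluorescent disks (channels A and B) that translate apart along x following
#' a separation schedule. The analytic ground-truth division ratio at each
#' frame is the complement of the normalized disk-overlap area. Optional
#' Gaussian read noise, Poisson shot noise and a late-frame background ramp
#' emulate the imaging artefacts of real time-lapse data (including the
#' background rise caused by slight droplet dissolution late in an
#' experiment).
#'
#' @param nFrames number of frames.
#' @param frameDim frame size c(rows, cols) in px.
#' @param radius disk radius (px).
#' @param separation per-frame centre separations (px); default a linear ramp
#'   from 0 to 2.4 radius between frames at 20% and 80% of the movie.
#' @param intensity foreground intensity.
#' @param background constant background level.
#' @param readNoise Gaussian read-noise standard deviation (0 = off).
#' @param shotScale photons per intensity unit for Poisson shot noise
#'   (Inf = off).
#' @param bgDrift amplitude of a quadratic late-frame background ramp
#'   (0 = off).
#' @param seed RNG seed; mandatory when any noise source is on.
#' @return list with \code{stack} (an \linkS4class{ImageStack}, channels A and
#'   B) and \code{truth} (data.frame with \code{frame}, \code{separation},
#'   \code{rDiv}).
#' @examples
#' mv <- makeDivisionMovie(nFrames = 10)
#' mv$truth$rDiv
#' @export
makeDivisionMovie <- function(nFrames = 40, frameDim = c(112, 112),
                              radius = 20, separation = NULL, intensity = 1,
                              background = 0.05, readNoise = 0,
                              shotScale = Inf, bgDrift = 0, seed = NULL) {
  if (is.null(separation))
    separation <- separationSchedule(nFrames, max(1, round(0.2 * nFrames)),
                                     round(0.8 * nFrames), 2.4 * radius)
  if (length(separation) != nFrames)
    stop("separation schedule must cover every frame")
  noisy <- readNoise > 0 || is.finite(shotScale) || bgDrift > 0
  if (noisy && is.null(seed)) stop("seed is mandatory when noise is on")
  if (!is.null(seed)) set.seed(seed)
  c0 <- rev(frameDim) / 2          # (x, y)
  if (max(separation) / 2 + radius > min(c0))
    stop("disks leave the frame; enlarge frameDim or shorten the schedule")
  dat <- array(0, c(frameDim, 2L, nFrames))
  for (f in seq_len(nFrames)) {
    off <- separation[f] / 2
    a <- .diskMatrix(frameDim, c0 + c(-off, 0), radius) * intensity
    b <- .diskMatrix(frameDim, c0 + c(off, 0), radius) * intensity
    bg <- background + bgDrift * (f / nFrames)^2
    for (k in 1:2) {
      fr <- (if (k == 1) a else b) + bg
      if (is.finite(shotScale))
        fr <- matrix(stats::rpois(length(fr), pmax(fr, 0) * shotScale) /
                       shotScale, frameDim[1], frameDim[2])
      if (readNoise > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), sd = readNoise),
                          frameDim[1], frameDim[2])
      dat[, , k, f] <- fr
    }
  }
  list(stack = imageStack(dat, c("A", "B")),
       truth = data.frame(frame = seq_len(nFrames), separation = separation,
                          rDiv = scheduleDivisionRatio(separation, radius)))
}

#' Synthetic three-channel pathway movie
#'
#' Ternary-droplet movie: a static central disk (channel A) from which the B
#' and C disks separate in opposite directions at programmed times. The
#' ground-truth division time of each component is where its analytic overlap
#' ratio crosses one half, so the programmed pathway label and delta tau are
#' known exactly.
#'
#' @param nFrames,frameDim,radius,intensity,background,readNoise,shotScale,bgDrift,seed
#'   as in \code{\link{makeDivisionMovie}}.
#' @param sepB,sepC per-frame separation schedules of B and C from A; defaults
#'   ramp B at 60-90% and C at 15-45% of the movie (C first: Pathway 1).
#' @return list with \code{stack} (channels A, B, C), \code{truth} (per-frame
#'   analytic rDiv of both components) and \code{tauTruth} (list with
#'   \code{tauB}, \code{tauC}, \code{deltaTau}).
#' @export
makeTernaryMovie <- function(nFrames = 60, frameDim = c(140, 140),
                             radius = 20, sepB = NULL, sepC = NULL,
                             intensity = 1, background = 0.05, readNoise = 0,
                             shotScale = Inf, bgDrift = 0, seed = NULL) {
  if (is.null(sepB))
    sepB <- separationSchedule(nFrames, round(0.6 * nFrames),
                               round(0.9 * nFrames), 2.4 * radius)
  if (is.null(sepC))
    sepC <- separationSchedule(nFrames, max(1, round(0.15 * nFrames)),
                               round(0.45 * nFrames), 2.4 * radius)
  if (length(sepB) != nFrames || length(sepC) != nFrames)
    stop("separation schedules must cover every frame")
  noisy <- readNoise > 0 || is.finite(shotScale) || bgDrift > 0
  if (noisy && is.null(seed)) stop("seed is mandatory when noise is on")
  if (!is.null(seed)) set.seed(seed)
  c0 <- rev(frameDim) / 2
  if (max(c(sepB, sepC)) + radius > min(c0))
    stop("disks leave the frame; enlarge frameDim or shorten the schedules")
  dat <- array(0, c(frameDim, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    disks <- list(
      A = .diskMatrix(frameDim, c0, radius),
      B = .diskMatrix(frameDim, c0 + c(sepB[f], 0), radius),
      C = .diskMatrix(frameDim, c0 - c(sepC[f], 0), radius)
    )
    bg <- background + bgDrift * (f / nFrames)^2
    for (k in 1:3) {
      fr <- disks[[k]] * intensity + bg
      if (is.finite(shotScale))
        fr <- matrix(stats::rpois(length(fr), pmax(fr, 0) * shotScale) /
                       shotScale, frameDim[1], frameDim[2])
      if (readNoise > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), sd = readNoise),
                          frameDim[1], frameDim[2])
      dat[, , k, f] <- fr
    }
  }
  truth <- data.frame(frame = seq_len(nFrames),
                      rDivB = scheduleDivisionRatio(sepB, radius),
                      rDivC = scheduleDivisionRatio(sepC, radius))
  tauB <- .crossingTime(truth$frame, truth$rDivB, 0.5)
  tauC <- .crossingTime(truth$frame, truth$rDivC, 0.5)
  dt <- deltaTau(tauB, tauC)
  list(stack = imageStack(dat, c("A", "B", "C")), truth = truth,
       tauTruth = list(tauB = as.numeric(tauB), tauC = as.numeric(tauC),
                       deltaTau = dt$deltaTau, pathway = dt$pathway))
}

#' Noisy uncleaved-linker observations from the well-mixed simulator
#'
#' Simulates the circuit kinetics, samples the uncleaved-linker fraction of
#' each circuit at the observation times, and applies seeded multiplicative
#' Gaussian noise.
#'
#' @param model a \linkS4class{CircuitModel}.
#' @param times observation times.
#' @param sigma multiplicative noise standard deviation (0 = noiseless).
#' @param seed RNG seed (mandatory when sigma > 0).
#' @return data.frame with columns \code{time}, \code{label}, \code{w}
#'   (observed) and \code{wTrue}.
#' @export
makeNoisyTraces <- function(model, times, sigma = 0.05, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma > 0 && is.null(seed)) stop("seed is mandatory when noise is on")
  if (!is.null(seed)) set.seed(seed)
  traj <- simulateWellMixed(model, times)
  labs <- vapply(model@circuits, function(c) c@label, character(1))
  do.call(rbind, lapply(labs, function(l) {
    wTrue <- uncleavedFraction(traj, l)
    w <- if (sigma > 0)
      pmax(wTrue * (1 + stats::rnorm(length(wTrue), sd = sigma)), 0)
    else wTrue
    data.frame(time = times, label = l, w = w, wTrue = wTrue)
  }))
}

#' Recover circuit kinetics from noisy traces
#'
#' Least-squares recovery of the inhibitor-hybridization rate and the
#' effective enzymatic release capacity (the product of turnover and enzyme
#' level) from observed uncleaved-linker traces, by fitting the well-mixed
#' model with \code{minpack.lm::nls.lm} on log-scaled parameters.
#'
#' @param observed data.frame with columns \code{time}, \code{label},
#'   \code{w} (e.g. from \code{\link{makeNoisyTraces}}).
#' @param template a \linkS4class{CircuitModel} fixing everything except the
#'   fitted parameters.
#' @param start named numeric starting values, elements \code{kHybRNA} and
#'   \code{kCatE}.
#' @param gridFactors multiplicative factors applied to \code{start} to build
#'   a coarse multistart grid; the local fit starts from the grid point with
#'   the smallest residual sum of squares. The uncleaved-linker trace is
#'   switch-like, so the least-squares surface has several basins and a purely
#'   local fit can stall; the coarse scan makes the recovery robust to the
#'   starting guess.
#' @return list with \code{kHybRNA}, \code{kCatE} (estimates) and \code{fit}
#'   (the nls.lm object).
#' @export
recoverKinetics <- function(observed, template,
                            start = c(kHybRNA = 0.1, kCatE = 1e-3),
                            gridFactors = c(0.1, 0.3, 1, 3, 10)) {
  stopifnot(all(c("time", "label", "w") %in% names(observed)),
            all(c("kHybRNA", "kCatE") %in% names(start)))
  times <- sort(unique(observed$time))
  labs <- unique(observed$label)
  resid <- function(logPar) {
    m <- template
    m@kHybRNA <- exp(logPar[1])
    m@kCat <- exp(logPar[2])
    m@enzyme <- 1                       # kCatE = kCat * enzyme, lumped
    traj <- simulateWellMixed(m, times)
    unlist(lapply(labs, function(l) {
      obs <- observed[observed$label == l, ]
      uncleavedFraction(traj, l)[match(obs$time, times)] - obs$w
    }))
  }
  p0 <- log(start[c("kHybRNA", "kCatE")])
  best <- p0; bestSSR <- Inf
  for (f1 in gridFactors) for (f2 in gridFactors) {
    p <- p0 + log(c(f1, f2))
    ssr <- sum(resid(p)^2)
    if (ssr < bestSSR) { bestSSR <- ssr; best <- p }
  }
  fit <- minpack.lm::nls.lm(par = best, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  est <- exp(fit$par)
  list(kHybRNA = unname(est[1]), kCatE = unname(est[2]), fit = fit)
}
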