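## Hybrid LV segmentation: seeded region growing, a shrink-only two-phase
## active contour on the phase image, and constrained re-growth on the
## amplitude image, followed by ED/ES detection on the time-activity curve.

.NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Seeded region growing with a running-maximum threshold
#'
#' Grows an 8-connected region from the seed, accepting a neighbouring
#' pixel whenever its value is at least \code{thresholdFraction} times the
#' running maximum of the region grown so far (the classic count-based LV
#' edge criterion).  Pixels once accepted stay in the region even if the
#' running maximum later rises.  Traversal order is fixed (breadth-first,
#' neighbours in raster order) so the result is fully deterministic.
#'
#' @param image numeric matrix.
#' @param seed integer(2) (row, col); the seed value must be > 0.
#' @param thresholdFraction inclusion fraction in (0, 1] (default 0.5).
#' @param bounds optional logical matrix; growth never leaves it.
#' @return Logical mask: connected, containing the seed.
#' @export
regionGrow <- function(image, seed, thresholdFraction = 0.5, bounds = NULL) {
  stopifnot(is.matrix(image), length(seed) == 2L)
  nr <- nrow(image); nc <- ncol(image)
  sr <- as.integer(seed[1]); sc <- as.integer(seed[2])
  if (sr < 1L || sr > nr || sc < 1L || sc > nc)
    stop("seed outside image bounds")
  if (!is.null(bounds)) {
    stopifnot(identical(dim(bounds), dim(image)))
    if (!bounds[sr, sc]) stop("seed outside bounds")
  }
  if (image[sr, sc] <= 0) stop("seed value must be > 0")
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must be in (0, 1]")

  inReg <- matrix(FALSE, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  inReg[sr, sc] <- TRUE
  seen[sr, sc] <- TRUE
  runMax <- image[sr, sc]
  queue <- matrix(c(sr, sc), 1L, 2L)
  head <- 1L
  while (head <= nrow(queue)) {
    p <- queue[head, ]; head <- head + 1L
    for (k in seq_len(8L)) {
      r <- p[1] + .NEIGH8[k, 1L]; c <- p[2] + .NEIGH8[k, 2L]
      if (r < 1L || r > nr || c < 1L || c > nc) next
      if (seen[r, c]) next
      if (!is.null(bounds) && !bounds[r, c]) { seen[r, c] <- TRUE; next }
      seen[r, c] <- TRUE
      if (image[r, c] >= thresholdFraction * runMax) {
        inReg[r, c] <- TRUE
        if (image[r, c] > runMax) runMax <- image[r, c]
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  inReg
}

## 8-connected component of 'mask' containing 'seed' (logical matrix out)
.componentOf <- function(mask, seed) {
  if (!mask[seed[1], seed[2]]) return(matrix(FALSE, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  lab == lab[seed[1], seed[2]]
}

## 3 x 3 majority vote used as morphological smoothing
.majority <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  W <- .windowStack(m, 3L)
  matrix(rowSums(W) >= 5, nrow(mask), ncol(mask))
}

#' Shrink-only two-phase active contour refinement
#'
#' Region-based (two-phase, piecewise-constant) contour evolution on an
#' image, initialised at \code{initMask} and constrained never to grow
#' outside it: each iterate keeps the pixels closer to the inside mean than
#' to the outside mean, applies a 3 x 3 majority smoothing, intersects with
#' the previous mask (monotone shrink) and retains the connected component
#' containing the seed.  Evolution stops at \code{maxIter} iterations or
#' when fewer than \code{tolFraction} of the image pixels change.
#'
#' @param image numeric matrix (typically a phase-difference image).
#' @param initMask logical matrix containing the seed.
#' @param seed integer(2) (row, col).
#' @param maxIter iteration cap (default 200).
#' @param smoothing number of majority-smoothing passes per iteration
#'   (default 1; 0 disables smoothing).
#' @param tolFraction stop tolerance as a fraction of image pixels
#'   (default 0.001).
#' @return Logical mask, subset of \code{initMask}, connected, containing
#'   the seed.  Errors if the evolution collapses to an empty mask, which
#'   signals a bad seed or insufficient phase contrast.
#' @export
activeContourRefine <- function(image, initMask, seed, maxIter = 200L,
                                smoothing = 1L, tolFraction = 0.001) {
  stopifnot(is.matrix(image), identical(dim(image), dim(initMask)))
  if (!initMask[seed[1], seed[2]]) stop("initMask must contain the seed")
  mask <- .componentOf(initMask, seed)
  npix <- length(image)
  for (it in seq_len(maxIter)) {
    inside <- image[mask]
    c1 <- mean(inside)
    c2 <- if (all(mask)) c1 else mean(image[!mask])
    keep <- (image - c1)^2 <= (image - c2)^2
    new <- mask & keep
    if (smoothing > 0L)
      for (s in seq_len(smoothing)) new <- .majority(new) & mask
    new <- new & mask
    if (!new[seed[1], seed[2]]) {
      ## smoothing ate the seed pixel: keep it if evolution hasn't collapsed
      if (!any(new)) stop("active contour collapsed to an empty mask")
      new[seed[1], seed[2]] <- TRUE
    }
    new <- .componentOf(new, seed)
    if (!any(new)) stop("active contour collapsed to an empty mask")
    changed <- sum(xor(mask, new))
    mask <- new
    if (changed < tolFraction * npix) break
  }
  if (!any(mask)) stop("active contour collapsed to an empty mask")
  mask
}

#' Detect end-diastole and end-systole on a time-activity curve
#'
#' ED is the frame of maximal counts, ES the frame of minimal counts; ties
#' are broken by the earliest frame.
#'
#' @param tac numeric vector of per-frame counts (length >= 3, all >= 0).
#' @return Integer(2): (edFrame, esFrame), 1-based.
#' @export
detectEdEs <- function(tac) {
  stopifnot(length(tac) >= 3L)
  if (any(tac < 0)) stop("negative counts in time-activity curve")
  if (max(tac) == min(tac))
    stop("constant time-activity curve: ED/ES undefined")
  c(ed = which.max(tac), es = which.min(tac))
}

#' Hybrid region-growing / active-contour LV segmentation
#'
#' Delineates the LV on every frame in four steps: (1) seeded region
#' growing on each (filtered, background-corrected) frame gives an initial
#' contour per frame; (2) a shrink-only two-phase active contour on the
#' phase image, restricted to pixels whose phase lies within
#' \code{gateHalfWidth} degrees of the seed's phase (the ventricular phase
#' gate, which excludes atria and great vessels moving in phase
#' opposition), refines each initial contour; (3) region growing on the
#' amplitude image from the same seed, bounded by the step-2 mask, yields
#' the final contour; (4) the step-3 masks are applied back to the frames
#' and ED/ES are detected on the resulting time-activity curve.
#'
#' @param cine A (typically filtered and background-corrected)
#'   \code{\linkS4class{GatedCine}}.
#' @param maps Matching \code{\linkS4class{HarmonicMaps}}.
#' @param seed integer(2) (row, col) inside the LV.
#' @param rgFraction region-growing inclusion fraction (default 0.25; see
#'   the methods vignette for why the pipeline default is below the
#'   classic 0.5 of \code{\link{regionGrow}}).
#' @param acIter,acSmoothing active-contour iteration cap and smoothing
#'   passes (defaults 200 and 1).
#' @param gateHalfWidth ventricular phase gate half-width in degrees
#'   (default 90).
#' @return An \code{\linkS4class{LVSegmentation}}.
#' @export
acrgSegment <- function(cine, maps, seed, rgFraction = 0.25,
                        acIter = 200L, acSmoothing = 1L,
                        gateHalfWidth = 90) {
  stopifnot(is(cine, "GatedCine"), is(maps, "HarmonicMaps"))
  f <- frames(cine)
  d <- dim(f)
  stopifnot(identical(dim(maps@phase), d[1:2]))
  sr <- as.integer(seed[1]); sc <- as.integer(seed[2])
  if (maps@amplitude[sr, sc] <= 0 || maps@lowAmplitude[sr, sc])
    stop("seed has zero amplitude (background?): choose a seed inside the LV")

  TT <- d[3]
  inits <- lapply(seq_len(TT),                                # step 1
                  function(t) regionGrow(f[, , t], c(sr, sc), rgFraction))

  ## The seed supplies the LV location; its timing reference is estimated
  ## robustly as the amplitude-weighted circular mean phase over the first
  ## frame's initial contour, because a single pixel's phase is
  ## noise-limited at the chamber centre where the amplitude is lowest.
  w <- maps@amplitude[inits[[1L]]]
  zref <- sum(w * exp(1i * maps@phase[inits[[1L]]] * pi / 180))
  seedPhase <- if (Mod(zref) > 0) (Arg(zref) * 180 / pi) %% 360
               else maps@phase[sr, sc]
  if (seedPhase >= 360) seedPhase <- 0

  gate <- .angDiff(maps@phase, seedPhase) <= gateHalfWidth &
    !maps@lowAmplitude
  gate[sr, sc] <- TRUE     # the operator asserts the seed is ventricular
  ## absolute angular distance from the reference phase, in [0, 180]: the
  ## natural dissimilarity for circular phase data, and a plain real image
  ## the two-phase contour can work on (ventricle near 0, structures in
  ## phase opposition near 180, noise spread towards 90).  Low-amplitude
  ## pixels carry no timing signal at all, so they are assigned maximal
  ## dissimilarity rather than their (meaningless) zero phase.
  phdiff <- .angDiff(maps@phase, seedPhase)
  phdiff[maps@lowAmplitude] <- 180

  out <- array(FALSE, d)
  step2 <- array(FALSE, d)
  for (t in seq_len(TT)) {
    init <- inits[[t]]
    init2 <- init & gate
    if (!init2[sr, sc])
      stop(sprintf("frame %d: phase gate excluded the seed", t))
    m2 <- activeContourRefine(phdiff, init2, c(sr, sc),       # step 2
                              maxIter = acIter, smoothing = acSmoothing)
    m3 <- regionGrow(maps@amplitude, c(sr, sc),               # step 3
                     rgFraction, bounds = m2)
    if (!any(m3)) stop(sprintf("frame %d: empty final mask", t))
    step2[, , t] <- m2
    out[, , t] <- m3
  }
  tac <- vapply(seq_len(TT), function(t) sum(f[, , t][out[, , t]]),
                numeric(1))
  edes <- detectEdEs(tac)
  new("LVSegmentation", masks = out, seed = c(sr, sc),
      edFrame = as.integer(edes[1]), esFrame = as.integer(edes[2]),
      intermediateMasks = list(step2 = step2))
}
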