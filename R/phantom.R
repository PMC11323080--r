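## Synthetic beating-LV phantom: ground truth for every downstream test.
##
## The LV is an ellipsoid whose volume follows a raised-cosine systolic
## pulse; the per-pixel noise-free intensity is the projected chamber
## thickness times an activity constant, so total LV counts are exactly
## proportional to chamber volume and count-based EF equals volumetric EF.

#' Phantom configuration
#'
#' Validated configuration for \code{\link{generatePhantom}}.  Defaults
#' emulate a resting 16-frame acquisition of a normal LV: 64 x 64 matrix,
#' true EF 0.60, end-diastolic counts close to 1e4, a background plateau, a
#' lateral lung field, physiological systolic fraction 0.375, frame time
#' 50 ms (75 bpm) and 4 mm pixels.
#'
#' @param imageSize square matrix size in pixels (default 64).
#' @param nFrames gated frames T (default 16).
#' @param trueEf ejection fraction in (0, 1) (default 0.6).
#' @param edSemiAxes numeric(3) (a, b, c): ED ellipsoid semi-axes in
#'   pixels along image columns, image rows, and depth (default 14, 10, 10).
#' @param center numeric(2) (row, col) of the LV centre; default places
#'   the LV slightly left of centre, leaving room for the lung field.
#' @param activity counts per unit projected thickness (default 1.705,
#'   giving about 1e4 end-diastolic counts at the default axes).
#' @param backgroundLevel plateau counts/pixel over the whole image
#'   (default 2).
#' @param lungLevel extra counts/pixel in the lung rectangle (default 6).
#' @param systolicFraction fraction of the cycle in systole (default 0.375).
#' @param dyssyncSectors number of delayed angular sectors, 0..6
#'   (default 0).
#' @param dyssyncDelay sector phase delay in degrees [0, 360) (default 0).
#' @param poisson apply Poisson counting noise (default FALSE).
#' @param rngSeed integer seed for the Poisson draw (default 1).
#' @param frameTime milliseconds per frame (default 50).
#' @param pixelSpacing mm per pixel (default 4).
#' @return A validated list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(imageSize = 64L, nFrames = 16L, trueEf = 0.6,
                          edSemiAxes = c(14, 10, 10), center = NULL,
                          activity = 1.705, backgroundLevel = 2,
                          lungLevel = 6, systolicFraction = 0.375,
                          dyssyncSectors = 0L, dyssyncDelay = 0,
                          poisson = FALSE, rngSeed = 1L,
                          frameTime = 50, pixelSpacing = 4) {
  if (trueEf <= 0 || trueEf >= 1) stop("trueEf must be in (0, 1)")
  if (length(edSemiAxes) != 3L || any(edSemiAxes <= 0))
    stop("edSemiAxes must be three positive semi-axes")
  if (is.null(center))
    center <- c(round(imageSize / 2), round(imageSize / 2) - round(imageSize / 8))
  if (center[2] - edSemiAxes[1] < 8 || center[1] - edSemiAxes[2] < 8 ||
      center[2] + edSemiAxes[1] > imageSize - 8 ||
      center[1] + edSemiAxes[2] > imageSize - 8)
    stop("LV must fit inside the image with a margin of at least 8 pixels")
  if (dyssyncSectors < 0L || dyssyncSectors > 6L)
    stop("dyssyncSectors must be 0..6")
  if (dyssyncDelay < 0 || dyssyncDelay >= 360)
    stop("dyssyncDelay must be in [0, 360)")
  if (systolicFraction <= 0 || systolicFraction >= 1)
    stop("systolicFraction must be in (0, 1)")
  structure(list(
    imageSize = as.integer(imageSize), nFrames = as.integer(nFrames),
    trueEf = trueEf, edSemiAxes = edSemiAxes, center = center,
    activity = activity, backgroundLevel = backgroundLevel,
    lungLevel = lungLevel, systolicFraction = systolicFraction,
    dyssyncSectors = as.integer(dyssyncSectors),
    dyssyncDelay = dyssyncDelay, poisson = isTRUE(poisson),
    rngSeed = as.integer(rngSeed), frameTime = frameTime,
    pixelSpacing = pixelSpacing), class = "PhantomConfig")
}

## raised-cosine systolic pulse, s(0) = 0 (ED), s(Ts) = 1 (ES), smooth
## return over diastole; periodic in [0, T)
.systolicPulse <- function(tf, TT, Ts) {
  tf <- tf %% TT
  ifelse(tf <= Ts,
         (1 - cos(pi * tf / Ts)) / 2,
         (1 + cos(pi * (tf - Ts) / (TT - Ts))) / 2)
}

#' Generate a synthetic beating-LV gated cine with ground truth
#'
#' The chamber volume follows \eqn{V(t) = V_{ED}(1 - EF\,s(t))} with a
#' raised-cosine pulse \eqn{s(t)}; the ellipsoid semi-axes scale by
#' \eqn{\lambda(t) = (V(t)/V_{ED})^{1/3}} and each pixel receives
#' \code{activity} times the projected chamber thickness
#' \eqn{2c(t)\sqrt{1 - (x/a(t))^2 - (y/b(t))^2}}, so summed LV counts are
#' exactly proportional to volume.  A background plateau covers the image
#' and a lung rectangle sits lateral to the LV.  Optionally the LV is split
#' into 6 angular sectors with the first \code{dyssyncSectors} of them
#' time-shifted by \code{dyssyncDelay} degrees of cycle phase, and Poisson
#' counting noise is applied under \code{rngSeed}.
#'
#' @param config A \code{\link{phantomConfig}} list.
#' @return List with \code{cine} (a \code{\linkS4class{GatedCine}}) and
#'   \code{truth} (a \code{\linkS4class{PhantomTruth}}).
#' @export
generatePhantom <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "PhantomConfig"))
  n <- config$imageSize
  TT <- config$nFrames
  a <- config$edSemiAxes[1]; b <- config$edSemiAxes[2]
  cax <- config$edSemiAxes[3]
  ctr <- config$center
  Ts <- config$systolicFraction * TT

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cols - ctr[2]   # along semi-axis a
  dy <- rows - ctr[1]   # along semi-axis b

  ## sector index 1..6 by angle around the centre
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  sectorIdx <- pmin(floor(theta / 60) + 1L, 6L)
  offsets <- rep(0, 6)
  if (config$dyssyncSectors > 0L)
    offsets[seq_len(config$dyssyncSectors)] <- config$dyssyncDelay

  ## lung rectangle lateral (right) of the LV
  lungRect <- matrix(FALSE, n, n)
  lc0 <- min(n - 1L, round(ctr[2] + a + round(0.3 * a)))
  lc1 <- min(n, lc0 + round(1.2 * a))
  lr0 <- max(1L, round(ctr[1] - 1.2 * b)); lr1 <- min(n, round(ctr[1] + 1.2 * b))
  lungRect[lr0:lr1, lc0:lc1] <- TRUE

  framesArr <- array(0, c(n, n, TT))
  truthMasks <- array(FALSE, c(n, n, TT))
  volCurve <- numeric(TT)
  edv <- 4 / 3 * pi * a * b * cax

  for (t in seq_len(TT)) {
    tf <- t - 1L
    img <- matrix(config$backgroundLevel, n, n)
    img[lungRect] <- img[lungRect] + config$lungLevel
    vsum <- 0
    for (s in seq_len(6L)) {
      shift <- offsets[s] / 360 * TT
      sv <- .systolicPulse(tf - shift, TT, Ts)
      lam <- (1 - config$trueEf * sv)^(1 / 3)
      vsum <- vsum + (edv / 6) * lam^3
      inSec <- sectorIdx == s
      rho2 <- (dx / (a * lam))^2 + (dy / (b * lam))^2
      thick <- 2 * cax * lam * sqrt(pmax(1 - rho2, 0))
      lv <- inSec & rho2 < 1
      img[lv] <- img[lv] + config$activity * thick[lv]
      truthMasks[, , t] <- truthMasks[, , t] | lv
    }
    volCurve[t] <- vsum
    framesArr[, , t] <- img
  }

  if (config$poisson) {
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(config$rngSeed)
    framesArr[] <- rpois(length(framesArr), framesArr)
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  } else {
    framesArr <- round(framesArr * 1e9) / 1e9
  }

  mbd <- TT * config$frameTime
  metaObj <- AcquisitionMeta(
    frameTime = config$frameTime, heartRate = 60000 / mbd,
    acceptedBeats = 180, rejectedBeats = 20, meanBeatDuration = mbd,
    pixelSpacing = rep(config$pixelSpacing, 2L), nFrames = TT)
  cine <- GatedCine(framesArr, metaObj)

  ed <- which.max(volCurve); es <- which.min(volCurve)
  truth <- new("PhantomTruth",
               ef = (volCurve[ed] - volCurve[es]) / volCurve[ed],
               masks = truthMasks, edFrame = as.integer(ed),
               esFrame = as.integer(es), sectorPhaseOffsets = offsets,
               volumeCurve = volCurve)
  list(cine = cine, truth = truth)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical matrices of equal dimensions.
#' @return Dice coefficient 2|a & b| / (|a| + |b|).
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
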