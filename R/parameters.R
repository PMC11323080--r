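## The biomarker layer: count-, time- and shape-based parameters extracted
## from a segmented gated blood-pool cine.

#' Time-activity curve of a segmentation
#'
#' Element t is the summed counts of frame t inside mask t.
#'
#' @param cine A \code{\linkS4class{GatedCine}}.
#' @param seg A matching \code{\linkS4class{LVSegmentation}}.
#' @return Numeric vector of per-frame counts.
#' @export
timeActivityCurve <- function(cine, seg) {
  f <- frames(cine)
  m <- masks(seg)
  if (!identical(dim(f), dim(m))) stop("cine and segmentation shapes differ")
  vapply(seq_len(dim(f)[3]), function(t) sum(f[, , t][m[, , t]]), numeric(1))
}

#' Count-based LV ejection fraction
#'
#' \eqn{100 (EDC - ESC) / EDC} on a background-corrected time-activity
#' curve.
#'
#' @param tac numeric per-frame counts (background-corrected).
#' @param ed,es ED and ES frame indices (1-based).
#' @return LVEF in percent.
#' @export
computeLvef <- function(tac, ed, es) {
  if (tac[ed] <= 0) stop("non-positive end-diastolic counts")
  100 * (tac[ed] - tac[es]) / tac[ed]
}

#' First-harmonic ("phase image") LVEF estimate
#'
#' Under the first-harmonic model the end-diastolic and end-systolic counts
#' of the masked region are approximately \eqn{\sum(A_0 + A_1)} and
#' \eqn{\sum(A_0 - A_1)}, giving
#' \eqn{LVEF \approx 100 \cdot 2\sum A_1 / (\sum A_0 + \sum A_1)}.
#'
#' @param maps A \code{\linkS4class{HarmonicMaps}}.
#' @param edMask logical matrix (the end-diastolic LV mask).
#' @return Phase LVEF in percent.
#' @export
phaseLvef <- function(maps, edMask) {
  stopifnot(identical(dim(edMask), dim(maps@dc)))
  if (!any(edMask)) stop("empty mask")
  sA0 <- sum(maps@dc[edMask])
  sA1 <- sum(maps@amplitude[edMask])
  den <- sA0 + sA1
  if (den <= 0) stop("non-positive end-diastolic harmonic counts")
  100 * 2 * sA1 / den
}

#' Peak systolic ejection rate
#'
#' The steepest frame-to-frame count fall between ED and ES, normalised by
#' the end-diastolic counts, in units of end-diastolic-count fractions per
#' second.
#'
#' @param tac numeric per-frame counts.
#' @param ed ED frame index (1-based).
#' @param frameTime milliseconds per frame (> 0).
#' @return Peak ejection rate (EDC fractions / s); 0 for a flat curve.
#' @export
ejectionRate <- function(tac, ed, frameTime) {
  if (tac[ed] <= 0) stop("non-positive end-diastolic counts")
  if (!is.finite(frameTime) || frameTime <= 0) stop("frameTime must be > 0")
  TT <- length(tac)
  es <- which.min(tac)
  if (es == ed) return(0)
  path <- ed
  t <- ed
  while (t != es) {               # walk forward cyclically from ED to ES
    t <- if (t == TT) 1L else t + 1L
    path <- c(path, t)
  }
  drops <- -diff(tac[path])
  max(c(drops, 0)) / (tac[ed] * frameTime / 1000)
}

## brute-force (reference) approximate entropy; Pincus convention:
## Chebyshev distance, self-matches included, natural log
.apenSlow <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1L
    logC <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- 0
        for (k in 0:(mm - 1L)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > d) d <- dk
        }
        if (d <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / n)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

## vectorised approximate entropy, identical definition
.apenFast <- function(x, m, r) {
  N <- length(x)
  D <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    n <- N - mm + 1L
    M <- D[seq_len(n), seq_len(n), drop = FALSE]
    if (mm > 1L)
      for (k in seq_len(mm - 1L))
        M <- pmax(M, D[k + seq_len(n), k + seq_len(n), drop = FALSE])
    C <- rowSums(M <= r) / n
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic \eqn{\Phi^m(r) - \Phi^{m+1}(r)} with
#' Chebyshev distance, self-matches included and natural logarithm.  The
#' fast mode is a vectorised computation; the slow mode is a literal
#' brute-force triple loop retained as the reference implementation — the
#' two agree to machine precision.
#'
#' @param x numeric signal, length >= m + 2.
#' @param m embedding dimension (positive integer, default 2).
#' @param r tolerance (>= 0).
#' @param mode \code{"fast"} or \code{"slow"}.
#' @return ApEn value.  Near-periodic signals can give marginally negative
#'   values because the two template counts are normalised over different
#'   numbers of windows; this is a property of the estimator, not an error.
#' @export
approxEntropy <- function(x, m = 2L, r, mode = c("fast", "slow")) {
  mode <- match.arg(mode)
  m <- as.integer(m)
  if (m < 1L) stop("m must be a positive integer")
  if (length(x) < m + 2L) stop("signal too short for embedding dimension")
  if (!is.finite(r) || r < 0) stop("tolerance r must be >= 0")
  if (mode == "slow") .apenSlow(x, m, r) else .apenFast(x, m, r)
}

#' Range-bounded approximate entropy
#'
#' ApEn with the tolerance fixed to a fraction of the signal range,
#' \eqn{r = r_{frac} (\max x - \min x)}, which makes the statistic
#' invariant under affine rescaling of the signal.
#'
#' @param x numeric signal.
#' @param m embedding dimension (default 2).
#' @param rFrac tolerance as a fraction of the range, in (0, 1]
#'   (default 0.2).
#' @param mode passed to \code{\link{approxEntropy}}.
#' @return Bounded ApEn value.
#' @export
boundedApen <- function(x, m = 2L, rFrac = 0.2, mode = "fast") {
  if (rFrac <= 0 || rFrac > 1) stop("rFrac must be in (0, 1]")
  rng <- max(x) - min(x)
  if (rng <= 0) stop("zero-range signal")
  approxEntropy(x, m, rFrac * rng, mode)
}

#' Phase-distribution statistics of the LV
#'
#' From the amplitude-weighted phase histogram and the amplitude-weighted
#' phasor sum over the masked pixels:
#' \itemize{
#'   \item \code{e_raw}: Shannon entropy \eqn{-\sum p_i \log_2 p_i} (bits),
#'   \item \code{e_norm}: \code{e_raw / log2(nBins)} in [0, 1]
#'     (the bounded entropy),
#'   \item \code{synchrony}: \eqn{|\sum A e^{i\phi}| / \sum A} in [0, 1],
#'   \item \code{mean_phase}: argument of the phasor sum, degrees [0, 360),
#'   \item \code{phase_sd}: amplitude-weighted standard deviation (degrees)
#'     of the phases unwrapped to (mean_phase - 180, mean_phase + 180].
#' }
#'
#' @param maps A \code{\linkS4class{HarmonicMaps}}.
#' @param mask logical matrix, non-empty, with positive total amplitude.
#' @param nBins histogram bins (default 64).
#' @return Named list (e_raw, e_norm, synchrony, mean_phase, phase_sd).
#' @export
phaseStatistics <- function(maps, mask, nBins = 64L) {
  h <- phaseHistogram(maps, mask, nBins, weighted = TRUE)
  p <- h$probabilities
  p <- p[p > 0]
  eRaw <- -sum(p * log2(p))
  eNorm <- eRaw / log2(length(h$probabilities))

  amp <- maps@amplitude[mask]
  amp[maps@lowAmplitude[mask]] <- 0      # flagged pixels carry no timing
  ph <- maps@phase[mask] * pi / 180
  z <- sum(amp * exp(1i * ph))
  sA <- sum(amp)
  synchrony <- Mod(z) / sA
  meanPhase <- (Arg(z) * 180 / pi) %% 360
  if (meanPhase >= 360) meanPhase <- 0
  dev <- ((maps@phase[mask] - meanPhase + 180) %% 360) - 180
  phaseSd <- sqrt(sum(amp * dev^2) / sA)
  list(e_raw = max(0, eRaw), e_norm = min(1, max(0, eNorm)),
       synchrony = min(1, synchrony),
       mean_phase = meanPhase, phase_sd = phaseSd)
}

#' Spatial approximate entropy of the phase image
#'
#' Range-bounded ApEn of the row-major sequence of phase values inside the
#' ED mask (diastolic), the ES mask (systolic), and their mean.  A
#' zero-range phase sequence (perfectly synchronous region) returns 0 with
#' a warning rather than erroring, so fully synchronous scans still yield
#' complete parameter sets.
#'
#' @param maps A \code{\linkS4class{HarmonicMaps}}.
#' @param edMask,esMask logical matrices with at least m + 2 pixels.
#' @param m embedding dimension (default 2).
#' @param rFrac tolerance fraction of range (default 0.2).
#' @return Named list (apen_d, apen_s, apen_ds).
#' @export
apenSpatial <- function(maps, edMask, esMask, m = 2L, rFrac = 0.2) {
  seqOf <- function(mask) {
    if (sum(mask) < m + 2L) stop("mask smaller than m + 2 pixels")
    ## row-major ordering of the masked phase values
    as.vector(t(maps@phase))[as.vector(t(mask))]
  }
  one <- function(mask) {
    x <- seqOf(mask)
    if (max(x) - min(x) <= 0) {
      warning("zero-range phase sequence: spatial ApEn reported as 0")
      return(0)
    }
    boundedApen(x, m, rFrac)
  }
  d <- one(edMask); s <- one(esMask)
  list(apen_d = d, apen_s = s, apen_ds = (d + s) / 2)
}

## contour perimeter with the two-weight (0.948 / 1.340) digital-length
## estimator, which is close to unbiased for smooth boundaries
.perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) stop("no contour found")
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  n <- nrow(pts)
  if (n < 3L) stop("degenerate contour")
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  st <- abs(nxt - pts)
  diag_ <- st[, 1] == 1 & st[, 2] == 1
  axial <- xor(st[, 1] == 1, st[, 2] == 1)
  sum(axial) * 0.948 + sum(diag_) * 1.340
}

#' Shape metrics of a binary LV mask
#'
#' Area (pixels, and mm^2 when the pixel spacing is known), perimeter from
#' the boundary polygon of the 8-connected contour, circularity
#' \eqn{4\pi A / P^2}, and the second-central-moment equivalent ellipse:
#' full long/short axes (pixels) and elongation = long/short >= 1.
#'
#' @param mask logical matrix with at least 5 pixels, not a 1-pixel line.
#' @param pixelSpacing numeric(2) mm/pixel or \code{NA}.
#' @return Named list (area_px, area_mm2, circularity, elongation,
#'   long_axis, short_axis).
#' @export
shapeMetrics <- function(mask, pixelSpacing = c(NA_real_, NA_real_)) {
  stopifnot(is.matrix(mask))
  area <- sum(mask)
  if (area < 5L) stop("degenerate mask: fewer than 5 pixels")
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  dr <- idx[, 1] - mu[1]; dc <- idx[, 2] - mu[2]
  cov <- matrix(c(mean(dr * dr), mean(dr * dc),
                  mean(dr * dc), mean(dc * dc)), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  if (ev[2] <= 1e-9) stop("degenerate mask: 1-pixel-wide line")
  longAxis <- 4 * sqrt(ev[1])
  shortAxis <- 4 * sqrt(ev[2])
  per <- .perimeter(mask)
  circ <- 4 * pi * area / per^2
  areaMm2 <- if (all(!is.na(pixelSpacing)))
    area * prod(pixelSpacing) else NA_real_
  list(area_px = area, area_mm2 = areaMm2, circularity = circ,
       elongation = longAxis / shortAxis,
       long_axis = longAxis, short_axis = shortAxis)
}

#' Fractional shortening of the LV axes
#'
#' \eqn{FS = 100 (L_{ED} - L_{ES}) / L_{ED}} per axis.  A negative FS
#' (ES axis longer than ED) is returned as-is, flagged by its sign.
#'
#' @param edAxes numeric(2) (long, short) at ED, both > 0.
#' @param esAxes numeric(2) (long, short) at ES.
#' @return Named list (fs_long, fs_short), percent.
#' @export
fractionalShortening <- function(edAxes, esAxes) {
  if (any(edAxes <= 0)) stop("non-positive ED axis")
  list(fs_long = 100 * (edAxes[1] - esAxes[1]) / edAxes[1],
       fs_short = 100 * (edAxes[2] - esAxes[2]) / edAxes[2])
}

#' Lung-to-heart count ratio
#'
#' Mean counts/pixel in the lung ROI divided by mean counts/pixel in the LV
#' mask, measured on the time-averaged, background-uncorrected frame.
#'
#' @param frame numeric matrix (time-averaged raw frame).
#' @param lungRoi,lvMask disjoint, non-empty logical masks.
#' @return LHR (> 0).
#' @export
lungHeartRatio <- function(frame, lungRoi, lvMask) {
  stopifnot(identical(dim(frame), dim(lungRoi)),
            identical(dim(frame), dim(lvMask)))
  if (!any(lungRoi) || !any(lvMask)) stop("empty mask")
  if (any(lungRoi & lvMask)) stop("lung ROI overlaps the LV mask")
  lv <- mean(frame[lvMask])
  if (lv <= 0) stop("zero mean LV counts")
  mean(frame[lungRoi]) / lv
}

#' Beat statistics from acquisition metadata
#'
#' Derives whichever of heart rate / mean beat duration is missing from the
#' other (\eqn{HR = 60000 / \bar{d}}), and the rejected-beat fraction when
#' beat counts are present.
#'
#' @param meta An \code{\linkS4class{AcquisitionMeta}}.
#' @return Named list (heart_rate, mean_beat_duration, rejected_fraction,
#'   frame_time); absent quantities are \code{NA}.
#' @export
beatStatistics <- function(meta) {
  stopifnot(is(meta, "AcquisitionMeta"))
  hr <- meta@heartRate
  mbd <- meta@meanBeatDuration
  if (is.na(hr) && is.na(mbd))
    stop("both heart rate and mean beat duration are absent")
  if (is.na(hr)) hr <- 60000 / mbd
  if (is.na(mbd)) mbd <- 60000 / hr
  rf <- NA_real_
  if (!is.na(meta@acceptedBeats) && !is.na(meta@rejectedBeats)) {
    tot <- meta@acceptedBeats + meta@rejectedBeats
    rf <- if (tot > 0) meta@rejectedBeats / tot else NA_real_
  }
  list(heart_rate = hr, mean_beat_duration = mbd,
       rejected_fraction = rf, frame_time = meta@frameTime)
}

## bounding box (rowMin, rowMax, colMin, colMax) of a logical mask
.bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

## default lung ROI: rectangle of LV-bbox height, half a bbox-width wide,
## lateral (increasing columns) of the LV; clipped to the image
.defaultLungRoi <- function(dims, bbox) {
  w <- bbox[4] - bbox[3] + 1L
  c0 <- bbox[4] + max(1L, round(0.25 * w))
  c1 <- min(dims[2], c0 + max(2L, round(0.5 * w)))
  if (c0 >= c1) return(NULL)
  roi <- matrix(FALSE, dims[1], dims[2])
  roi[bbox[1]:bbox[2], c0:c1] <- TRUE
  roi
}

#' Extract the full biomarker vector from a gated cine
#'
#' One-call orchestration of the whole pipeline: spatial filtering (default
#' median-modified Wiener, 5 x 5), background ROI construction and
#' subtraction (location 1, width 4 by default, measured on the
#' time-averaged filtered frame), first-harmonic analysis, hybrid
#' region-growing / active-contour LV segmentation, and every parameter of
#' the \code{\linkS4class{ParameterSet}}.  Processing settings are recorded
#' in the result's provenance.
#'
#' @param cine A raw \code{\linkS4class{GatedCine}}.
#' @param seed integer(2) (row, col) inside the LV.
#' @param filterKind,filterKernel filter bank settings (defaults
#'   \code{"mmwf"}, 5).
#' @param backgroundLoc background ROI location 1..6 (default 1).
#' @param backgroundWidth background band width in pixels (default 4).
#' @param nBins phase-histogram bins (default 64).
#' @param m,rFrac ApEn embedding dimension and range fraction
#'   (defaults 2 and 0.2).
#' @param rgFraction,acIter,acSmoothing segmentation settings (see
#'   \code{\link{acrgSegment}}).
#' @param lungRoi optional logical matrix; when \code{NULL} a default
#'   rectangle lateral to the LV is used, and the lung-to-heart ratio is
#'   reported absent if that rectangle does not fit in the image or touches
#'   the LV.
#' @return A \code{\linkS4class{ParameterSet}}.
#' @export
computeAll <- function(cine, seed,
                       filterKind = "mmwf", filterKernel = 5L,
                       backgroundLoc = 1L, backgroundWidth = 4L,
                       nBins = 64L, m = 2L, rFrac = 0.2,
                       rgFraction = 0.25, acIter = 200L, acSmoothing = 1L,
                       lungRoi = NULL) {
  stopifnot(is(cine, "GatedCine"))
  rawAvg <- apply(frames(cine), c(1, 2), mean)

  filtered <- filterCine(cine, filterKind, filterKernel)
  favg <- apply(frames(filtered), c(1, 2), mean)

  ## provisional LV extent for placing the background ring
  provisional <- regionGrow(favg, seed, rgFraction)
  bbox <- .bbox(provisional)
  rois <- buildBackgroundRois(favg, bbox, width = backgroundWidth)
  bkg <- measureBackground(favg, rois[[backgroundLoc]])
  corrected <- correctBackground(filtered, bkg)

  maps <- firstHarmonic(corrected)
  seg <- acrgSegment(corrected, maps, seed, rgFraction = rgFraction,
                     acIter = acIter, acSmoothing = acSmoothing)
  ed <- edFrame(seg); es <- esFrame(seg)
  edMask <- masks(seg)[, , ed]
  esMask <- masks(seg)[, , es]

  tac <- timeActivityCurve(corrected, seg)
  mt <- meta(cine)
  ft <- mt@frameTime
  lvef <- computeLvef(tac, ed, es)
  phLvef <- phaseLvef(maps, edMask)
  ejr <- if (!is.na(ft)) ejectionRate(tac, ed, ft) else NA_real_

  ## phase-distribution ROI: pixels inside the chamber on every frame
  ## (border pixels that empty completely during systole have pulse-like
  ## curves whose first-harmonic timing reflects wall motion, not chamber
  ## emptying, and would inflate the dyssynchrony indices)
  roiMask <- apply(masks(seg), c(1, 2), all)
  if (!any(roiMask)) roiMask <- esMask
  phst <- phaseStatistics(maps, roiMask, nBins)
  apTac <- approxEntropy(tac, m, 0.2 * sd(tac))
  bApTac <- boundedApen(tac, m, rFrac)
  apSp <- apenSpatial(maps, edMask, esMask, m, rFrac)

  spacing <- mt@pixelSpacing
  shpEd <- shapeMetrics(edMask, spacing)
  shpEs <- shapeMetrics(esMask, spacing)
  fs <- fractionalShortening(c(shpEd$long_axis, shpEd$short_axis),
                             c(shpEs$long_axis, shpEs$short_axis))

  if (is.null(lungRoi)) lungRoi <- .defaultLungRoi(dim(rawAvg), .bbox(edMask))
  lhr <- NA_real_
  if (!is.null(lungRoi) && any(lungRoi) && !any(lungRoi & edMask))
    lhr <- lungHeartRatio(rawAvg, lungRoi, edMask)

  beats <- tryCatch(beatStatistics(mt),
                    error = function(e) list(heart_rate = NA_real_,
                                             mean_beat_duration = NA_real_,
                                             rejected_fraction = NA_real_,
                                             frame_time = ft))

  ParameterSet(
    values = c(
      lvef = lvef, phase_lvef = phLvef, ejection_rate = ejr,
      e_raw = phst$e_raw, e_norm = phst$e_norm,
      apen = apTac, b_apen = bApTac,
      apen_d = apSp$apen_d, apen_s = apSp$apen_s, apen_ds = apSp$apen_ds,
      synchrony = phst$synchrony, phase_sd = phst$phase_sd,
      mean_phase = phst$mean_phase, lhr = lhr,
      circ_ed = shpEd$circularity, circ_es = shpEs$circularity,
      elong_ed = shpEd$elongation, elong_es = shpEs$elongation,
      fs_long = fs$fs_long, fs_short = fs$fs_short,
      lv_size_ed = shpEd$area_px, lv_size_es = shpEs$area_px,
      lv_size_ed_mm2 = shpEd$area_mm2, lv_size_es_mm2 = shpEs$area_mm2,
      counts_ed = tac[ed], counts_es = tac[es],
      heart_rate = beats$heart_rate,
      mean_beat_duration = beats$mean_beat_duration,
      rejected_fraction = beats$rejected_fraction,
      frame_time = if (is.null(beats$frame_time)) NA_real_ else beats$frame_time),
    provenance = list(
      filter = filterKind, kernel = filterKernel,
      background_loc = backgroundLoc, background_width = backgroundWidth,
      background_value = bkg, seed = c(seed[1], seed[2]),
      rg_fraction = rgFraction, ac_iter = acIter,
      n_bins = nBins, apen_m = m, apen_r_frac = rFrac,
      ed_frame = ed, es_frame = es,
      version = as.character(utils::packageVersion("mugatools"))))
}
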