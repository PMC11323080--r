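## Per-pixel first-harmonic (Fourier) analysis of the count-time curves.
##
## Convention used everywhere in the package:
##   c(t) = A0 + A1 * cos(2 pi t / T - phi),  t = 0 .. T-1 (frame index
##   relative to the first gated frame), phi in degrees in [0, 360).
## A positive phi is a positive lag: pixels that peak later in the cycle
## carry a larger phase.

#' First-harmonic phase/amplitude/DC maps of a gated cine
#'
#' Fits \eqn{c(t) = A_0 + A_1 \cos(2\pi t/T - \phi)} to every pixel's
#' count-time curve via the first discrete-Fourier coefficient.  Pixels
#' whose amplitude falls below \code{epsFraction} of the image maximum
#' amplitude carry no reliable timing: their phase is set to 0 and they are
#' flagged low-amplitude.
#'
#' @param cine A \code{\linkS4class{GatedCine}} with T >= 3 frames.
#' @param epsFraction low-amplitude threshold as a fraction of the maximum
#'   amplitude (default 1e-9).
#' @return A \code{\linkS4class{HarmonicMaps}} object.
#' @export
firstHarmonic <- function(cine, epsFraction = 1e-9) {
  stopifnot(is(cine, "GatedCine"))
  f <- frames(cine)
  d <- dim(f)
  TT <- d[3]
  if (TT < 3L) stop("need at least 3 frames for harmonic analysis")
  M <- matrix(f, d[1] * d[2], TT)
  t <- 0:(TT - 1)
  w <- exp(-2i * pi * t / TT)
  X1 <- as.vector(M %*% w)
  a0 <- rowMeans(M)
  a1 <- 2 * Mod(X1) / TT
  phi <- (-Arg(X1) * 180 / pi) %% 360
  phi[phi >= 360] <- 0          # guard: tiny negatives mod 360 give 360
  ## absolute floor absorbs FFT round-off on exactly constant pixels
  eps <- max(epsFraction * max(a1), 1e-10 * max(abs(a0)), .Machine$double.xmin)
  low <- a1 < eps
  phi[low] <- 0
  new("HarmonicMaps",
      dc = matrix(a0, d[1], d[2]),
      amplitude = matrix(a1, d[1], d[2]),
      phase = matrix(phi, d[1], d[2]),
      lowAmplitude = matrix(low, d[1], d[2]))
}

#' Amplitude-weighted phase histogram
#'
#' Bins the phases of the masked pixels into \code{nBins} equal bins
#' spanning [0, 360), each bin's mass being the summed pixel amplitude
#' (or the pixel count when \code{weighted = FALSE}), normalised to 1.
#' Bins are half-open [a, b); the last bin is closed at 360.
#'
#' @param maps A \code{\linkS4class{HarmonicMaps}}.
#' @param mask logical matrix, non-empty.
#' @param nBins number of bins (default 64).
#' @param weighted amplitude-weight the histogram (default TRUE), the
#'   convention of clinical phase analysis; unweighted is available for
#'   comparison.
#' @return List with \code{binEdges} (length nBins + 1) and
#'   \code{probabilities} (length nBins, summing to 1).
#' @export
phaseHistogram <- function(maps, mask, nBins = 64L, weighted = TRUE) {
  stopifnot(is(maps, "HarmonicMaps"), identical(dim(mask), dim(maps@phase)))
  if (!any(mask)) stop("empty mask")
  ph <- maps@phase[mask]
  amp <- maps@amplitude[mask]
  amp[maps@lowAmplitude[mask]] <- 0      # flagged pixels carry no timing
  w <- if (weighted) amp else as.numeric(amp > 0)
  if (sum(w) <= 0) stop("zero total amplitude in mask")
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 2L)
  idx <- pmin(floor(ph / (360 / nBins)) + 1L, nBins)
  p <- vapply(seq_len(nBins), function(b) sum(w[idx == b]), numeric(1))
  p <- p / sum(p)
  list(binEdges = seq(0, 360, length.out = nBins + 1L), probabilities = p)
}

## smallest absolute angular difference in degrees, result in [0, 180]
.angDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
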