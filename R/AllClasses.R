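#' @import methods
#' @importFrom stats sd var cor median qt lm coef confint anova setNames
#'   complete.cases rpois p.adjust predict
#' @importFrom utils write.csv read.csv
NULL

#' Acquisition metadata for a gated cine scan
#'
#' Holds the gating information recorded by the gamma camera: milliseconds
#' per frame, heart rate, accepted/rejected beat counts, mean beat duration
#' and pixel spacing.  Fields that the source file did not record are stored
#' as \code{NA} ("absent") and are never silently defaulted.
#'
#' @slot frameTime numeric, milliseconds per gated frame (> 0).
#' @slot heartRate numeric, beats per minute (> 0) or \code{NA}.
#' @slot acceptedBeats numeric, number of accepted beats (>= 0) or \code{NA}.
#' @slot rejectedBeats numeric, number of rejected beats (>= 0) or \code{NA}.
#' @slot meanBeatDuration numeric, milliseconds (> 0) or \code{NA}.
#' @slot pixelSpacing numeric(2), mm per pixel (row, col), both > 0, or
#'   \code{c(NA, NA)}.
#' @slot nFrames integer, number of gated frames (>= 1).
#'
#' @export
setClass("AcquisitionMeta",
  representation(
    frameTime = "numeric",
    heartRate = "numeric",
    acceptedBeats = "numeric",
    rejectedBeats = "numeric",
    meanBeatDuration = "numeric",
    pixelSpacing = "numeric",
    nFrames = "integer"
  ),
  prototype(
    frameTime = NA_real_, heartRate = NA_real_,
    acceptedBeats = NA_real_, rejectedBeats = NA_real_,
    meanBeatDuration = NA_real_, pixelSpacing = c(NA_real_, NA_real_),
    nFrames = 1L
  )
)

setValidity("AcquisitionMeta", function(object) {
  msgs <- character()
  chkpos <- function(x, nm) {
    if (!is.na(x) && x <= 0) sprintf("'%s' must be strictly positive", nm)
    else character()
  }
  msgs <- c(msgs,
    chkpos(object@frameTime, "frameTime"),
    chkpos(object@heartRate, "heartRate"),
    chkpos(object@meanBeatDuration, "meanBeatDuration"))
  for (nm in c("acceptedBeats", "rejectedBeats")) {
    x <- slot(object, nm)
    if (!is.na(x) && x < 0)
      msgs <- c(msgs, sprintf("'%s' must be >= 0", nm))
  }
  if (length(object@pixelSpacing) != 2L)
    msgs <- c(msgs, "'pixelSpacing' must have length 2")
  else if (any(!is.na(object@pixelSpacing) & object@pixelSpacing <= 0))
    msgs <- c(msgs, "'pixelSpacing' values must be strictly positive")
  if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
      object@nFrames < 1L)
    msgs <- c(msgs, "'nFrames' must be an integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct acquisition metadata
#'
#' @param frameTime milliseconds per frame (> 0) or \code{NA}.
#' @param heartRate beats per minute or \code{NA}.
#' @param acceptedBeats,rejectedBeats beat counts (>= 0) or \code{NA}.
#' @param meanBeatDuration milliseconds or \code{NA}.
#' @param pixelSpacing numeric(2) mm/pixel or \code{NA}.
#' @param nFrames number of gated frames.
#' @return An \code{\linkS4class{AcquisitionMeta}} object.
#' @export
AcquisitionMeta <- function(frameTime = NA_real_, heartRate = NA_real_,
                            acceptedBeats = NA_real_, rejectedBeats = NA_real_,
                            meanBeatDuration = NA_real_,
                            pixelSpacing = c(NA_real_, NA_real_),
                            nFrames = 1L) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("AcquisitionMeta",
      frameTime = as.numeric(frameTime), heartRate = as.numeric(heartRate),
      acceptedBeats = as.numeric(acceptedBeats),
      rejectedBeats = as.numeric(rejectedBeats),
      meanBeatDuration = as.numeric(meanBeatDuration),
      pixelSpacing = as.numeric(pixelSpacing), nFrames = as.integer(nFrames))
}

#' Gated blood-pool cine scan
#'
#' The universal input object: a stack of T count images (rows x cols x T)
#' plus acquisition metadata.  Counts are integer-valued when raw and
#' real-valued after background correction or filtering; they are never
#' negative.  Frame 1 is the first gated frame after the R-wave; pixel
#' (1, 1) is the top-left corner.
#'
#' @slot frames numeric array, rows x cols x T, all values >= 0, T >= 8.
#' @slot meta An \code{\linkS4class{AcquisitionMeta}}.
#'
#' @export
setClass("GatedCine",
  representation(frames = "array", meta = "AcquisitionMeta"))

setValidity("GatedCine", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be a 3-d array (rows x cols x T)")
  if (d[3] < 8L)
    return(sprintf("too few frames: %d (need >= 8)", d[3]))
  if (anyNA(object@frames))
    return("'frames' contains NA values")
  if (any(object@frames < 0))
    return("negative counts in 'frames'")
  if (object@meta@nFrames != d[3])
    return("meta 'nFrames' disagrees with the frame count")
  TRUE
})

#' Construct a gated cine scan
#'
#' @param frames numeric array rows x cols x T (T >= 8), values >= 0.
#' @param meta An \code{\linkS4class{AcquisitionMeta}}; its \code{nFrames}
#'   is set from \code{frames} if left at the default.
#' @return A \code{\linkS4class{GatedCine}}.
#' @export
GatedCine <- function(frames, meta = AcquisitionMeta()) {
  frames <- as.array(frames)
  storage.mode(frames) <- "double"
  if (length(dim(frames)) == 3L) meta@nFrames <- dim(frames)[3]
  new("GatedCine", frames = frames, meta = meta)
}

#' Per-pixel first-harmonic maps
#'
#' Result of fitting c(t) = A0 + A1 cos(2 pi t / T - phi) to every pixel's
#' count-time curve: the DC image (A0), amplitude image (A1 >= 0) and phase
#' image (phi in degrees, [0, 360)).  Pixels whose amplitude is below a
#' small fraction of the image maximum carry no reliable timing and are
#' flagged low-amplitude with phase set to 0.
#'
#' @slot dc numeric matrix of A0 (counts).
#' @slot amplitude numeric matrix of A1 (counts, >= 0).
#' @slot phase numeric matrix of phi (degrees in [0, 360)).
#' @slot lowAmplitude logical matrix flagging unreliable pixels.
#'
#' @export
setClass("HarmonicMaps",
  representation(dc = "matrix", amplitude = "matrix", phase = "matrix",
                 lowAmplitude = "matrix"))

setValidity("HarmonicMaps", function(object) {
  d <- dim(object@dc)
  if (!identical(dim(object@amplitude), d) ||
      !identical(dim(object@phase), d) ||
      !identical(dim(object@lowAmplitude), d))
    return("all maps must share the same dimensions")
  if (any(object@amplitude < 0))
    return("'amplitude' must be >= 0 everywhere")
  if (any(object@phase < 0 | object@phase >= 360))
    return("'phase' must lie in [0, 360)")
  TRUE
})

#' Left-ventricle segmentation of a gated cine
#'
#' Per-frame boolean LV masks produced by the hybrid region-growing /
#' active-contour pipeline, together with the seed point used and the
#' detected end-diastolic and end-systolic frame indices.
#'
#' @slot masks logical array rows x cols x T; every mask is non-empty,
#'   8-connected and contains the seed.
#' @slot seed integer(2), (row, col) of the seed pixel.
#' @slot edFrame,esFrame integer frame indices (1-based), distinct.
#'
#' @export
setClass("LVSegmentation",
  representation(masks = "array", seed = "integer",
                 edFrame = "integer", esFrame = "integer",
                 intermediateMasks = "list"),
  prototype(intermediateMasks = list()))

setValidity("LVSegmentation", function(object) {
  d <- dim(object@masks)
  if (length(d) != 3L) return("'masks' must be rows x cols x T")
  if (!is.logical(object@masks)) return("'masks' must be logical")
  if (length(object@seed) != 2L) return("'seed' must be (row, col)")
  TT <- d[3]
  if (object@edFrame < 1L || object@edFrame > TT ||
      object@esFrame < 1L || object@esFrame > TT)
    return("ED/ES frame index out of range")
  if (object@edFrame == object@esFrame)
    return("ED and ES frames must differ")
  for (t in seq_len(TT)) {
    m <- object@masks[, , t]
    if (!any(m)) return(sprintf("mask %d is empty", t))
    if (!m[object@seed[1], object@seed[2]])
      return(sprintf("mask %d does not contain the seed", t))
  }
  TRUE
})

#' Full biomarker vector for one scan
#'
#' Named numeric values for every count-, time- and shape-based parameter
#' the toolbox extracts, plus a provenance list recording the processing
#' configuration (filter, background, seed, version).  Absent values are
#' \code{NA}.
#'
#' @slot values named numeric vector; see \code{\link{parameterNames}} for
#'   the fixed column order used on export.
#' @slot provenance list of processing settings.
#'
#' @export
setClass("ParameterSet",
  representation(values = "numeric", provenance = "list"))

#' Canonical parameter order
#'
#' The fixed, documented column order used by \code{\link{exportParameters}}.
#'
#' @return Character vector of parameter names.
#' @export
parameterNames <- function() {
  c("lvef", "phase_lvef", "ejection_rate",
    "e_raw", "e_norm", "apen", "b_apen",
    "apen_d", "apen_s", "apen_ds",
    "synchrony", "phase_sd", "mean_phase", "lhr",
    "circ_ed", "circ_es", "elong_ed", "elong_es",
    "fs_long", "fs_short",
    "lv_size_ed", "lv_size_es", "lv_size_ed_mm2", "lv_size_es_mm2",
    "counts_ed", "counts_es",
    "heart_rate", "mean_beat_duration", "rejected_fraction", "frame_time")
}

setValidity("ParameterSet", function(object) {
  if (!identical(names(object@values), parameterNames()))
    return("'values' must be named exactly as parameterNames()")
  v <- object@values
  ok <- function(nm) !is.na(v[[nm]])
  if (ok("lvef") && v[["lvef"]] > 100) return("lvef > 100")
  if (ok("synchrony") && (v[["synchrony"]] < 0 || v[["synchrony"]] > 1))
    return("synchrony outside [0, 1]")
  if (ok("e_norm") && (v[["e_norm"]] < 0 || v[["e_norm"]] > 1))
    return("e_norm outside [0, 1]")
  for (nm in c("elong_ed", "elong_es"))
    if (ok(nm) && v[[nm]] < 1) return(sprintf("%s < 1", nm))
  TRUE
})

#' Construct a ParameterSet
#'
#' @param values named numeric values; missing names are filled with
#'   \code{NA}.
#' @param provenance list of processing settings.
#' @return A \code{\linkS4class{ParameterSet}}.
#' @export
ParameterSet <- function(values = numeric(), provenance = list()) {
  full <- setNames(rep(NA_real_, length(parameterNames())), parameterNames())
  bad <- setdiff(names(values), parameterNames())
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  full[names(values)] <- as.numeric(values)
  new("ParameterSet", values = full, provenance = provenance)
}

#' Ground truth for a generated phantom
#'
#' @slot ef numeric, the true ejection fraction in (0, 1).
#' @slot masks logical array rows x cols x T of true LV supports.
#' @slot edFrame,esFrame integer, true ED/ES frame indices (1-based).
#' @slot sectorPhaseOffsets numeric(6), per-sector phase delay in degrees.
#' @slot volumeCurve numeric(T), analytic chamber volume per frame (pixel^3).
#'
#' @export
setClass("PhantomTruth",
  representation(ef = "numeric", masks = "array",
                 edFrame = "integer", esFrame = "integer",
                 sectorPhaseOffsets = "numeric", volumeCurve = "numeric"))

setValidity("PhantomTruth", function(object) {
  v <- object@volumeCurve
  ed <- which.max(v); es <- which.min(v)
  ef <- (v[ed] - v[es]) / v[ed]
  if (abs(ef - object@ef) > 1e-9)
    return("volume curve does not reproduce the stated ejection fraction")
  TRUE
})

## ---- accessors ------------------------------------------------------------

#' @describeIn GatedCine-class The frame stack (rows x cols x T array).
#' @param object a package object.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @export
setMethod("frames", "GatedCine", function(object) object@frames)

#' @describeIn GatedCine-class Acquisition metadata.
#' @export
setGeneric("meta", function(object) standardGeneric("meta"))
#' @export
setMethod("meta", "GatedCine", function(object) object@meta)

#' @describeIn GatedCine-class Number of gated frames.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "GatedCine", function(object) dim(object@frames)[3])

#' @describeIn HarmonicMaps-class DC (A0) image.
#' @export
setGeneric("dcImage", function(object) standardGeneric("dcImage"))
#' @export
setMethod("dcImage", "HarmonicMaps", function(object) object@dc)

#' @describeIn HarmonicMaps-class Amplitude (A1) image.
#' @export
setGeneric("amplitudeImage", function(object) standardGeneric("amplitudeImage"))
#' @export
setMethod("amplitudeImage", "HarmonicMaps", function(object) object@amplitude)

#' @describeIn HarmonicMaps-class Phase image in degrees.
#' @export
setGeneric("phaseImage", function(object) standardGeneric("phaseImage"))
#' @export
setMethod("phaseImage", "HarmonicMaps", function(object) object@phase)

#' @describeIn HarmonicMaps-class Low-amplitude flag image.
#' @export
setGeneric("lowAmplitude", function(object) standardGeneric("lowAmplitude"))
#' @export
setMethod("lowAmplitude", "HarmonicMaps", function(object) object@lowAmplitude)

#' @describeIn LVSegmentation-class Per-frame LV masks.
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))
#' @export
setMethod("masks", "LVSegmentation", function(object) object@masks)
#' @export
setMethod("masks", "PhantomTruth", function(object) object@masks)

#' @describeIn LVSegmentation-class End-diastolic frame index.
#' @export
setGeneric("edFrame", function(object) standardGeneric("edFrame"))
#' @export
setMethod("edFrame", "LVSegmentation", function(object) object@edFrame)
#' @export
setMethod("edFrame", "PhantomTruth", function(object) object@edFrame)

#' @describeIn LVSegmentation-class End-systolic frame index.
#' @export
setGeneric("esFrame", function(object) standardGeneric("esFrame"))
#' @export
setMethod("esFrame", "LVSegmentation", function(object) object@esFrame)
#' @export
setMethod("esFrame", "PhantomTruth", function(object) object@esFrame)

#' @describeIn ParameterSet-class Named numeric parameter vector.
#' @export
setGeneric("parameterValues", function(object) standardGeneric("parameterValues"))
#' @export
setMethod("parameterValues", "ParameterSet", function(object) object@values)

#' @describeIn ParameterSet-class Provenance list.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @export
setMethod("provenance", "ParameterSet", function(object) object@provenance)

#' @describeIn PhantomTruth-class True ejection fraction.
#' @export
setGeneric("trueEF", function(object) standardGeneric("trueEF"))
#' @export
setMethod("trueEF", "PhantomTruth", function(object) object@ef)

#' @describeIn PhantomTruth-class Analytic volume curve.
#' @export
setGeneric("volumeCurve", function(object) standardGeneric("volumeCurve"))
#' @export
setMethod("volumeCurve", "PhantomTruth", function(object) object@volumeCurve)

## ---- show methods ---------------------------------------------------------

setMethod("show", "GatedCine", function(object) {
  d <- dim(object@frames)
  cat(sprintf("GatedCine: %d x %d pixels, %d frames\n", d[1], d[2], d[3]))
  m <- object@meta
  cat(sprintf("  total counts %.4g; frame time %s ms; heart rate %s bpm\n",
              sum(object@frames),
              ifelse(is.na(m@frameTime), "absent", format(m@frameTime)),
              ifelse(is.na(m@heartRate), "absent", format(m@heartRate))))
  invisible(NULL)
})

setMethod("show", "HarmonicMaps", function(object) {
  d <- dim(object@dc)
  cat(sprintf("HarmonicMaps: %d x %d; max amplitude %.4g; %d low-amplitude pixels\n",
              d[1], d[2], max(object@amplitude), sum(object@lowAmplitude)))
  invisible(NULL)
})

setMethod("show", "LVSegmentation", function(object) {
  d <- dim(object@masks)
  sizes <- apply(object@masks, 3, sum)
  cat(sprintf("LVSegmentation: %d frames; mask size %d-%d px; seed (%d, %d); ED frame %d, ES frame %d\n",
              d[3], min(sizes), max(sizes), object@seed[1], object@seed[2],
              object@edFrame, object@esFrame))
  invisible(NULL)
})

setMethod("show", "ParameterSet", function(object) {
  v <- object@values
  cat("ParameterSet\n")
  shown <- v[!is.na(v)]
  for (nm in names(shown))
    cat(sprintf("  %-20s %.6g\n", nm, shown[[nm]]))
  if (any(is.na(v)))
    cat("  absent:", paste(names(v)[is.na(v)], collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: EF %.3f; ED frame %d, ES frame %d; %d frames\n",
              object@ef, object@edFrame, object@esFrame,
              length(object@volumeCurve)))
  invisible(NULL)
})
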