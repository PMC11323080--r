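## Reading and writing gated cine scans: the portable JSON fixture
## container, the DICOM dialect, and the CSV parameter table export.

#' Read a gated cine scan
#'
#' Two dialects are supported.  \code{"fixture"} is the package's portable
#' container written by \code{\link{writeFixture}}: a JSON file holding the
#' frame stack and a metadata block; the round trip is exact on integer
#' frames.  \code{"dicom"} reads an uncompressed little-endian multi-frame
#' nuclear-medicine DICOM file (8 or 16 bits/pixel), taking metadata only
#' from the tags that are actually present — an absent tag yields an
#' absent metadata field, never a default.  Frames are kept in stored
#' (trigger-time) order and raw counts are untouched.
#'
#' @param path file path.
#' @param dialect \code{"fixture"} or \code{"dicom"}.
#' @return A \code{\linkS4class{GatedCine}}.
#' @export
readGatedScan <- function(path, dialect = c("fixture", "dicom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (dialect == "dicom") return(.readDicomCine(path))

  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable file: ", path))
  if (is.null(obj$frames) || is.null(obj$dim))
    stop("unreadable file: not a cine fixture")
  d <- as.integer(obj$dim)
  if (length(d) != 3L) stop("unreadable file: malformed dimensions")
  if (d[3] < 8L) stop("too few frames: ", d[3])
  v <- as.numeric(obj$frames)
  if (length(v) != prod(d)) stop("inconsistent frame dimensions")
  if (any(v < 0)) stop("negative counts")
  f <- array(v, d)
  mt <- obj$meta
  g <- function(nm) if (is.null(mt[[nm]])) NA_real_ else as.numeric(mt[[nm]])
  ps <- if (is.null(mt[["pixel_spacing"]])) c(NA_real_, NA_real_)
        else as.numeric(mt[["pixel_spacing"]])
  metaObj <- AcquisitionMeta(
    frameTime = g("frame_time"), heartRate = g("heart_rate"),
    acceptedBeats = g("accepted_beats"), rejectedBeats = g("rejected_beats"),
    meanBeatDuration = g("mean_beat_duration"),
    pixelSpacing = ps, nFrames = d[3])
  GatedCine(f, metaObj)
}

#' Write a cine scan to the portable fixture container
#'
#' Serialises the frame stack (column-major, with its dimensions) and a
#' metadata block to JSON at full precision.  Absent metadata fields are
#' omitted from the block, and \code{\link{readGatedScan}} inverts the file
#' exactly.
#'
#' @param cine A valid \code{\linkS4class{GatedCine}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeFixture <- function(cine, path) {
  stopifnot(is(cine, "GatedCine"))
  validObject(cine)
  m <- meta(cine)
  mt <- list()
  put <- function(nm, x) if (!all(is.na(x))) mt[[nm]] <<- x
  put("frame_time", m@frameTime)
  put("heart_rate", m@heartRate)
  put("accepted_beats", m@acceptedBeats)
  put("rejected_beats", m@rejectedBeats)
  put("mean_beat_duration", m@meanBeatDuration)
  put("pixel_spacing", m@pixelSpacing)
  obj <- list(container = "gated-cine-fixture", version = 1L,
              dim = dim(frames(cine)), meta = mt,
              frames = as.vector(frames(cine)))
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("unwritable path: ", path)
  invisible(path)
}

#' Export parameter sets to a CSV table
#'
#' One row per scan in the fixed column order of
#' \code{\link{parameterNames}}; absent values are written as empty cells,
#' never as 0.  The file is directly ingestible by the statistics layer.
#'
#' @param rows list of \code{\linkS4class{ParameterSet}} objects (>= 1).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportParameters <- function(rows, path) {
  if (is(rows, "ParameterSet")) rows <- list(rows)
  if (length(rows) == 0L) stop("no parameter sets to export")
  stopifnot(all(vapply(rows, function(r) is(r, "ParameterSet"), logical(1))))
  tab <- as.data.frame(do.call(rbind, lapply(rows, parameterValues)))
  names(tab) <- parameterNames()
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a parameter table written by exportParameters
#'
#' @param path CSV path.
#' @return data.frame with numeric columns; empty cells become \code{NA}.
#' @export
readParameterTable <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
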