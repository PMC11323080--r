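## Minimal DICOM reader for uncompressed little-endian multi-frame
## nuclear-medicine images.  No R DICOM package is available to this
## package's dependency set, so the small subset of the standard the
## toolbox needs is parsed directly: the part-10 preamble and file meta
## group, explicit- and implicit-VR little-endian datasets, the gating
## tags, and unsigned 8/16-bit pixel data.

.TS_IMPLICIT <- "1.2.840.10008.1.2"
.TS_EXPLICIT <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
.u32 <- function(raw, off) {
  as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
}
.rawStr <- function(raw, off, len) {
  if (len == 0) return("")
  b <- raw[(off + 1L):(off + len)]
  b <- b[b != as.raw(0)]                 # drop NUL padding
  trimws(rawToChar(b))
}

## parse one dataset (element sequence) from offset; returns named list
## keyed "gggg,eeee" with raw value bytes
.parseElements <- function(raw, off, explicit, stopAtPixels = TRUE) {
  n <- length(raw)
  out <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    grp <- .u16(raw, off); ele <- .u16(raw, off + 2L)
    tag <- sprintf("%04x,%04x", grp, ele)
    if (explicit) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (vr %in% longVRs) {
        len <- .u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, off + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- .u32(raw, off + 4L); hdr <- 8L
    }
    if (len == 4294967295) {            # undefined length (sequences)
      if (tag == "7fe0,0010")
        stop("unreadable file: encapsulated (compressed) pixel data")
      stop("unreadable file: undefined-length sequence not supported")
    }
    valOff <- off + hdr
    if (valOff + len > n) stop("unreadable file: truncated DICOM element")
    out[[tag]] <- list(vr = vr, off = valOff, len = len)
    off <- valOff + len
    if (stopAtPixels && tag == "7fe0,0010") break
  }
  out
}

.readDicomCine <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L) stop("unreadable file: too short for DICOM")
  explicit <- TRUE
  off <- 0L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") {
    ## file meta group: always explicit VR little endian
    metaEls <- .parseMetaGroup(raw, 132L)
    ts <- metaEls$ts
    off <- metaEls$end
    if (ts == .TS_IMPLICIT) explicit <- FALSE
    else if (ts != .TS_EXPLICIT && nzchar(ts))
      stop("unreadable file: unsupported transfer syntax ", ts)
  } else {
    stop("unreadable file: missing DICM marker")
  }

  els <- .parseElements(raw, off, explicit)
  gv <- function(tag) els[[tag]]
  str <- function(tag) {
    e <- gv(tag); if (is.null(e)) return(NA_character_)
    .rawStr(raw, e$off, e$len)
  }
  num <- function(tag) {
    s <- str(tag)
    if (is.na(s) || !nzchar(s)) NA_real_ else as.numeric(s)
  }
  us <- function(tag) {
    e <- gv(tag); if (is.null(e)) return(NA_integer_)
    .u16(raw, e$off)
  }

  nFrames <- num("0028,0008")
  rowsN <- us("0028,0010"); colsN <- us("0028,0011")
  bits <- us("0028,0100")
  pixRep <- us("0028,0103")
  if (is.na(nFrames) || is.na(rowsN) || is.na(colsN))
    stop("unreadable file: missing image dimensions")
  if (nFrames < 8) stop("too few frames: ", nFrames)
  if (is.na(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L))
    stop("unreadable file: unsupported bits allocated ", bits)
  if (!is.na(pixRep) && pixRep != 0L)
    stop("unreadable file: signed pixel data not supported")

  pe <- gv("7fe0,0010")
  if (is.null(pe)) stop("unreadable file: no pixel data")
  npix <- rowsN * colsN * nFrames
  bytesPer <- bits %/% 8L
  if (pe$len < npix * bytesPer)
    stop("inconsistent frame dimensions: pixel data too small")
  con <- raw[(pe$off + 1L):(pe$off + npix * bytesPer)]
  v <- readBin(con, "integer", n = npix, size = bytesPer,
               signed = FALSE, endian = "little")
  ## DICOM stores each frame row-major (first row first)
  arr <- array(NA_real_, c(rowsN, colsN, nFrames))
  per <- rowsN * colsN
  for (t in seq_len(nFrames))
    arr[, , t] <- matrix(v[((t - 1) * per + 1):(t * per)],
                         nrow = rowsN, ncol = colsN, byrow = TRUE)
  if (any(arr < 0)) stop("negative counts")

  spacingStr <- str("0028,0030")
  spacing <- if (is.na(spacingStr)) c(NA_real_, NA_real_)
             else as.numeric(strsplit(spacingStr, "\\\\")[[1]])[1:2]
  metaObj <- AcquisitionMeta(
    frameTime = num("0018,1063"),
    heartRate = num("0018,1088"),
    acceptedBeats = num("0018,1083"),
    rejectedBeats = num("0018,1084"),
    meanBeatDuration = NA_real_,
    pixelSpacing = spacing,
    nFrames = as.integer(nFrames))
  GatedCine(arr, metaObj)
}

## parse the group-0002 file meta elements (explicit VR); returns the
## transfer syntax UID and the offset of the first dataset byte
.parseMetaGroup <- function(raw, off) {
  n <- length(raw)
  ts <- ""
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    grp <- .u16(raw, off)
    if (grp != 2L) break
    ele <- .u16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (vr %in% longVRs) {
      len <- .u32(raw, off + 8L); hdr <- 12L
    } else {
      len <- .u16(raw, off + 6L); hdr <- 8L
    }
    valOff <- off + hdr
    if (ele == 16L) ts <- .rawStr(raw, valOff, len)   # (0002,0010)
    off <- as.integer(valOff + len)
  }
  list(ts = ts, end = off)
}
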