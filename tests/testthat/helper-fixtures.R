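# Shared fixtures: all test inputs are generated in code at run time.

# centre seed of the default phantom geometry
phantomSeed <- c(32L, 24L)

# run the pipeline stages up to segmentation, mirroring computeAll's
# orchestration, so tests can inspect intermediate objects
segmentPipeline <- function(cine, seed = phantomSeed, rgFraction = 0.25) {
  filt <- filterCine(cine)
  favg <- apply(frames(filt), c(1, 2), mean)
  prov <- regionGrow(favg, seed, rgFraction)
  bb <- mugatools:::.bbox(prov)
  bkg <- measureBackground(favg, buildBackgroundRois(favg, bb)[[1]])
  corr <- correctBackground(filt, bkg)
  maps <- firstHarmonic(corr)
  seg <- acrgSegment(corr, maps, seed, rgFraction = rgFraction)
  list(corr = corr, maps = maps, seg = seg)
}

# small cine whose every pixel follows a first-harmonic law
# c(t) = a0 + a1 * cos(2*pi*t/T - phi_deg)
harmonicCine <- function(a0, a1, phiDeg, n = 8L, T = 16L) {
  t <- 0:(T - 1)
  arr <- array(0, c(n, n, T))
  for (k in seq_len(T))
    arr[, , k] <- a0 + a1 * cos(2 * pi * t[k] / T - phiDeg * pi / 180)
  arr[arr < 0] <- 0
  GatedCine(arr, AcquisitionMeta(frameTime = 50, nFrames = T))
}

# minimal explicit-VR little-endian multi-frame DICOM writer used to
# exercise the reader; tags are written in ascending order
writeMiniDicom <- function(path, framesArr,
                           frameTime = NULL, heartRate = NULL,
                           intervalsAcquired = NULL,
                           intervalsRejected = NULL,
                           pixelSpacing = NULL,
                           transferSyntax = "1.2.840.10008.1.2.1") {
  d <- dim(framesArr)
  con <- file(path, "wb")
  on.exit(close(con))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  strEl <- function(grp, ele, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(c(grp, ele))
    writeChar(vr, con, eos = NULL)
    u16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  usEl <- function(grp, ele, v) {
    u16(c(grp, ele)); writeChar("US", con, eos = NULL); u16(2L); u16(v)
  }

  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  strEl(0x0002, 0x0010, "UI", transferSyntax)

  if (!is.null(frameTime)) strEl(0x0018, 0x1063, "DS", as.character(frameTime))
  if (!is.null(intervalsAcquired))
    strEl(0x0018, 0x1083, "IS", as.character(intervalsAcquired))
  if (!is.null(intervalsRejected))
    strEl(0x0018, 0x1084, "IS", as.character(intervalsRejected))
  if (!is.null(heartRate)) strEl(0x0018, 0x1088, "IS", as.character(heartRate))
  strEl(0x0028, 0x0008, "IS", as.character(d[3]))
  usEl(0x0028, 0x0010, d[1])
  usEl(0x0028, 0x0011, d[2])
  if (!is.null(pixelSpacing))
    strEl(0x0028, 0x0030, "DS",
          paste(pixelSpacing[1], pixelSpacing[2], sep = "\\"))
  usEl(0x0028, 0x0100, 16L)
  usEl(0x0028, 0x0103, 0L)

  npix <- prod(d)
  u16(c(0x7FE0, 0x0010))
  writeChar("OW", con, eos = NULL)
  u16(0L)                                   # reserved
  writeBin(as.integer(npix * 2), con, size = 4, endian = "little")
  pix <- integer(npix)
  per <- d[1] * d[2]
  for (t in seq_len(d[3]))                  # row-major within each frame
    pix[((t - 1) * per + 1):(t * per)] <- as.integer(t(framesArr[, , t]))
  writeBin(pix, con, size = 2, endian = "little")
  invisible(path)
}

# rasterised ellipse mask (full axes 2a x 2b) centred in an n x n image
ellipseMask <- function(n, a, b, ctr = c((n + 1) / 2, (n + 1) / 2)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((cols - ctr[2]) / a)^2 + ((rows - ctr[1]) / b)^2 <= 1
}
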