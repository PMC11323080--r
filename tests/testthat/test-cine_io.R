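test_that("fixture round-trip is the identity on frames and metadata", {
  ph <- generatePhantom(phantomConfig(poisson = TRUE, rngSeed = 3L))
  path <- tempfile(fileext = ".json")
  writeFixture(ph$cine, path)
  back <- readGatedScan(path, "fixture")
  expect_identical(frames(back), frames(ph$cine))
  expect_equal(meta(back)@frameTime, meta(ph$cine)@frameTime)
  expect_equal(meta(back)@heartRate, meta(ph$cine)@heartRate)
  expect_equal(meta(back)@pixelSpacing, meta(ph$cine)@pixelSpacing)
  # frame sums invariant: the reader never reorders pixels
  expect_equal(apply(frames(back), 3, sum), apply(frames(ph$cine), 3, sum))
  unlink(path)
})

test_that("absent metadata stays absent through the fixture container", {
  arr <- array(1, c(8, 8, 8))
  cine <- GatedCine(arr, AcquisitionMeta(frameTime = 40, nFrames = 8L))
  path <- tempfile(fileext = ".json")
  writeFixture(cine, path)
  txt <- readLines(path, warn = FALSE)
  expect_false(any(grepl("heart_rate", txt)))
  back <- readGatedScan(path, "fixture")
  expect_true(is.na(meta(back)@heartRate))
  expect_true(all(is.na(meta(back)@pixelSpacing)))
  expect_equal(meta(back)@frameTime, 40)
  unlink(path)
})

test_that("fixture reader rejects malformed input", {
  arr <- array(2, c(8, 8, 8))
  cine <- GatedCine(arr)
  path <- tempfile(fileext = ".json")
  writeFixture(cine, path)
  # truncated file
  raw <- readLines(path, warn = FALSE)
  writeLines(substr(paste(raw, collapse = ""), 1, 50), path)
  expect_error(readGatedScan(path, "fixture"), "unreadable")
  # negative counts
  writeFixture(cine, path)
  txt <- jsonlite::read_json(path, simplifyVector = TRUE)
  txt$frames[1] <- -1
  jsonlite::write_json(txt, path, auto_unbox = TRUE, digits = NA)
  expect_error(readGatedScan(path, "fixture"), "negative counts")
  # missing file
  expect_error(readGatedScan(tempfile(), "fixture"), "unreadable")
  unlink(path)
})

test_that("dicom dialect reads frames, gating tags, and absent fields", {
  set.seed(11)
  arr <- array(sample(0:500, 6 * 5 * 8, TRUE), c(6, 5, 8))
  path <- tempfile(fileext = ".dcm")
  writeMiniDicom(path, arr, frameTime = 50, heartRate = 75,
                 intervalsAcquired = 180, intervalsRejected = 20,
                 pixelSpacing = c(4, 4))
  cine <- readGatedScan(path, "dicom")
  expect_equal(frames(cine), array(as.numeric(arr), dim(arr)))
  m <- meta(cine)
  expect_equal(m@frameTime, 50)
  expect_equal(m@heartRate, 75)
  expect_equal(m@acceptedBeats, 180)
  expect_equal(m@rejectedBeats, 20)
  expect_equal(m@pixelSpacing, c(4, 4))
  unlink(path)

  # absent tags give absent fields, never defaults
  writeMiniDicom(path, arr)
  m2 <- meta(readGatedScan(path, "dicom"))
  expect_true(is.na(m2@frameTime))
  expect_true(is.na(m2@heartRate))
  expect_true(all(is.na(m2@pixelSpacing)))
  unlink(path)
})

test_that("dicom reader enforces the minimum frame count", {
  arr <- array(1L, c(4, 4, 4))
  path <- tempfile(fileext = ".dcm")
  writeMiniDicom(path, arr)
  expect_error(readGatedScan(path, "dicom"), "too few frames")
  unlink(path)
})

test_that("parameter export writes fixed columns and survives re-ingest", {
  p1 <- ParameterSet(c(lvef = 61.25, synchrony = 0.97, e_norm = 0.12,
                       counts_ed = 10234.5))
  p2 <- ParameterSet(c(lvef = 48.5, phase_sd = 22.1, elong_ed = 1.4))
  path <- tempfile(fileext = ".csv")
  exportParameters(list(p1, p2), path)
  tab <- readParameterTable(path)
  expect_identical(names(tab), parameterNames())
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lvef, c(61.25, 48.5), tolerance = 1e-9)
  expect_equal(tab$counts_ed[1], 10234.5, tolerance = 1e-9)
  # absent values round-trip as NA (empty cells), not 0
  expect_true(is.na(tab$lhr[1]))
  expect_true(is.na(tab$synchrony[2]))
  raw <- readLines(path)
  expect_false(grepl(",0,", strsplit(raw[3], "lhr")[[1]][1]))
  expect_error(exportParameters(list(), path), "no parameter sets")
  unlink(path)
})

test_that("GatedCine validity enforces the domain invariants", {
  expect_error(GatedCine(array(1, c(8, 8, 4))), "too few frames")
  bad <- array(1, c(8, 8, 8)); bad[1, 1, 1] <- -5
  expect_error(GatedCine(bad), "negative")
  expect_error(AcquisitionMeta(frameTime = -1), "positive")
  expect_error(AcquisitionMeta(rejectedBeats = -2), ">= 0")
})
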