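test_that("time-activity curve sums masked counts and is linear", {
  ph <- generatePhantom(phantomConfig())
  r <- segmentPipeline(ph$cine)
  tac <- timeActivityCurve(r$corr, r$seg)
  expect_length(tac, 16L)
  t1 <- sum(frames(r$corr)[, , 1][masks(r$seg)[, , 1]])
  expect_equal(tac[1], t1)
  scaled <- GatedCine(frames(r$corr) * 3, meta(r$corr))
  expect_equal(timeActivityCurve(scaled, r$seg), 3 * tac)
})

test_that("count-based LVEF follows its closed form", {
  expect_equal(computeLvef(c(10000, 8000, 4000), 1, 3), 60)
  expect_equal(computeLvef(c(500, 500), 1, 2), 0)
  expect_equal(computeLvef(c(1000, 500), 1, 2), 50)
  expect_error(computeLvef(c(0, 1), 1, 2), "non-positive")
})

test_that("phase LVEF follows the first-harmonic formula and tracks counts", {
  maps <- firstHarmonic(harmonicCine(100, 25, 30))
  mask <- matrix(TRUE, 8, 8)
  expect_equal(phaseLvef(maps, mask), 40, tolerance = 1e-6)
  flat <- firstHarmonic(GatedCine(array(50, c(8, 8, 16))))
  expect_equal(phaseLvef(flat, mask), 0, tolerance = 1e-9)

  # pure first-harmonic cine: phase LVEF within 2 points of count LVEF
  cine <- harmonicCine(100, 25, 0)
  m <- firstHarmonic(cine)
  tac <- vapply(1:16, function(t) sum(frames(cine)[, , t]), numeric(1))
  edes <- detectEdEs(tac)
  expect_lt(abs(phaseLvef(m, mask) - computeLvef(tac, edes[1], edes[2])), 2)
})

test_that("ejection rate is the peak normalised systolic count fall", {
  tac <- c(100, 60, 40, 35, 40, 60, 80, 95)
  expect_equal(ejectionRate(tac, 1, 50), (100 - 60) / (100 * 0.05))
  expect_equal(ejectionRate(rep(80, 8), 1, 50), 0)
  # phantom: frame-difference peak matches the analytic volume-curve peak
  ph <- generatePhantom(phantomConfig())
  v <- volumeCurve(ph$truth)
  tacTruth <- vapply(1:16, function(t)
    sum(frames(ph$cine)[, , t][masks(ph$truth)[, , t]]) -
      2 * sum(masks(ph$truth)[, , t]), numeric(1))
  er <- ejectionRate(tacTruth, which.max(tacTruth), 50)
  analytic <- max(-diff(v)) / (max(v) * 0.05)
  expect_lt(abs(er - analytic) / analytic, 0.10)
})

test_that("fast ApEn equals the brute-force oracle on frozen cases", {
  x1 <- rep(c(1, 2, 3), 10)
  expect_equal(approxEntropy(x1, 2, 0.5, mode = "slow"),
               -5.7650811746690067e-05, tolerance = 1e-9)
  expect_equal(approxEntropy(x1, 2, 0.5, mode = "fast"),
               approxEntropy(x1, 2, 0.5, mode = "slow"), tolerance = 1e-12)
  x2 <- rep(c(0, 1), 10)
  expect_equal(approxEntropy(x2, 1, 0.1, mode = "slow"),
               -0.0013856817075275085, tolerance = 1e-9)
  expect_equal(approxEntropy(x2, 1, 0.1, mode = "fast"),
               approxEntropy(x2, 1, 0.1, mode = "slow"), tolerance = 1e-12)
  # constant signal has zero ApEn at any tolerance
  expect_equal(approxEntropy(rep(4, 20), 2, 0.5), 0)
  expect_error(approxEntropy(1:10, 2, -0.1), "r must be")
  expect_error(approxEntropy(c(1, 2), 1, 0.1), "too short")
})

test_that("bounded ApEn is affine-invariant and matches the explicit radius", {
  set.seed(1)
  x <- runif(100)
  expect_equal(boundedApen(x, 2, 0.2), 0.9438224716945236, tolerance = 1e-9)
  expect_equal(boundedApen(x, 2, 0.2),
               approxEntropy(x, 2, 0.2 * (max(x) - min(x))), tolerance = 1e-12)
  expect_equal(boundedApen(7 * x + 3, 2, 0.2), boundedApen(x, 2, 0.2),
               tolerance = 1e-9)
  expect_error(boundedApen(rep(2, 50), 2, 0.2), "zero-range")
})

test_that("phase statistics hit their degenerate closed forms", {
  # all phases equal
  maps <- firstHarmonic(harmonicCine(100, 25, 45))
  mask <- matrix(TRUE, 8, 8)
  st <- phaseStatistics(maps, mask)
  expect_equal(st$e_norm, 0, tolerance = 1e-9)
  expect_equal(st$synchrony, 1, tolerance = 1e-9)
  expect_equal(st$phase_sd, 0, tolerance = 1e-6)
  expect_equal(st$mean_phase, 45, tolerance = 1e-6)

  # equal amplitude at 0 and 180: synchrony 0, two occupied bins
  arr <- array(0, c(4, 4, 16))
  for (k in 1:16) {
    v <- 100 + 20 * cos(2 * pi * (k - 1) / 16)
    w <- 100 + 20 * cos(2 * pi * (k - 1) / 16 - pi)
    arr[, , k] <- matrix(c(v, w), 4, 4)
  }
  m2 <- firstHarmonic(GatedCine(arr, AcquisitionMeta(nFrames = 16L)))
  st2 <- phaseStatistics(m2, matrix(TRUE, 4, 4), 64L)
  expect_equal(st2$synchrony, 0, tolerance = 1e-9)
  expect_equal(st2$e_norm, 1 / log2(64), tolerance = 1e-9)

  # doubling all amplitudes changes nothing
  mapsX <- new("HarmonicMaps", dc = dcImage(m2),
               amplitude = 2 * amplitudeImage(m2), phase = phaseImage(m2),
               lowAmplitude = lowAmplitude(m2))
  stX <- phaseStatistics(mapsX, matrix(TRUE, 4, 4), 64L)
  expect_equal(stX$e_raw, st2$e_raw, tolerance = 1e-12)
  expect_equal(stX$synchrony, st2$synchrony, tolerance = 1e-12)
})

test_that("spatial ApEn composes its parts and handles degeneracy", {
  ph <- generatePhantom(phantomConfig(poisson = TRUE, rngSeed = 7L))
  maps <- firstHarmonic(filterCine(ph$cine))
  edM <- masks(ph$truth)[, , edFrame(ph$truth)]
  esM <- masks(ph$truth)[, , esFrame(ph$truth)]
  sp <- apenSpatial(maps, edM, esM)
  # hand-composed from the exported primitives (row-major sequences)
  seqOf <- function(msk) as.vector(t(phaseImage(maps)))[as.vector(t(msk))]
  expect_equal(sp$apen_d, boundedApen(seqOf(edM), 2, 0.2), tolerance = 1e-12)
  expect_equal(sp$apen_s, boundedApen(seqOf(esM), 2, 0.2), tolerance = 1e-12)
  expect_equal(sp$apen_ds, (sp$apen_d + sp$apen_s) / 2, tolerance = 1e-12)
  # identical masks give identical values
  spSame <- apenSpatial(maps, edM, edM)
  expect_equal(spSame$apen_d, spSame$apen_s)
  # uniform phase -> zero with a warning, not an error
  flat <- new("HarmonicMaps", dc = dcImage(maps),
              amplitude = amplitudeImage(maps),
              phase = matrix(90, 64, 64),
              lowAmplitude = matrix(FALSE, 64, 64))
  w <- capture_warnings(spZ <- apenSpatial(flat, edM, esM))
  expect_true(all(grepl("zero-range", w)))
  expect_equal(spZ$apen_ds, 0)
  tiny <- matrix(FALSE, 64, 64); tiny[1, 1:3] <- TRUE
  expect_error(apenSpatial(maps, tiny, esM), "smaller than")
})

test_that("shape metrics are calibrated on discs and ellipses", {
  disc <- ellipseMask(50, 20, 20)
  sm <- shapeMetrics(disc)
  expect_equal(sm$elongation, 1, tolerance = 0.02)
  expect_gte(sm$circularity, 0.95)
  expect_lte(sm$circularity, 1.05)
  expect_equal(sm$area_px, sum(disc))

  ell <- ellipseMask(60, 20, 10)
  sme <- shapeMetrics(ell)
  expect_equal(sme$elongation, 2, tolerance = 0.05 * 2)
  expect_equal(sme$long_axis, 40, tolerance = 2)
  expect_equal(sme$area_mm2, NA_real_)
  sm2 <- shapeMetrics(ell, pixelSpacing = c(2, 2))
  expect_equal(sm2$area_mm2, 4 * sme$area_px)

  two <- matrix(FALSE, 10, 10); two[5, 5:6] <- TRUE
  expect_error(shapeMetrics(two), "degenerate")
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_error(shapeMetrics(line), "degenerate")
})

test_that("fractional shortening and LHR follow their definitions", {
  fs <- fractionalShortening(c(40, 30), c(30, 24))
  expect_equal(fs$fs_long, 25)
  expect_equal(fs$fs_short, 20)
  expect_equal(fractionalShortening(c(40, 30), c(40, 30))$fs_long, 0)
  expect_lt(fractionalShortening(c(40, 30), c(44, 30))$fs_long, 0)
  expect_error(fractionalShortening(c(0, 30), c(30, 24)), "non-positive")

  frame <- matrix(0, 10, 10)
  lung <- matrix(FALSE, 10, 10); lung[1:2, 1:2] <- TRUE
  lv <- matrix(FALSE, 10, 10); lv[6:9, 6:9] <- TRUE
  frame[lung] <- 2; frame[lv] <- 8
  expect_equal(lungHeartRatio(frame, lung, lv), 0.25)
  expect_equal(lungHeartRatio(frame * 5, lung, lv), 0.25)
  bad <- lung; bad[6, 6] <- TRUE
  expect_error(lungHeartRatio(frame, bad, lv), "overlaps")
})

test_that("beat statistics derive the missing quantity", {
  m1 <- AcquisitionMeta(frameTime = 50, meanBeatDuration = 1000,
                        acceptedBeats = 90, rejectedBeats = 10, nFrames = 16L)
  b1 <- beatStatistics(m1)
  expect_equal(b1$heart_rate, 60)
  expect_equal(b1$rejected_fraction, 0.10)
  m2 <- AcquisitionMeta(heartRate = 75, nFrames = 16L)
  expect_equal(beatStatistics(m2)$mean_beat_duration, 800)
  expect_true(is.na(beatStatistics(m2)$rejected_fraction))
  m3 <- AcquisitionMeta(frameTime = 50, nFrames = 16L)
  expect_error(beatStatistics(m3), "absent")
})

test_that("computeAll is deterministic and scale-aware", {
  ph <- generatePhantom(phantomConfig(poisson = TRUE, rngSeed = 5L))
  p1 <- computeAll(ph$cine, phantomSeed)
  p2 <- computeAll(ph$cine, phantomSeed)
  expect_identical(parameterValues(p1), parameterValues(p2))

  # scaling counts leaves every intensity-invariant parameter unchanged
  scaled <- GatedCine(frames(ph$cine) * 2, meta(ph$cine))
  p3 <- computeAll(scaled, phantomSeed)
  v1 <- parameterValues(p1); v3 <- parameterValues(p3)
  for (nm in c("lvef", "phase_lvef", "synchrony", "lhr"))
    expect_equal(v3[[nm]], v1[[nm]], tolerance = 0.02, info = nm)
  expect_equal(v3[["counts_ed"]], 2 * v1[["counts_ed"]], tolerance = 0.02)
  prov <- provenance(p1)
  expect_equal(prov$filter, "mmwf")
  expect_equal(prov$kernel, 5L)
})
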