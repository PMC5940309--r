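# Synthetic-data generators: reproducibility, photon bookkeeping,
# illumination-mode contrasts and side-view rendering.

test_that("generators are pure functions of spec and seed", {
  a <- makeBeadStack(beadScene(seed = 3))
  b <- makeBeadStack(beadScene(seed = 3))
  c <- makeBeadStack(beadScene(seed = 4))
  expect_identical(intensityValues(a$stack), intensityValues(b$stack))
  expect_identical(a$truth, b$truth)
  expect_false(identical(intensityValues(a$stack), intensityValues(c$stack)))
  m1 <- makeBleachMovie(nucleusScene(timePoints = 3, seed = 6))
  m2 <- makeBleachMovie(nucleusScene(timePoints = 3, seed = 6))
  expect_identical(intensityValues(m1$movie), intensityValues(m2$movie))
})

test_that("zero-noise bead voxels match independent numerical quadrature", {
  spec <- beadScene(nBeads = 1, readNoise = 0, shotNoise = FALSE, offset = 0,
                    seed = 2)
  res <- makeBeadStack(spec)
  b <- res$truth[1, ]
  v <- intensityValues(res$stack)
  px <- 0.1; dz <- 0.2
  # independent oracle: adaptive quadrature of the Gaussian over voxels
  gint <- function(lo, hi, c0, s) {
    stats::integrate(function(u) exp(-(u - c0)^2 / (2 * s^2)), lo, hi,
                     rel.tol = 1e-10)$value / (hi - lo)
  }
  iy <- round(b$y / px) + 1; ix <- round(b$x / px) + 1; iz <- round(b$z / dz) + 1
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 1), c(-1, -1, 2))) {
    yy <- iy + off[1]; xx <- ix + off[2]; zz <- iz + off[3]
    expected <- b$amplitude *
      gint((xx - 1.5) * px, (xx - 0.5) * px, b$x, b$sx) *
      gint((yy - 1.5) * px, (yy - 0.5) * px, b$y, b$sy) *
      gint((zz - 1.5) * dz, (zz - 0.5) * dz, b$z, b$sz)
    expect_equal(v[yy, xx, zz], expected, tolerance = 1e-6)
  }
  # beads outside the acquired volume are rejected
  bad <- beadScene(nBeads = 1, seed = 2)
  bad@geometry$beads$z <- 100
  expect_error(makeBeadStack(bad), "outside")
})

test_that("photon bookkeeping: monotone depletion, conservation at zero rate", {
  dec <- makeBleachMovie(nucleusScene(mode = "sheet", timePoints = 10,
                                      seed = 4, readNoise = 0,
                                      shotNoise = FALSE))
  expect_true(all(diff(dec$truth$totalFluorophore) < 0))
  flat <- makeBleachMovie(nucleusScene(mode = "epi", bleachRate = 0,
                                       timePoints = 10, seed = 4,
                                       readNoise = 0, shotNoise = FALSE))
  expect_equal(diff(flat$truth$totalFluorophore), rep(0, 9), tolerance = 1e-9)
  expect_error(makeBleachMovie(nucleusScene(timePoints = 3, exposure = 0,
                                            seed = 1)), "exposure")
})

test_that("sheet illumination outlasts epi at matched initial signal", {
  mk <- function(mode) {
    res <- makeBleachMovie(nucleusScene(mode = mode, timePoints = 30,
                                        seed = 3))
    movie <- subtractOffset(res$movie)
    rois <- defaultRoiMasks(movie)
    list(trace = bleachTrace(movie, rois$signal, rois$background),
         dose = res$doseRate)
  }
  epi <- mk("epi"); sheet <- mk("sheet")
  # matched initial in-focus integrated density (within noise)
  expect_equal(epi$trace@rawIntegratedDensity[1] /
                 sheet$trace@rawIntegratedDensity[1], 1, tolerance = 0.05)
  f50e <- framesToFraction(epi$trace, 0.5)
  f50s <- framesToFraction(sheet$trace, 0.5)
  expect_false(f50e$censored)
  expect_gt(f50s$frames, f50e$frames)
  # every threshold of the summary preserves the ordering
  se <- framesTo(bleachSummary(epi$trace))
  ss <- framesTo(bleachSummary(sheet$trace))
  expect_true(all(ss >= se))
  # measured bleaching-rate ratio tracks the analytic dose ratio
  rateRatio <- fitBleachRate(epi$trace)$rate / fitBleachRate(sheet$trace)$rate
  expect_equal(rateRatio / (epi$dose / sheet$dose), 1, tolerance = 0.1)
})

test_that("doubling the exposure halves frames-to-50% within one time point", {
  mk <- function(expo) {
    res <- makeBleachMovie(nucleusScene(mode = "epi", exposure = expo,
                                        timePoints = 40, seed = 9,
                                        readNoise = 0, shotNoise = FALSE))
    movie <- subtractOffset(res$movie)
    rois <- defaultRoiMasks(movie)
    framesToFraction(bleachTrace(movie, rois$signal, rois$background,
                                 frameExposure = expo), 0.5)$frames
  }
  f1 <- mk(0.1); f2 <- mk(0.2)
  expect_lte(abs(f1 - 2 * f2), 41)
})

test_that("SBR decays monotonically toward its floor under bleaching", {
  res <- makeBleachMovie(nucleusScene(mode = "epi", timePoints = 40, seed = 2,
                                      readNoise = 0, shotNoise = FALSE))
  movie <- subtractOffset(res$movie)
  rois <- defaultRoiMasks(movie)
  tr <- bleachTrace(movie, rois$signal, rois$background)
  expect_true(all(diff(tr@sbr) < 0))
  expect_true(all(tr@sbr >= 1))
  expect_lt(tr@sbr[40] / tr@sbr[1], 0.25)
})

test_that("side views round-trip through measurement", {
  mask <- defaultMask()
  map <- propagate(mask, 0.488)
  src <- measureSheet(map)
  # noiseless pass-through reproduces the source metrics
  quiet <- makeSheetSideView(map, background = 0, peakCounts = 1,
                             readNoise = 0, shotNoise = FALSE)
  mq <- measureSheet(sideViewToMap(quiet, map, background = 0))
  expect_equal(mq@fwhmFocus, src@fwhmFocus, tolerance = 5e-3)
  expect_equal(mq@sheetLength, src@sheetLength, tolerance = 5e-3)
  # seeded noisy view at peak SNR 20 recovers the design width
  noisy <- makeSheetSideView(map, background = 10, peakCounts = 400,
                             readNoise = 2, seed = 11)
  mn <- measureSheet(sideViewToMap(noisy, map, background = 10))
  expect_equal(mn@fwhmFocus, 4.3, tolerance = 0.2 / 4.3)
  # identical seeds give identical images
  expect_identical(noisy, makeSheetSideView(map, background = 10,
                                            peakCounts = 400, readNoise = 2,
                                            seed = 11))
  # background-only input fails cleanly
  blank <- matrix(10, nrow(intensityValues(map)), ncol(intensityValues(map)))
  expect_error(sideViewToMap(blank, map, background = 10), "background-only")
})
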