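# Bead PSF fitting, SBR, photobleaching traces and kymographs.

test_that("noiseless synthetic beads are recovered at the analytic FWHM", {
  spec <- beadScene(nBeads = 1, readNoise = 0, shotNoise = FALSE, seed = 2)
  res <- makeBeadStack(spec)
  stack <- subtractOffset(res$stack)
  seeds <- detectBeads(stack, 0.5)
  expect_equal(nrow(seeds), 1)
  fit <- fitBead(stack, seeds[1, ])
  expect_equal(unname(fit@fwhm), c(0.212, 0.212, 0.565), tolerance = 0.01)
  # the FWHM/sigma constant is exact by construction
  expect_equal(fit@fwhm / fit@sigma, rep(2 * sqrt(2 * log(2)), 3))
  # fitted centre matches the planted bead
  expect_equal(fit@center[["x"]], res$truth$x[1], tolerance = 0.02)
  expect_equal(fit@depth, res$truth$z[1], tolerance = 0.05)
})

test_that("12 noisy beads at SNR 20 are detected and recovered within 2%", {
  fx <- beadFixture()
  expect_equal(nrow(fx$seeds), 12)
  # seeds sit within one voxel of a planted bead
  vs <- c(0.1, 0.1, 0.2)
  for (i in seq_len(nrow(fx$seeds))) {
    pos <- (fx$seeds[i, c("x", "y", "z")] - 1) * vs
    dmin <- min(sqrt((fx$truth$x - pos[1])^2 + (fx$truth$y - pos[2])^2 +
                       (fx$truth$z - pos[3])^2))
    expect_lt(dmin, sqrt(sum(vs^2)))
  }
  tab <- beadTable(fx$fits)
  expect_equal(nrow(tab), 12)
  meanSigma <- colMeans(tab[c("fwhm_x", "fwhm_y", "fwhm_z")]) /
    (2 * sqrt(2 * log(2)))
  expect_equal(unname(meanSigma), c(0.09, 0.09, 0.24), tolerance = 0.02)
})

test_that("bead detection is deterministic and silent on blank noise", {
  fx <- beadFixture()
  s2 <- detectBeads(fx$stack, 0.3)
  expect_identical(fx$seeds, s2)
  blank <- ImageStack(array(abs(rnorm(20 * 20 * 10, 0, 1)), c(20, 20, 10)),
                      c(x = 0.1, y = 0.1, z = 0.2), offsetSubtracted = TRUE)
  expect_equal(nrow(detectBeads(blank, 0.5)), 0)
})

test_that("clipped beads and flat windows are rejected", {
  fx <- beadFixture()
  expect_error(fitBead(fx$stack, c(2L, 2L, 2L)), "clipped")
})

test_that("FWHM comparison behaves like a Welch t-test with SEM reporting", {
  g <- lapply(1:12, function(i) syntheticBeadFit(c(0.09, 0.09, 0.24)))
  same <- compareFWHM(g, g, "x")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  # two draws from one distribution: non-significant in >= 90% of reps
  set.seed(99)
  nonsig <- 0
  for (r in 1:20) {
    a <- lapply(rnorm(12, 0.09, 0.005), function(s)
      syntheticBeadFit(c(s, 0.09, 0.24)))
    b <- lapply(rnorm(12, 0.09, 0.005), function(s)
      syntheticBeadFit(c(s, 0.09, 0.24)))
    if (!compareFWHM(a, b, "x")$significant) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 18)
  # a 5-SD shift is detected decisively
  set.seed(100)
  a <- lapply(rnorm(12, 0.09, 0.005), function(s)
    syntheticBeadFit(c(s, 0.09, 0.24)))
  b <- lapply(rnorm(12, 0.115, 0.005), function(s)
    syntheticBeadFit(c(s, 0.09, 0.24)))
  shifted <- compareFWHM(a, b, "x")
  expect_lt(shifted$p, 0.001)
  expect_error(compareFWHM(a[1], b, "x"), "two beads")
})

test_that("stacks with identical PSF but different illumination labels agree", {
  fitsFor <- function(seed) {
    res <- makeBeadStack(beadScene(seed = seed))
    st <- subtractOffset(res$stack)
    seeds <- detectBeads(st, 0.3)
    suppressWarnings(lapply(seq_len(nrow(seeds)),
                            function(i) fitBead(st, seeds[i, ])))
  }
  sheetGrp <- beadFixture()$fits
  epiGrp <- fitsFor(8)
  for (ax in c("x", "y", "z")) {
    cmp <- compareFWHM(sheetGrp, epiGrp, ax)
    expect_gt(cmp$p, 0.05)
  }
})

test_that("SBR has a floor of one and scales with the signal mean", {
  img <- matrix(50, 10, 10)
  sig <- matrix(FALSE, 10, 10); sig[4:6, 4:6] <- TRUE
  expect_equal(sbr(img, sig, !sig), 1)
  img2 <- img; img2[sig] <- 200
  expect_equal(sbr(img2, sig, !sig), 4)
  expect_error(sbr(img, sig, sig), "disjoint")
  expect_error(sbr(matrix(0, 5, 5), matrix(c(TRUE, rep(FALSE, 24)), 5),
                   matrix(c(FALSE, TRUE, rep(FALSE, 23)), 5)), "zero")
})

test_that("bleach traces count every z-plane exposure and track decay", {
  # the reference protocol: 0.5-um steps over 20 um = 41 planes per point
  spec <- nucleusScene(mode = "epi", timePoints = 12, seed = 5,
                       readNoise = 0, shotNoise = FALSE)
  res <- makeBleachMovie(spec)
  movie <- subtractOffset(res$movie)
  expect_equal(dim(intensityValues(movie))[3], 41)
  rois <- defaultRoiMasks(movie)
  tr <- bleachTrace(movie, rois$signal, rois$background)
  expect_equal(tr@frames, seq_len(12) * 41)
  # constant movie gives a flat trace
  spec0 <- nucleusScene(mode = "epi", bleachRate = 0, timePoints = 6,
                        seed = 5, readNoise = 0, shotNoise = FALSE)
  res0 <- makeBleachMovie(spec0)
  movie0 <- subtractOffset(res0$movie)
  rois0 <- defaultRoiMasks(movie0)
  tr0 <- bleachTrace(movie0, rois0$signal, rois0$background)
  expect_equal(diff(tr0@rawIntegratedDensity), rep(0, 5), tolerance = 1e-9)
  # noiseless decay: fitted rate within 5% of the generator constant
  rate <- fitBleachRate(tr)$rate
  expect_equal(rate, spec@photophysics$bleachRate, tolerance = 0.05)
  expect_error(bleachTrace(movie, rois$signal[1:5, 1:5], rois$background),
               "dimensions")
})

test_that("frames-to-fraction matches the exponential closed form", {
  # 20 random (tau, dt) pairs against 41 * ceil(tau * ln(1/f) / dt)
  set.seed(7)
  for (r in 1:20) {
    tau <- runif(1, 5, 200)
    dt <- runif(1, 1, 15)
    tr <- analyticTrace(tau, dt, 400)
    for (f in c(0.9, 0.8, 0.7, 0.6, 0.5)) {
      expect_equal(framesToFraction(tr, f)$frames,
                   41 * ceiling(tau * log(1 / f) / dt))
    }
  }
  tr <- analyticTrace(50, 10, 30)
  expect_equal(framesToFraction(tr, 1.0)$frames, 0)
  # monotone: counts nonincreasing as the fraction rises
  s <- bleachSummary(tr)
  expect_true(all(diff(framesTo(s)) >= 0))  # ordered 90 -> 50
  expect_false(any(s@censored))
  # censoring when the trace never crosses
  short <- analyticTrace(1e6, 1, 5)
  r <- framesToFraction(short, 0.5)
  expect_true(r$censored)
  expect_equal(r$frames, max(short@frames))
})

test_that("kymographs map static and moving spots to the expected stripes", {
  nt <- 15
  mov <- array(0, c(32, 32, nt))
  for (t in seq_len(nt)) mov[16, 10, t] <- 100          # static spot
  st <- ImageStack(mov, c(x = 1, y = 1, z = 1), offsetSubtracted = TRUE)
  k <- kymograph(st, rbind(c(2, 16), c(30, 16)), width = 3)
  expect_equal(nrow(k), nt)
  hits <- apply(k, 1, which.max)
  expect_equal(diff(hits), rep(0, nt - 1))              # vertical stripe
  mov2 <- array(0, c(32, 32, nt))
  for (t in seq_len(nt)) mov2[16, 8 + t, t] <- 100      # 1 px/frame
  st2 <- ImageStack(mov2, c(x = 1, y = 1, z = 1), offsetSubtracted = TRUE)
  k2 <- kymograph(st2, rbind(c(2, 16), c(30, 16)), width = 3)
  hits2 <- apply(k2, 1, which.max)
  expect_equal(diff(hits2), rep(1, nt - 1))             # 45-degree stripe
  expect_error(kymograph(st, rbind(c(5, 5), c(5, 5))), "degenerate")
})
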