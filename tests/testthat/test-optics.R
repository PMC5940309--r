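# Closed-form design chain: widths, lengths, angles, objective quantities.

test_that("sheet width matches the reference design values and scales inversely", {
  # NA_eff for the 4.3-um sheet, from inverting the tilt relation at 2.4379 deg
  expect_equal(sheetWidth(0.042533, 0.488), 4.300, tolerance = 1e-4)
  # inverse of the 5.0-deg tilt example, checked by root-finding when frozen
  expect_equal(sheetWidth(0.087092, 0.488), 2.100, tolerance = 1e-4)
  # halving/doubling NA_eff scales w by 2x/0.5x
  expect_equal(sheetWidth(0.02, 0.488) / sheetWidth(0.04, 0.488), 2)
  # strictly decreasing in naEff
  na <- seq(0.01, 0.9, length.out = 50)
  expect_true(all(diff(sheetWidth(na, 0.488)) < 0))
  expect_error(sheetWidth(0, 0.488), "in-air")
  expect_error(sheetWidth(1.2, 0.488), "in-air")
})

test_that("Gaussian length is quadratic in width", {
  expect_equal(gaussianLength(4.3, 0.488), pi * 4.3^2 / (2 * 0.488))
  expect_equal(gaussianLength(4.3, 0.488), 59.52, tolerance = 1e-3)
  expect_equal(gaussianLength(2, 0.5) / gaussianLength(1, 0.5), 4)
  expect_equal(gaussianLength(1, 0.5), pi)
  expect_error(gaussianLength(-1, 0.5), "> 0")
})

test_that("elongated length from mask geometry follows the inverse-square law", {
  expect_equal(elongatedLengthFromMask(40, 1.7006, 0.488), 270, tolerance = 1e-3)
  expect_equal(elongatedLengthFromMask(40, 3.514, 0.488), 63.23, tolerance = 1e-3)
  expect_equal(elongatedLengthFromMask(40, 1, 0.5) /
                 elongatedLengthFromMask(40, 2, 0.5), 4)
  expect_error(elongatedLengthFromMask(40, 45, 0.488), "paraxial")
})

test_that("elongated length from width reproduces the published design points", {
  expect_equal(elongatedLengthFromWidth(4.3, 0.488), 269.3, tolerance = 1e-3)
  expect_equal(signif(elongatedLengthFromWidth(4.3, 0.488), 2), 270)
  expect_equal(elongatedLengthFromWidth(2.1, 0.488), 63.85, tolerance = 1e-3)
  expect_error(elongatedLengthFromWidth(0.1, 0.488), "must exceed")
})

test_that("field of view divides the field number and accepts manual overrides", {
  expect_equal(fieldOfView(22000, 60), 366.7, tolerance = 1e-3)
  expect_equal(fieldOfView(12345, 1), 12345)
  d <- designForObjective(oil60, gfp, fovOverride = 150)
  expect_equal(d$vov@fov, 150)
  expect_error(designForObjective(oil60, gfp, fovOverride = 500),
               "exceeds the objective's full FOV")
})

test_that("depth of field and lateral resolution match the objective comparison", {
  expect_equal(depthOfField(1.49, 0.515, 1.52), 0.568, tolerance = 1e-3)
  expect_equal(depthOfField(1.1, 0.515, 1.33), 0.911, tolerance = 1e-3)
  expect_equal(depthOfField(0.5, 0.5, 1.0) / depthOfField(1.0, 0.5, 1.33) *
                 1.33, 4, tolerance = 1e-12)
  expect_error(depthOfField(1.6, 0.515, 1.52), "< nIm")
  expect_equal(lateralResolution(1.49, 0.515), 0.211, tolerance = 1e-3)
  expect_equal(lateralResolution(1.1, 0.515), 0.286, tolerance = 2e-3)
  # the high-NA oil lens offers a 26% lateral-resolution gain over the
  # 1.1-NA water-dipping lens
  expect_equal(100 * (1 - 1.1 / 1.49), 26.2, tolerance = 1e-2)
  expect_equal(100 * (1 - lateralResolution(1.49, 0.515) /
                        lateralResolution(1.1, 0.515)), 26.2, tolerance = 1e-2)
})

test_that("tilt angle reproduces the published angles and decreases with width", {
  expect_equal(tiltAngle(4.3, 0.488), 2.44, tolerance = 1e-2)
  expect_equal(signif(tiltAngle(4.3, 0.488), 2), 2.4)
  expect_equal(tiltAngle(2.1, 0.488), 5.00, tolerance = 1e-3)
  w <- seq(1, 100, length.out = 200)
  th <- tiltAngle(w, 0.488)
  expect_true(all(diff(th) < 0))
  expect_lt(tiltAngle(1e5, 0.488), 1e-3)
  expect_error(tiltAngle(0.1, 0.488), "must exceed")
})

test_that("width/angle round trip and length/angle identity hold to 1e-9", {
  a <- exp(seq(log(0.001), log(0.9), length.out = 40))
  back <- sin(tiltAngle(sheetWidth(a, 0.51), 0.51) * pi / 180)
  expect_equal(back, a, tolerance = 1e-9)
  w <- exp(seq(log(0.5), log(300), length.out = 60))
  lp <- elongatedLengthFromWidth(w, 0.488)
  th <- tiltAngle(w, 0.488) * pi / 180
  expect_equal(lp * tan(th)^2 / 0.488, rep(1, length(w)), tolerance = 1e-9)
})

test_that("the elongation ratio approaches pi/ln2 in the small-angle limit", {
  w <- seq(2, 50, length.out = 30)
  ratio <- elongatedLengthFromWidth(w, 0.488) / gaussianLength(w, 0.488)
  expect_equal(ratio, rep(pi / log(2), length(w)), tolerance = 5e-3)
  expect_equal(pi / log(2), 4.5324, tolerance = 1e-4)
})

test_that("optimal width beats the DOF across a 1000-point parameter sweep", {
  set.seed(42)
  fov <- runif(1000, 50, 600)
  dof <- runif(1000, 0.2, 10)
  lam <- runif(1000, 0.38, 0.6)
  w <- optimalSheetWidth(fov, dof, lam)
  expect_true(all(w > dof))
  # monotone nondecreasing in fov and lambda
  fovs <- seq(50, 600, length.out = 100)
  expect_true(all(diff(optimalSheetWidth(fovs, 1, 0.488)) >= 0))
  lams <- seq(0.38, 0.6, length.out = 100)
  expect_true(all(diff(optimalSheetWidth(150, 1, lams)) >= 0))
  # short-wavelength limit: w falls toward the DOF-governed floor
  lamSmall <- 10^seq(-1, -6, length.out = 12)
  wLim <- optimalSheetWidth(150, 2, lamSmall)
  expect_true(all(diff(wLim) < 0))
  expect_equal(wLim[12], 2, tolerance = 1e-3)
})

test_that("equation evaluations are pure", {
  expect_identical(tiltAngle(4.3, 0.488), tiltAngle(4.3, 0.488))
  expect_identical(optimalSheetWidth(150, 0.6, 0.488),
                   optimalSheetWidth(150, 0.6, 0.488))
})

test_that("the full design chain is internally consistent and deterministic", {
  d1 <- designForObjective(oil60, gfp, f = 40, fovOverride = 150)
  d2 <- designForObjective(oil60, gfp, f = 40, fovOverride = 150)
  expect_identical(d1, d2)
  s <- d1$spec
  # pairwise identities among w, theta, L'
  expect_equal(s@theta, tiltAngle(s@w, s@lambdaEx), tolerance = 1e-12)
  expect_equal(s@lPrime, elongatedLengthFromWidth(s@w, s@lambdaEx),
               tolerance = 1e-12)
  expect_equal(s@lPrime * tan(s@theta * pi / 180)^2, s@lambdaEx,
               tolerance = 1e-9)
  # the sheet covers the field
  expect_gte(s@lPrime, d1$vov@fov)
  # the mask radius reproduces the length through the mask relation
  expect_equal(elongatedLengthFromMask(40, d1$r1, s@lambdaEx), s@lPrime,
               tolerance = 1e-9)
  # volume-of-view sanity for a high-NA lens
  expect_gt(d1$vov@fov / d1$vov@dof, 10)
})

test_that("catalog scans cover 90 objectives with w > DOF throughout", {
  cat90 <- syntheticObjectiveCatalog(90)
  tab <- catalogScan(cat90, gfp)
  expect_equal(nrow(tab), 90)
  ok <- tab$note == ""
  expect_true(all(ok))
  expect_true(all(tab$w > tab$dof))
  expect_true(all(tab$fov / tab$dof > 10))
  # single-objective catalog agrees with the design chain
  one <- catalogScan(list(oil60), gfp)
  d <- designForObjective(oil60, gfp)
  expect_equal(one$w, d$spec@w)
  expect_equal(one$theta, d$spec@theta)
  expect_equal(one$l_prime, d$spec@lPrime)
  expect_error(catalogScan(list(), gfp), "empty")
})

test_that("scan trends mirror the published figure shapes", {
  cat90 <- syntheticObjectiveCatalog(90)
  tab <- catalogScan(cat90, gfp)
  tab <- tab[order(tab$na), ]
  # optimal width falls with NA (monotone trend, rank correlation)
  expect_lt(cor(rank(tab$na), rank(tab$w)), -0.9)
  # theta-vs-w traces decrease monotonically for all five preset fluorophores
  for (fl in fluorophorePresets()) {
    fovs <- seq(60, 500, length.out = 40)
    w <- optimalSheetWidth(fovs, 0.57, fl@lambdaEx)
    th <- tiltAngle(w, fl@lambdaEx)
    o <- order(w)
    expect_true(all(diff(th[o]) < 0))
  }
})

test_that("invalid objectives and fluorophores are rejected", {
  expect_error(Objective("bad", 60, 1.6, 22000, 1.52, "oil"), "na")
  expect_error(Objective("bad", -1, 1.4, 22000, 1.52, "oil"), "magnification")
  expect_error(Fluorophore("bad", 0.515, 0.488), "Stokes")
})
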