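# Shared fixtures. Everything is generated in code; nothing is read from
# disk. The default calibrated mask is cached by the package for the
# session, so repeated calls are cheap.

gfp <- fluorophorePresets()$GFP
oil60 <- Objective("60x/1.49-oil", 60, 1.49, 22000, 1.52, "oil")
water25 <- Objective("25x/1.1-water", 25, 1.1, 22000, 1.33, "water")

# 12-bead reference stack at peak SNR 20 (generated once per test run)
beadFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- makeBeadStack(beadScene(seed = 7))
      stack <- subtractOffset(res$stack)
      seeds <- detectBeads(stack, 0.3)
      fits <- suppressWarnings(
        lapply(seq_len(nrow(seeds)), function(i) fitBead(stack, seeds[i, ])))
      cache <<- list(stack = stack, truth = res$truth, seeds = seeds,
                     fits = fits)
    }
    cache
  }
})

# build a BeadFit directly from per-axis sigmas (for statistics tests that
# do not need image rendering)
syntheticBeadFit <- function(sigma) {
  new("BeadFit", center = c(x = 0, y = 0, z = 0), sigma = sigma,
      fwhm = 2 * sqrt(2 * log(2)) * sigma, amplitude = rep(400, 3),
      baseline = rep(0, 3), depth = 0, rss = 0)
}

# analytic single-exponential BleachTrace: points at t = 0, dt, 2 dt, ...
# so the first time point is the 100% reference
analyticTrace <- function(tau, dtPoint, nPoints, framesPerPoint = 41,
                          exposure = 0.1) {
  i <- 0:nPoints
  new("BleachTrace", frames = i * framesPerPoint,
      rawIntegratedDensity = exp(-i * dtPoint / tau),
      sbr = rep(1, nPoints + 1), frameExposure = exposure)
}
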