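## Seeded synthetic-data generators: sub-diffraction bead stacks, nuclear
## photobleaching movies under epi or sheet illumination, and noisy sheet
## side views. Every generator is a pure function of (spec, seed): identical
## specs give bit-identical output.
##
## Detector model: Poisson shot noise on the expected photon count, additive
## Gaussian read noise, constant camera offset (recorded in the stack so
## downstream subtraction is exact). Bleaching is first-order in local
## excitation dose (single species, no dark-state recovery), emulating an
## ATP-arrested sample; an optional linear fluorophore-production term
## explores turnover compensation and is off by default.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Bead-stack scene specification
#'
#' Convenience constructor for a \linkS4class{SceneSpec} describing
#' sub-diffraction beads in gel: bead positions are drawn once (from the
#' seed) inside the volume with a safety margin, rendered with the given
#' image-space sigmas. The default emulates a 12-bead field at peak
#' signal-to-noise 20 under a high-NA detection lens (0.1-um pixels,
#' 0.2-um z-steps).
#'
#' @param nBeads number of beads.
#' @param sigma image-space Gaussian sigma c(x, y, z), um.
#' @param snr peak signal-to-noise ratio; the Poisson-limited peak amplitude
#'   is \code{snr^2} counts.
#' @param frameSize pixels c(y, x).
#' @param pixelSize xy pixel size, um.
#' @param zStep z-step, um.
#' @param zRange z-range, um.
#' @param offset camera offset, counts.
#' @param readNoise Gaussian read noise sd, counts.
#' @param shotNoise apply Poisson noise?
#' @param seed RNG seed.
#' @return A \linkS4class{SceneSpec}.
#' @export
beadScene <- function(nBeads = 12, sigma = c(0.09, 0.09, 0.24), snr = 20,
                      frameSize = c(96, 96), pixelSize = 0.1,
                      zStep = 0.2, zRange = 8, offset = 100,
                      readNoise = 2, shotNoise = TRUE, seed = 1) {
  amp <- snr^2
  nz <- round(zRange / zStep) + 1L
  ext <- c(x = frameSize[2] * pixelSize, y = frameSize[1] * pixelSize,
           z = (nz - 1) * zStep)
  # keep beads clear of the edges by a full fit window (1.5 um half-width)
  margin <- 4 * sigma + c(1.7, 1.7, 1.8)
  # jittered grid placement keeps every pair at least ~3 FWHM apart, as in
  # a well-dispersed bead mount
  ngx <- ceiling(sqrt(nBeads)); ngy <- ceiling(nBeads / ngx)
  cellx <- (ext[["x"]] - 2 * margin[1]) / ngx
  celly <- (ext[["y"]] - 2 * margin[2]) / ngy
  idx <- seq_len(nBeads) - 1L
  beads <- withSeed(seed, {
    data.frame(
      x = margin[1] + ((idx %% ngx) + 0.5) * cellx +
        stats::runif(nBeads, -0.2, 0.2) * cellx,
      y = margin[2] + ((idx %/% ngx) + 0.5) * celly +
        stats::runif(nBeads, -0.2, 0.2) * celly,
      z = stats::runif(nBeads, margin[3], ext[["z"]] - margin[3]),
      sx = sigma[1], sy = sigma[2], sz = sigma[3], amplitude = amp)
  })
  new("SceneSpec",
      geometry = list(kind = "beads", beads = beads),
      photophysics = list(bleachRate = 0, production = 0),
      illumination = list(mode = "epi", sheetFWHM = NA_real_, tiltTheta = 0),
      detector = list(gain = 1, offset = offset, readNoise = readNoise,
                      shotNoise = shotNoise),
      acquisition = list(zStep = zStep, zRange = zRange, exposure = 0.1,
                         timePoints = 1L, frameSize = as.integer(frameSize),
                         pixelSize = pixelSize),
      seed = seed)
}

#' Nucleus bleaching-movie scene specification
#'
#' A \linkS4class{SceneSpec} for a photobleaching time lapse of fluorescent
#' nuclei. The acquisition defaults follow the reference protocol: 100-ms
#' frame exposure, 0.5-um z-step over a 20-um range (41 planes per time
#' point), no delay between time points. Illumination is either uniform
#' over the whole z-extent ("epi") or a Gaussian z-profile of FWHM
#' \code{sheetFWHM} centred on the plane being acquired ("sheet"),
#' optionally sheared across x by \code{tiltTheta}.
#'
#' @param mode \code{"epi"} or \code{"sheet"}.
#' @param sheetFWHM sheet FWHM, um (sheet mode).
#' @param tiltTheta sheet tilt, degrees (shear of the sheet centre across x).
#' @param nNuclei number of nuclei.
#' @param bleachRate first-order bleach rate per unit excitation dose
#'   (intensity x seconds).
#' @param production linear fluorophore production per second (speculative
#'   turnover term; 0 = arrested sample).
#' @param timePoints number of time points.
#' @param frameSize pixels c(y, x).
#' @param pixelSize xy pixel size, um.
#' @param zStep,zRange,exposure acquisition protocol (um, um, s).
#' @param offset,readNoise,shotNoise detector model.
#' @param background constant out-of-focus/autofluorescence background
#'   added to the expected signal, counts.
#' @param seed RNG seed.
#' @return A \linkS4class{SceneSpec}.
#' @export
nucleusScene <- function(mode = c("sheet", "epi"), sheetFWHM = 4.3,
                         tiltTheta = 2.4, nNuclei = 2, bleachRate = 0.017,
                         production = 0, timePoints = 30L,
                         frameSize = c(48, 48), pixelSize = 0.4,
                         zStep = 0.5, zRange = 20, exposure = 0.1,
                         offset = 100, readNoise = 2, shotNoise = TRUE,
                         background = 20, seed = 1) {
  mode <- match.arg(mode)
  nz <- round(zRange / zStep) + 1L
  ext <- c(x = frameSize[2] * pixelSize, y = frameSize[1] * pixelSize,
           z = (nz - 1) * zStep)
  nuclei <- withSeed(seed, {
    data.frame(
      x = stats::runif(nNuclei, 0.3 * ext[["x"]], 0.7 * ext[["x"]]),
      y = stats::runif(nNuclei, 0.3 * ext[["y"]], 0.7 * ext[["y"]]),
      z = stats::runif(nNuclei, 0.35 * ext[["z"]], 0.65 * ext[["z"]]),
      rx = 2.5, ry = 2.5, rz = 2.5, density = 400)
  })
  new("SceneSpec",
      geometry = list(kind = "nuclei", nuclei = nuclei),
      photophysics = list(bleachRate = bleachRate, production = production),
      illumination = list(mode = mode, sheetFWHM = sheetFWHM,
                          tiltTheta = tiltTheta),
      detector = list(gain = 1, offset = offset, readNoise = readNoise,
                      shotNoise = shotNoise, background = background),
      acquisition = list(zStep = zStep, zRange = zRange, exposure = exposure,
                         timePoints = as.integer(timePoints),
                         frameSize = as.integer(frameSize),
                         pixelSize = pixelSize),
      seed = seed)
}

# mean of a 1D Gaussian over voxel [lo, hi] with centre c, sd s, peak 1
voxelGauss <- function(lo, hi, c, s) {
  s * sqrt(2 * pi) * (stats::pnorm((hi - c) / s) - stats::pnorm((lo - c) / s)) /
    (hi - lo)
}

applyDetector <- function(expected, det) {
  noisy <- if (isTRUE(det$shotNoise))
    array(stats::rpois(length(expected), lambda = pmax(expected, 0)),
          dim = dim(expected))
  else expected
  if (det$readNoise > 0)
    noisy <- noisy + array(stats::rnorm(length(expected), 0, det$readNoise),
                           dim = dim(expected))
  noisy * det$gain + det$offset
}

#' Generate a synthetic bead stack
#'
#' Renders each bead as a 3D Gaussian analytically integrated over voxels
#' (separable error-function products), applies shot and read noise and the
#' camera offset, and returns the stack together with the ground-truth bead
#' table. Same spec, same stack, bit for bit.
#'
#' @param spec a \linkS4class{SceneSpec} from \code{\link{beadScene}}.
#' @return list with \code{stack} (an \linkS4class{ImageStack}) and
#'   \code{truth} (data.frame of centres, sigmas, amplitudes).
#' @export
makeBeadStack <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  if (!identical(spec@geometry$kind, "beads"))
    stop("spec does not describe a bead scene")
  acq <- spec@acquisition
  nz <- round(acq$zRange / acq$zStep) + 1L
  ny <- acq$frameSize[1]; nx <- acq$frameSize[2]
  px <- acq$pixelSize; dz <- acq$zStep
  beads <- spec@geometry$beads
  ext <- c(x = nx * px, y = ny * px, z = (nz - 1) * dz)
  if (any(beads$x < 0 | beads$x > ext[["x"]] | beads$y < 0 |
          beads$y > ext[["y"]] | beads$z < 0 | beads$z > ext[["z"]]))
    stop("bead outside the acquired volume")
  xs <- (seq_len(nx) - 1) * px; ys <- (seq_len(ny) - 1) * px
  zs <- (seq_len(nz) - 1) * dz
  expected <- array(0, dim = c(ny, nx, nz))
  for (i in seq_len(nrow(beads))) {
    b <- beads[i, ]
    gx <- voxelGauss(xs - px / 2, xs + px / 2, b$x, b$sx)
    gy <- voxelGauss(ys - px / 2, ys + px / 2, b$y, b$sy)
    gz <- voxelGauss(zs - dz / 2, zs + dz / 2, b$z, b$sz)
    expected <- expected + b$amplitude * outer(outer(gy, gx), gz)
  }
  vals <- withSeed(spec@seed + 1L, applyDetector(expected, spec@detector))
  stack <- ImageStack(vals, c(x = px, y = px, z = dz),
                      cameraOffset = spec@detector$offset,
                      offsetSubtracted = FALSE)
  list(stack = stack, truth = beads)
}

#' Generate a synthetic photobleaching movie
#'
#' Evolves a fluorophore field over ellipsoidal nuclei under the chosen
#' illumination: each z-plane exposure deposits dose
#' \code{I_exc(z) * exposure} everywhere (uniform for "epi", a Gaussian
#' z-profile centred on the acquired plane for "sheet", optionally sheared
#' across x by the tilt angle), depleting the field as
#' \code{dF = -bleachRate * I_exc * F * dt}. The detected image of a plane
#' is the fluorophore content of its 1-z-step slab. Detection is scaled per
#' mode so both start from the same initial in-focus integrated density.
#'
#' @param spec a \linkS4class{SceneSpec} from \code{\link{nucleusScene}}.
#' @return list with \code{movie} (4D \linkS4class{ImageStack}),
#'   \code{truth} (data.frame: timePoint, frames, totalFluorophore) and
#'   \code{doseRate} (mean excitation dose per time point inside nuclei).
#' @export
makeBleachMovie <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  if (!identical(spec@geometry$kind, "nuclei"))
    stop("spec does not describe a nucleus scene")
  acq <- spec@acquisition
  il <- spec@illumination
  ph <- spec@photophysics
  if (acq$exposure <= 0) stop("exposure must be > 0")
  nuc <- spec@geometry$nuclei
  if (nrow(nuc) == 0L) stop("no nuclei in the scene")
  nz <- round(acq$zRange / acq$zStep) + 1L
  ny <- acq$frameSize[1]; nx <- acq$frameSize[2]
  px <- acq$pixelSize; dz <- acq$zStep; dt <- acq$exposure
  nt <- acq$timePoints
  xs <- (seq_len(nx) - 1) * px; ys <- (seq_len(ny) - 1) * px
  zs <- (seq_len(nz) - 1) * dz
  # initial fluorophore field: ellipsoid indicator x density
  F0 <- array(0, dim = c(ny, nx, nz))
  inside <- array(FALSE, dim = c(ny, nx, nz))
  for (i in seq_len(nrow(nuc))) {
    n <- nuc[i, ]
    e <- outer(outer((ys - n$y)^2 / n$ry^2, (xs - n$x)^2 / n$rx^2, "+"),
               (zs - n$z)^2 / n$rz^2, "+")
    F0 <- F0 + n$density * (e <= 1)
    inside <- inside | (e <= 1)
  }
  k <- ph$bleachRate
  sheet <- identical(il$mode, "sheet")
  w <- il$sheetFWHM
  shear <- tan(deg2rad(il$tiltTheta %||% 0))
  # per-plane illumination profiles I_exc(y, x, z) collapsed to (x, z)
  zmat <- matrix(zs, nx, nz, byrow = TRUE)           # voxel z per (x, z)
  planeDose <- function(zj) {
    if (!sheet) return(matrix(1, nx, nz))
    ctr <- zj + shear * (xs - mean(xs))              # sheared sheet centre
    exp(-4 * log(2) * sweep(zmat, 1, ctr)^2 / w^2)
  }
  doses <- lapply(zs, planeDose)                     # fixed per plane index
  Ff <- F0
  frames <- numeric(nt); total <- numeric(nt)
  planesExpected <- array(0, dim = c(ny, nx, nz, nt))
  for (t in seq_len(nt)) {
    for (j in seq_len(nz)) {
      planesExpected[, , j, t] <- Ff[, , j]
      dj <- doses[[j]]
      if (k > 0) {
        decay <- exp(-k * dj * dt)                   # (x, z)
        Ff <- sweep(Ff, c(2, 3), decay, "*")
      }
      if (ph$production > 0) Ff <- Ff + ph$production * dt * inside
    }
    frames[t] <- t * nz
    total[t] <- sum(Ff)
  }
  # equalise initial in-focus integrated density across modes
  target <- 2e5
  scale <- target / sum(planesExpected[, , , 1])
  expected <- planesExpected * scale + (spec@detector$background %||% 0)
  vals <- withSeed(spec@seed + 2L, applyDetector(expected, spec@detector))
  movie <- ImageStack(vals, c(x = px, y = px, z = dz),
                      frameInterval = nz * dt,
                      cameraOffset = spec@detector$offset,
                      offsetSubtracted = FALSE)
  # mean dose per time point inside the nuclei (for rate-ratio checks)
  doseMean <- mean(vapply(seq_len(nz), function(j) mean(doses[[j]]), numeric(1))) * nz * dt
  list(movie = movie,
       truth = data.frame(timePoint = seq_len(nt), frames = frames,
                          totalFluorophore = total),
       doseRate = doseMean)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a noisy side view of a simulated sheet
#'
#' Scales an \linkS4class{IntensityMap} to detector counts, adds a constant
#' background and applies the detector noise model, emulating a camera view
#' of the sheet from the side through fluorescent medium.
#'
#' @param map an \linkS4class{IntensityMap}.
#' @param background constant background, counts.
#' @param peakCounts counts at the focal peak; at Poisson-limited peak SNR
#'   s use \code{s^2}.
#' @param readNoise Gaussian read noise sd, counts.
#' @param shotNoise apply Poisson noise?
#' @param seed RNG seed.
#' @return numeric matrix of counts, same shape as the map values.
#' @export
makeSheetSideView <- function(map, background = 10, peakCounts = 400,
                              readNoise = 2, shotNoise = TRUE, seed = 1) {
  stopifnot(is(map, "IntensityMap"))
  expected <- map@values * peakCounts + background
  det <- list(gain = 1, offset = 0, readNoise = readNoise,
              shotNoise = shotNoise)
  withSeed(seed, applyDetector(expected, det))
}

#' Wrap a measured side view back into an IntensityMap
#'
#' Background-subtracts a side-view image, clamps negatives, symmetrises in
#' x (the pattern of an even mask is even; averaging mirrored pixels halves
#' the noise without biasing widths) and renormalises, so
#' \code{\link{measureSheet}} can run on measured data.
#'
#' @param img counts matrix from \code{\link{makeSheetSideView}}.
#' @param map the source \linkS4class{IntensityMap} (grid and mask
#'   provenance).
#' @param background background to subtract, counts.
#' @return An \linkS4class{IntensityMap}.
#' @export
sideViewToMap <- function(img, map, background = 10) {
  stopifnot(is(map, "IntensityMap"))
  v <- pmax(img - background, 0)
  v <- (v + v[nrow(v):1, , drop = FALSE]) / 2
  # light moving-average smoothing along x: the kernel is ~100x narrower
  # than the central fringe, so widths are unbiased while the shot-noise
  # bias on the peak estimate (which sets the half-max level) is suppressed
  kern <- rep(1 / 7, 7)
  v <- apply(v, 2, function(col) stats::filter(col, kern, sides = 2))
  v[is.na(v)] <- 0
  if (max(v) <= 0) stop("background-only image: no sheet signal to measure")
  iz0 <- which.min(abs(map@grid@z))
  pk <- max(v[, iz0])
  if (pk <= 0) stop("no signal at the focal plane")
  new("IntensityMap", values = v / pk, grid = map@grid,
      lambdaEx = map@lambdaEx, mask = map@mask, rawPeak = pk)
}
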