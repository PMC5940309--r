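#' @import methods
NULL

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # Gaussian FWHM / sigma
SHEET_C <- sqrt(2 * log(2)) / pi    # w * NA_eff / lambda for a focused sheet

#' Fluorophore description
#'
#' Excitation/emission wavelength pair for a fluorescent label. Wavelengths
#' are vacuum wavelengths in micrometres; the Stokes shift must be positive.
#'
#' @slot name label, e.g. \code{"GFP"}.
#' @slot lambdaEx peak excitation wavelength, um.
#' @slot lambdaEm peak emission wavelength, um.
#' @export
setClass("Fluorophore",
  representation(name = "character", lambdaEx = "numeric", lambdaEm = "numeric"),
  validity = function(object) {
    if (length(object@lambdaEx) != 1L || length(object@lambdaEm) != 1L)
      return("lambdaEx and lambdaEm must be scalars")
    if (!(object@lambdaEx > 0.2 && object@lambdaEx < object@lambdaEm &&
          object@lambdaEm < 1.0))
      return("need 0.2 um < lambdaEx < lambdaEm < 1.0 um (positive Stokes shift)")
    TRUE
  })

#' Detection objective description
#'
#' Parameters of a detection objective lens that drive the sheet design
#' chain: magnification, numerical aperture, field number and the
#' coverslip-immersion refractive index.
#'
#' @slot id label.
#' @slot magnification lateral magnification (dimensionless, > 0).
#' @slot na numerical aperture, must satisfy 0 < na < nImmersion.
#' @slot fieldNumber field number, um.
#' @slot nImmersion coverslip-immersion medium refractive index.
#' @slot immersion one of \code{"air"}, \code{"water"}, \code{"oil"}.
#' @export
setClass("Objective",
  representation(id = "character", magnification = "numeric", na = "numeric",
                 fieldNumber = "numeric", nImmersion = "numeric",
                 immersion = "character"),
  validity = function(object) {
    if (!(object@magnification > 0)) return("magnification must be > 0")
    if (!(object@nImmersion >= 1.0 && object@nImmersion <= 1.6))
      return("nImmersion must lie in [1.0, 1.6]")
    if (!(object@na > 0 && object@na < object@nImmersion))
      return("need 0 < na < nImmersion")
    if (!(object@fieldNumber > 0)) return("fieldNumber must be > 0")
    if (!object@immersion %in% c("air", "water", "oil", "other"))
      return("immersion must be air/water/oil/other")
    TRUE
  })

#' Field and depth of view of an objective
#'
#' The 1D field-of-view diameter and depth of field, both in micrometres.
#'
#' @slot fov field-of-view diameter, um.
#' @slot dof depth of field, um.
#' @export
setClass("VolumeOfView",
  representation(fov = "numeric", dof = "numeric"),
  validity = function(object) {
    if (!(object@fov > 0 && object@dof > 0)) return("fov and dof must be > 0")
    TRUE
  })

#' Designed light-sheet geometry
#'
#' A fully designed tilted light sheet: its focal FWHM width, unmasked
#' Gaussian length, interference-elongated length, tilt half-angle and
#' effective illumination NA. The unfocused horizontal breadth \code{b} is
#' carried as metadata only and never computed.
#'
#' @slot w sheet FWHM at focus, um.
#' @slot lGauss unmasked Gaussian sheet length L, um.
#' @slot lPrime mask-elongated sheet length L', um.
#' @slot theta tilt half-angle, degrees.
#' @slot naEff effective illumination NA (in-air convention).
#' @slot lambdaEx excitation wavelength, um.
#' @slot breadth unfocused horizontal breadth b, um (may be NA).
#' @export
setClass("SheetSpec",
  representation(w = "numeric", lGauss = "numeric", lPrime = "numeric",
                 theta = "numeric", naEff = "numeric", lambdaEx = "numeric",
                 breadth = "numeric"),
  validity = function(object) {
    if (!(object@w > 0)) return("w must be > 0")
    if (!(object@theta > 0 && object@theta < 90))
      return("theta must lie in (0, 90) degrees")
    id <- object@lPrime * tan(object@theta * pi / 180)^2
    if (abs(id / object@lambdaEx - 1) > 1e-6)
      return("lPrime and theta are inconsistent: lPrime * tan(theta)^2 != lambdaEx")
    if (object@theta < 20 && !(object@lPrime > object@lGauss))
      return("elongation regime violated: lPrime <= lGauss at theta < 20 degrees")
    TRUE
  })

#' Quadruple-slit pupil mask
#'
#' Geometry of a four-slit photomask placed at the principal plane of a
#' cylindrical lens: two symmetric slit pairs centred at \code{pairRadii}
#' (mm from the optical axis) with widths \code{slitWidths} (mm). The
#' binary transmission is even by construction.
#'
#' @slot f cylindrical lens focal length, mm.
#' @slot pairRadii centre radii (inner, outer) of the slit pairs, mm.
#' @slot slitWidths slit widths (inner, outer), mm.
#' @export
setClass("SlitMask",
  representation(f = "numeric", pairRadii = "numeric", slitWidths = "numeric"),
  validity = function(object) {
    r <- object@pairRadii; w <- object@slitWidths
    if (length(r) != 2L || length(w) != 2L)
      return("pairRadii and slitWidths must each have length 2")
    if (!(object@f > 0)) return("f must be > 0")
    if (!(r[1] > 0 && r[2] > r[1])) return("need 0 < r_inner < r_outer")
    if (any(w <= 0)) return("slit widths must be > 0")
    if (r[1] - w[1] / 2 < 0) return("inner slit pair crosses the optical axis")
    if (r[2] - w[2] / 2 <= r[1] + w[1] / 2) return("slit pairs overlap")
    if (r[2] + w[2] / 2 >= object@f / 4)
      return("outermost slit edge exceeds f/4 (non-paraxial)")
    TRUE
  })

#' Simulation grid for the sheet cross-section
#'
#' Transverse (x, sheet-width axis) and axial (z, relative to the lens focal
#' plane) sample positions in micrometres. Both axes must be uniform and
#' x must be symmetric about 0 so that even masks give even patterns.
#'
#' @slot x transverse samples, um.
#' @slot z axial samples, um.
#' @export
setClass("FieldGrid",
  representation(x = "numeric", z = "numeric"),
  validity = function(object) {
    if (length(object@x) < 9L) return("x grid too small")
    dx <- diff(object@x)
    if (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1])) return("x grid must be uniform")
    if (max(abs(object@x + rev(object@x))) > 1e-9 * max(abs(object@x)))
      return("x grid must be symmetric about 0")
    if (length(object@z) > 1L) {
      dz <- diff(object@z)
      if (max(abs(dz - dz[1])) > 1e-9 * abs(dz[1])) return("z grid must be uniform")
    }
    TRUE
  })

#' Simulated sheet intensity cross-section
#'
#' Nonnegative intensity I(x, z) produced by scalar paraxial propagation of
#' a plane-wave pupil through a \linkS4class{SlitMask}, normalised so that
#' the peak at focus equals 1. \code{rawPeak} retains the unnormalised peak
#' so absolute energies can be recovered.
#'
#' @slot values intensity matrix, rows = x, cols = z.
#' @slot grid a \linkS4class{FieldGrid}.
#' @slot lambdaEx excitation wavelength, um.
#' @slot mask the \linkS4class{SlitMask} that produced the map.
#' @slot rawPeak unnormalised focal peak intensity.
#' @export
setClass("IntensityMap",
  representation(values = "matrix", grid = "FieldGrid", lambdaEx = "numeric",
                 mask = "SlitMask", rawPeak = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) return("intensity must be nonnegative")
    if (nrow(object@values) != length(object@grid@x) ||
        ncol(object@values) != length(object@grid@z))
      return("values dimensions must match grid")
    v <- object@values
    asym <- max(abs(v - v[nrow(v):1, , drop = FALSE])) / max(v)
    if (asym > 1e-6) return("intensity not symmetric in x (even mask expected)")
    TRUE
  })

#' Measured metrics of a simulated sheet
#'
#' @slot fwhmFocus FWHM of the central peak at focus, um.
#' @slot sheetLength contiguous axial range with on-axis intensity >= 50\%
#'   of the focal maximum, um.
#' @slot centralEnergyFraction fraction of focal-plane energy between the
#'   first beat-envelope minima flanking x = 0.
#' @slot sideLobePeakRatio tallest secondary maximum over the central maximum.
#' @export
setClass("SheetMetrics",
  representation(fwhmFocus = "numeric", sheetLength = "numeric",
                 centralEnergyFraction = "numeric",
                 sideLobePeakRatio = "numeric"),
  validity = function(object) {
    if (!(object@fwhmFocus > 0)) return("fwhmFocus must be > 0")
    f <- object@centralEnergyFraction
    if (!(f >= 0 && f <= 1)) return("centralEnergyFraction must lie in [0, 1]")
    TRUE
  })

#' Voxel-calibrated image stack
#'
#' 3D (y, x, z) or 4D (y, x, z, t) nonnegative intensity data with voxel
#' sizes in micrometres. \code{offsetSubtracted} tracks whether the camera
#' offset has already been removed, so it is subtracted exactly once.
#'
#' @slot values numeric array, dims (y, x, z) or (y, x, z, t).
#' @slot voxelSize named numeric, um per axis: x, y, z.
#' @slot frameInterval time between time points, s (NA for 3D stacks).
#' @slot cameraOffset constant detector offset, counts.
#' @slot offsetSubtracted logical flag.
#' @export
setClass("ImageStack",
  representation(values = "array", voxelSize = "numeric",
                 frameInterval = "numeric", cameraOffset = "numeric",
                 offsetSubtracted = "logical"),
  validity = function(object) {
    nd <- length(dim(object@values))
    if (!nd %in% c(3L, 4L)) return("values must be a 3D or 4D array")
    if (!all(c("x", "y", "z") %in% names(object@voxelSize)))
      return("voxelSize must be named with x, y, z")
    if (any(object@voxelSize[c("x", "y", "z")] <= 0))
      return("voxel sizes must be > 0")
    if (object@offsetSubtracted && min(object@values) < -1e-6 * max(abs(object@values)) - 1e-9) {
      # negative residuals after offset subtraction are allowed (noise),
      # but grossly negative data suggest a double subtraction
      if (min(object@values) < -object@cameraOffset - 1e-9)
        return("values more negative than -cameraOffset: offset subtracted twice?")
    }
    TRUE
  })

#' Per-axis Gaussian fit of one bead
#'
#' @slot center fitted centre (x, y, z), um.
#' @slot sigma fitted Gaussian sigma per axis, um.
#' @slot fwhm 2*sqrt(2*ln2)*sigma per axis, um.
#' @slot amplitude fitted peak amplitude per axis, counts.
#' @slot baseline fitted baseline per axis, counts.
#' @slot depth fitted z-centre minus the lowest acquired plane, um.
#' @slot rss summed residual sum-of-squares of the three 1D fits.
#' @export
setClass("BeadFit",
  representation(center = "numeric", sigma = "numeric", fwhm = "numeric",
                 amplitude = "numeric", baseline = "numeric",
                 depth = "numeric", rss = "numeric"),
  validity = function(object) {
    if (length(object@sigma) != 3L || length(object@fwhm) != 3L)
      return("sigma and fwhm must have length 3 (x, y, z)")
    if (max(abs(object@fwhm / object@sigma - FWHM_SIGMA)) > 1e-9)
      return("fwhm/sigma must equal 2*sqrt(2*ln2)")
    TRUE
  })

#' Photobleaching time series
#'
#' Background-corrected raw integrated density and signal-to-background
#' ratio per time point, with the cumulative camera frame count (every
#' z-plane exposure counts as one frame).
#'
#' @slot frames cumulative frame index per time point, strictly increasing.
#' @slot rawIntegratedDensity background-corrected summed counts.
#' @slot sbr signal-to-background ratio per time point.
#' @slot frameExposure exposure per frame, s.
#' @export
setClass("BleachTrace",
  representation(frames = "numeric", rawIntegratedDensity = "numeric",
                 sbr = "numeric", frameExposure = "numeric"),
  validity = function(object) {
    if (length(object@frames) < 1L) return("empty trace")
    if (any(diff(object@frames) <= 0)) return("frames must be strictly increasing")
    if (length(object@rawIntegratedDensity) != length(object@frames))
      return("rawIntegratedDensity length must match frames")
    if (any(object@sbr < 0)) return("sbr must be >= 0")
    TRUE
  })

#' Frames-to-fraction photobleaching summary
#'
#' Cumulative frame counts at which the integrated density first drops
#' below 90, 80, 70, 60 and 50 percent of its initial value.
#'
#' @slot framesTo named numeric, names "90".."50".
#' @slot censored named logical, TRUE where the threshold was never crossed.
#' @export
setClass("BleachSummary",
  representation(framesTo = "numeric", censored = "logical"),
  validity = function(object) {
    v <- object@framesTo
    if (is.unsorted(v, strictly = FALSE))
      return("framesTo must be nondecreasing from 90% down to 50%")
    TRUE
  })

#' Synthetic-scene specification
#'
#' Everything a generator needs to render a bead stack or bleaching movie:
#' object geometry, photophysics, illumination model, detector model and
#' acquisition protocol, plus the RNG seed. Generators are pure functions
#' of (spec, seed): the same spec always yields the same data.
#'
#' @slot geometry list; for beads: data.frame with x, y, z (um), sigma
#'   (length-3), amplitude; for nuclei: data.frame with x, y, z, rx, ry, rz
#'   (um), density.
#' @slot photophysics list: \code{bleachRate} (per unit excitation dose),
#'   \code{production} (linear fluorophore production per second, default 0).
#' @slot illumination list: \code{mode} ("epi" or "sheet"), \code{sheetFWHM}
#'   (um), \code{tiltTheta} (degrees, sheet shear across x).
#' @slot detector list: \code{gain}, \code{offset} (counts), \code{readNoise}
#'   (counts sd), \code{shotNoise} (logical).
#' @slot acquisition list: \code{zStep}, \code{zRange} (um), \code{exposure}
#'   (s), \code{timePoints}, \code{frameSize} (pixels y, x), \code{pixelSize}
#'   (um).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(geometry = "list", photophysics = "list",
                 illumination = "list", detector = "list",
                 acquisition = "list", seed = "numeric"),
  validity = function(object) {
    ph <- object@photophysics
    if (!is.null(ph$bleachRate) && ph$bleachRate < 0)
      return("bleachRate must be >= 0")
    det <- object@detector
    if (!is.null(det$readNoise) && det$readNoise < 0)
      return("readNoise must be >= 0")
    acq <- object@acquisition
    if (!is.null(acq$zStep) && acq$zStep <= 0) return("zStep must be > 0")
    if (!is.null(acq$exposure) && acq$exposure < 0) return("exposure must be >= 0")
    il <- object@illumination
    if (!is.null(il$mode) && !il$mode %in% c("epi", "sheet"))
      return("illumination mode must be 'epi' or 'sheet'")
    TRUE
  })
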