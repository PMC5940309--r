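## Closed-form design chain for a tilted interference light sheet.
##
## Convention (important): all sheet equations use the vacuum excitation
## wavelength together with the in-air convergence half-angle of the dry
## cylindrical lens. The refractive index of the sample medium drops out of
## the width/length/angle chain across a flat chamber wall (the in-medium
## wavelength shrinks by n while the refraction-compressed angle grows the
## geometric focus by the same factor), so n appears only in the detection
## depth of field. Lengths are um at every interface except lens/mask
## geometry, which is mm. Angles are degrees at interfaces, radians inside.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Sheet FWHM from effective NA
#'
#' Focal full-width at half maximum of a cylindrical-lens light sheet,
#' \code{w = sqrt(2 ln 2) * lambda / (pi * NA_eff)}. Strictly decreasing in
#' \code{naEff}.
#'
#' @param naEff effective illumination NA (in-air convention), in (0, 1).
#' @param lambdaEx excitation wavelength, um.
#' @return Sheet FWHM, um.
#' @examples
#' sheetWidth(0.042533, 0.488)  # ~4.3 um
#' @export
sheetWidth <- function(naEff, lambdaEx) {
  if (any(lambdaEx <= 0)) stop("lambdaEx must be > 0")
  if (any(naEff <= 0) || any(naEff >= 1))
    stop("naEff must lie in (0, 1): the effective NA is the in-air sine of ",
         "the convergence half-angle of the dry cylindrical lens")
  SHEET_C * lambdaEx / naEff
}

#' Gaussian sheet length
#'
#' Distance over which an unmasked sheet of focal FWHM \code{w} stays at its
#' diffraction-limited width, \code{L = pi w^2 / (2 lambda)}. Quadratic in w.
#'
#' @param w sheet FWHM, um.
#' @param lambdaEx excitation wavelength, um.
#' @return Gaussian sheet length L, um.
#' @examples
#' gaussianLength(4.3, 0.488)
#' @export
gaussianLength <- function(w, lambdaEx) {
  if (any(w <= 0) || any(lambdaEx <= 0)) stop("w and lambdaEx must be > 0")
  pi * w^2 / (2 * lambdaEx)
}

#' Elongated sheet length from mask geometry
#'
#' Depth of field of the interference-elongated sheet in terms of the inner
#' slit-pair radius: \code{L' = lambda * f^2 / r1^2}. \code{f} and \code{r1}
#' are in mm, the result in um (the mm^2/mm^2 ratio is dimensionless, so the
#' um wavelength carries the unit).
#'
#' @param f cylindrical lens focal length, mm.
#' @param r1 inner slit-pair centre radius, mm; must satisfy r1 < f.
#' @param lambdaEx excitation wavelength, um.
#' @return Elongated sheet length L', um.
#' @examples
#' elongatedLengthFromMask(40, 1.7006, 0.488)  # ~270 um
#' @export
elongatedLengthFromMask <- function(f, r1, lambdaEx) {
  if (any(f <= 0) || any(r1 <= 0)) stop("f and r1 must be > 0")
  if (any(r1 >= f)) stop("r1 must be < f (paraxial slit geometry)")
  if (any(lambdaEx <= 0)) stop("lambdaEx must be > 0")
  lambdaEx * (f / r1)^2
}

#' Elongated sheet length from sheet width
#'
#' Combines the width and mask-length relations into
#' \code{L' = lambda / tan^2(asin(sqrt(2 ln 2) lambda / (pi w)))}.
#'
#' @param w sheet FWHM, um; must exceed \code{sqrt(2 ln 2) lambda / pi}.
#' @param lambdaEx excitation wavelength, um.
#' @return Elongated sheet length L', um.
#' @examples
#' elongatedLengthFromWidth(4.3, 0.488)  # ~269.3 um (270 at 2 s.f.)
#' elongatedLengthFromWidth(2.1, 0.488)  # ~63.9 um
#' @export
elongatedLengthFromWidth <- function(w, lambdaEx) {
  wmin <- SHEET_C * lambdaEx
  if (any(w <= wmin))
    stop(sprintf("w must exceed sqrt(2 ln 2) * lambda / pi = %.4g um", wmin))
  th <- asin(SHEET_C * lambdaEx / w)
  lambdaEx / tan(th)^2
}

#' Field of view of an objective
#'
#' \code{FOV = FN / M}, the full 1D field diameter. A smaller field may be
#' chosen manually downstream (e.g. a camera chip); see
#' \code{\link{designForObjective}}'s \code{fovOverride}.
#'
#' @param fn field number, um.
#' @param m lateral magnification.
#' @return Field-of-view diameter, um.
#' @examples
#' fieldOfView(22000, 60)
#' @export
fieldOfView <- function(fn, m) {
  if (any(fn <= 0) || any(m <= 0)) stop("fn and m must be > 0")
  fn / m
}

#' Depth of field of an objective
#'
#' \code{DOF = 1.61 * n_im * lambda_em / NA^2}, the theoretical axial
#' resolution for a given fluorophore and immersion medium.
#'
#' @param na numerical aperture; must satisfy na < nIm.
#' @param lambdaEm peak emission wavelength, um.
#' @param nIm coverslip-immersion medium refractive index.
#' @return Depth of field, um.
#' @examples
#' depthOfField(1.49, 0.515, 1.52)  # ~0.568 um
#' @export
depthOfField <- function(na, lambdaEm, nIm) {
  if (any(na <= 0)) stop("na must be > 0")
  if (any(na >= nIm)) stop("na must be < nIm (the aperture cannot exceed the medium index)")
  if (any(lambdaEm <= 0)) stop("lambdaEm must be > 0")
  1.61 * nIm * lambdaEm / na^2
}

#' Rayleigh lateral resolution
#'
#' \code{r = 0.61 * lambda_em / NA}.
#'
#' @param na numerical aperture.
#' @param lambdaEm peak emission wavelength, um.
#' @return Lateral resolution, um.
#' @examples
#' lateralResolution(1.49, 0.515)  # ~0.211 um
#' @export
lateralResolution <- function(na, lambdaEm) {
  if (any(na <= 0) || any(lambdaEm <= 0)) stop("na and lambdaEm must be > 0")
  0.61 * lambdaEm / na
}

#' Optimal sheet width for an objective
#'
#' Width of the thinnest tilted sheet whose slab still covers the
#' FOV x DOF field rectangle when inclined at the tilt angle the width
#' itself dictates (\code{\link{tiltAngle}}). Geometrically the covering
#' condition is \code{w = F sin(theta) + DOF cos(theta)} with
#' \code{F = FOV^2 / sqrt(DOF^2 + FOV^2)} the chord projection of the field
#' diameter; substituting \code{sin(theta) = sqrt(2 ln 2) lambda / (pi w)}
#' yields a quadratic in \code{w^2} solved here in closed form.
#'
#' The result is gated by self-checks: it must exceed the DOF for every
#' physical input and be monotone nondecreasing in \code{fov} and
#' \code{lambdaEx}; a violation signals a transcription fault rather than a
#' design.
#'
#' @param fov field-of-view diameter, um.
#' @param dof depth of field, um.
#' @param lambdaEx excitation wavelength, um.
#' @return Optimal sheet FWHM, um (always > dof).
#' @examples
#' optimalSheetWidth(150, 0.568, 0.488)
#' @export
optimalSheetWidth <- function(fov, dof, lambdaEx) {
  if (any(fov <= 0) || any(dof <= 0) || any(lambdaEx <= 0))
    stop("fov, dof and lambdaEx must be > 0")
  cc <- SHEET_C * lambdaEx                      # sqrt(2 ln 2) lambda / pi
  ff <- fov^2 / sqrt(dof^2 + fov^2)             # chord projection of the FOV
  disc <- dof^4 + 4 * cc * ff * dof^2 - 4 * cc^2 * dof^2
  if (any(disc < 0)) stop("optimal-width discriminant negative: probable transcription fault")
  w2 <- dof^2 / 2 + cc * ff + sqrt(disc) / 2
  w <- sqrt(w2)
  if (any(w <= dof))
    stop("self-check failed: optimal width does not exceed the DOF; ",
         "probable transcription fault in the width formula")
  w
}

#' Tilt half-angle of the converging sheet
#'
#' \code{theta = asin(sqrt(2 ln 2) lambda / (pi w))} in degrees: the maximal
#' angle at which the focused sheet should be tilted so its lower edge skims
#' the coverslip. Strictly decreasing in \code{w}.
#'
#' @param w sheet FWHM, um; must exceed \code{sqrt(2 ln 2) lambda / pi}.
#' @param lambdaEx excitation wavelength, um.
#' @return Tilt half-angle, degrees.
#' @examples
#' tiltAngle(4.3, 0.488)  # ~2.44 deg
#' tiltAngle(2.1, 0.488)  # ~5.00 deg
#' @export
tiltAngle <- function(w, lambdaEx) {
  wmin <- SHEET_C * lambdaEx
  if (any(w <= wmin))
    stop(sprintf("w must exceed sqrt(2 ln 2) * lambda / pi = %.4g um", wmin))
  rad2deg(asin(SHEET_C * lambdaEx / w))
}

#' Design a sheet for an objective/fluorophore pair
#'
#' Runs the full design chain: field of view (or a manual override), depth
#' of field, optimal sheet width, tilt angle, elongated and Gaussian sheet
#' lengths, effective NA, and the inner slit-pair radius of a mask on a lens
#' of focal length \code{f} that realises the elongated length.
#'
#' @param obj an \linkS4class{Objective}.
#' @param fluor a \linkS4class{Fluorophore}.
#' @param f cylindrical lens focal length, mm.
#' @param fovOverride optional manual field of view, um; must not exceed the
#'   objective's full field of view.
#' @return A list with elements \code{spec} (a \linkS4class{SheetSpec}),
#'   \code{vov} (a \linkS4class{VolumeOfView}) and \code{r1} (inner
#'   slit-pair radius, mm).
#' @examples
#' d <- designForObjective(Objective("60x", 60, 1.49, 22000, 1.52, "oil"),
#'                         fluorophorePresets()$GFP, f = 40,
#'                         fovOverride = 150)
#' d$spec
#' @export
designForObjective <- function(obj, fluor, f = 40, fovOverride = NULL) {
  stopifnot(is(obj, "Objective"), is(fluor, "Fluorophore"))
  lamEx <- fluor@lambdaEx
  fovFull <- fieldOfView(obj@fieldNumber, obj@magnification)
  fov <- fovFull
  if (!is.null(fovOverride)) {
    if (fovOverride > fovFull)
      stop(sprintf("fovOverride (%.4g um) exceeds the objective's full FOV (%.4g um); only a fraction of the full field may be selected",
                   fovOverride, fovFull))
    if (fovOverride <= 0) stop("fovOverride must be > 0")
    fov <- fovOverride
  }
  dof <- depthOfField(obj@na, fluor@lambdaEm, obj@nImmersion)
  w <- tryCatch(optimalSheetWidth(fov, dof, lamEx),
                error = function(e) stop("optimal-width step failed: ",
                                         conditionMessage(e), call. = FALSE))
  theta <- tryCatch(tiltAngle(w, lamEx),
                    error = function(e) stop("tilt-angle step failed: ",
                                             conditionMessage(e), call. = FALSE))
  lPrime <- elongatedLengthFromWidth(w, lamEx)
  lG <- gaussianLength(w, lamEx)
  naEff <- sin(deg2rad(theta))
  r1 <- f * sqrt(lamEx / lPrime)                # invert L' = lambda f^2 / r1^2
  spec <- new("SheetSpec", w = w, lGauss = lG, lPrime = lPrime, theta = theta,
              naEff = naEff, lambdaEx = lamEx, breadth = NA_real_)
  list(spec = spec, vov = new("VolumeOfView", fov = fov, dof = dof), r1 = r1)
}

#' Scan a catalog of objectives
#'
#' Runs \code{\link{designForObjective}} over a list of objectives and one
#' fluorophore, returning one row per objective in catalog order. Rows whose
#' design chain fails carry the error message in the \code{note} column and
#' NA numbers.
#'
#' @param objectives list of \linkS4class{Objective} objects.
#' @param fluor a \linkS4class{Fluorophore}.
#' @param f cylindrical lens focal length, mm.
#' @return data.frame with columns id, na, fov, dof, w, theta, l_prime, note.
#' @examples
#' cat3 <- list(Objective("a", 60, 1.49, 22000, 1.52, "oil"),
#'              Objective("b", 25, 1.10, 22000, 1.33, "water"))
#' catalogScan(cat3, fluorophorePresets()$GFP)
#' @export
catalogScan <- function(objectives, fluor, f = 40) {
  if (length(objectives) == 0L) stop("empty objective catalog")
  rows <- lapply(objectives, function(obj) {
    res <- tryCatch(designForObjective(obj, fluor, f = f),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(id = obj@id, na = obj@na, fov = NA_real_, dof = NA_real_,
                 w = NA_real_, theta = NA_real_, l_prime = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(id = obj@id, na = obj@na, fov = res$vov@fov,
                 dof = res$vov@dof, w = res$spec@w, theta = res$spec@theta,
                 l_prime = res$spec@lPrime, note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Synthetic objective catalog
#'
#' A deterministic 90-objective catalog spanning NA 0.1-1.49 across air,
#' water and oil immersion with realistic magnification/field-number
#' pairings, emulating the commercial range used for design scans.
#'
#' @param n number of objectives (default 90).
#' @return list of \linkS4class{Objective} objects.
#' @export
syntheticObjectiveCatalog <- function(n = 90) {
  stopifnot(n >= 2)
  nas <- seq(0.1, 1.49, length.out = n)
  mags <- c(4, 10, 20, 25, 40, 60, 100)
  lapply(seq_len(n), function(i) {
    na <- nas[i]
    if (na <= 0.95) { nIm <- 1.00; imm <- "air" }
    else if (na <= 1.27) { nIm <- 1.33; imm <- "water" }
    else { nIm <- 1.52; imm <- "oil" }
    # higher NA lenses come in higher magnifications
    m <- mags[pmin(length(mags), 1L + floor(na / 1.5 * (length(mags) - 1L) + (i %% 2)))]
    Objective(sprintf("obj%02d_%gx_%.2f", i, m, na), m, na, 22000, nIm, imm)
  })
}
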