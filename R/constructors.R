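#' Create a Fluorophore
#'
#' @param name label.
#' @param lambdaEx excitation wavelength, um.
#' @param lambdaEm peak emission wavelength, um.
#' @return A \linkS4class{Fluorophore}.
#' @examples
#' gfp <- Fluorophore("GFP", 0.488, 0.515)
#' @export
Fluorophore <- function(name, lambdaEx, lambdaEm) {
  new("Fluorophore", name = as.character(name),
      lambdaEx = as.numeric(lambdaEx), lambdaEm = as.numeric(lambdaEm))
}

#' Create an Objective
#'
#' @param id label.
#' @param magnification lateral magnification.
#' @param na numerical aperture.
#' @param fieldNumber field number, um.
#' @param nImmersion coverslip-immersion refractive index.
#' @param immersion \code{"air"}, \code{"water"} or \code{"oil"}.
#' @return An \linkS4class{Objective}.
#' @examples
#' obj <- Objective("60x/1.49", 60, 1.49, 22000, 1.52, "oil")
#' @export
Objective <- function(id, magnification, na, fieldNumber, nImmersion,
                      immersion = "oil") {
  new("Objective", id = as.character(id),
      magnification = as.numeric(magnification), na = as.numeric(na),
      fieldNumber = as.numeric(fieldNumber),
      nImmersion = as.numeric(nImmersion), immersion = as.character(immersion))
}

#' Create a quadruple-slit mask
#'
#' @param f cylindrical lens focal length, mm.
#' @param pairRadii centre radii (inner, outer) of the slit pairs, mm.
#' @param slitWidths slit widths (inner, outer), mm.
#' @return A \linkS4class{SlitMask}.
#' @examples
#' m <- SlitMask(40, c(0.5, 1.7), c(0.3, 0.3))
#' @export
SlitMask <- function(f, pairRadii, slitWidths) {
  new("SlitMask", f = as.numeric(f), pairRadii = as.numeric(pairRadii),
      slitWidths = as.numeric(slitWidths))
}

#' Create a simulation grid
#'
#' @param x transverse samples, um (uniform, symmetric about 0).
#' @param z axial samples, um.
#' @return A \linkS4class{FieldGrid}.
#' @export
FieldGrid <- function(x, z = 0) {
  new("FieldGrid", x = as.numeric(x), z = as.numeric(z))
}

#' Create an ImageStack
#'
#' @param values 3D (y, x, z) or 4D (y, x, z, t) nonnegative array.
#' @param voxelSize named numeric (x, y, z), um.
#' @param frameInterval seconds between time points (4D only).
#' @param cameraOffset constant detector offset, counts.
#' @param offsetSubtracted has the offset already been removed?
#' @return An \linkS4class{ImageStack}.
#' @export
ImageStack <- function(values, voxelSize, frameInterval = NA_real_,
                       cameraOffset = 0, offsetSubtracted = FALSE) {
  if (is.null(names(voxelSize)) && length(voxelSize) == 3L)
    names(voxelSize) <- c("x", "y", "z")
  new("ImageStack", values = values, voxelSize = voxelSize,
      frameInterval = as.numeric(frameInterval),
      cameraOffset = as.numeric(cameraOffset),
      offsetSubtracted = isTRUE(offsetSubtracted))
}

#' Subtract the camera offset from a stack (exactly once)
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return The stack with \code{cameraOffset} subtracted and the
#'   \code{offsetSubtracted} flag set. Subtracting twice is an error.
#' @export
subtractOffset <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  if (stack@offsetSubtracted)
    stop("camera offset has already been subtracted from this stack")
  stack@values <- stack@values - stack@cameraOffset
  stack@offsetSubtracted <- TRUE
  stack
}

#' Bundled fluorophore presets
#'
#' The five common fluorescent proteins used throughout the design scans,
#' with their peak excitation wavelengths (383, 433, 488, 513 and 587 nm)
#' and nominal peak emission wavelengths.
#'
#' @return Named list of \linkS4class{Fluorophore} objects: BFP, CFP, GFP,
#'   YFP, mCherry.
#' @examples
#' fluorophorePresets()$GFP
#' @export
fluorophorePresets <- function() {
  list(
    BFP     = Fluorophore("BFP",     0.383, 0.445),
    CFP     = Fluorophore("CFP",     0.433, 0.475),
    GFP     = Fluorophore("GFP",     0.488, 0.515),
    YFP     = Fluorophore("YFP",     0.513, 0.527),
    mCherry = Fluorophore("mCherry", 0.587, 0.610)
  )
}

setMethod("show", "Fluorophore", function(object) {
  cat(sprintf("Fluorophore %s: ex %.0f nm, em %.0f nm\n", object@name,
              object@lambdaEx * 1000, object@lambdaEm * 1000))
})

setMethod("show", "Objective", function(object) {
  cat(sprintf("Objective %s: %gx / NA %.2f (%s, n = %.2f), FN %g um\n",
              object@id, object@magnification, object@na, object@immersion,
              object@nImmersion, object@fieldNumber))
})

setMethod("show", "SheetSpec", function(object) {
  cat("Tilted light-sheet design\n")
  cat(sprintf("  w (FWHM at focus): %s um\n", signif(object@w, 3)))
  cat(sprintf("  L (Gaussian length): %s um\n", signif(object@lGauss, 3)))
  cat(sprintf("  L' (elongated length): %s um\n", signif(object@lPrime, 3)))
  cat(sprintf("  theta (tilt half-angle): %s deg\n", signif(object@theta, 3)))
  cat(sprintf("  NA_eff: %s   lambda_ex: %.0f nm\n", signif(object@naEff, 3),
              object@lambdaEx * 1000))
})

setMethod("show", "SlitMask", function(object) {
  cat(sprintf("Quadruple-slit mask (f = %g mm)\n", object@f))
  cat(sprintf("  inner pair: +/-%.4f mm, width %.4f mm\n",
              object@pairRadii[1], object@slitWidths[1]))
  cat(sprintf("  outer pair: +/-%.4f mm, width %.4f mm\n",
              object@pairRadii[2], object@slitWidths[2]))
})

setMethod("show", "IntensityMap", function(object) {
  g <- object@grid
  cat(sprintf("IntensityMap: %d x-samples (%.2f um step) x %d z-samples\n",
              length(g@x), diff(g@x[1:2]),
              length(g@z)))
  cat(sprintf("  lambda_ex %.0f nm, peak normalised to 1\n",
              object@lambdaEx * 1000))
})

setMethod("show", "SheetMetrics", function(object) {
  cat("Sheet metrics\n")
  cat(sprintf("  FWHM at focus: %s um\n", signif(object@fwhmFocus, 4)))
  cat(sprintf("  sheet length (50%% on-axis): %s um\n",
              signif(object@sheetLength, 4)))
  cat(sprintf("  central energy fraction: %.3f\n",
              object@centralEnergyFraction))
  cat(sprintf("  side-lobe peak ratio: %.3f\n", object@sideLobePeakRatio))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@values)
  kind <- if (length(d) == 4L) "4D movie (y, x, z, t)" else "3D stack (y, x, z)"
  cat(sprintf("ImageStack: %s, dims %s\n", kind, paste(d, collapse = " x ")))
  cat(sprintf("  voxel size (x, y, z): %s um; offset %g (%ssubtracted)\n",
              paste(signif(object@voxelSize[c("x", "y", "z")], 3), collapse = ", "),
              object@cameraOffset,
              if (object@offsetSubtracted) "" else "not "))
})

setMethod("show", "BeadFit", function(object) {
  cat(sprintf("BeadFit: FWHM (x, y, z) = %s um at depth %.2f um\n",
              paste(signif(object@fwhm, 3), collapse = ", "), object@depth))
})

setMethod("show", "BleachTrace", function(object) {
  cat(sprintf("BleachTrace: %d time points, %g frames total, sbr %0.2f -> %0.2f\n",
              length(object@frames), max(object@frames),
              object@sbr[1], object@sbr[length(object@sbr)]))
})

setMethod("show", "BleachSummary", function(object) {
  cat("Frames acquired before bleaching to:\n")
  for (nm in names(object@framesTo))
    cat(sprintf("  %s%%: %g frames%s\n", nm, object@framesTo[[nm]],
                if (object@censored[[nm]]) " (censored)" else ""))
})

# --- small accessors -------------------------------------------------------

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))

#' Accessors
#'
#' \code{intensityValues} returns the raw numeric array of an
#' \linkS4class{IntensityMap} or \linkS4class{ImageStack};
#' \code{sheetFWHM}, \code{sheetLength}, \code{centralEnergyFraction}
#' read \linkS4class{SheetMetrics}; \code{beadFWHM} reads the per-axis FWHM
#' of a \linkS4class{BeadFit}.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("intensityValues", "IntensityMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("intensityValues", "ImageStack", function(object) object@values)

#' @rdname accessors
#' @export
sheetFWHM <- function(object) {
  if (is(object, "SheetMetrics")) object@fwhmFocus else object@w
}

#' @rdname accessors
#' @export
sheetLength <- function(object) object@sheetLength

#' @rdname accessors
#' @export
centralEnergyFraction <- function(object) object@centralEnergyFraction

#' @rdname accessors
#' @export
beadFWHM <- function(object) {
  stopifnot(is(object, "BeadFit"))
  stats::setNames(object@fwhm, c("x", "y", "z"))
}

#' @rdname accessors
#' @export
framesTo <- function(object) {
  stopifnot(is(object, "BleachSummary"))
  object@framesTo
}
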