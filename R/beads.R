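## Bead point-spread-function quantification: per-axis 1D Gaussian fits of
## the intensity profiles through a bead, mirroring the usual bead-stack
## quality-control procedure. FWHM = 2 sqrt(2 ln 2) sigma throughout.

# 1D pixel-integrated Gaussian + baseline fit via Levenberg-Marquardt.
# The model averages the Gaussian over each pixel (error-function
# difference), so the finite pixel size does not inflate the fitted sigma
# (a plain Gaussian model biases sigma^2 upward by step^2/12).
fitGaussian1D <- function(pos, val) {
  base0 <- min(val)
  amp0 <- max(val) - base0
  if (amp0 <= 0) stop("flat profile: Gaussian fit impossible")
  mu0 <- pos[which.max(val)]
  step <- pos[2] - pos[1]
  # initial sigma from the count of samples above half maximum: robust to
  # baseline noise, unlike a windowed second moment
  nAbove <- sum(val > base0 + amp0 / 2)
  sd0 <- max(nAbove * step, step) / FWHM_SIGMA
  # fit only the peak neighbourhood so a neighbouring bead's flank at the
  # window edge cannot corrupt the fit
  keep <- abs(pos - mu0) <= max(6 * sd0, 4 * step)
  df <- data.frame(pos = pos[keep], val = val[keep])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      val ~ b + a * s * sqrt(2 * pi) *
        (pnorm((pos - mu + step / 2) / s) - pnorm((pos - mu - step / 2) / s)) /
        step,
      data = df,
                      start = list(b = base0, a = amp0, mu = mu0, s = sd0),
                      lower = c(-Inf, 0, min(df$pos), step / 10),
                      upper = c(Inf, Inf, max(df$pos), diff(range(pos))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  list(baseline = cf[["b"]], amplitude = cf[["a"]], center = cf[["mu"]],
       sigma = cf[["s"]], rss = sum(stats::resid(fit)^2))
}

#' Fit one bead with per-axis Gaussians
#'
#' Extracts a window around a seed voxel, locates the intensity-weighted
#' centroid, and fits a 1D Gaussian (amplitude, centre, sigma, baseline) to
#' the axis-aligned intensity profile along each of x, y and z, each profile
#' averaged over a 3-pixel band in the other axes to suppress noise. FWHM is
#' \code{2 sqrt(2 ln 2) sigma}; depth is the fitted z-centre above the lowest
#' acquired plane (the coverslip proxy).
#'
#' @param stack an offset-subtracted 3D \linkS4class{ImageStack}.
#' @param seed integer voxel c(y, x, z) near the bead.
#' @param window cube half-width around the seed, um.
#' @return A \linkS4class{BeadFit}.
#' @export
fitBead <- function(stack, seed, window = 1.5) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@values
  if (length(dim(v)) != 3L) stop("fitBead needs a 3D stack")
  vs <- stack@voxelSize
  half <- ceiling(window / vs[c("y", "x", "z")])
  d <- dim(v)
  lo <- seed - half; hi <- seed + half
  if (any(lo < 1L) || any(hi > d))
    stop("bead window clipped by the stack edge; move the seed or shrink the window")
  sub <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (sum(sub) <= 0) stop("empty window: no intensity to fit")
  ds <- dim(sub)
  # intensity-weighted centroid in a small neighbourhood of the window
  # centre (the seed is a local maximum); a whole-window centroid would be
  # pulled by neighbouring beads
  ctr0 <- half + 1L
  nb <- function(i, n) max(1L, i - 2L):min(n, i + 2L)
  loc <- sub[nb(ctr0[1], ds[1]), nb(ctr0[2], ds[2]), nb(ctr0[3], ds[3]),
             drop = FALSE]
  loc <- pmax(loc, 0)
  lw <- sum(loc)
  if (lw <= 0) stop("empty window: no intensity to fit")
  cy <- ctr0[1] - min(2L, ctr0[1] - 1L) - 1L +
    round(sum(slice.index(loc, 1) * loc) / lw)
  cx <- ctr0[2] - min(2L, ctr0[2] - 1L) - 1L +
    round(sum(slice.index(loc, 2) * loc) / lw)
  cz <- ctr0[3] - min(2L, ctr0[3] - 1L) - 1L +
    round(sum(slice.index(loc, 3) * loc) / lw)
  cy <- min(max(cy, 2L), ds[1] - 1L)
  cx <- min(max(cx, 2L), ds[2] - 1L)
  cz <- min(max(cz, 2L), ds[3] - 1L)
  band <- function(i, n) max(1L, i - 1L):min(n, i + 1L)
  profX <- apply(sub[band(cy, ds[1]), , band(cz, ds[3]), drop = FALSE], 2, mean)
  profY <- apply(sub[, band(cx, ds[2]), band(cz, ds[3]), drop = FALSE], 1, mean)
  profZ <- apply(sub[band(cy, ds[1]), band(cx, ds[2]), , drop = FALSE], 3, mean)
  fx <- fitGaussian1D((seq_len(ds[2]) - 1) * vs[["x"]], profX)
  fy <- fitGaussian1D((seq_len(ds[1]) - 1) * vs[["y"]], profY)
  fz <- fitGaussian1D((seq_len(ds[3]) - 1) * vs[["z"]], profZ)
  # centres back in absolute um (stack origin at voxel 1 = 0 um)
  ctr <- c(x = unname((lo[2] - 1) * vs[["x"]] + fx$center),
           y = unname((lo[1] - 1) * vs[["y"]] + fy$center),
           z = unname((lo[3] - 1) * vs[["z"]] + fz$center))
  sig <- c(fx$sigma, fy$sigma, fz$sigma)
  fwhm <- FWHM_SIGMA * sig
  if (fwhm[3] < max(fwhm[1:2]))
    warning("axial FWHM below lateral FWHM: unusual for a detection PSF")
  new("BeadFit", center = ctr, sigma = sig, fwhm = fwhm,
      amplitude = c(fx$amplitude, fy$amplitude, fz$amplitude),
      baseline = c(fx$baseline, fy$baseline, fz$baseline),
      depth = ctr[["z"]], rss = fx$rss + fy$rss + fz$rss)
}

#' Detect bead seeds in a stack
#'
#' Local maxima above \code{threshold} times the global maximum, separated
#' by at least three expected FWHMs. Ordering is deterministic: descending
#' intensity, ties broken by scan order.
#'
#' @param stack an offset-subtracted 3D \linkS4class{ImageStack}.
#' @param threshold relative threshold in (0, 1).
#' @param expectedFWHM expected bead image FWHM c(x, y, z), um, setting the
#'   minimum separation.
#' @return matrix of integer seeds, one row per bead, columns y, x, z
#'   (possibly zero rows).
#' @export
detectBeads <- function(stack, threshold = 0.3,
                        expectedFWHM = c(0.25, 0.25, 0.6)) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@values
  if (length(dim(v)) != 3L) stop("detectBeads needs a 3D stack")
  d <- dim(v)
  # noise-floor gate: a stack with no candidate brighter than 10 robust
  # noise SDs above the median has no detectable beads at all
  noise <- stats::mad(v)
  if (max(v) - stats::median(v) < 10 * max(noise, .Machine$double.eps))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("y", "x", "z"))))
  cut <- threshold * max(v)
  minSep <- 3 * expectedFWHM / stack@voxelSize[c("y", "x", "z")]
  # candidate voxels above the cut, checked against their 26-neighbourhood
  idx <- which(v >= cut)
  if (length(idx) == 0L) return(matrix(integer(0), 0, 3,
                                       dimnames = list(NULL, c("y", "x", "z"))))
  coord <- arrayInd(idx, d)
  isMax <- vapply(seq_along(idx), function(i) {
    p <- coord[i, ]
    yl <- max(1L, p[1] - 1L):min(d[1], p[1] + 1L)
    xl <- max(1L, p[2] - 1L):min(d[2], p[2] + 1L)
    zl <- max(1L, p[3] - 1L):min(d[3], p[3] + 1L)
    v[p[1], p[2], p[3]] >= max(v[yl, xl, zl])
  }, logical(1))
  coord <- coord[isMax, , drop = FALSE]
  vals <- v[coord]
  ord <- order(-vals, coord[, 3], coord[, 1], coord[, 2])
  coord <- coord[ord, , drop = FALSE]
  keep <- logical(nrow(coord))
  for (i in seq_len(nrow(coord))) {
    p <- coord[i, ]
    ok <- TRUE
    if (any(keep)) {
      prev <- coord[keep, , drop = FALSE]
      sep <- abs(sweep(prev, 2, p))
      ok <- all(rowSums(sweep(sep, 2, minSep, ">=")) > 0)
    }
    keep[i] <- ok
  }
  out <- coord[keep, , drop = FALSE]
  colnames(out) <- c("y", "x", "z")
  out
}

#' Compare bead FWHMs between two illumination groups
#'
#' Two-sample two-sided Welch t-test on one axis's FWHM, with per-group
#' mean and standard error of the mean as reported alongside such scatter
#' plots.
#'
#' @param groupA,groupB lists of \linkS4class{BeadFit} objects (n >= 2 each).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param alpha significance level (default 0.05).
#' @return list with t, p, significant, meanA, semA, meanB, semB, axis.
#' @export
compareFWHM <- function(groupA, groupB, axis = c("x", "y", "z"),
                        alpha = 0.05) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  getF <- function(g) vapply(g, function(b) b@fwhm[ai], numeric(1))
  a <- getF(groupA); b <- getF(groupB)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two beads per group")
  if (isTRUE(all.equal(a, b))) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha,
       meanA = mean(a), semA = sem(a), meanB = mean(b), semB = sem(b),
       axis = axis)
}

#' Tabulate bead fits
#'
#' @param fits list of \linkS4class{BeadFit} objects.
#' @return data.frame, one row per bead.
#' @export
beadTable <- function(fits) {
  do.call(rbind, lapply(fits, function(b)
    data.frame(x = b@center[["x"]], y = b@center[["y"]], z = b@center[["z"]],
               fwhm_x = b@fwhm[1], fwhm_y = b@fwhm[2], fwhm_z = b@fwhm[3],
               depth = b@depth, rss = b@rss)))
}
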