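## Photobleaching and signal-to-background quantification of time-lapse
## movies. Conventions: camera offset is subtracted once (tracked by the
## ImageStack flag); local background is handled as a second, explicit step
## (annulus or user mask); cumulative frame counts include every z-plane
## exposure, not just time points.

#' Signal-to-background ratio of one frame
#'
#' Mean of the signal pixels over mean of the background pixels, on
#' offset-subtracted data rebased so the background floor maps to a ratio
#' of 1 for a spatially uniform image.
#'
#' @param frame 2D numeric matrix (offset already subtracted).
#' @param signalMask,backgroundMask logical matrices of the same shape;
#'   must be disjoint and nonempty.
#' @return SBR, a nonnegative scalar with floor 1.0 for uniform images.
#' @examples
#' img <- matrix(50, 8, 8); img[3:5, 3:5] <- 200
#' sig <- img > 100
#' sbr(img, sig, !sig)
#' @export
sbr <- function(frame, signalMask, backgroundMask) {
  stopifnot(is.matrix(frame))
  if (!any(signalMask) || !any(backgroundMask))
    stop("signal and background masks must be nonempty")
  if (any(signalMask & backgroundMask))
    stop("signal and background masks must be disjoint")
  bg <- mean(frame[backgroundMask])
  if (bg == 0) stop("background mean is zero: SBR undefined")
  mean(frame[signalMask]) / bg
}

#' Photobleaching trace of a movie
#'
#' Per time point: z-maximum-intensity projection, then raw integrated
#' density = sum over the signal ROI minus ROI area times the mean of the
#' background ROI, plus the SBR of the projection. Frame counts accumulate
#' every z-plane exposure (e.g. 41 frames per time point for a 0.5-um step
#' over a 20-um range).
#'
#' @param movie a 4D \linkS4class{ImageStack} (y, x, z, t), offset
#'   subtracted.
#' @param signalMask logical matrix (y, x), or list of one per time point.
#' @param backgroundMask logical matrix (y, x), or list of one per time
#'   point.
#' @param frameExposure exposure per frame, s.
#' @return A \linkS4class{BleachTrace}.
#' @export
bleachTrace <- function(movie, signalMask, backgroundMask,
                        frameExposure = 0.1) {
  stopifnot(is(movie, "ImageStack"))
  v <- movie@values
  if (length(dim(v)) != 4L) stop("bleachTrace needs a 4D movie (y, x, z, t)")
  if (!movie@offsetSubtracted)
    stop("subtract the camera offset first (subtractOffset)")
  d <- dim(v)
  nz <- d[3]; nt <- d[4]
  maskAt <- function(m, t) if (is.list(m)) m[[t]] else m
  rid <- numeric(nt); sb <- numeric(nt)
  for (t in seq_len(nt)) {
    sm <- maskAt(signalMask, t); bm <- maskAt(backgroundMask, t)
    if (!identical(dim(sm), d[1:2]) || !identical(dim(bm), d[1:2]))
      stop("ROI mask dimensions do not match the frame")
    proj <- apply(v[, , , t, drop = FALSE], c(1, 2), max)
    rid[t] <- sum(proj[sm]) - sum(sm) * mean(proj[bm])
    sb[t] <- sbr(proj, sm, bm)
  }
  new("BleachTrace", frames = seq_len(nt) * nz, rawIntegratedDensity = rid,
      sbr = sb, frameExposure = frameExposure)
}

#' Frames acquired before bleaching to a fraction
#'
#' Cumulative frame count at the first time point whose raw integrated
#' density falls below \code{fraction} times the initial value. No
#' smoothing is applied: the first crossing decides. If the trace never
#' crosses, the total frame count is returned with \code{censored = TRUE}.
#'
#' @param trace a \linkS4class{BleachTrace}; the first time point is the
#'   100\% reference.
#' @param fraction retained-intensity fraction, e.g. 0.5.
#' @return list with \code{frames} and \code{censored}.
#' @export
framesToFraction <- function(trace, fraction) {
  stopifnot(is(trace, "BleachTrace"))
  if (length(trace@frames) == 0L) stop("empty trace")
  if (fraction >= 1) return(list(frames = 0, censored = FALSE))
  ref <- trace@rawIntegratedDensity[1]
  hit <- which(trace@rawIntegratedDensity < fraction * ref)[1]
  if (is.na(hit))
    list(frames = trace@frames[length(trace@frames)], censored = TRUE)
  else
    list(frames = trace@frames[hit], censored = FALSE)
}

#' Frames-to-fraction summary across the standard thresholds
#'
#' @param trace a \linkS4class{BleachTrace}.
#' @param fractions retained-intensity fractions (default 0.9 .. 0.5).
#' @return A \linkS4class{BleachSummary}.
#' @export
bleachSummary <- function(trace, fractions = c(0.9, 0.8, 0.7, 0.6, 0.5)) {
  res <- lapply(fractions, function(f) framesToFraction(trace, f))
  frames <- vapply(res, `[[`, numeric(1), "frames")
  cens <- vapply(res, `[[`, logical(1), "censored")
  names(frames) <- names(cens) <- as.character(round(fractions * 100))
  new("BleachSummary", framesTo = frames, censored = cens)
}

#' Fit a single-exponential bleach rate
#'
#' Least-squares fit of \code{I0 exp(-rate * t)} to the integrated-density
#' trace against cumulative exposure time (frames times frame exposure).
#'
#' @param trace a \linkS4class{BleachTrace}.
#' @return list with \code{rate} (per second of cumulative exposure) and
#'   \code{I0}.
#' @export
fitBleachRate <- function(trace) {
  stopifnot(is(trace, "BleachTrace"))
  tt <- trace@frames * trace@frameExposure
  y <- trace@rawIntegratedDensity
  if (any(y <= 0)) {
    keep <- y > 0
    tt <- tt[keep]; y <- y[keep]
  }
  if (length(y) < 3L) stop("too few positive points to fit a rate")
  cf <- stats::coef(stats::lm(log(y) ~ tt))
  st <- list(I0 = exp(cf[[1]]), rate = max(-cf[[2]], 1e-12))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-rate * tt),
                      start = st, lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(st[c("rate", "I0")])
  cf <- stats::coef(fit)
  list(rate = cf[["rate"]], I0 = cf[["I0"]])
}

#' Kymograph along a polyline
#'
#' Samples the movie along a polyline at unit-pixel steps and, per sample,
#' takes the maximum across a band of \code{width} pixels perpendicular to
#' the local line direction. Rows are time points, columns positions.
#'
#' @param movie a 3D (y, x, t) or 4D (y, x, z, t) \linkS4class{ImageStack};
#'   4D movies are z-maximum projected per time point.
#' @param line numeric matrix of polyline vertices, columns x, y (pixels).
#' @param width band width in pixels (odd).
#' @return numeric matrix, \code{nt} rows by number of line samples.
#' @export
kymograph <- function(movie, line, width = 3L) {
  stopifnot(is(movie, "ImageStack"))
  v <- movie@values
  nd <- length(dim(v))
  if (!nd %in% c(3L, 4L)) stop("kymograph needs a (y, x, t) or (y, x, z, t) stack")
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline needs at least two vertices")
  segLen <- sqrt(rowSums((line[-1, , drop = FALSE] -
                          line[-nrow(line), , drop = FALSE])^2))
  if (sum(segLen) < 1) stop("degenerate (zero-length) line")
  # unit-pixel samples along the polyline with local direction
  pts <- NULL; dirs <- NULL
  for (i in seq_len(nrow(line) - 1L)) {
    p0 <- line[i, ]; p1 <- line[i + 1L, ]
    n <- max(1L, ceiling(segLen[i]))
    tfrac <- seq(0, 1, length.out = n + 1L)
    if (i > 1L) tfrac <- tfrac[-1]
    seg <- cbind(p0[1] + tfrac * (p1[1] - p0[1]),
                 p0[2] + tfrac * (p1[2] - p0[2]))
    u <- (p1 - p0) / segLen[i]
    pts <- rbind(pts, seg)
    dirs <- rbind(dirs, matrix(u, nrow(seg), 2, byrow = TRUE))
  }
  perp <- cbind(-dirs[, 2], dirs[, 1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  d <- dim(v)
  nt <- d[nd]
  bilinear <- function(img, xx, yy) {
    x0 <- floor(xx); y0 <- floor(yy)
    fx <- xx - x0; fy <- yy - y0
    x0 <- pmin(pmax(x0, 1L), ncol(img) - 1L)
    y0 <- pmin(pmax(y0, 1L), nrow(img) - 1L)
    img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
      img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
      img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
  }
  if (any(pts[, 1] < 1) || any(pts[, 1] > d[2]) ||
      any(pts[, 2] < 1) || any(pts[, 2] > d[1]))
    stop("polyline leaves the image bounds")
  out <- matrix(0, nt, nrow(pts))
  for (t in seq_len(nt)) {
    img <- if (nd == 4L) apply(v[, , , t, drop = FALSE], c(1, 2), max)
           else v[, , t]
    acc <- matrix(0, length(offs), nrow(pts))
    for (j in seq_along(offs)) {
      xx <- pts[, 1] + offs[j] * perp[, 1]
      yy <- pts[, 2] + offs[j] * perp[, 2]
      xx <- pmin(pmax(xx, 1), d[2]); yy <- pmin(pmax(yy, 1), d[1])
      acc[j, ] <- bilinear(img, xx, yy)
    }
    out[t, ] <- apply(acc, 2, max)
  }
  out
}

#' Default nucleus/background ROI masks for a movie
#'
#' Signal mask from Otsu thresholding the first time point's z-projection;
#' background from a dilated annulus around it. The published procedure
#' leaves ROI geometry unstated, so this default is explicit and
#' reproducible rather than canonical.
#'
#' @param movie a 4D \linkS4class{ImageStack}, offset subtracted.
#' @param dilate annulus width in pixels.
#' @return list with \code{signal} and \code{background} logical matrices.
#' @export
defaultRoiMasks <- function(movie, dilate = 3L) {
  stopifnot(is(movie, "ImageStack"))
  v <- movie@values
  if (length(dim(v)) != 4L) stop("defaultRoiMasks needs a 4D movie")
  proj <- apply(v[, , , 1, drop = FALSE], c(1, 2), max)
  thr <- otsuThreshold(proj)
  sig <- proj > thr
  grown <- dilateMask(sig, dilate)
  ring <- dilateMask(grown, dilate) & !grown
  if (!any(ring)) ring <- !grown
  list(signal = sig, background = ring)
}

# Otsu threshold; EBImage's implementation when available, else the
# textbook between-class-variance maximiser on a 256-bin histogram
otsuThreshold <- function(img) {
  rng <- range(img)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    sc <- (img - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    return(EBImage::otsu(sc, range = c(0, 1)) * (rng[2] - rng[1]) + rng[1])
  }
  h <- graphics::hist(img, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p); mu <- cumsum(p * mids); muT <- mu[length(mu)]
  bc <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

dilateMask <- function(mask, n) {
  for (i in seq_len(n)) {
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-nrow(mask), , drop = FALSE])
    le <- cbind(mask[, -1, drop = FALSE], FALSE)
    ri <- cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
    mask <- mask | up | dn | le | ri
  }
  mask
}
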