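## CSV catalogs, multi-page TIFF stacks with JSON sidecars, and JSON
## metric reports. CSV dialect: comma-separated, UTF-8, header required,
## decimal point. All format handling is delegated to read.csv, the tiff
## package and jsonlite.

#' Read an objective catalog CSV
#'
#' Expected header:
#' \code{id,magnification,na,field_number_um,n_immersion,immersion}.
#' Malformed rows are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return list of \linkS4class{Objective} objects.
#' @export
readObjectiveCatalog <- function(path) {
  need <- c("id", "magnification", "na", "field_number_um", "n_immersion",
            "immersion")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("objective catalog is missing columns: ", paste(missing, collapse = ", "))
  out <- vector("list", nrow(df))
  bad <- character(0)
  for (i in seq_len(nrow(df))) {
    obj <- tryCatch(
      Objective(df$id[i], df$magnification[i], df$na[i],
                df$field_number_um[i], df$n_immersion[i], df$immersion[i]),
      error = function(e) conditionMessage(e))
    if (is.character(obj)) bad <- c(bad, sprintf("line %d: %s", i + 1L, obj))
    else out[[i]] <- obj
  }
  if (length(bad))
    stop("invalid objective rows:\n", paste(bad, collapse = "\n"))
  out
}

#' Write an objective catalog CSV
#'
#' @param objectives list of \linkS4class{Objective} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeObjectiveCatalog <- function(objectives, path) {
  df <- do.call(rbind, lapply(objectives, function(o)
    data.frame(id = o@id, magnification = o@magnification, na = o@na,
               field_number_um = o@fieldNumber, n_immersion = o@nImmersion,
               immersion = o@immersion, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a fluorophore table CSV
#'
#' Expected header: \code{name,lambda_ex_um,lambda_em_um}.
#'
#' @param path CSV file path.
#' @return named list of \linkS4class{Fluorophore} objects.
#' @export
readFluorophoreTable <- function(path) {
  need <- c("name", "lambda_ex_um", "lambda_em_um")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("fluorophore table is missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    Fluorophore(df$name[i], df$lambda_ex_um[i], df$lambda_em_um[i]))
  names(out) <- df$name
  out
}

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are z-planes (3D) or z-planes within consecutive time points (4D,
#' z fastest). Data are stored as 32-bit float; integer data round-trip
#' losslessly. Axis order and voxel metadata go to a JSON sidecar next to
#' the TIFF.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path; the sidecar is written with extension
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@values
  d <- dim(v)
  nd <- length(d)
  pages <- if (nd == 3L) lapply(seq_len(d[3]), function(z) v[, , z])
  else {
    idx <- expand.grid(z = seq_len(d[3]), t = seq_len(d[4]))
    lapply(seq_len(nrow(idx)), function(i) v[, , idx$z[i], idx$t[i]])
  }
  # power-of-two scale: division is a float exponent shift, so integer
  # counts below 2^24 survive the 32-bit float page exactly
  sc <- 2^ceiling(log2(max(abs(v), 1)))
  tiff::writeTIFF(lapply(pages, function(p) p / sc), path,
                  bits.per.sample = 32L)
  meta <- list(axes = if (nd == 3L) "yxz" else "yxzt",
               dim = d, scale = sc,
               integer_data = all(v == round(v)),
               voxel_size_um = as.list(stack@voxelSize[c("x", "y", "z")]),
               frame_interval_s = if (is.finite(stack@frameInterval))
                 stack@frameInterval,
               camera_offset = stack@cameraOffset,
               offset_subtracted = stack@offsetSubtracted)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by \code{writeStack}
#'
#' Refuses to guess: a missing or axis-less sidecar is an error.
#'
#' @param path TIFF path with JSON sidecar.
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path) {
  side <- sidecarPath(path)
  if (!file.exists(side))
    stop("missing sidecar JSON with axis and voxel metadata: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$axes) || is.null(meta$voxel_size_um))
    stop("sidecar lacks axes or voxel_size_um; refusing to guess")
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  v <- array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
  v <- v * meta$scale
  if (isTRUE(meta$integer_data)) v <- round(v)
  if (identical(meta$axes, "yxzt")) dim(v) <- d
  else if (!identical(meta$axes, "yxz")) stop("unsupported axis order: ", meta$axes)
  vs <- unlist(meta$voxel_size_um)[c("x", "y", "z")]
  ImageStack(v, vs,
             frameInterval = meta$frame_interval_s %||% NA_real_,
             cameraOffset = meta$camera_offset %||% 0,
             offsetSubtracted = isTRUE(meta$offset_subtracted))
}

#' Write an intensity map as TIFF + sidecar JSON
#'
#' Single-page 32-bit TIFF of I(x, z) with grid spacing, wavelength and
#' mask geometry in the sidecar.
#'
#' @param map an \linkS4class{IntensityMap}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeIntensityMap <- function(map, path) {
  stopifnot(is(map, "IntensityMap"))
  v <- map@values / max(map@values)
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  g <- map@grid
  meta <- list(kind = "intensity_map", rows = "x", cols = "z",
               dx_um = diff(g@x[1:2]),
               dz_um = if (length(g@z) > 1) diff(g@z[1:2]) else 0,
               x0_um = g@x[1], z0_um = g@z[1],
               lambda_ex_um = map@lambdaEx,
               mask = list(f_mm = map@mask@f,
                           pair_radii_mm = map@mask@pairRadii,
                           slit_widths_mm = map@mask@slitWidths))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
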