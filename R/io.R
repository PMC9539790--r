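# Image-stack and localization-table input/output.
#
# Images are exchanged as standard single- or multi-page 16-bit grayscale
# TIFF. Localization tables are delimited text in either the ThunderSTORM
# column dialect (`"x [nm]"`, `"intensity [photon]"`, ...) or a minimal
# dialect (`x_nm`, `y_nm`, ...). All coordinates are continuous nanometres
# with the origin at the outer corner of the first pixel, so a localization
# at the centre of pixel (i, j) (1-based) has x_nm = (j - 0.5) * pixel size.

#' Construct an image stack
#'
#' A light container for a stack of camera frames: a 3-D integer-count array
#' indexed (frame, row, col) plus acquisition metadata.
#'
#' @param frames 3-D numeric array (frame, row, col), or a single matrix
#'   which is promoted to a 1-frame stack. All values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size_nm camera pixel pitch in nm (127 nm for the reference
#'   EMCCD setup).
#' @param bit_depth camera digitizer depth; default 16.
#' @param exposure_ms exposure time per frame in ms (metadata only).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_nm, bit_depth = 16L,
                        exposure_ms = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a matrix or a 3-D array (frame, row, col)")
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  if (dim(frames)[1L] < 1L) stop("stack must contain at least one frame")
  vmax <- 2^bit_depth - 1
  rng <- range(frames)
  if (rng[1L] < 0 || rng[2L] > vmax)
    stop(sprintf("frame values must lie in [0, %d]", as.integer(vmax)))
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 bit_depth = as.integer(bit_depth),
                 exposure_ms = exposure_ms),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px, %.3g nm/px, %d-bit\n",
              d[1L], d[2L], d[3L], x$pixel_size_nm, x$bit_depth))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1L]

#' Extract one frame as a matrix
#' @param stack an `image_stack`.
#' @param i frame index (1-based).
#' @return numeric matrix (row, col).
#' @export
get_frame <- function(stack, i) {
  d <- dim(stack$frames)
  if (i < 1L || i > d[1L]) stop("frame index out of range")
  matrix(stack$frames[i, , ], d[2L], d[3L])
}

#' Read a grayscale TIFF image or stack
#'
#' Reads single- or multi-page grayscale TIFF files into an [image_stack].
#' Integer sample values are preserved exactly.
#'
#' @param path file path.
#' @param pixel_size_nm camera pixel pitch in nm to attach as metadata.
#' @param convert if `TRUE`, non-integer (float) TIFF data are accepted and
#'   rounded; by default they are rejected.
#' @param exposure_ms optional exposure metadata.
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, pixel_size_nm, convert = FALSE,
                             exposure_ms = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  probe <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(probe)) probe <- list(probe)
  # 8/16-bit TIFF stores unsigned integers; 32-bit is floating point
  bits <- attr(probe[[1L]], "bits.per.sample") %||% 16L
  if (bits >= 32L) {
    if (!convert) stop("float TIFF input; pass convert = TRUE to round")
    pages <- lapply(probe, round)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  for (p in pages) {
    if (length(dim(p)) > 2L && dim(p)[3L] > 1L)
      stop("multi-channel (non-grayscale) TIFF not supported")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) > 2L) p <- p[, , 1L]
    p
  })
  frames <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  image_stack(frames, pixel_size_nm, exposure_ms = exposure_ms)
}

#' Write an image stack as 16-bit grayscale TIFF
#'
#' @param stack an [image_stack] (or a bare matrix / 3-D array).
#' @param path output path; multi-frame stacks become multi-page TIFF.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack, 1)
  vmax <- 2^16 - 1
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    m <- get_frame(stack, i)
    if (max(m) > vmax) stop("values exceed 16-bit range")
    m / vmax
  })
  if (length(pages) == 1L) pages <- pages[[1L]]
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# Column naming of the two supported localization-table dialects.
# canonical name -> file column name
.ts_columns <- c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
                 sigma_nm = "sigma [nm]", photons = "intensity [photon]",
                 uncertainty_nm = "uncertainty [nm]",
                 background = "offset [photon]")
.min_columns <- c(frame = "frame", x_nm = "x_nm", y_nm = "y_nm",
                  sigma_nm = "sigma_nm", photons = "photons",
                  uncertainty_nm = "uncertainty_nm",
                  background = "background")

#' Make a localization table
#'
#' Canonical in-memory form of a set of single-molecule localizations: a
#' `data.frame` with columns `frame` (1-based acquisition frame), `x_nm`,
#' `y_nm` (continuous nm, origin at the outer corner of pixel (1,1)),
#' and optionally `sigma_nm` (fitted PSF sd), `photons`, `uncertainty_nm`
#' (localization precision) and `background` (photons/pixel).
#'
#' @param frame,x_nm,y_nm mandatory fields (recycled to common length).
#' @param sigma_nm,photons,uncertainty_nm,background optional fields; `NA`
#'   when absent.
#' @param ... further columns kept as annotations.
#' @return a `data.frame` of localizations.
#' @export
localization_table <- function(frame, x_nm, y_nm, sigma_nm = NA_real_,
                               photons = NA_real_, uncertainty_nm = NA_real_,
                               background = NA_real_, ...) {
  n <- length(x_nm)
  rec <- function(v) if (length(v) == 1L && n != 1L) rep(v, length.out = n) else v
  df <- data.frame(frame = rec(as.integer(frame)), x_nm = x_nm, y_nm = y_nm,
                   sigma_nm = rec(sigma_nm), photons = rec(photons),
                   uncertainty_nm = rec(uncertainty_nm),
                   background = rec(background), ...)
  if (nrow(df) && any(df$frame < 1L)) stop("frame indices must be >= 1")
  df
}

#' Read a localization table (ThunderSTORM or minimal CSV dialect)
#'
#' @param path CSV file with a header naming at least frame, x and y
#'   columns in one of the supported dialects.
#' @param dialect `"auto"` (default), `"thunderstorm"` or `"minimal"`.
#' @param camera_pixel_nm needed only when coordinates are stored in camera
#'   pixels (`"x [px]"` columns); they are converted as
#'   `x_nm = x_px * camera_pixel_nm`.
#' @return a `data.frame` as produced by [localization_table()]; columns not
#'   part of the dialect are preserved unchanged.
#' @export
read_localizations <- function(path, dialect = c("auto", "thunderstorm", "minimal"),
                               camera_pixel_nm = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(raw)
  if (dialect == "auto")
    dialect <- if ("x [nm]" %in% nm || "x [px]" %in% nm) "thunderstorm" else "minimal"
  cols <- if (dialect == "thunderstorm") .ts_columns else .min_columns
  px_mode <- dialect == "thunderstorm" && !("x [nm]" %in% nm) && ("x [px]" %in% nm)
  if (px_mode) {
    if (is.null(camera_pixel_nm))
      stop("coordinates in pixels: camera_pixel_nm is required")
    cols[["x_nm"]] <- "x [px]"; cols[["y_nm"]] <- "y [px]"
  }
  mandatory <- c("frame", "x_nm", "y_nm")
  missing <- mandatory[!(cols[mandatory] %in% nm)]
  if (length(missing))
    stop(sprintf("missing mandatory column(s): %s",
                 paste(cols[missing], collapse = ", ")))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(cols)) {
    file_col <- cols[[canon]]
    if (file_col %in% nm) {
      v <- raw[[file_col]]
      if (canon %in% mandatory && nrow(raw) > 0L && !is.numeric(v))
        stop(sprintf("non-numeric values in column '%s'", file_col))
      out[[canon]] <- if (nrow(raw) == 0L) numeric(0) else v
    } else out[[canon]] <- rep(NA_real_, nrow(raw))
  }
  if (px_mode) {
    out$x_nm <- out$x_nm * camera_pixel_nm
    out$y_nm <- out$y_nm * camera_pixel_nm
  }
  out$frame <- as.integer(out$frame)
  extra <- setdiff(nm, cols)
  for (e in extra) out[[e]] <- raw[[e]]
  out
}

#' Write a localization table
#'
#' @param records a localization `data.frame` (see [localization_table()]).
#' @param path output CSV path.
#' @param dialect `"thunderstorm"` (default) or `"minimal"` column naming.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(records, path,
                                dialect = c("thunderstorm", "minimal")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "thunderstorm") .ts_columns else .min_columns
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (canon in names(cols))
    out[[cols[[canon]]]] <- if (canon %in% names(records)) records[[canon]] else NA_real_
  extra <- setdiff(names(records), names(cols))
  for (e in extra) out[[e]] <- records[[e]]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
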