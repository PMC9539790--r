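# Registration of the diffraction-limited anisotropy map onto the
# super-resolution coordinate frame, and joint anisotropy-nanostructure
# statistics. The two modalities are acquired on the same camera and are
# assumed to share one coordinate frame; mapping between the grids is a
# pure scale. Pixels are half-open intervals [k*p, (k+1)*p) with floor
# assignment everywhere.

#' Upscale an anisotropy map to the render grid without interpolation
#'
#' Pure nearest-neighbour replication: output pixel (i, j) copies the
#' source pixel containing its centre, so no new values are created. A
#' 512 x 512 map at 127 nm/px upscaled to a 10 nm grid gives the canonical
#' 6502 x 6502 overlay image.
#'
#' @param map an [anisotropy_map].
#' @param render_pixel_nm target grid pitch; must be finer than the
#'   camera pixel.
#' @return list with `r` and `valid_mask` on the render grid,
#'   `render_pixel_nm`, and `scale` (= camera pixel / render pixel).
#' @export
upscale_anisotropy <- function(map, render_pixel_nm = 10) {
  src <- map$pixel_size_nm
  if (render_pixel_nm >= src)
    stop("render pixel must be smaller than the camera pixel")
  n_out <- function(n_src) floor(n_src * src / render_pixel_nm)
  nr <- n_out(nrow(map$r)); nc <- n_out(ncol(map$r))
  ridx <- pmin(floor(((seq_len(nr) - 0.5) * render_pixel_nm) / src) + 1L,
               nrow(map$r))
  cidx <- pmin(floor(((seq_len(nc) - 0.5) * render_pixel_nm) / src) + 1L,
               ncol(map$r))
  list(r = map$r[ridx, cidx, drop = FALSE],
       valid_mask = map$valid_mask[ridx, cidx, drop = FALSE],
       render_pixel_nm = render_pixel_nm, scale = src / render_pixel_nm)
}

#' Annotate localizations with their camera pixel's anisotropy
#'
#' Each localization receives the r value (and validity flag) of the
#' camera pixel containing it: pixel indices are
#' `floor(coordinate / pixel size)` (a localization exactly on a boundary
#' belongs to the lower-index pixel). Localizations on masked pixels are
#' flagged invalid and should be excluded from summaries.
#'
#' @param records a localization `data.frame` sharing the map's origin and
#'   field of view.
#' @param map an [anisotropy_map].
#' @return records with added columns `cam_row`, `cam_col` (1-based),
#'   `r` and `r_valid`.
#' @export
assign_anisotropy <- function(records, map) {
  p <- map$pixel_size_nm
  row <- floor(records$y_nm / p) + 1L
  col <- floor(records$x_nm / p) + 1L
  if (nrow(records) &&
      (min(row) < 1L || max(row) > nrow(map$r) ||
       min(col) < 1L || max(col) > ncol(map$r)))
    stop("localization outside the anisotropy map extent")
  idx <- cbind(row, col)
  records$cam_row <- row
  records$cam_col <- col
  records$r <- map$r[idx]
  records$r_valid <- map$valid_mask[idx]
  records
}

#' Cluster-class composition per anisotropy bin
#'
#' For each anisotropy bin, the fraction of (valid-pixel) localizations
#' classified as nanocluster, microcluster and diffuse - the summary that
#' shows which nanoscale organizations hide behind pixels of equal
#' anisotropy.
#'
#' @param annotated records from [assign_anisotropy()] with an added
#'   `class` column (`"nanocluster"` / `"microcluster"` / `"diffuse"`).
#' @param bin_edges anisotropy breaks; default width 0.05 over \[0, 0.5\].
#' @return `data.frame(bin_lo, bin_hi, n, frac_nanocluster,
#'   frac_microcluster, frac_diffuse)`; fractions sum to 1 in occupied
#'   bins and are `NA` in empty bins.
#' @export
composition_by_anisotropy <- function(annotated,
                                      bin_edges = seq(0, 0.5, by = 0.05)) {
  ok <- annotated$r_valid & !is.na(annotated$r)
  df <- annotated[ok, , drop = FALSE]
  idx <- findInterval(df$r, bin_edges, rightmost.closed = TRUE)
  inb <- idx >= 1L & idx <= length(bin_edges) - 1L
  df <- df[inb, , drop = FALSE]; idx <- idx[inb]
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    n = tabulate(idx, nbins = nb))
  for (cls in c("nanocluster", "microcluster", "diffuse")) {
    cnt <- tabulate(idx[df$class == cls], nbins = nb)
    out[[paste0("frac_", cls)]] <- ifelse(out$n > 0L, cnt / out$n, NA_real_)
  }
  out
}

#' Nearest-neighbour distance map and its correlation with anisotropy
#'
#' Builds a camera-grid map of the median nearest-neighbour distance of
#' the localizations within each pixel (dataset-wide NN distances), then
#' computes the Pearson correlation between that map and the anisotropy
#' map over pixels valid in both.
#'
#' @param records a localization `data.frame`.
#' @param map an [anisotropy_map].
#' @return list with `nn_map` (matrix, NA where no localizations),
#'   `pearson` (NA with a warning if fewer than 2 jointly valid pixels or
#'   zero variance), and `n_pixels` used.
#' @export
nn_map_and_correlation <- function(records, map) {
  p <- map$pixel_size_nm
  nnd <- nearest_neighbor_distances(records)
  row <- floor(records$y_nm / p) + 1L
  col <- floor(records$x_nm / p) + 1L
  ok <- row >= 1L & row <= nrow(map$r) & col >= 1L & col <= ncol(map$r)
  nn_map <- matrix(NA_real_, nrow(map$r), ncol(map$r))
  idx <- (col[ok] - 1L) * nrow(map$r) + row[ok]
  med <- tapply(nnd[ok], idx, median)
  nn_map[as.integer(names(med))] <- med
  joint <- !is.na(nn_map) & map$valid_mask
  if (sum(joint) < 2L) {
    warning("fewer than 2 jointly valid pixels; correlation undefined")
    return(list(nn_map = nn_map, pearson = NA_real_, n_pixels = sum(joint)))
  }
  a <- nn_map[joint]; b <- map$r[joint]
  if (var(a) == 0 || var(b) == 0) {
    warning("zero variance; correlation undefined")
    return(list(nn_map = nn_map, pearson = NA_real_, n_pixels = sum(joint)))
  }
  list(nn_map = nn_map, pearson = cor(a, b), n_pixels = sum(joint))
}

#' Costes-thresholded Pearson colocalization
#'
#' Orthogonal (total least squares) regression `img2 ~ a img1 + b` sets a
#' threshold pair; the threshold is walked down `img1`'s range until the
#' Pearson correlation of the sub-threshold pixel population drops to
#' <= 0, and the colocalization coefficient is the Pearson correlation
#' over pixels above both thresholds.
#'
#' @param img1,img2 numeric matrices of equal shape.
#' @param n_steps number of candidate threshold levels walked.
#' @return list `(threshold1, threshold2, pearson, pearson_full, slope,
#'   intercept, n_above)`.
#' @export
costes_pearson <- function(img1, img2, n_steps = 200L) {
  if (!identical(dim(img1), dim(img2))) stop("images must share a shape")
  v1 <- as.vector(img1); v2 <- as.vector(img2)
  if (var(v1) == 0 || var(v2) == 0) stop("zero-variance image")
  # orthogonal regression via principal axis of the covariance
  cv <- cov(cbind(v1, v2))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  a <- ev[2L] / ev[1L]
  b <- mean(v2) - a * mean(v1)
  thr <- seq(max(v1), min(v1), length.out = n_steps)
  t_found <- min(v1) - 1e-9 * max(abs(v1), 1)   # fallback: everything above
  for (t1 in thr) {
    below <- v1 <= t1 & v2 <= a * t1 + b
    if (sum(below) > 2L && var(v1[below]) > 0 && var(v2[below]) > 0) {
      if (cor(v1[below], v2[below]) <= 0) { t_found <- t1; break }
    }
  }
  above <- v1 > t_found & v2 > a * t_found + b
  pearson <- if (sum(above) > 2L && var(v1[above]) > 0 && var(v2[above]) > 0)
    cor(v1[above], v2[above]) else NA_real_
  list(threshold1 = t_found, threshold2 = a * t_found + b,
       pearson = pearson, pearson_full = cor(v1, v2),
       slope = a, intercept = b, n_above = sum(above))
}
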