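# Pixel-wise steady-state fluorescence anisotropy (homoFRET) mapping.
#
# Under linearly polarized excitation, energy migration between identical
# fluorophores within Foerster distance depolarizes the emission, so the
# per-pixel anisotropy
#
#     r = (I_par - G * I_perp) / (I_par + 2 * G * I_perp)
#
# reports the average self-association state inside each diffraction-limited
# pixel: lower r means more homoFRET, hence more dimer/oligomer. G corrects
# for the unequal sensitivity of the two polarization detection paths and is
# calibrated on an isotropic (freely rotating) fluorophore solution.

#' Construct a polarized image pair
#'
#' Co-registered parallel (`i_par`) and perpendicular (`i_perp`) polarized
#' emission images of the same field, as acquired through a polarizing
#' beam splitter onto two cameras.
#'
#' @param i_par,i_perp numeric matrices of equal shape, nonnegative counts.
#' @param pixel_size_nm camera pixel pitch (nm).
#' @param saturation_level digitizer saturation value (counts).
#' @return an object of class `polarized_pair`.
#' @export
polarized_pair <- function(i_par, i_perp, pixel_size_nm = 127,
                           saturation_level = 65535) {
  if (!is.matrix(i_par) || !is.matrix(i_perp) ||
      !identical(dim(i_par), dim(i_perp)))
    stop("`i_par` and `i_perp` must be matrices of identical shape")
  if (min(i_par) < 0 || min(i_perp) < 0)
    stop("intensities must be nonnegative")
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  structure(list(i_par = i_par, i_perp = i_perp,
                 pixel_size_nm = pixel_size_nm,
                 saturation_level = saturation_level),
            class = "polarized_pair")
}

#' Construct an anisotropy map
#'
#' @param r numeric matrix of per-pixel anisotropy values.
#' @param valid_mask logical matrix; `r` is meaningful only where `TRUE`.
#' @param pixel_size_nm pixel pitch (nm).
#' @param g_factor the G factor used (NA for ground-truth maps).
#' @return an object of class `anisotropy_map`.
#' @export
anisotropy_map <- function(r, valid_mask, pixel_size_nm, g_factor = NA_real_) {
  if (!identical(dim(r), dim(valid_mask)))
    stop("`r` and `valid_mask` must have identical shape")
  r[!valid_mask] <- NA_real_
  structure(list(r = r, valid_mask = valid_mask,
                 pixel_size_nm = pixel_size_nm, g_factor = g_factor),
            class = "anisotropy_map")
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat(sprintf("<anisotropy_map> %d x %d px at %.3g nm/px, %d valid (%.1f%%)\n",
              nrow(x$r), ncol(x$r), x$pixel_size_nm, sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  r: median %.3f, range [%.3f, %.3f]\n",
                median(x$r[x$valid_mask]), min(x$r[x$valid_mask]),
                max(x$r[x$valid_mask])))
  invisible(x)
}

#' Calibrate the G factor from an isotropic standard
#'
#' The G factor is the intensity ratio `mean(I_par) / mean(I_perp)` of the
#' two detection channels imaging a freely rotating fluorophore solution
#' (e.g. 100 nM fluorescein), whose true anisotropy is ~0, computed over
#' unsaturated pixels above background.
#'
#' @param standard_pair a [polarized_pair] of the isotropic standard.
#' @param intensity_threshold minimum `i_par + i_perp` for a pixel to be
#'   used; default 0 (all unsaturated pixels).
#' @return the scalar G factor.
#' @export
compute_g_factor <- function(standard_pair, intensity_threshold = 0) {
  p <- standard_pair
  ok <- p$i_par < p$saturation_level & p$i_perp < p$saturation_level &
    (p$i_par + p$i_perp) >= intensity_threshold
  if (!any(ok)) stop("no valid pixels in standard pair")
  denom <- mean(p$i_perp[ok])
  if (denom <= 0) stop("mean perpendicular intensity is zero")
  mean(p$i_par[ok]) / denom
}

#' Compute a G-factor-corrected anisotropy map
#'
#' Applies `r = (I_par - G I_perp) / (I_par + 2 G I_perp)` per pixel.
#' Pixels are masked invalid when either channel is saturated (the ratio
#' needs two real intensities), when the total intensity
#' `I_par + 2 G I_perp` falls below `intensity_threshold` (near-background
#' pixels), or when that denominator is not positive.
#'
#' @param pair a [polarized_pair].
#' @param g_factor the detection-path correction factor G.
#' @param intensity_threshold absolute threshold on `I_par + 2 G I_perp`;
#'   `NA` (default) estimates it as 3x the robust background sigma of the
#'   total-intensity image border. Kept constant across cells in a study.
#' @param offset_par,offset_perp optional constant dark offsets subtracted
#'   from each channel before the ratio (inputs are otherwise assumed
#'   offset-subtracted).
#' @return an [anisotropy_map].
#' @export
compute_anisotropy_map <- function(pair, g_factor,
                                   intensity_threshold = NA_real_,
                                   offset_par = 0, offset_perp = 0) {
  stop_if_not_scalar_pos(g_factor, "g_factor")
  ipar <- pair$i_par - offset_par
  iperp <- pair$i_perp - offset_perp
  total <- ipar + 2 * g_factor * iperp
  if (is.na(intensity_threshold))
    intensity_threshold <- 3 * robust_background_sigma(total, border = 2L)
  valid <- pair$i_par < pair$saturation_level &
    pair$i_perp < pair$saturation_level &
    total > 0 & total >= intensity_threshold
  r <- matrix(NA_real_, nrow(ipar), ncol(ipar))
  r[valid] <- (ipar[valid] - g_factor * iperp[valid]) / total[valid]
  anisotropy_map(r, valid, pair$pixel_size_nm, g_factor)
}

#' Histogram of valid anisotropy values
#'
#' @param map an [anisotropy_map].
#' @param bin_edges increasing breaks covering all valid r values; default
#'   width-0.05 bins over \[-0.5, 1\].
#' @return `data.frame(bin_lo, bin_hi, count)`; counts sum to the number of
#'   valid pixels. Bins are half-open `[lo, hi)`, last bin closed.
#' @export
anisotropy_histogram <- function(map, bin_edges = seq(-0.5, 1, by = 0.05)) {
  v <- map$r[map$valid_mask]
  if (!length(v)) stop("map has no valid pixels")
  if (min(v) < bin_edges[1L] || max(v) > bin_edges[length(bin_edges)])
    stop("bin_edges do not cover the range of valid r values")
  idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1L], count = counts)
}

#' Cumulative anisotropy curve
#'
#' Empirical cumulative distribution of the valid pixel anisotropies, the
#' summary used to compare conditions (e.g. fixation vs permeabilization):
#' a right-shift of the curve means a shift toward higher anisotropy, i.e.
#' less self-association.
#'
#' @param map an [anisotropy_map].
#' @return `data.frame(r, cum_fraction)` sorted by `r`, nondecreasing and
#'   ending at 1.
#' @export
cumulative_anisotropy_curve <- function(map) {
  v <- sort(map$r[map$valid_mask])
  if (!length(v)) stop("map has no valid pixels")
  data.frame(r = v, cum_fraction = seq_along(v) / length(v))
}
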