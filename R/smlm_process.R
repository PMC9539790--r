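# Localization post-processing: precision/photon filtering, sub-nanometre
# duplicate merging, cross-correlation drift correction and Gaussian
# rendering.

#' Filter localizations by precision and photon count
#'
#' Keeps records with `uncertainty_min_nm < uncertainty_nm <=
#' uncertainty_max_nm` and `photons >= photon_min`, preserving order.
#' The default window (6, 40] nm reflects the observation that thermal and
#' electronic noise produce artefactual localizations with uncertainties of
#' 0-6 nm, while sample noise dominates above 40 nm.
#'
#' @param records a localization `data.frame`.
#' @param uncertainty_min_nm,uncertainty_max_nm keep-window bounds (nm);
#'   the lower bound is exclusive, the upper inclusive.
#' @param photon_min minimum photon count.
#' @return the filtered `data.frame` (never more rows than the input).
#' @export
filter_localizations <- function(records, uncertainty_min_nm = 6,
                                 uncertainty_max_nm = 40, photon_min = 100) {
  keep <- records$uncertainty_nm > uncertainty_min_nm &
    records$uncertainty_nm <= uncertainty_max_nm &
    records$photons >= photon_min
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Merge duplicate localizations within a radius
#'
#' Repeated blinks of one fluorophore (or the 1-2 dyes on one nanobody)
#' produce near-identical coordinates that would read as self-clustering.
#' All pairs of localizations within `radius_nm` of each other - across
#' frames - are joined into a graph, and each connected component is
#' replaced by a single record: photon-weighted centroid position, summed
#' photons, earliest frame, minimum uncertainty (photon-weighted means for
#' sigma and background). The transitive-closure rule means a chain of
#' sub-radius steps merges into one record; the operation is idempotent
#' once no remaining pair falls within the radius.
#'
#' @param records a localization `data.frame`.
#' @param radius_nm merge radius; default 1 nm.
#' @return merged `data.frame`, ordered by each component's earliest
#'   original row.
#' @export
merge_duplicates <- function(records, radius_nm = 1) {
  n <- nrow(records)
  if (n < 2L) return(records)
  pts <- cbind(records$x_nm, records$y_nm)
  k <- min(n, 16L)
  nn <- RANN::nn2(pts, pts, k = k, searchtype = "radius", radius = radius_nm)
  edges <- NULL
  idx <- nn$nn.idx
  from <- rep(seq_len(n), k)
  to <- as.vector(idx)
  ok <- to > 0L & to != from
  edges <- cbind(from[ok], to[ok])
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
  } else edges <- matrix(integer(), 0L, 2L)
  comp <- edge_components(n, edges)
  w <- records$photons
  if (all(is.na(w))) w <- rep(1, n)
  w[is.na(w) | w <= 0] <- 1e-9
  first <- tapply(seq_len(n), comp, min)
  agg <- function(f, ...) as.numeric(tapply(seq_len(n), comp, f, ...))
  wm <- function(v) as.numeric(tapply(seq_len(n), comp,
                                      function(i) sum(v[i] * w[i]) / sum(w[i])))
  out <- localization_table(
    frame = as.integer(tapply(records$frame, comp, min)),
    x_nm = wm(records$x_nm), y_nm = wm(records$y_nm),
    sigma_nm = wm(records$sigma_nm),
    photons = as.numeric(tapply(records$photons, comp, sum)),
    uncertainty_nm = as.numeric(tapply(records$uncertainty_nm, comp, min)),
    background = wm(records$background))
  out[order(first), , drop = FALSE]
}

# 2-D histogram of localizations on a render grid with fixed extent.
bin_localizations <- function(x_nm, y_nm, render_pixel_nm, nr, nc) {
  row <- floor(y_nm / render_pixel_nm) + 1L
  col <- floor(x_nm / render_pixel_nm) + 1L
  ok <- row >= 1L & row <= nr & col >= 1L & col <= nc
  matrix(tabulate((col[ok] - 1L) * nr + row[ok], nbins = nr * nc), nr, nc)
}

# Subpixel image translation by cross-correlation with local upsampled-DFT
# refinement (matrix-multiply DFT around the integer peak). Returns
# c(row_shift, col_shift) such that img is ref translated by that many
# pixels (positive = toward larger indices).
register_translation <- function(ref, img, upsample = 100L) {
  register_translation_fft(fft(ref), fft(img), upsample)
}

# Same, from precomputed FFTs (lets callers reuse per-image transforms).
# Refinement evaluates the cross-correlation on local shift grids by
# matrix-multiply DFT, coarse-to-fine, so cost stays modest at high
# upsampling factors.
register_translation_fft <- function(fref, fimg, upsample = 100L) {
  nr <- nrow(fref); nc <- ncol(fref)
  f <- fimg * Conj(fref)
  cc <- fft(f, inverse = TRUE)
  peak <- which.max(Mod(cc))
  pr <- ((peak - 1L) %% nr)
  pc <- ((peak - 1L) %/% nr)
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  if (upsample <= 1L) return(c(pr, pc))
  fr <- (seq_len(nr) - 1L); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- (seq_len(nc) - 1L); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  eval_cc <- function(rshifts, cshifts) {
    kernr <- exp(2i * pi / nr * outer(rshifts, fr))
    kernc <- exp(2i * pi / nc * outer(fc, cshifts))
    Mod(kernr %*% f %*% kernc)
  }
  best <- c(pr, pc)
  step <- 1
  while (step > 1 / upsample) {
    step <- max(step / 10, 1 / upsample)
    rs <- best[1L] + seq(-7, 7) * step
    cs <- best[2L] + seq(-7, 7) * step
    g <- eval_cc(rs, cs)
    pk <- which.max(g)
    best <- c(rs[((pk - 1L) %% length(rs)) + 1L],
              cs[((pk - 1L) %/% length(rs)) + 1L])
  }
  best
}

#' Estimate stage drift by redundant cross-correlation
#'
#' Splits the acquisition into `n_bins` contiguous temporal bins, renders
#' each bin's localizations as a (lightly smoothed) 2-D histogram at
#' `render_pixel_nm`, and measures subpixel displacements between bin
#' images by phase cross-correlation with upsampled-DFT refinement. With
#' `reference = "pairwise"` (default) every bin pair is registered and the
#' per-bin displacements are solved by least squares - the redundancy
#' averages down the per-pair registration noise; `reference = "first"`
#' registers each bin against the first only. Per-frame displacements are
#' linearly interpolated between bin-centre frames; beyond the first and
#' last bin centres the adjacent segment's slope is continued (constant
#' extrapolation would systematically truncate half a bin of drift at
#' each end).
#'
#' @param records a localization `data.frame`.
#' @param n_bins number of temporal bins (each needs >= `min_locs_per_bin`
#'   localizations).
#' @param render_pixel_nm histogram pixel size for registration.
#' @param upsample subpixel refinement factor (displacement resolution
#'   `render_pixel_nm / upsample`).
#' @param blur_px Gaussian smoothing (sigma, render pixels) applied to each
#'   bin image before correlation; stabilizes the correlation peak for
#'   sparse bins. 0 disables.
#' @param reference `"pairwise"` (redundant, all bin pairs) or `"first"`.
#' @param min_locs_per_bin minimum localizations per bin.
#' @return a `drift_trace`: list with `displacement_nm` (`n_frames x 2`
#'   matrix of (dx, dy) relative to frame 1), `bin_centers` (frames),
#'   `bin_displacement_nm`.
#' @export
estimate_drift <- function(records, n_bins = 10L, render_pixel_nm = 10,
                           upsample = 100L, blur_px = 1,
                           reference = c("pairwise", "first"),
                           min_locs_per_bin = 50L) {
  reference <- match.arg(reference)
  if (n_bins < 2L) stop("need at least 2 temporal bins")
  max_frame <- max(records$frame)
  edges <- seq(0.5, max_frame + 0.5, length.out = n_bins + 1L)
  bin <- findInterval(records$frame, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, n_bins)
  if (any(counts < min_locs_per_bin))
    stop(sprintf("each temporal bin needs >= %d localizations (min found %d)",
                 min_locs_per_bin, min(counts)))
  nr <- ceiling((max(records$y_nm) + 1) / render_pixel_nm)
  nc <- ceiling((max(records$x_nm) + 1) / render_pixel_nm)
  ffts <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    h <- bin_localizations(records$x_nm[sel], records$y_nm[sel],
                           render_pixel_nm, nr, nc)
    if (blur_px > 0) h <- gaussian_blur(h, blur_px)
    ffts[[b]] <- fft(h)
  }
  disp <- matrix(0, n_bins, 2L)   # (dx, dy) nm
  if (reference == "first") {
    for (b in 2:n_bins) {
      sh <- register_translation_fft(ffts[[1L]], ffts[[b]], upsample)
      disp[b, ] <- c(sh[2L], sh[1L]) * render_pixel_nm
    }
  } else {
    pairs <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
    meas <- matrix(0, nrow(pairs), 2L)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      sh <- register_translation_fft(ffts[[i]], ffts[[j]], upsample)
      meas[k, ] <- c(sh[2L], sh[1L]) * render_pixel_nm
    }
    # least squares: d_j - d_i = s_ij with d_1 = 0
    a <- matrix(0, nrow(pairs), n_bins - 1L)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (i > 1L) a[k, i - 1L] <- -1
      a[k, j - 1L] <- 1
    }
    disp[2:n_bins, 1L] <- qr.solve(a, meas[, 1L])
    disp[2:n_bins, 2L] <- qr.solve(a, meas[, 2L])
  }
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  frames <- seq_len(max_frame)
  interp_ends <- function(v) {
    out <- approx(centers, v, xout = frames, rule = 2)$y
    nb <- length(centers)
    lo <- frames < centers[1L]
    hi <- frames > centers[nb]
    slope1 <- (v[2L] - v[1L]) / (centers[2L] - centers[1L])
    slopen <- (v[nb] - v[nb - 1L]) / (centers[nb] - centers[nb - 1L])
    out[lo] <- v[1L] + slope1 * (frames[lo] - centers[1L])
    out[hi] <- v[nb] + slopen * (frames[hi] - centers[nb])
    out
  }
  dx <- interp_ends(disp[, 1L])
  dy <- interp_ends(disp[, 2L])
  # displacements are measured relative to bin 1; re-reference to frame 1
  dx <- dx - dx[1L]; dy <- dy - dy[1L]
  structure(list(displacement_nm = cbind(dx = dx, dy = dy),
                 bin_centers = centers, bin_displacement_nm = disp,
                 render_pixel_nm = render_pixel_nm),
            class = "drift_trace")
}

#' Apply (subtract) a drift trace
#'
#' @param records a localization `data.frame`.
#' @param trace a [estimate_drift()] result, or an `n_frames x 2` matrix
#'   of cumulative (dx, dy) displacements in nm.
#' @return records with `x_nm`, `y_nm` corrected
#'   (`x - dx(frame)`, `y - dy(frame)`).
#' @export
apply_drift <- function(records, trace) {
  d <- if (inherits(trace, "drift_trace")) trace$displacement_nm else trace
  f <- pmin(pmax(records$frame, 1L), nrow(d))
  records$x_nm <- records$x_nm - d[f, 1L]
  records$y_nm <- records$y_nm - d[f, 2L]
  records
}

#' Gaussian rendering of a localization dataset
#'
#' Every localization contributes a unit-integral 2-D Gaussian whose sigma
#' is its own localization uncertainty, so the rendering is representative
#' of the precision of each point; the image integral equals the record
#' count up to boundary loss.
#'
#' @param records a localization `data.frame`.
#' @param render_pixel_nm output pixel size; default 10 nm.
#' @param extent_nm `c(width, height)`; default covers all records.
#' @param amplitude `"unit"` (each record integrates to 1) or `"photons"`
#'   (weighted by photon count).
#' @param fixed_sigma_nm override the per-record sigma with a constant.
#' @return numeric matrix (row, col) at `render_pixel_nm` pitch.
#' @export
render_gaussian <- function(records, render_pixel_nm = 10, extent_nm = NULL,
                            amplitude = c("unit", "photons"),
                            fixed_sigma_nm = NULL) {
  amplitude <- match.arg(amplitude)
  if (!nrow(records)) stop("no records to render")
  if (is.null(extent_nm))
    extent_nm <- c(max(records$x_nm), max(records$y_nm)) + 3 * render_pixel_nm
  nr <- ceiling(extent_nm[2L] / render_pixel_nm)
  nc <- ceiling(extent_nm[1L] / render_pixel_nm)
  img <- matrix(0, nr, nc)
  sig <- if (!is.null(fixed_sigma_nm)) rep(fixed_sigma_nm, nrow(records))
         else records$uncertainty_nm
  if (any(is.na(sig))) stop("records need uncertainty_nm (or fixed_sigma_nm)")
  amp <- if (amplitude == "photons") records$photons else rep(1, nrow(records))
  for (i in seq_len(nrow(records)))
    img <- add_psf(img, records$x_nm[i], records$y_nm[i], amp[i],
                   sig[i], render_pixel_nm)
  img
}

#' Per-frame PSF nearest-neighbour separation
#'
#' Measures how well separated the active PSFs are within single frames -
#' the quantity that decides whether a labelling strategy risks
#' overlapping-PSF mislocalization. Uniformly samples `k` distinct frames,
#' detects and fits each frame's PSFs, and pools the within-frame
#' nearest-neighbour distances; frames with fewer than two fitted PSFs
#' contribute nothing.
#'
#' @param stack an [image_stack].
#' @param k number of frames to sample (default 10).
#' @param seed integer seed for the frame sample.
#' @param ... passed to [localize_stack()] machinery
#'   (`peak_threshold`, `psf_sigma_nm`, ...).
#' @param camera a [camera_model()].
#' @return list with `distances_nm` (pooled), `mean_nm`, `sem_nm`,
#'   `frames` (sampled frame indices), `per_frame` (list of per-frame
#'   distance vectors) and `fits` (list of the per-frame localization
#'   tables, e.g. for edge-corrected re-analyses).
#' @export
sample_frames_psf_separation <- function(stack, k = 10L, seed = NULL,
                                         camera = NULL, ...) {
  if (k > n_frames(stack)) stop("k exceeds the number of frames")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(camera))
    camera <- camera_model(pixel_size_nm = stack$pixel_size_nm)
  frames <- sort(sample.int(n_frames(stack), k))
  per_frame <- list()
  fits <- list()
  for (f in frames) {
    img <- get_frame(stack, f)
    cand <- detect_candidates(img)
    if (nrow(cand) < 2L) next
    loc <- fit_localizations(img, cand, frame = f, camera = camera, ...)
    if (nrow(loc) < 2L) next
    fits[[as.character(f)]] <- loc
    per_frame[[as.character(f)]] <-
      nearest_neighbor_distances(cbind(loc$x_nm, loc$y_nm))
  }
  d <- unlist(per_frame, use.names = FALSE) %||% numeric()
  list(distances_nm = d,
       mean_nm = if (length(d)) mean(d) else NA_real_,
       sem_nm = if (length(d) > 1L) sd(d) / sqrt(length(d)) else NA_real_,
       frames = frames, per_frame = per_frame, fits = fits)
}
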