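# Ground-truth synthetic microscopy simulator.
#
# Emulates the data the correlated STORM/homoFRET method consumes: a
# molecule field with diffuse, microclustered and nanoclustered populations
# of monomers and dimers/oligomers; a polarized TIRF image pair whose
# channel expectations satisfy the anisotropy equation exactly before
# noise; and a blinking-movie stack of two-state (on/off, bleachable)
# emitters imaged as pixel-integrated Gaussian PSFs under Poisson shot
# noise and Gaussian camera read noise, with optional linear stage drift.
# Every generator is deterministic given its seed.

#' Camera model
#'
#' @param pixel_size_nm effective pixel pitch; default 127 nm (EMCCD with
#'   60x/1.45 objective).
#' @param read_noise_e Gaussian read noise sigma, electrons rms.
#' @param gain_e_per_count electrons per digitizer count.
#' @param offset_counts dark offset added to every pixel (counts).
#' @param saturation_level digitizer saturation (counts, <= 2^16 - 1).
#' @return a `camera_model` list. EMCCD excess (multiplication) noise is
#'   deliberately not modelled; shot + read noise suffice for testing the
#'   estimators.
#' @export
camera_model <- function(pixel_size_nm = 127, read_noise_e = 1.6,
                         gain_e_per_count = 1, offset_counts = 100,
                         saturation_level = 65535L) {
  if (saturation_level > 2^16 - 1) stop("saturation_level exceeds 16-bit range")
  structure(list(pixel_size_nm = pixel_size_nm, read_noise_e = read_noise_e,
                 gain_e_per_count = gain_e_per_count,
                 offset_counts = offset_counts,
                 saturation_level = saturation_level),
            class = "camera_model")
}

#' Blinking kinetics of a photoswitchable emitter
#'
#' Memoryless two-state model: geometric on and off dwell times, with a
#' per-on-frame photobleaching probability. For artifact-free localization
#' the off state must live much longer than the on state, so a ratio below
#' 10 triggers a warning.
#'
#' @param mean_on_frames,mean_off_frames mean dwell times (frames).
#' @param bleach_probability_per_on probability of irreversible bleaching
#'   per frame spent on.
#' @param photons_per_frame_mean,photons_per_frame_sigma mean and sd of the
#'   lognormal per-frame photon yield while on.
#' @param psf_sigma_nm Gaussian PSF standard deviation; default 120 nm
#'   (~diffraction-limited for far-red emission at NA 1.45).
#' @return a `blink_kinetics` list.
#' @export
blink_kinetics <- function(mean_on_frames = 1, mean_off_frames = 150,
                           bleach_probability_per_on = 0.02,
                           photons_per_frame_mean = 2000,
                           photons_per_frame_sigma = 700,
                           psf_sigma_nm = 120) {
  stop_if_not_scalar_pos(mean_on_frames, "mean_on_frames")
  stop_if_not_scalar_pos(mean_off_frames, "mean_off_frames")
  if (mean_off_frames / mean_on_frames < 10)
    warning("mean_off_frames / mean_on_frames < 10: expect overlapping PSFs")
  structure(list(mean_on_frames = mean_on_frames,
                 mean_off_frames = mean_off_frames,
                 bleach_probability_per_on = bleach_probability_per_on,
                 photons_per_frame_mean = photons_per_frame_mean,
                 photons_per_frame_sigma = photons_per_frame_sigma,
                 psf_sigma_nm = psf_sigma_nm),
            class = "blink_kinetics")
}

#' Generate a ground-truth molecule field
#'
#' Molecules are a homogeneous Poisson "diffuse" background plus, for each
#' cluster, a fixed number of molecules placed uniformly inside a disc.
#' Each molecule carries an oligomeric state (`monomer`, `dimer`,
#' `oligomer`), assigned Bernoulli per molecule from the relevant
#' oligomer fraction (dimers and higher oligomers are split by
#' `dimer_fraction`; both engage in homoFRET).
#'
#' @param field_size_nm `c(width, height)` of the field (nm).
#' @param diffuse_density_um2 intensity of the diffuse background
#'   (molecules per square micron).
#' @param cluster_spec `NULL`, or a `data.frame` with columns `x_nm`,
#'   `y_nm` (disc centre), `diameter_nm`, `n` (molecules) and optionally
#'   `oligomer_fraction` (default 0) and `class` (free-text label such as
#'   `"nano"` / `"micro"`).
#' @param diffuse_oligomer_fraction fraction of diffuse molecules in a
#'   self-associated (dimer/oligomer) state.
#' @param dimer_fraction fraction of self-associated molecules labelled
#'   `dimer` rather than `oligomer` (anisotropy treats them alike).
#' @param margin_nm keep the diffuse background this far from the field
#'   edges (emulates a cell not touching the frame border; avoids
#'   edge-clipped PSFs in downstream fitting).
#' @param seed integer seed; the field is reproducible given the seed.
#' @return a `molecule_field`: list with `molecules`
#'   (`data.frame(x_nm, y_nm, state, cluster_id)`, `cluster_id` 0 for
#'   diffuse), `field_size_nm`, `cluster_spec`, `seed`. Cluster molecules
#'   falling outside the field are dropped with a warning.
#' @export
generate_molecule_field <- function(field_size_nm, diffuse_density_um2 = 0,
                                    cluster_spec = NULL,
                                    diffuse_oligomer_fraction = 0,
                                    dimer_fraction = 0.5, margin_nm = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- field_size_nm[1L]; h <- field_size_nm[2L]
  if (w <= 0 || h <= 0) stop("field dimensions must be positive")
  if (2 * margin_nm >= min(w, h)) stop("margin_nm too large for the field")
  assign_state <- function(n, olig_frac) {
    assoc <- runif(n) < olig_frac
    state <- rep("monomer", n)
    if (any(assoc))
      state[assoc] <- ifelse(runif(sum(assoc)) < dimer_fraction,
                             "dimer", "oligomer")
    state
  }
  # diffuse Poisson background
  lambda_nm2 <- diffuse_density_um2 / 1e6
  wi <- w - 2 * margin_nm; hi <- h - 2 * margin_nm
  n_diff <- rpois(1L, lambda_nm2 * wi * hi)
  mol <- data.frame(x_nm = runif(n_diff, margin_nm, w - margin_nm),
                    y_nm = runif(n_diff, margin_nm, h - margin_nm),
                    state = assign_state(n_diff, diffuse_oligomer_fraction),
                    cluster_id = rep(0L, n_diff))
  # clustered populations: uniform in a disc
  if (!is.null(cluster_spec) && nrow(cluster_spec)) {
    if (is.null(cluster_spec$oligomer_fraction))
      cluster_spec$oligomer_fraction <- 0
    if (is.null(cluster_spec$class)) cluster_spec$class <- NA_character_
    if (any(cluster_spec$diameter_nm <= 0))
      stop("cluster diameters must be positive")
    for (k in seq_len(nrow(cluster_spec))) {
      cs <- cluster_spec[k, ]
      rad <- cs$diameter_nm / 2 * sqrt(runif(cs$n))
      ang <- runif(cs$n, 0, 2 * pi)
      x <- cs$x_nm + rad * cos(ang); y <- cs$y_nm + rad * sin(ang)
      inside <- x >= 0 & x <= w & y >= 0 & y <= h
      if (!all(inside))
        warning(sprintf("cluster %d extends outside the field; %d molecule(s) clipped",
                        k, sum(!inside)))
      mol <- rbind(mol, data.frame(
        x_nm = x[inside], y_nm = y[inside],
        state = assign_state(sum(inside), cs$oligomer_fraction),
        cluster_id = rep(k, sum(inside))))
    }
  }
  structure(list(molecules = mol, field_size_nm = c(w, h),
                 cluster_spec = cluster_spec, seed = seed),
            class = "molecule_field")
}

#' @export
print.molecule_field <- function(x, ...) {
  cat(sprintf("<molecule_field> %d molecules in %.0f x %.0f nm (%d cluster(s))\n",
              nrow(x$molecules), x$field_size_nm[1L], x$field_size_nm[2L],
              if (is.null(x$cluster_spec)) 0L else nrow(x$cluster_spec)))
  invisible(x)
}

# Bin molecules onto the camera grid; returns list(n_total, n_assoc) count
# matrices. Grid covers the field with ceiling(extent / pixel) pixels.
bin_molecules <- function(field, pixel_size_nm) {
  nr <- max(1L, ceiling(field$field_size_nm[2L] / pixel_size_nm))
  nc <- max(1L, ceiling(field$field_size_nm[1L] / pixel_size_nm))
  m <- field$molecules
  row <- pmin(nr, floor(m$y_nm / pixel_size_nm) + 1L)
  col <- pmin(nc, floor(m$x_nm / pixel_size_nm) + 1L)
  idx <- (col - 1L) * nr + row
  n_total <- matrix(tabulate(idx, nbins = nr * nc), nr, nc)
  assoc <- m$state != "monomer"
  n_assoc <- matrix(tabulate(idx[assoc], nbins = nr * nc), nr, nc)
  list(n_total = n_total, n_assoc = n_assoc)
}

#' Ground-truth anisotropy map of a molecule field
#'
#' Per camera pixel, the oligomer-fraction-weighted anisotropy
#' `r = (n_monomer * r_monomer + n_assoc * r_oligomer) / n`; pixels with no
#' molecules are masked.
#'
#' @param field a [generate_molecule_field()] result.
#' @param camera_pixel_nm camera pixel pitch (nm).
#' @param r_monomer,r_oligomer anisotropy of monomers and of
#'   dimers/oligomers; defaults 0.40 and 0.15 (midpoints of the ranges
#'   typical of clustered monomeric vs oligomeric receptor regions).
#' @return an [anisotropy_map] (with `g_factor = NA`).
#' @export
true_anisotropy_map <- function(field, camera_pixel_nm = 127,
                                r_monomer = 0.40, r_oligomer = 0.15) {
  b <- bin_molecules(field, camera_pixel_nm)
  r <- matrix(NA_real_, nrow(b$n_total), ncol(b$n_total))
  occ <- b$n_total > 0
  r[occ] <- ((b$n_total[occ] - b$n_assoc[occ]) * r_monomer +
               b$n_assoc[occ] * r_oligomer) / b$n_total[occ]
  anisotropy_map(r, occ, camera_pixel_nm)
}

# Apply camera: expected photons -> recorded counts.
camera_counts <- function(expected_photons, camera, noise) {
  if (noise) {
    e <- rpois(length(expected_photons), expected_photons)
    if (camera$read_noise_e > 0)
      e <- e + rnorm(length(e), 0, camera$read_noise_e)
    counts <- round(e / camera$gain_e_per_count + camera$offset_counts)
  } else {
    counts <- expected_photons / camera$gain_e_per_count + camera$offset_counts
  }
  counts <- pmin(pmax(counts, 0), camera$saturation_level)
  matrix(counts, nrow(expected_photons), ncol(expected_photons))
}

#' Render a polarized TIRF image pair from a molecule field
#'
#' Per camera pixel the expected total signal is
#' `S = brightness_per_molecule * n_molecules`, split between the channels
#' so the anisotropy equation holds exactly before noise:
#' `I_par = S (1 + 2 r) / 3` and `I_perp = S (1 - r) / (3 G)`, where `r` is
#' the pixel's ground-truth anisotropy and G the simulated detection-path
#' imbalance. Poisson shot noise and Gaussian read noise are then applied
#' per channel.
#'
#' @inheritParams true_anisotropy_map
#' @param g_factor simulated detection G factor (the perpendicular channel
#'   is recorded with 1/G sensitivity).
#' @param brightness_per_molecule expected total photons contributed by one
#'   molecule over the exposure.
#' @param camera a [camera_model()].
#' @param noise apply shot/read noise and quantization (`TRUE`) or return
#'   exact expectations (`FALSE`).
#' @param seed integer seed.
#' @return list with `pair` (a [polarized_pair]) and `true_r` (an
#'   [anisotropy_map] of the ground truth).
#' @export
render_polarized_pair <- function(field, g_factor = 0.93, r_monomer = 0.40,
                                  r_oligomer = 0.15,
                                  brightness_per_molecule = 2000,
                                  camera = camera_model(), noise = TRUE,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (r in c(r_monomer, r_oligomer))
    if (r <= -0.5 || r >= 1)
      stop("anisotropy values must lie in the open interval (-0.5, 1)")
  truth <- true_anisotropy_map(field, camera$pixel_size_nm,
                               r_monomer, r_oligomer)
  b <- bin_molecules(field, camera$pixel_size_nm)
  s <- brightness_per_molecule * b$n_total
  r <- truth$r
  r[!truth$valid_mask] <- 0   # S = 0 there anyway
  ipar <- s * (1 + 2 * r) / 3
  iperp <- s * (1 - r) / (3 * g_factor)
  pair <- polarized_pair(camera_counts(ipar, camera, noise),
                         camera_counts(iperp, camera, noise),
                         pixel_size_nm = camera$pixel_size_nm,
                         saturation_level = camera$saturation_level)
  list(pair = pair, true_r = truth)
}

#' Simulate two-state blinking trajectories
#'
#' Each molecule follows a memoryless on/off Markov chain (geometric dwell
#' times) started from its stationary distribution, with irreversible
#' bleaching applied per on-frame. Photon yields per on-frame are lognormal.
#'
#' @param n_molecules number of emitters.
#' @param kinetics a [blink_kinetics()].
#' @param n_frames number of acquisition frames.
#' @param seed integer seed.
#' @return `data.frame(frame, molecule, photons)`, one row per emitting
#'   molecule-frame.
#' @export
simulate_blinking <- function(n_molecules, kinetics, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  p_on <- kinetics$mean_on_frames /
    (kinetics$mean_on_frames + kinetics$mean_off_frames)
  p_off_to_on <- 1 / kinetics$mean_off_frames
  p_on_to_off <- 1 / kinetics$mean_on_frames
  m <- kinetics$photons_per_frame_mean
  s <- kinetics$photons_per_frame_sigma
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  state <- ifelse(runif(n_molecules) < p_on, 1L, 0L)  # 1 on, 0 off, -1 bleached
  out_frame <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    on <- which(state == 1L)
    if (length(on)) {
      out_frame[[f]] <- data.frame(
        frame = f, molecule = on,
        photons = rlnorm(length(on), meanlog, sdlog))
      # bleaching per on-frame
      bleach <- runif(length(on)) < kinetics$bleach_probability_per_on
      state[on[bleach]] <- -1L
    }
    # dwell-time transitions for next frame
    on2 <- which(state == 1L)
    off <- which(state == 0L)
    if (length(on2)) {
      leave <- runif(length(on2)) < p_on_to_off
      state[on2[leave]] <- 0L
    }
    if (length(off)) {
      wake <- runif(length(off)) < p_off_to_on
      state[off[wake]] <- 1L
    }
  }
  out <- do.call(rbind, out_frame)
  if (is.null(out)) out <- data.frame(frame = integer(), molecule = integer(),
                                      photons = numeric())
  out
}

# One-axis pixel-integration fractions of a Gaussian PSF: fraction of a
# unit-intensity Gaussian centred at pos_nm falling into pixels 1..n of
# pitch a (difference of normal CDFs; matches the fitting model exactly).
psf_axis_fractions <- function(pos_nm, sigma_nm, pixel_nm, n) {
  edges <- (0:n) * pixel_nm
  p <- pnorm((edges - pos_nm) / sigma_nm)
  diff(p)
}

# Add one PSF (total photons N) to an expectation image, in place-ish.
add_psf <- function(img, x_nm, y_nm, n_photons, sigma_nm, pixel_nm) {
  nr <- nrow(img); nc <- ncol(img)
  ey <- psf_axis_fractions(y_nm, sigma_nm, pixel_nm, nr)
  ex <- psf_axis_fractions(x_nm, sigma_nm, pixel_nm, nc)
  # restrict to +-6 sigma for speed (truncated mass ~2e-9)
  rad <- 6 * sigma_nm
  rows <- max(1L, floor((y_nm - rad) / pixel_nm) + 1L):min(nr, floor((y_nm + rad) / pixel_nm) + 1L)
  cols <- max(1L, floor((x_nm - rad) / pixel_nm) + 1L):min(nc, floor((x_nm + rad) / pixel_nm) + 1L)
  img[rows, cols] <- img[rows, cols] + n_photons * outer(ey[rows], ex[cols])
  img
}

#' Render a STORM blinking-movie stack
#'
#' Simulates the acquisition of a super-resolution dataset: molecules of a
#' [generate_molecule_field()] blink per [simulate_blinking()]; while on,
#' each emits a pixel-integrated 2-D Gaussian PSF at its position plus the
#' cumulative stage drift; the camera applies shot noise, read noise,
#' offset and quantization. The exact emitting positions per frame are
#' returned as ground truth.
#'
#' @param field a [generate_molecule_field()] result.
#' @param kinetics a [blink_kinetics()].
#' @param camera a [camera_model()].
#' @param n_frames frames to acquire (the reference protocol uses
#'   10,000-15,000 at 30 ms; simulations use fewer).
#' @param drift_per_frame_nm either `c(dx, dy)` nm per frame (cumulative
#'   drift in frame k is `(k - 1) * rate`) or an `n_frames x 2` matrix of
#'   per-frame cumulative displacements.
#' @param noise apply camera noise (`TRUE`) or return exact expectations.
#' @param seed integer seed.
#' @return list with `stack` (an [image_stack]), `truth`
#'   (`data.frame(frame, molecule, x_nm, y_nm, photons)` of emitting,
#'   drift-shifted positions) and `drift_truth` (`n_frames x 2` matrix of
#'   cumulative displacements).
#' @export
render_storm_stack <- function(field, kinetics = blink_kinetics(),
                               camera = camera_model(), n_frames = 1000L,
                               drift_per_frame_nm = c(0, 0), noise = TRUE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  drift <- if (is.matrix(drift_per_frame_nm)) {
    if (nrow(drift_per_frame_nm) != n_frames)
      stop("drift matrix must have n_frames rows")
    drift_per_frame_nm
  } else {
    cbind((seq_len(n_frames) - 1L) * drift_per_frame_nm[1L],
          (seq_len(n_frames) - 1L) * drift_per_frame_nm[2L])
  }
  blinks <- simulate_blinking(nrow(field$molecules), kinetics, n_frames)
  nr <- max(1L, ceiling(field$field_size_nm[2L] / camera$pixel_size_nm))
  nc <- max(1L, ceiling(field$field_size_nm[1L] / camera$pixel_size_nm))
  frames <- array(0, c(n_frames, nr, nc))
  truth <- blinks
  truth$x_nm <- field$molecules$x_nm[blinks$molecule] + drift[blinks$frame, 1L]
  truth$y_nm <- field$molecules$y_nm[blinks$molecule] + drift[blinks$frame, 2L]
  split_idx <- split(seq_len(nrow(truth)), truth$frame)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, nr, nc)
    rows <- split_idx[[as.character(f)]]
    for (i in rows)
      img <- add_psf(img, truth$x_nm[i], truth$y_nm[i], truth$photons[i],
                     kinetics$psf_sigma_nm, camera$pixel_size_nm)
    frames[f, , ] <- camera_counts(img, camera, noise)
  }
  list(stack = image_stack(frames, camera$pixel_size_nm),
       truth = truth[, c("frame", "molecule", "x_nm", "y_nm", "photons")],
       drift_truth = drift)
}
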