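cam0 <- camera_model(offset_counts = 0, read_noise_e = 0)

psf_frame <- function(x_nm, y_nm, n_photons = 2000, bg = 0, nr = 15,
                      nc = 15, sigma = 120, pixel = 127) {
  img <- matrix(0, nr, nc)
  for (i in seq_along(x_nm))
    img <- corrfret:::add_psf(img, x_nm[i], y_nm[i], n_photons, sigma, pixel)
  img + bg
}

test_that("candidate detection finds isolated PSFs and nothing else", {
  expect_equal(nrow(detect_candidates(matrix(7, 32, 32))), 0L)

  one <- psf_frame(16.2 * 127, 15.4 * 127, 3000, nr = 32, nc = 32)
  d1 <- detect_candidates(one)
  expect_equal(nrow(d1), 1L)
  pk <- which(one == max(one), arr.ind = TRUE)
  expect_equal(c(d1$row, d1$col), unname(pk[1, ]))

  two <- one + psf_frame(6.2 * 127, 15.4 * 127, 3000, nr = 32, nc = 32)
  expect_equal(nrow(detect_candidates(two)), 2L)
})

test_that("noise-free PSF fits recover position to < 0.01 nm", {
  x0 <- 7.3 * 127; y0 <- 8.1 * 127
  img <- psf_frame(x0, y0, 2000, bg = 10)
  fit <- fit_localizations(img, data.frame(row = 8, col = 8), camera = cam0,
                           gof_p_threshold = 0)
  expect_equal(nrow(fit), 1L)
  expect_lt(abs(fit$x_nm - x0), 0.01)
  expect_lt(abs(fit$y_nm - y0), 0.01)
  expect_equal(fit$sigma_nm, 120, tolerance = 1e-3)
  expect_equal(fit$photons, 2000, tolerance = 1e-3)
})

test_that("overlapping emitters fail the goodness-of-fit screen", {
  set.seed(2)
  pair <- psf_frame(c(6.9, 7.9) * 127, c(7.5, 7.5) * 127, 2000, bg = 10)
  img <- matrix(rpois(225, pair), 15, 15)
  rejected <- fit_localizations(img, data.frame(row = 8, col = 8),
                                camera = cam0)
  expect_equal(nrow(rejected), 0L)
  kept <- fit_localizations(img, data.frame(row = 8, col = 8),
                            camera = cam0, gof_p_threshold = 0)
  expect_lt(kept$gof_p, 1e-3)
  # single-emitter control passes
  sing <- matrix(rpois(225, psf_frame(7.4 * 127, 7.5 * 127, 2000, bg = 10)),
                 15, 15)
  expect_equal(nrow(fit_localizations(sing, data.frame(row = 8, col = 8),
                                      camera = cam0)), 1L)
})

test_that("precision/photon filtering keeps exactly the in-band records", {
  toy <- make_toy_records()
  kept <- filter_localizations(toy, 6, 40, photon_min = 100)
  # uncertainties 3, 5.9, 6 are noise-band; 40.1, 45 beyond; photons 50 cut
  expect_equal(kept$frame, c(4L, 5L, 6L, 7L))
  expect_identical(kept, toy[toy$frame %in% 4:7, ])
  expect_lte(nrow(kept), nrow(toy))
  expect_equal(nrow(filter_localizations(toy, 6, 40, photon_min = 1e6)), 0L)
})

test_that("duplicate merging is transitive, weighted and idempotent", {
  rec <- localization_table(
    frame = c(3L, 1L, 5L),
    x_nm = c(100.0, 100.4, 500),
    y_nm = c(200.0, 200.3, 500),
    sigma_nm = 120, photons = c(1000, 3000, 500),
    uncertainty_nm = c(12, 8, 20), background = 5)
  m <- merge_duplicates(rec, radius_nm = 1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$x_nm[1], (100.0 * 1000 + 100.4 * 3000) / 4000)
  expect_equal(m$y_nm[1], (200.0 * 1000 + 200.3 * 3000) / 4000)
  expect_equal(m$photons[1], 4000)
  expect_equal(m$frame[1], 1L)            # earliest frame
  expect_equal(m$uncertainty_nm[1], 8)    # minimum uncertainty
  expect_identical(merge_duplicates(m, 1), m)

  # two records 5 nm apart stay distinct
  far <- localization_table(frame = c(1L, 1L), x_nm = c(0, 5), y_nm = c(0, 0),
                            photons = 100, uncertainty_nm = 10)
  expect_equal(nrow(merge_duplicates(far, 1)), 2L)

  # chain A-B-C at 0.8 nm spacing collapses by transitive closure
  chain <- localization_table(frame = 1:3, x_nm = c(0, 0.8, 1.6),
                              y_nm = 0, photons = 100, uncertainty_nm = 10)
  expect_equal(nrow(merge_duplicates(chain, 1)), 1L)
})

test_that("drift traces apply, invert and respect nulls", {
  rec <- make_drift_records(201, rate = c(0, 0), n_frames = 600)
  zero <- matrix(0, 600, 2)
  expect_identical(apply_drift(rec, zero), rec)

  tr <- estimate_drift(rec, n_bins = 5, render_pixel_nm = 10, upsample = 50)
  expect_equal(unname(tr$displacement_nm[1, ]), c(0, 0))
  expect_lt(max(abs(tr$displacement_nm)), 5)

  # apply then un-apply is the identity
  some <- cbind(seq(0, 30, length.out = 600), seq(0, -12, length.out = 600))
  back <- apply_drift(apply_drift(rec, some), -some)
  expect_equal(back$x_nm, rec$x_nm)
  expect_equal(back$y_nm, rec$y_nm)
})

test_that("injected drift is recovered and correction reduces error", {
  rate <- c(0.05, -0.03)
  rec <- make_drift_records(301, rate = rate, n_frames = 1200)
  tr <- estimate_drift(rec, n_bins = 12, render_pixel_nm = 10,
                       upsample = 100)
  truth <- cbind((seq_len(1200) - 1) * rate[1], (seq_len(1200) - 1) * rate[2])
  # trace tracks the injected line
  expect_lt(max(abs(tr$displacement_nm - truth)), 8)
  corrected <- apply_drift(rec, tr)
  # mean displacement error shrinks substantially after correction
  resid_unc <- mean(abs(rec$x_nm - (rec$x_nm - truth[rec$frame, 1])))
  expect_gt(resid_unc, 0)  # sanity
  drift_err_unc <- mean(abs(truth[rec$frame, 1]))
  drift_err_cor <- mean(abs(truth[rec$frame, 1] -
                              tr$displacement_nm[rec$frame, 1]))
  expect_lt(drift_err_cor, drift_err_unc / 5)

  # reversing the acquisition negates the trace
  rev_rec <- rec
  rev_rec$frame <- max(rec$frame) + 1L - rec$frame
  tr_rev <- estimate_drift(rev_rec, n_bins = 12, render_pixel_nm = 10,
                           upsample = 100)
  end_fwd <- tr$displacement_nm[1200, ]
  end_rev <- tr_rev$displacement_nm[1200, ]
  expect_equal(unname(end_rev), -unname(end_fwd), tolerance = 0.15)

  expect_error(estimate_drift(rec[1:100, ], n_bins = 10,
                              min_locs_per_bin = 50), "localizations")
})

test_that("Gaussian rendering integrates to the record count", {
  one <- localization_table(frame = 1L, x_nm = 500, y_nm = 400,
                            photons = 1000, uncertainty_nm = 15)
  img1 <- render_gaussian(one, render_pixel_nm = 10,
                          extent_nm = c(1000, 1000))
  expect_equal(sum(img1), 1, tolerance = 1e-3)

  two <- rbind(one, one)
  img2 <- render_gaussian(two, render_pixel_nm = 10,
                          extent_nm = c(1000, 1000))
  expect_equal(img2, 2 * img1)

  # dense cluster renders with its maximum at the cluster centre
  set.seed(6)
  cl <- localization_table(frame = 1L,
                           x_nm = rnorm(200, 600, 20),
                           y_nm = rnorm(200, 700, 20),
                           photons = 1000, uncertainty_nm = 12)
  img <- render_gaussian(cl, render_pixel_nm = 10,
                         extent_nm = c(1200, 1200))
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_lt(abs(pk[1, "col"] * 10 - 600), 30)
  expect_lt(abs(pk[1, "row"] * 10 - 700), 30)
})

test_that("per-frame PSF separation handles constructed geometries", {
  # frames of exactly two PSFs a fixed distance apart -> SEM 0
  d_true <- 6 * 127
  frames <- array(0, c(4, 24, 24))
  for (f in 1:4)
    frames[f, , ] <- psf_frame(c(8, 8 + 6) * 127 - 63.5, c(9, 9) * 127 - 63.5,
                               3000, nr = 24, nc = 24)
  st <- image_stack(round(frames), 127)
  sep <- sample_frames_psf_separation(st, k = 4, seed = 1,
                                      gof_p_threshold = 0)
  expect_equal(length(sep$distances_nm), 8L)
  expect_equal(unname(sep$mean_nm), d_true, tolerance = 1e-3)
  expect_lt(sep$sem_nm, 1e-6)

  sep2 <- sample_frames_psf_separation(st, k = 4, seed = 1,
                                       gof_p_threshold = 0)
  expect_identical(sep$distances_nm, sep2$distances_nm)
  expect_error(sample_frames_psf_separation(st, k = 10), "exceeds")
})

test_that("per-frame PSF separation follows the 2-D Poisson expectation", {
  # sparse frames; compare edge-corrected mean NN distance of the fitted
  # PSFs with 0.5/sqrt(lambda) at the fitted density (minus-sampling
  # boundary correction: central points only, neighbours anywhere)
  w <- 128 * 127; marg <- 500
  ratios <- vapply(1:3, function(s) {
    f <- generate_molecule_field(c(w, w), diffuse_density_um2 = 28,
                                 margin_nm = marg, seed = 50 + s)
    kin <- blink_kinetics(mean_off_frames = 600,
                          photons_per_frame_mean = 5000,
                          photons_per_frame_sigma = 500,
                          bleach_probability_per_on = 0)
    st <- render_storm_stack(f, kin, camera_model(), n_frames = 20,
                             seed = 150 + s)
    sep <- sample_frames_psf_separation(st$stack, k = 10, seed = 250 + s)
    nfit <- sum(vapply(sep$fits, nrow, 1L))
    lam_hat <- (nfit / length(sep$fits)) / ((w - 2 * marg)^2)
    guard <- 1.2 * 0.5 / sqrt(lam_hat)
    dc <- unlist(lapply(sep$fits, function(lo) {
      dn <- nearest_neighbor_distances(lo)
      cen <- lo$x_nm > marg + guard & lo$x_nm < w - marg - guard &
        lo$y_nm > marg + guard & lo$y_nm < w - marg - guard
      dn[cen]
    }))
    mean(dc) / (0.5 / sqrt(lam_hat))
  }, numeric(1L))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("PSF separation drops as active-emitter density rises", {
  w <- 64 * 127
  means <- vapply(c(40, 120, 360), function(dens) {
    f <- generate_molecule_field(c(w, w), diffuse_density_um2 = dens,
                                 margin_nm = 450, seed = 71)
    kin <- blink_kinetics(mean_off_frames = 600,
                          photons_per_frame_mean = 5000,
                          photons_per_frame_sigma = 500,
                          bleach_probability_per_on = 0)
    st <- render_storm_stack(f, kin, camera_model(), n_frames = 12,
                             seed = 72)
    sample_frames_psf_separation(st$stack, k = 8, seed = 73)$mean_nm
  }, numeric(1L))
  expect_true(all(diff(means) < 0))
})
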