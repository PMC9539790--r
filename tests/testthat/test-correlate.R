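mk_map <- function(r, mask = NULL, px = 127) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(r), ncol(r))
  anisotropy_map(r, mask, px)
}

test_that("no-interpolation upscaling replicates values exactly", {
  # 1x1 map at integer scale k -> k x k constant block
  up <- upscale_anisotropy(mk_map(matrix(0.3, 1, 1), px = 100),
                           render_pixel_nm = 20)
  expect_identical(dim(up$r), c(5L, 5L))
  expect_true(all(up$r == 0.3))

  # unique-valued source: output value set == input value set
  src <- matrix(seq(0.1, 0.9, length.out = 9), 3, 3)
  up3 <- upscale_anisotropy(mk_map(src, px = 127), render_pixel_nm = 10)
  expect_identical(dim(up3$r), c(38L, 38L))
  expect_setequal(unique(as.vector(up3$r)), as.vector(src))

  # mask upscales identically to values
  msk <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  upm <- upscale_anisotropy(mk_map(matrix(1:4 / 10, 2, 2), msk, px = 40),
                            render_pixel_nm = 10)
  expect_identical(upm$valid_mask, is.na(upm$r) == FALSE)

  expect_error(upscale_anisotropy(mk_map(matrix(0.2, 2, 2), px = 10), 20),
               "smaller")
})

test_that("upscale then per-source-pixel majority vote restores the map", {
  set.seed(3)
  src <- matrix(runif(64, 0, 0.5), 8, 8)
  up <- upscale_anisotropy(mk_map(src, px = 127), render_pixel_nm = 10)
  down <- matrix(NA_real_, 8, 8)
  ridx <- floor(((seq_len(nrow(up$r)) - 0.5) * 10) / 127) + 1L
  cidx <- floor(((seq_len(ncol(up$r)) - 0.5) * 10) / 127) + 1L
  for (i in 1:8) for (j in 1:8) {
    vals <- up$r[ridx == i, cidx == j]
    tab <- table(vals)
    down[i, j] <- as.numeric(names(tab)[which.max(tab)])
  }
  expect_equal(down, src, tolerance = 1e-12)
})

test_that("localizations inherit the anisotropy of their camera pixel", {
  r <- matrix(seq(0.05, 0.45, length.out = 9), 3, 3)
  mask <- matrix(TRUE, 3, 3); mask[2, 2] <- FALSE
  map <- mk_map(r, mask)
  rec <- localization_table(
    frame = 1:4,
    x_nm = c(63.5, 127, 200, 380),   # centre px1 | exact boundary | px2 | px3
    y_nm = c(63.5, 63.5, 190, 380),
    photons = 1000, uncertainty_nm = 10)
  ann <- assign_anisotropy(rec, map)
  expect_equal(ann$cam_col, c(1L, 2L, 2L, 3L))
  expect_equal(ann$r[1], r[1, 1])
  expect_equal(ann$r[2], r[1, 2])     # boundary follows the floor convention
  expect_false(ann$r_valid[3])        # masked pixel (2,2) flagged
  expect_true(ann$r_valid[4])

  outside <- localization_table(frame = 1L, x_nm = 500, y_nm = 50,
                                photons = 1, uncertainty_nm = 1)
  expect_error(assign_anisotropy(outside, map), "extent")
})

test_that("annotation equals sampling the upscaled grid (registration consistency)", {
  set.seed(14)
  src <- matrix(runif(100, 0, 0.5), 10, 10)
  mask <- matrix(runif(100) > 0.2, 10, 10)
  map <- mk_map(src, mask)
  up <- upscale_anisotropy(map, render_pixel_nm = 10)
  rec <- localization_table(frame = 1L,
                            x_nm = runif(300, 0, 10 * 127 - 1e-6),
                            y_nm = runif(300, 0, 10 * 127 - 1e-6),
                            photons = 1, uncertainty_nm = 1)
  ann <- assign_anisotropy(rec, map)
  rr <- pmin(floor(rec$y_nm / 10) + 1L, nrow(up$r))
  cc <- pmin(floor(rec$x_nm / 10) + 1L, ncol(up$r))
  # the camera pitch (127) is not a multiple of the render pitch (10), so
  # render pixels straddling a camera-pixel boundary legitimately disagree
  # with the direct camera assignment; equality holds off the straddle set
  clean <- floor(((rr - 0.5) * 10) / 127) == floor(rec$y_nm / 127) &
    floor(((cc - 0.5) * 10) / 127) == floor(rec$x_nm / 127)
  expect_gt(mean(clean), 0.8)
  expect_identical(ann$r[clean], up$r[cbind(rr, cc)][clean])
  expect_identical(ann$r_valid[clean], up$valid_mask[cbind(rr, cc)][clean])
})

test_that("composition fractions sum to one in occupied bins", {
  map <- mk_map(matrix(c(0.12, 0.42), 1, 2))
  rec <- localization_table(frame = 1L,
                            x_nm = c(rep(60, 30), rep(190, 10)),
                            y_nm = rep(60, 40), photons = 1,
                            uncertainty_nm = 1)
  ann <- assign_anisotropy(rec, map)
  ann$class <- c(rep("diffuse", 30), rep("nanocluster", 10))
  comp <- composition_by_anisotropy(ann, bin_edges = seq(0, 0.5, 0.05))
  occ <- comp$n > 0
  sums <- rowSums(comp[occ, c("frac_nanocluster", "frac_microcluster",
                              "frac_diffuse")])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(is.na(comp$frac_diffuse[!occ])))
  expect_equal(comp$frac_diffuse[comp$bin_lo == 0.10], 1)
  expect_equal(comp$frac_nanocluster[comp$bin_lo == 0.40], 1)
})

test_that("single-class datasets give fraction one in every occupied bin", {
  set.seed(15)
  map <- mk_map(matrix(runif(25, 0, 0.5), 5, 5))
  rec <- localization_table(frame = 1L, x_nm = runif(200, 0, 635 - 1),
                            y_nm = runif(200, 0, 635 - 1),
                            photons = 1, uncertainty_nm = 1)
  ann <- assign_anisotropy(rec, map)
  ann$class <- "microcluster"
  comp <- composition_by_anisotropy(ann)
  expect_true(all(comp$frac_microcluster[comp$n > 0] == 1))
})

test_that("nearest-neighbour maps correlate with planted density contrast", {
  # pixel with one localization: median NN = that localization's distance
  map <- mk_map(matrix(c(0.1, 0.4), 1, 2))
  rec <- localization_table(frame = 1L, x_nm = c(30, 40, 200),
                            y_nm = c(60, 60, 60), photons = 1,
                            uncertainty_nm = 1)
  out <- nn_map_and_correlation(rec, map)
  expect_equal(out$nn_map[1, 2], 160)
  expect_equal(out$nn_map[1, 1], 10)

  # high-r pixels seeded with dense points -> negative r vs NN correlation
  set.seed(16)
  r <- matrix(runif(64, 0, 0.5), 8, 8)
  xs <- c(); ys <- c()
  for (i in 1:8) for (j in 1:8) {
    n <- if (r[i, j] > 0.25) 40 else 6
    xs <- c(xs, runif(n, (j - 1) * 127, j * 127 - 1e-9))
    ys <- c(ys, runif(n, (i - 1) * 127, i * 127 - 1e-9))
  }
  rec2 <- localization_table(frame = 1L, x_nm = xs, y_nm = ys,
                             photons = 1, uncertainty_nm = 1)
  out2 <- nn_map_and_correlation(rec2, mk_map(r))
  expect_lt(out2$pearson, -0.3)

  # zero-variance NN map flags an undefined correlation
  map3 <- mk_map(matrix(c(0.1, 0.4, 0.2), 1, 3))
  same <- localization_table(frame = 1L, x_nm = c(30, 50, 287, 307),
                             y_nm = 60, photons = 1, uncertainty_nm = 1)
  expect_warning(res <- nn_map_and_correlation(same, map3), "variance")
  expect_true(is.na(res$pearson))
})

test_that("Costes thresholding recovers colocalization under background", {
  set.seed(17)
  i1 <- matrix(runif(128^2, 0, 100), 128)
  expect_equal(costes_pearson(i1, i1)$pearson, 1.0, tolerance = 1e-9)

  # independent images: near-zero coefficient
  nulls <- vapply(1:5, function(s) {
    set.seed(100 + s)
    a <- matrix(runif(128^2, 0, 100), 128)
    b <- matrix(runif(128^2, 0, 100), 128)
    costes_pearson(a, b)$pearson
  }, numeric(1L))
  expect_true(all(abs(nulls) < 0.1))

  # img2 = img1 plus strong uncorrelated background confined to the dim
  # (sub-threshold) region: Costes recovers the true colocalization that
  # the naive full-image coefficient washes out
  set.seed(18)
  blob <- matrix(FALSE, 128, 128); blob[40:90, 40:90] <- TRUE
  sig <- matrix(0, 128, 128)
  sig[blob] <- runif(sum(blob), 80, 160)
  img1 <- sig + matrix(runif(128^2, 0, 8), 128)
  img2 <- sig + matrix(runif(128^2, 0, 8), 128)
  img2[!blob] <- runif(sum(!blob), 0, 150)   # independent sub-threshold haze
  cp <- costes_pearson(img1, img2)
  expect_gt(cp$pearson, cp$pearson_full)
  expect_gt(cp$pearson, 0.85)

  expect_error(costes_pearson(matrix(1, 4, 4), matrix(1:16, 4, 4)),
               "variance")
  expect_error(costes_pearson(matrix(1:4, 2, 2), matrix(1:6, 2, 3)),
               "shape")
})
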