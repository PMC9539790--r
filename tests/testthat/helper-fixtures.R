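# Shared fixtures and independent oracles. Everything is generated in code
# at test time; no stored data.

# ---- brute-force geometry oracles -----------------------------------------

# O(n^2) nearest-neighbour distances.
brute_nn <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    d2 <- (xy[, 1L] - xy[i, 1L])^2 + (xy[, 2L] - xy[i, 2L])^2
    sqrt(min(d2[-i]))
  }, numeric(1L))
}

# O(n^3)-ish Delaunay edge set via the empty-circumcircle property.
# Suitable for small n with points in general position.
brute_delaunay_edges <- function(xy) {
  n <- nrow(xy)
  edges <- matrix(integer(), 0L, 2L)
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p <- xy[i, ]; q <- xy[j, ]; r <- xy[k, ]
    d <- 2 * (p[1L] * (q[2L] - r[2L]) + q[1L] * (r[2L] - p[2L]) +
                r[1L] * (p[2L] - q[2L]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p^2) * (q[2L] - r[2L]) + sum(q^2) * (r[2L] - p[2L]) +
             sum(r^2) * (p[2L] - q[2L])) / d
    uy <- (sum(p^2) * (r[1L] - q[1L]) + sum(q^2) * (p[1L] - r[1L]) +
             sum(r^2) * (q[1L] - p[1L])) / d
    rad2 <- (p[1L] - ux)^2 + (p[2L] - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    inside <- (xy[others, 1L] - ux)^2 + (xy[others, 2L] - uy)^2 <
      rad2 * (1 - 1e-12)
    if (!any(inside))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(t(apply(edges, 1L, sort)))
}

sorted_edge_key <- function(edges) {
  e <- t(apply(edges, 1L, sort))
  sort(paste(e[, 1L], e[, 2L]))
}

# ---- planted-field builders (frozen study conditions) ---------------------

# Segmentation-regime field: 2 nanoclusters (50 nm, 100 mol), 4
# microclusters (200 nm, 420 mol), diffuse background 400 / um^2.
make_cluster_field <- function(seed) {
  cs <- rbind(
    data.frame(x_nm = c(1500, 4500), y_nm = c(1500, 4500),
               diameter_nm = 50, n = 100, class = "nano"),
    data.frame(x_nm = c(1500, 3000, 4500, 2000),
               y_nm = c(4500, 3000, 1500, 3000),
               diameter_nm = 200, n = 420, class = "micro"))
  generate_molecule_field(c(6000, 6000), diffuse_density_um2 = 400,
                          cluster_spec = cs, seed = seed)
}

# Truth class per molecule of make_cluster_field.
cluster_field_truth_class <- function(field) {
  ifelse(field$molecules$cluster_id == 0L, "diffuse",
         ifelse(field$molecules$cluster_id <= 2L, "nanocluster",
                "microcluster"))
}

# Field constructed so the three mean-distance populations are resolved:
# nano d_i ~ 4.6 nm, micro ~ 13 nm, diffuse ~ 70 nm.
make_trimodal_field <- function(seed) {
  nano <- data.frame(x_nm = rep(seq(700, 5300, length.out = 4), 2),
                     y_nm = rep(c(1000, 2200), each = 4),
                     diameter_nm = 50, n = 120, class = "nano")
  micro <- data.frame(x_nm = seq(800, 5200, length.out = 5),
                      y_nm = rep(4400, 5),
                      diameter_nm = 200, n = 240, class = "micro")
  generate_molecule_field(c(6000, 6000), diffuse_density_um2 = 250,
                          cluster_spec = rbind(nano, micro), seed = seed)
}

# Mode count of a mean-distance sample: kde on log10 scale, maxima above
# 5% of the global maximum.
count_distance_modes <- function(d, bw = 0.08, prominence = 0.05) {
  dens <- stats::density(log10(d), bw = bw)
  pk <- which(diff(sign(diff(dens$y))) == -2) + 1L
  sum(dens$y[pk] > prominence * max(dens$y))
}

# ---- end-to-end pipeline (frozen study conditions) ------------------------

# Monomer nanoclusters (r 0.40) on an oligomeric diffuse background
# (r 0.15) in a 20 x 20 px camera field; homoFRET pair + STORM stack from
# the same ground truth. Returns per-class mean assigned anisotropy.
run_end_to_end <- function(seed) {
  w <- 20 * 127
  cs <- data.frame(x_nm = c(900, 1700), y_nm = c(900, 1640),
                   diameter_nm = 50, n = 90, class = "nano",
                   oligomer_fraction = 0)
  field <- generate_molecule_field(c(w, w), diffuse_density_um2 = 300,
                                   cluster_spec = cs,
                                   diffuse_oligomer_fraction = 1,
                                   margin_nm = 500, seed = seed)
  cam <- camera_model(offset_counts = 100, read_noise_e = 1.6)
  hp <- render_polarized_pair(field, g_factor = 0.93,
                              brightness_per_molecule = 600,
                              camera = cam, noise = TRUE, seed = seed + 1L)
  amap <- compute_anisotropy_map(hp$pair, 0.93, intensity_threshold = 1000)
  kin <- blink_kinetics(mean_off_frames = 600, photons_per_frame_mean = 3000,
                        bleach_probability_per_on = 0.01)
  st <- render_storm_stack(field, kin, cam, n_frames = 1500,
                           seed = seed + 2L)
  locs <- localize_stack(st$stack, cam, psf_sigma_nm = 120)
  locs <- filter_localizations(locs, uncertainty_min_nm = 0.5,
                               uncertainty_max_nm = 40, photon_min = 300)
  locs <- merge_duplicates(locs, 1)
  locs <- locs[locs$x_nm > 0 & locs$x_nm < w &
                 locs$y_nm > 0 & locs$y_nm < w, ]
  tess <- tessellate(locs)
  seg <- segment_clusters(tess, density_factor = 2, min_locs = 25)
  ann <- assign_anisotropy(locs, amap)
  ann$class <- ifelse(seg$assignment > 0L,
                      seg$clusters$class[seg$assignment], "diffuse")
  ok <- ann$r_valid
  list(r_by_class = tapply(ann$r[ok], ann$class[ok], mean),
       locs = locs, seg = seg, map = amap, truth = st$truth)
}

# Drift-scenario localization table: clustered field, blinking truth
# positions, linear drift, Gaussian localization noise. Sized near the
# scale of a real acquisition (~90k localizations for 2000 frames).
make_drift_records <- function(seed, rate = c(0.05, -0.03),
                               n_frames = 2000L) {
  set.seed(seed)
  cs <- data.frame(x_nm = runif(30, 600, 4400), y_nm = runif(30, 600, 4400),
                   diameter_nm = 150, n = 800, class = "micro")
  field <- generate_molecule_field(c(5000, 5000), diffuse_density_um2 = 100,
                                   cluster_spec = cs, seed = seed)
  bl <- simulate_blinking(nrow(field$molecules),
                          blink_kinetics(mean_off_frames = 600,
                                         bleach_probability_per_on = 0),
                          n_frames, seed = seed + 1L)
  localization_table(
    frame = bl$frame,
    x_nm = field$molecules$x_nm[bl$molecule] +
      (bl$frame - 1L) * rate[1L] + rnorm(nrow(bl), 0, 10),
    y_nm = field$molecules$y_nm[bl$molecule] +
      (bl$frame - 1L) * rate[2L] + rnorm(nrow(bl), 0, 10),
    photons = bl$photons, uncertainty_nm = 10)
}

# Ten-record toy table with hand-checkable filter behaviour.
make_toy_records <- function() {
  localization_table(
    frame = 1:10,
    x_nm = seq(100, 1000, by = 100),
    y_nm = rep(500, 10),
    sigma_nm = 120,
    photons = c(500, 500, 500, 500, 500, 500, 500, 500, 50, 500),
    uncertainty_nm = c(3, 5.9, 6, 6.1, 20, 39, 40, 40.1, 20, 45),
    background = 5)
}
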