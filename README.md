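# corrfret

Correlative STORM / homoFRET analysis of membrane-protein organization.

Membrane receptors live in equilibria of monomers, dimers and oligomers,
arranged in diffuse regions, microclusters and nanoclusters. Neither
property is observable alone with a single technique:

* **homoFRET anisotropy imaging** maps self-association. Energy migration
  between identical fluorophores within Förster distance depolarizes the
  emission under polarized excitation, so the per-pixel steady-state
  anisotropy

  *r* = (I<sub>∥</sub> − G·I<sub>⊥</sub>) / (I<sub>∥</sub> + 2G·I<sub>⊥</sub>)

  drops where molecules self-associate (G is the detection-path
  correction, calibrated on an isotropic dye standard). The map is
  diffraction-limited: one value per ~127 nm camera pixel.
* **STORM** resolves nanoscale structure: stochastically blinking emitters
  are localized frame by frame by maximum-likelihood Gaussian PSF fitting
  to tens-of-nanometre precision, and the pooled localizations are
  segmented into clusters by Voronoi tessellation.

`corrfret` implements both arms and the registration between them, so
each nanoscale cluster carries the self-association value of the pixel it
occupies — plus a ground-truth synthetic microscopy simulator that makes
every stage testable. For whom: microscopists and image-analysis
developers who want a tested, scriptable reference implementation of the
correlative pipeline.

## What is in the package

| Stage | Functions |
|---|---|
| I/O | `read_image_stack()`, `write_image_stack()` (16-bit grayscale TIFF), `read_localizations()`, `write_localizations()` (ThunderSTORM-style and minimal CSV), `read_config()` |
| Simulation | `generate_molecule_field()`, `render_polarized_pair()`, `render_storm_stack()`, `simulate_blinking()`, `true_anisotropy_map()` |
| homoFRET | `compute_g_factor()`, `compute_anisotropy_map()`, `anisotropy_histogram()`, `cumulative_anisotropy_curve()` |
| Localization | `detect_candidates()`, `fit_localizations()`, `localize_stack()`, `filter_localizations()`, `merge_duplicates()`, `estimate_drift()`, `apply_drift()`, `render_gaussian()`, `sample_frames_psf_separation()`, `mortensen_uncertainty()` |
| Clusters | `tessellate()`, `mean_distance_distribution()`, `segment_clusters()`, `classify_by_mean_distance()`, `cluster_metrics()`, `nearest_neighbor_distances()`, `compare_separation()` |
| Correlation | `upscale_anisotropy()`, `assign_anisotropy()`, `composition_by_anisotropy()`, `nn_map_and_correlation()`, `costes_pearson()` |

A thin command-line wrapper over these functions is installed at
`inst/scripts/corrfret` (subcommands `simulate`, `homofret`, `localize`,
`cluster`, `correlate`; every subcommand takes `--config`).

## Worked example

Simulate a field in which monomeric nanoclusters (r = 0.40) sit on an
oligomeric diffuse background (r = 0.15), image it with both modalities,
and recover the association:

```r
library(corrfret)

w <- 20 * 127                      # 20 x 20 camera pixels
cs <- data.frame(x_nm = c(900, 1700), y_nm = c(900, 1640),
                 diameter_nm = 50, n = 90, class = "nano",
                 oligomer_fraction = 0)
field <- generate_molecule_field(c(w, w), diffuse_density_um2 = 300,
                                 cluster_spec = cs,
                                 diffuse_oligomer_fraction = 1,
                                 margin_nm = 500, seed = 101)

cam <- camera_model(offset_counts = 100, read_noise_e = 1.6)

## homoFRET arm
hp <- render_polarized_pair(field, g_factor = 0.93,
                            brightness_per_molecule = 600,
                            camera = cam, seed = 102)
amap <- compute_anisotropy_map(hp$pair, g_factor = 0.93,
                               intensity_threshold = 1000)
amap
#> <anisotropy_map> 20 x 20 px at 127 nm/px, 138 valid (34.5%)
#>   r: median 0.137, range [0.096, 0.371]

## STORM arm
kin <- blink_kinetics(mean_off_frames = 600, photons_per_frame_mean = 3000,
                      bleach_probability_per_on = 0.01)
st  <- render_storm_stack(field, kin, cam, n_frames = 1500, seed = 103)
locs <- localize_stack(st$stack, cam, psf_sigma_nm = 120)
locs <- filter_localizations(locs, uncertainty_min_nm = 0.5,
                             uncertainty_max_nm = 40, photon_min = 300)
locs <- merge_duplicates(locs, radius_nm = 1)
locs <- locs[locs$x_nm > 0 & locs$x_nm < w & locs$y_nm > 0 & locs$y_nm < w, ]
nrow(locs)
#> [1] 1155

## cluster analysis and registration
tess <- tessellate(locs)
seg  <- segment_clusters(tess, density_factor = 2, min_locs = 25)
seg$clusters[, c("class", "n", "diameter_nm", "density_per_um2")]
#>         class  n diameter_nm density_per_um2
#> 1 nanocluster 97    41.89651        70360.06
#> 2 nanocluster 73    37.93015        64604.65

ann <- assign_anisotropy(locs, amap)
ann$class <- ifelse(seg$assignment > 0,
                    seg$clusters$class[seg$assignment], "diffuse")
tapply(ann$r[ann$r_valid], ann$class[ann$r_valid], mean)
#>     diffuse nanocluster
#>   0.1581075   0.3566656
```

The two planted 50 nm nanoclusters are segmented and classified by their
mean Voronoi-neighbour distance (recovered diameters run below the
planted 50 nm because the density threshold trims the disc rim), and
registration recovers the planted contrast: nanocluster-class
localizations carry a mean anisotropy of ~0.36 (monomeric) versus ~0.16
for the diffuse pool (oligomeric).

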