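---
title: "Correlated STORM / homoFRET analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated STORM / homoFRET analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corrfret)
```

## The problem

Membrane receptors such as cell-adhesion molecules exist in equilibria of
monomers, dimers and higher oligomers, and their nanoscale spatial
organization (diffuse regions, microclusters, nanoclusters) is invisible to
diffraction-limited microscopy. Two complementary measurements address the
two halves of the question:

* **homoFRET anisotropy imaging** reports *self-association*. Under linearly
  polarized excitation, energy migration between identical fluorophores
  within Förster distance (< 10 nm) depolarizes the emission. The per-pixel
  steady-state anisotropy

  $$r = \frac{I_\parallel - G\,I_\perp}{I_\parallel + 2G\,I_\perp}$$

  therefore falls where fluorophores self-associate. It is a ratio, hence
  independent of absolute intensity, but it is diffraction-limited: each
  127 nm camera pixel reports only the *average* association state of the
  molecules inside it.

* **STORM** (single-molecule localization microscopy) reports *nanoscale
  position*: stochastically blinking emitters are localized frame by frame
  to a precision of a few tens of nanometres, and the pooled localizations
  resolve cluster structure far below the diffraction limit — but say
  nothing about whether neighbouring molecules interact.

`corrfret` implements the full correlative pipeline: anisotropy maps from
polarized image pairs, localization tables from blinking movies, Voronoi
cluster analysis of the localizations, and the registration that assigns
each nanoscale cluster the anisotropy of the camera pixel it occupies. A
synthetic microscopy simulator with exact ground truth closes the loop so
that every stage is testable.

## The anisotropy engine (`homofret`)

`compute_anisotropy_map()` applies the equation above pixel-wise. The three
masking rules mirror standard practice: saturated pixels are excluded
(the ratio needs two real intensities), pixels whose total intensity
$I_\parallel + 2GI_\perp$ falls below a constant threshold are excluded as
near-background, and non-positive denominators (possible only after offset
subtraction of pathological input) are masked rather than raised as errors.
The default threshold is $3\times$ a robust (MAD) background sigma estimated
from the border of the total-intensity image; this heuristic presumes the
imaged cell does not touch the frame border, so simulations and full-field
inputs should pass an explicit `intensity_threshold`. The G factor is
calibrated with `compute_g_factor()` as the channel ratio of an isotropic
standard (e.g. 100 nM fluorescein); the package follows the equation's
literal placement of $G$ (multiplying $I_\perp$).

Inputs are assumed dark-offset subtracted; optional per-channel constant
offsets can be subtracted first. The two polarization channels are assumed
pixel-registered (a beam-splitter pair on one camera path); no automatic
channel registration is attempted.

## The localization engine (`smlm`)

Detection is a difference-of-Gaussians band-pass followed by 8-connected
local maxima above `peak_threshold` (default 4) times a robust noise sigma;
plateau ties resolve to the lexicographically smallest pixel.

Fitting maximizes the Poisson likelihood of an *integrated* symmetric 2-D
Gaussian — pixel values are differences of normal CDFs, not centre samples —
with parameters $(x, y, \sigma, N, b)$, on gain-converted photon counts
(`photons = (counts - offset) * gain`). Optimization is BFGS with analytic
gradients in $(x, y, \log\sigma, \log N, \log b)$; convergence at relative
log-likelihood change $10^{-8}$ or 100 iterations; divergent fits (centre
outside the window, absurd widths) are dropped. The reported precision is
the Mortensen maximum-likelihood expression with pixelation and background:
$\sigma_a^2 = \sigma^2 + a^2/12$,
$\tau = 2\pi\sigma_a^2 b /(N a^2)$,
$\mathrm{var} = \frac{\sigma_a^2}{N}\left(1 + 4\tau + \sqrt{2\tau/(1+4\tau)}\right)$.
In simulation the empirical RMSE at $N = 2000$, $b = 10$ sits essentially on
this bound.

Two numerical choices deserve note:

* **Goodness-of-fit screen.** Overlapping PSFs must be rejected (they
  mislocalize). The screen is a Pearson chi-square, but compared against a
  *moment-matched normal* reference ($\mathbb{E} = n_{px} - 5$,
  $\mathrm{Var} = \sum (2 + 1/\mu_i)$) rather than a $\chi^2$ tail: at the
  near-zero background counts of offset-subtracted EMCCD data the classical
  reference is so skewed that it rejected the majority of clean fits in
  simulation, while the z-form stays calibrated and still explodes for
  overlapping emitters (p $\sim 10^{-16}$ for a pair one pixel apart). The
  statistic is evaluated on the window interior (the outermost ring is
  dropped) so the flank of a *well-separated* neighbour entering a window
  corner cannot reject an otherwise clean fit. Threshold
  `gof_p_threshold = 1e-3`, in the configuration.
* **Filtering and merging.** The keep-window for localization precision is
  $(6, 40]$ nm — sub-6 nm "localizations" are thermal/electronic noise
  artefacts, above 40 nm is sample noise — with a photon floor (default
  100, exposed in the configuration since no canonical value exists).
  Localizations within ~1 nm of each other across frames (re-blinks, dual
  labels on one nanobody) are merged by connected components
  (transitive closure) into photon-weighted centroids; the operation is
  idempotent and never increases the record count.

### Drift correction

`estimate_drift()` renders temporal bins of localizations as lightly
smoothed 2-D histograms and registers them by FFT cross-correlation with
local matrix-DFT refinement (coarse-to-fine, default resolution
`render_pixel_nm / upsample` = 0.1 nm). Two design choices differ from the
simplest formulation, both adopted after quantifying their error in
simulation:

* **Redundant registration.** All bin *pairs* are registered and the
  per-bin displacements solved by least squares (`reference = "pairwise"`),
  rather than registering each bin against the first only. The redundancy
  averages down per-pair registration noise roughly twofold at 20 bins;
  bin-vs-first remains available as `reference = "first"`.
* **End extrapolation.** Between bin centres the trace is piecewise linear;
  beyond the first and last centres the adjacent segment's slope is
  continued. Constant extrapolation would structurally truncate half a bin
  of drift at each end — with 20 bins over 2000 frames at 0.058 nm/frame
  that alone is a 5.8 nm endpoint bias, larger than the total error budget
  of the validation.

With 20 bins, ~4400 localizations per bin and 10 nm render pixels, the
endpoint of a 0.05 nm/frame linear drift over 2000 frames is recovered to
1–4 nm.

## Voronoi cluster analysis (`clusters`)

`tessellate()` wraps a classical Voronoi/Delaunay construction (the `deldir`
sweep implementation) and derives the two statistics the analysis runs on:
$d_i$, the mean distance from localization $i$ to its Delaunay (natural)
neighbours — "adjacent nearest neighbours" is interpreted as Delaunay
adjacency — and the first-rank density $\delta_i = 1/\text{cell area}$.
Cells clipped by the bounding window (the finite-sample analogue of
unbounded convex-hull cells) are flagged and excluded from area and density
statistics, though their $d_i$ is still defined. Localization uncertainty
is deliberately not weighted into any cluster statistic.

`segment_clusters()` retains points with $\delta_i > \alpha \cdot
\overline{\delta}$ (default $\alpha = 2$, the SR-Tesseler-style first-rank
threshold), takes connected components of retained points under the
restricted Delaunay adjacency, and applies localization-count and area
bounds; everything else is the diffuse pool. Cluster morphometrics follow
the tessellation: area is the sum of member cell areas, the perimeter is
the total length of Voronoi edges separating members from non-members
(the boundary of the cell union), circularity $4\pi A/P^2$, diameter the
equivalent-circle $2\sqrt{A/\pi}$, density members per area. Because the
union boundary of Voronoi cells is jagged at the scale of single cells,
circularities of segmented point clusters run well below those of the
corresponding smooth shapes; the closed-form value is recovered exactly on
regular tilings (a $2\times2$ block of unit cells gives $A=4$, $P=8$,
circularity $\pi/4$).

Classes use the mean member $d_i$ with contiguous half-open bands:
$(0,6]$ nm nanocluster, $(6,30]$ microcluster, $(30,\infty)$ diffuse.
The printed integer labels ("1–6", "7–30", ">31") leave the gaps
$(6,7)$ and $(30,31)$ undefined; contiguous bands avoid unclassifiable
values. Edges are configurable.

A known property of the global threshold $\alpha\,\overline{\delta}$: the
mean runs over *all* finite cells, so a large mass of very dense
(nanocluster) points raises the threshold and can push microcluster rims
below retention. The segmentation validation conditions (see below) were
chosen inside the regime where the threshold separates micro from diffuse
densities cleanly; outside that regime the method — like its field-standard
counterpart — fragments sparse clusters.

## Registration and joint statistics (`correlate`)

The two modalities share one camera and coordinate frame, so registration
is a pure grid scale. `upscale_anisotropy()` replicates camera pixels onto
the render grid without interpolation (a $512\times512$ map at 127 nm/px
becomes exactly $6502\times6502$ at 10 nm); `assign_anisotropy()` gives
each localization the r value of the camera pixel containing it. The
boundary convention everywhere is half-open pixels $[kp, (k+1)p)$ with
floor assignment, so the two operations agree exactly (a tested
invariant). Summaries are the cluster-class composition per anisotropy bin
(default width 0.05 over $[0, 0.5]$), the per-camera-pixel median
nearest-neighbour-distance map and its Pearson correlation with the
anisotropy map, and Costes-thresholded Pearson colocalization (orthogonal
regression between channels; threshold walked down until the sub-threshold
population decorrelates).

## The simulator (`simulate`) and what passing tests mean

The simulator provides ground truth for every stage: molecule fields
(homogeneous Poisson diffuse background plus uniform-in-disc clusters, each
molecule carrying a monomer/dimer/oligomer state), polarized pairs whose
channel expectations satisfy the anisotropy equation exactly before noise
(so noise-free render → analyze inversions are exact to machine precision),
and blinking movies: memoryless two-state on/off kinetics with per-on-frame
bleaching, lognormal photon yields, pixel-integrated Gaussian PSFs
(matching the fitting model, which is what makes exact-inversion tests
possible), Poisson shot noise, Gaussian read noise, offset, quantization
and saturation, plus linear stage drift. Defaults: 127 nm pixels,
PSF $\sigma$ = 120 nm (diffraction-limited far-red emission at NA 1.45),
$r_\text{monomer} = 0.40$ and $r_\text{oligomer} = 0.15$ (midpoints of the
ranges typical of monomeric vs oligomeric receptor regions), ~2000–3000
photons per on-frame.

Deliberate non-features: EMCCD excess (multiplication) noise, dipole
orientation effects, 3-D PSFs, triplet-state hierarchies and
time-dependent anisotropy are not modelled. Passing tests therefore show
the *estimators* are correct under shot + read noise with ideal Gaussian
PSFs; they do not certify performance on real EMCCD data, where excess
noise roughly doubles the shot-noise variance and PSF aberrations bias
$\sigma$.

### Validation conditions (all generated in code, fixed seeds)

* **Anisotropy recovery:** a mixed 50/50 monomer/oligomer pixel at high
  photon count; 500 noise realizations recover the true r within 0.01 in
  the mean.
* **Localization:** $N=2000$, $b=10$, 500 Poisson fits; RMSE $\le 1.5\times$
  the Mortensen bound (empirically $\approx 1.0\times$).
* **Drift:** 12 clusters of 400 molecules plus diffuse background
  (~21,000 localizations — a desk-scale stand-in for the $10^5$–$10^6$ of
  a real dataset), 2000 frames, 20 bins.
* **Cluster recovery:** 2 nanoclusters (50 nm, 100 molecules) and 4
  microclusters (200 nm, 420 molecules) on a 400 µm⁻² diffuse background
  in a 6 × 6 µm field; 20 seeds. Class proportions recover within a few
  points, diameters within ~10%, and nanoclusters come out ~2.5–3× denser
  than microclusters.
* **Trimodality:** a field constructed with resolved density bands
  (nano $d_i \approx 4.6$ nm, micro $\approx 13$ nm, diffuse $\approx 70$
  nm). One field cannot both sit in the clean segmentation regime and
  show three resolved kde modes: the segmentation field's nano and micro
  bands (≈5 vs ≈9 nm) merge into one mode. Mode counting is peak-finding
  on a kde of $\log_{10} d_i$ (bw 0.08, prominence 5% of max).
* **End-to-end:** a 20 × 20 px field, monomeric ($r=0.40$) 50 nm
  nanoclusters of 90 molecules on a fully oligomeric ($r=0.15$) diffuse
  background of 300 µm⁻²; brightness 600 photons/molecule in the homoFRET
  channel (so cluster pixels stay below saturation); blinking
  1 on / 600 off frames, 1500 frames (the sparse-activation regime the
  method itself requires). The full pipeline — polarized render, anisotropy
  map, STORM render, detection, fitting, filtering, merging, tessellation,
  segmentation, classification, registration — recovers the planted
  association: nanocluster-class localizations carry higher mean r than
  diffuse-class ones (Δr ≈ +0.2) in ≥ 19/20 seeds.

Problem sizes throughout were chosen as the smallest that leave the
statistics of interest comfortably inside their tolerances.

## Known limitations

* The global density threshold couples cluster populations (above); very
  nanocluster-rich fields need a locally adaptive threshold, which is not
  implemented.
* Perimeter of clusters containing window-clipped cells omits the window
  segments; such clusters sit at the field border where metrics are
  unreliable anyway.
* The border-based automatic intensity threshold assumes signal-free
  borders.
* Costes thresholding walks a finite (default 200-step) grid of candidate
  thresholds, not every distinct intensity.
* `merge_duplicates()` considers at most 16 neighbours within the radius
  per record when building the merge graph; at the default 1 nm radius
  this is far beyond any realistic duplicate multiplicity.
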