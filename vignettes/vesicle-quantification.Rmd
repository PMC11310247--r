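---
title: "Quantifying intracellular vesicle dynamics with vesitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular vesicle dynamics with vesitrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesitrack)
```

## Scope and model

`vesitrack` quantifies the dynamics and spatial organisation of
diffraction-limited fluorescent particles — typically clathrin-coated
vesicles (CCVs) in live-cell time-lapse movies — and provides the
fixed-image readouts that usually accompany such experiments
(colocalization, radial distribution within cells, thresholded mean
intensity). Every stage can be exercised against simulated ground truth,
so the whole pipeline is testable without any external data.

The processing chain is:

1. **Detection.** A sub-resolution emitter images as an approximately
   Gaussian spot (the point spread function). Candidate peaks are local
   maxima of a Gaussian-smoothed copy of each frame that exceed the frame
   background (median pixel value) by at least `intensity_threshold`
   (default 5 a.u.). Each candidate is refined by weighted least-squares
   fitting of a 2-D isotropic Gaussian (offset, amplitude, center, width),
   with Poisson-motivated weights `1/max(pixel, 1)`. Fits are accepted
   when the fitted width lies in `[1, 15]` px and the fitted amplitude is
   at least the threshold.
2. **Linking.** Nearest-neighbour association, resolved greedily per frame
   in ascending distance order, within a 3 px radius; gaps of up to 5
   missing frames are bridged; tracks observed in fewer than 5 frames are
   discarded.
3. **Track statistics.** Per track, the mean square displacement
   \(MSD(\tau) = \frac{1}{N-\tau}\sum_t (x_{t+\tau}-x_t)^2 + (y_{t+\tau}-y_t)^2\);
   the apparent diffusion constant from the first four lags of the MSD
   curve via \(MSD(t) = 4Dt\) (D = slope/4); turning angles
   \(\alpha = |\mathrm{atan2}(\det(v_1,v_2), v_1\!\cdot\!v_2)|\) between
   consecutive displacements; and the asymmetry coefficient
   \(AC = P(\alpha \ge 150^\circ)/P(\alpha \le 30^\circ)\), the ratio of
   near-reversal to near-persistent steps. For isotropic Brownian motion
   the turning angle is uniform on \([0^\circ, 180^\circ]\) and AC is 1;
   directed transport concentrates angles near \(0^\circ\), driving AC
   towards 0 — the lower the AC, the more directional the motion.
4. **Fixed-image metrics.** Rolling-ball background subtraction, the
   Manders overlap coefficient (MOC) with Costes automatic thresholds, a
   cell-segmentation pipeline measuring each vesicle's distance to its
   parent cell centroid (with an area correction) and the radial
   fraction-at-distance profile, and the thresholded mean intensity used
   for whole-field stains.

Time is measured in frames and length in pixels throughout; physical
units enter only through a `calibration()` (`pixel_size_um`,
`frame_interval_s`, default 1 s per frame matching 1 frame/s live-cell
acquisition, and 0.16 µm/px as typical for a 63× high-NA objective).
`D[µm²/s] = D[px²/frame] · pixel_size_um² / frame_interval_s`.

## The simulator and what it does (not) emulate

`simulate_tracks()` draws stationary, Brownian (per-axis step variance
`2D`, so the ensemble MSD is `4Dτ`) or directed (`+v` px/frame along a
heading) trajectories, with permanent disappearance (`p_off`) and
transient blinking (`p_blink`; single-frame gaps by default, geometric
gap lengths optionally — needed to exercise the gap-closing rule).
`render_movie()` draws each visible particle as an isotropic Gaussian
evaluated at pixel centers (no sub-pixel area integration; adequate for
σ ≥ 1 px and matching the detector's fit model), applies Poisson noise to
the expected counts and then additive Gaussian read noise.
`make_coloc_pair()` builds two-channel scenes with a controllable shared
fraction of spot positions, and `make_cell_scene()` builds a segmentable
disk-shaped cell plus vesicles placed on a ring or uniformly over the
disk (uniform placement has mean radial distance `2R/3`, the reference
value for recovery tests).

The simulator deliberately omits photobleaching kinetics, camera gain and
EM-CCD excess noise, motion blur within the exposure, 3-D defocus, and
textured cell interiors. Passing tests therefore demonstrate correctness
of the algorithms under the stated image-formation model, not robustness
to every property of real movies.

## Parameter choices and numerical notes

* **Detection defaults** (5 a.u., σ ∈ [1, 15] px) and **linking defaults**
  (3 px, gap 5, min 5 frames) are the standard operating values for CCV
  tracking at ~1 frame/s and are the package defaults everywhere.
* **Background for thresholding** is the frame median (robust to sparse
  spots); each spot's photometric offset is nevertheless fitted locally.
* **Candidate gate.** Whether the intensity threshold applies to the
  smoothed candidate pixel or only to the fitted amplitude is ambiguous in
  common plugin descriptions; both gates are applied by default and the
  pre-filter image is configurable (`candidate_gate`).
* **Fit window** half-width is `ceiling(3 × candidate_smoothing_sigma)`
  (default smoothing σ = 2 px), capturing >99% of a diffraction-limited
  spot's mass. The Gaussian is isotropic — a single width parameter.
* **Diffusion fit** uses a free intercept by default: static localization
  error offsets the MSD curve without changing its slope. A through-origin
  variant (`intercept = "origin"`) implements the literal `MSD = 4Dt`.
* **Turning angle** uses the two-argument arctangent of (determinant, dot
  product); the single-argument arctangent of their ratio cannot separate
  0° from 180°.
* **AC bins** default to reversal ≥ 150° over persistence ≤ 30° (the
  180 ± 30° versus ± 30° definition). An alternative published wording
  (≥ 15° over ≤ 30°) yields overlapping bins and loses the
  directionality interpretation; it remains available through the
  `reversal_min`/`forward_max` arguments but is not the default. The
  orientation convention is fixed by the requirement that lower AC
  means more directed motion.
* **AC aggregation** is per field/movie (all displacements pooled),
  matching per-cell pooling of sparse vesicle steps; per-track values can
  be obtained by calling `turning_angles()`/`asymmetry_coefficient()` on
  single tracks.
* **Gap handling in MSD**: all pairs of observed frames at each lag are
  averaged (`n_pairs` is recorded); for gap-free tracks this reduces
  exactly to the `1/(N−τ)` formula.
* **Greedy vs optimal assignment.** Linking resolves conflicts greedily in
  ascending distance order with deterministic tie-breaks (lower track id,
  then lower detection row). This matches the nearest-neighbour
  description; a globally optimal assignment was considered out of scope.
  The gap-closing search radius stays fixed (an option scales it by
  `sqrt(gap)` for diffusive motion). Gap frames are not interpolated.
* **Rolling ball** is implemented as grayscale opening with a non-flat
  hemispherical structuring element (the classic formulation), with no
  pre-smoothing; a radius larger than the image degenerates to
  subtracting the image minimum. It removes structures wider than the
  ball, so it is applied to spot-scale signal, not to whole-cell plateaus.
* **Costes thresholds** for the MOC: the threshold pair moves down the
  orthogonal regression line of green on red until the correlation of the
  pixels below both thresholds reaches zero; the analysed set is the mask
  pixels where at least one channel exceeds its threshold, which makes
  spatially disjoint patterns score 0 rather than become undefined.
* **Cell masks** follow the standard recipe: rolling ball (50 px), linear
  rescale of the intensity window [3, 30] with clipping (read as a hard
  clip-and-rescale; whether the original described display rescaling or a
  clip is not determinable), Gaussian blur σ = 5, two-class Otsu, and
  removal of border-touching cells. Otsu is computed globally before
  labeling — per-object re-thresholding is unnecessary for well-separated
  cells and is left as a variant.
* **Vesicle identification** thresholds the speckle-enhanced (white
  top-hat, disk diameter 20) image at 2 × the mode of the masked nonzero
  histogram, after a light Gaussian smoothing (σ = 1.5 px) that narrows
  the top-hat noise floor; objects under 5 px are discarded as noise
  speckle; clumps split by watershed; objects shrink to intensity-weighted
  centroids (closer to the sub-pixel nature of the spots than binary
  centroids).
* **Area correction.** The literal normalisation
  `alpha = sqrt(area)/mean_distance` followed by multiplication collapses
  algebraically to `sqrt(area)`, erasing the radial information, so the
  default corrected distance is the dimensionless
  `mean_distance/sqrt(area)` — the only scale-removing,
  information-preserving reading. The literal mode is retained behind
  `mode = "paper_literal"` and warns. The dimensionless index is invariant
  under uniform rescaling of the full geometry — scene, PSF and the
  pipeline's own length scales (ball radius, blur σ, feature size) scaled
  together.
* **Radial profile**: four equal-width annuli from the centroid to the
  cell's farthest boundary point; for uniform placement the expected
  fractions are the annulus area ratios (1:3:5:7)/16.

## Typical problem sizes

The test-suite and acceptance fixtures use: 500 tracks × 100 frames for
diffusion recovery (median fitted D within 10%); ≥ 10⁴ pooled
displacements for the AC limits (AC(Brownian) = 1 ± 0.1, AC < 0.2 at
drift = 2 × step σ); 100 frames × 20 spots at peak signal-to-noise 10
for detection fidelity (recall/precision ≥ 0.95, localization RMSE
≤ 0.2 px); 40-particle movies for identity recovery (≥ 95%); and
192–320 px cell scenes with 40–70 vesicles for the radial pipeline
(ring radius recovered within 5%, uniform-disk mean within 5% of 2R/3).
Scenes are kept sparse enough that sub-resolution spot merging stays
rare; at high densities merged spots are reported as single objects,
which is a physical limit of diffraction-limited imaging rather than a
pipeline artifact.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
optics <- optics_model(image_shape = c(128L, 128L), read_noise_sigma = 3)
truth <- simulate_tracks(motion_model("brownian", D = 0.25), 10, 40,
                         shape = c(128L, 128L), seed = 1)
movie <- render_movie(truth, optics, seed = 2)

detections <- detect_movie(movie)
tracks <- link_tracks(detections)
summarize_field(tracks, cal = calibration())

curve <- msd(dplyr::filter(tracks, track_id == 1))
fit_diffusion(curve)
autoplot(curve, n_lags = 4)
```

## Known limitations

* Greedy linking can mis-assign identities at densities where particle
  spacings approach the link radius; the identity-recovery guarantee is
  stated for low densities (≤ 0.005 particles/px², step σ ≤ 1 px).
* The Costes procedure needs enough below-threshold pixels to estimate a
  correlation; on tiny images supply fixed thresholds.
* `D` from short, noisy tracks may be negative; values are reported
  as-is and should be summarised robustly (the field summary uses the
  median).
* The rolling ball is O(image × ball area); very large radii on large
  images are noticeably slower than the flat-kernel morphology used
  elsewhere.
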