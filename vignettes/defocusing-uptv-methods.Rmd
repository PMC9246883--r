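---
title: "Methods: defocusing µPTV in dptv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defocusing µPTV in dptv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dptv)
```

# The measurement model

`dptv` implements defocusing micro-particle tracking velocimetry for
brightfield video: individual seed beads are followed in 2D, and the depth
of each bead is read from the shape of its out-of-focus diffraction
pattern by comparison against a reference library of patterns recorded at
known heights. The method's core assumptions are:

* **Sparse seeding.** Each bead's pattern is imaged without overlap; the
  working guideline is a particle image density below 0.01 pixel/pixel.
  `particle_image_density()` measures it. The detector and linker have no
  anti-collision logic, so denser scenes degrade gracefully but visibly.
* **Sign-asymmetric defocus.** Patterns above and below focus must differ
  (in the real instrument this is arranged with the objective's correction
  collar). Without asymmetry, Z is known only up to sign.
* **Steady templates.** The library is valid only for the optics, bead
  size and illumination it was recorded with.

# Stages and their parameters

## Detection and linking

`log_detect()` applies a scale-normalized Laplacian-of-Gaussian at
`radius_px / sqrt(2)` (default radius 3 px, matching 3 µm beads at
0.32 µm/px), takes local maxima above a quality threshold, and refines
each to subpixel position with a per-axis 3-point parabola on the
response. Maxima on the image border are discarded; the refinement offset
is clamped to ±0.5 px. When no threshold is given, Otsu's method on the
positive response values is used, with an absolute floor of `1e-6` so a
featureless frame yields no spots rather than thresholding numerical
ripple.

`link_spots()` performs greedy globally-nearest-pair assignment between
consecutive frames under the gate `max_displacement_px`. Ties break by
lowest spot index; the input is canonically sorted first, so the result is
invariant to spot ordering within a frame. There is no gap closing: a
missed detection ends a track, and gaps are only ever filled by explicit
manual corrections (`merge_corrections()`), mirroring the
manual-correction workflow of GUI trackers. Full LAP-style linking is
deliberately out of scope — at the mandated density greedy linking
recovers ≥ 95% of true links (verified in the acceptance suite), and users
who need more can import TrackMate XML.

The gate must exceed the fastest in-plane motion per frame (in the bundled
duct scenes, ~10–17 px/frame); too small a gate fragments tracks rather
than corrupting them.

## The reference library

* `corrected_step_size(Δz, n_wf, n_air)` converts the desired in-fluid
  level spacing to an objective step, `Δz / (n_wf/n_air)`. Defaults
  `n_wf = 1.41` (45/55 v/v water/glycerol, index-matched to PDMS) and
  `n_air = 1`; both are configurable because the instrument indices are
  not universal.
* `brenner_focus()` locates the focal frame by the maximum Brenner
  gradient with the classic shift of 2 px, computed on full frames. Ties
  go to the lower index; a constant stack is an error, not a level-0
  answer.
* `build_library()` takes the **per-pixel median** of each level's crops
  (lower median for even counts, so every template value is an observed
  intensity). The median suppresses foreign objects and extreme
  deviations, which is also why the cross-correlation classifier is
  relatively robust to label bias.

## Tilt assessment and relabeling

If the calibration slide is tilted, beads recorded at one objective
height do not share a true depth: labels are biased by field position.
`estimate_tilt()` fits `z_predicted − z_label = a·x + b·y + z0` by least
squares. Two non-obvious choices:

* **Per-level intercepts.** With a tilted slide the median templates are
  themselves biased level by level; a pooled plane fit confounds that
  level-wise bias with the slopes. By default each level gets its own
  intercept, so slopes come purely from within-level variation across the
  field. `z0` is returned as the count-weighted mean of the level
  offsets.
* **Assess near focus.** The recommended practice (used by the test
  suite) is to fit on levels within a few µm of focus, where templates
  are sharp; at the range extremes, label clipping and score saturation
  attenuate the apparent slopes.

`relabel()` applies the plane to crop metadata and `rebuild_library()`
regroups crops onto the step grid by nearest level; an interior level left
empty after regrouping is filled by linear interpolation between its
populated neighbors (constant level spacing is an invariant of the
library). With median templates the accuracy gain from relabeling is
modest — the experiments that motivated the correction saw the largest
gains for learned classifiers, which consume *labels* directly — but it is
consistently positive at realistic beads-per-level counts, and the test
suite asserts exactly that.

## Z-classification

`classify_z()` scores a crop against every template by zero-lag,
zero-mean, unit-variance cross-correlation (affine-gain invariant by
construction) and refines the best level by a 3-point parabola through the
neighboring scores. Choices and edge rules:

* Zero lag only: spots are already subpixel-localized, and crops are cut
  at the nearest pixel with the residual offset recorded — pixel data are
  never resampled.
* Ties at the maximum resolve toward the focal plane, then the lower
  index.
* An exact template match (score 1) returns the node label without
  refinement; at the range ends the label is returned unrefined.
* A zero-variance crop is an error in `classify_z()` and a flagged `NA`
  in `classify_track()`; classification is strictly per-crop, with no
  temporal coupling — temporal cleanup belongs to the median filter.
* Crops that were border-padded at extraction are classified but their
  predictions are discarded by the pipeline (the truncated pattern is
  unreliable); the pathline simply splits there.

Any external per-crop regressor can replace this classifier through
`classify_track_with()`; the contract (one finite prediction per crop,
within the library's range) is validated so the downstream stages need no
knowledge of the classifier.

## Pathlines, filtering, velocities

`assemble_pathlines()` converts to physical units (`x = x_px · pixel
size`, `t = frame / fps`) and splits tracks at frame gaps or missing
depths — interpolating across a gap would mix time bases.
`median_filter_z()` applies a sliding median (default order 5) to Z only,
with symmetric window shrinkage at the ends (no invented data); order 5
removes both single-frame spikes and 2-frame "error plateaus".
`instantaneous_velocities()` differences consecutive spots, placing each
vector at the pair midpoint. `filter_wmax()` gates on the out-of-plane
component |w| by default — depth-classification errors show up as Z jumps —
with `mode = "magnitude"` available for full-speed gating.

`precision_eprec()` regresses each pathline's Z on its in-plane arc
length (one predictor, matching the "1-D" linear model used for the
published precision metric; a two-predictor `z ~ x + y` plane fit is
available via `predictor = "xy"`), and reports the median and
non-parametric IQR of the per-pathline residual RMSEs. Stationary
pathlines (no in-plane displacement, so the regression is undefined) are
excluded with a flag. Both σ and E_prec are computed with squared
residuals (true RMSEs).

## Lattice averaging and continuity

`lattice_average()` anchors the lattice at the lower data bound; with
overlap fraction f, element origins are spaced `element · (1 − f)`, so at
the default 50% overlap centers sit at half the element size and an
interior vector contributes to up to 8 elements. Element values are
arithmetic means.

`continuity_eta()` uses central differences on the element-center grid.
An element needs all six axis neighbors non-empty; boundary or
underpopulated elements are excluded, never imputed or one-sided — the
cost is coverage, the benefit is an unbiased interior estimate. The
per-element error is

η = |X − Y| / (|X| + |Y|),  X = ∂u/∂x,  Y = −(∂v/∂y + ∂w/∂z),

i.e. the normalized mismatch of the two quantities that incompressibility
forces to be equal. This form was chosen over normalizing by the sum of
the three absolute derivatives because only it reproduces the stated
anchors of the scale: η = 0 for perfect mass conservation and median
η̃ → 1 for uncorrelated components (X and Y then agree in sign with
probability ½, and disagreement puts η at exactly 1). η is invariant to
uniform velocity rescaling. On pathline-sampled synthetic data at
experiment scale (~80 k vectors, mm/s speeds, the reported localization
noise), η̃ versus element size reproduces the published qualitative shape:
worst at 1 µm³, minimum near 4 µm³, slight rise at 6 µm³, below 0.5
everywhere above 1 µm³.

## Droplet-frame transforms

For straight channels the droplet's per-frame centroid is subtracted
(`straight_frame_transform()`). For curved channels
(`curved_frame_transform()`) positions are taken to polar coordinates
about the arc center and the droplet's angular position θ(frame) is
subtracted, so a bead's arc displacement is removed *at its own radius*;
the result is unrolled to streamwise `s = r·(φ − θ)` and radial
`r − r_mid` with `r_mid = (r_inner + r_outer)/2` (250 µm for the 190/310
µm geometry). Both transforms are rigid per frame and exactly invertible.
θ(frame) may be supplied from a file or derived from the beads themselves
(`derive_arc_motion()`, median angular displacement by default — robust to
internal recirculation). Droplet segmentation is out of scope; motion
input is file-based.

# The synthetic world

`optical_model()` + `render_particle_image()` generate an analytic
ring-pattern point-spread function: a Gaussian core plus a cosine ring
system under a Gaussian annulus, evaluated exactly at pixel centers (no
FFT shifting). Defaults mirror the published optics: 0.32 µm/px, 3 µm
beads, 110 levels at 0.5 µm (54 µm range, focal plane at level 55 so the
range extends below −25 µm). The depth signature: ring radius grows with
|z| (`ring_gain` 0.12 µm/µm), and the sign of z is encoded three ways —
rings grow ~15% faster above focus, ring spacing is modulated by signed z
(`aberration_asymmetry` 0.012 µm⁻¹), and rings are brighter above focus
than below (tanh-saturating contrast factor). These values were chosen so
the model satisfies its stated contracts — the focal frame maximizes the
Brenner gradient, all 110 level patterns are mutually distinguishable
(pairwise NCC < 1, and < 0.99 at ±5 µm), and noise-free classification
recovers z well within one step — and were then frozen. Noise is additive
Gaussian only (`noise_sd`, default 0; 0.02 is used as the noise-matched
operating point in tests, a typical camera-noise fraction of dynamic
range); there is no shot noise, no illumination gradient, no optical
distortion growing with Z, and no droplet-interface refraction. A green
test therefore establishes the pipeline's correctness on an idealized
defocus family, not robustness to every experimental artifact.

Flows: the rectangular-duct Poiseuille profile is the classical Fourier
series (51 odd terms), rescaled so its cross-section integral equals the
volumetric flow rate (the normalization integral is computed once by
midpoint quadrature on a 201² grid and cached). The recirculation field
is a superposition of two divergence-free stream-function rolls with zero
normal flow on all box faces and droplet-like mirror symmetry (reflecting
across the horizontal mid-plane negates v and preserves u, w);
`secondary = 0` reduces it to closed planar rolls, used for the
closed-pathline tests. Advection is classical RK4 at fixed
`dt = 1/(10·fps)` — the fields are smooth, and a fixed step keeps runs
bit-reproducible. All randomness flows from one integer seed through a
deterministic mixing function; identical configurations give byte-identical
artifacts.

# Numerical and interface choices

* Coordinates are 0-based pixels with the origin at the center of the
  top-left pixel; conversion to µm happens in exactly one place (pathline
  assembly). Frames are 0-based.
* `w_max` defaults to gating |w| (the component the limit is named after
  and the one inflated by classification errors); full-magnitude gating is
  a flag.
* Library bundles are a multi-page TIFF (one page per level, ascending z)
  plus a JSON sidecar; scenes are TIFF + truth CSV + JSON. The TIFF
  reader/writer is a minimal baseline implementation (uncompressed
  grayscale, 8/16-bit, little-endian) because no TIFF binding is available
  in the target R environment; it round-trips its own files and is
  cross-validated against an independent Python reader in development.
* Pipeline configuration is a plain list with JSON on disk (`jsonlite`),
  not YAML — no YAML parser is available in the target environment and
  JSON round-trips the same structure losslessly.
* Every output CSV carries a `# dptv <version> config <hash>` header; the
  hash covers the analysis parameters but not output paths.

# Known limitations

* No overlap resolution: colliding beads produce detection and
  classification errors that only the density guideline and the median
  filter mitigate.
* Near-focus sign confusion: within ~±1 step of focus the above/below
  asymmetry is second-order, and a misaligned or noisy crop can flip the
  sign. Isolated flips are exactly what the order-5 median filter removes;
  a bead *parked* near focus for many frames can retain a small persistent
  error.
* The η̃ diagnostic needs all six neighbors populated, so sparse regions
  contribute nothing; with very sparse data the continuity field can be
  undefined everywhere (an error, by design).
* Training a learned classifier is out of scope; only the plug-in
  interface is provided.
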