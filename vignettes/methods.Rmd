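---
title: "pamvasc: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pamvasc: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamvasc)
```

This vignette documents the numerical model behind `pamvasc`, the default
parameter choices, and the design decisions where several defensible
options existed. The README shows how to *use* the package; this document
explains *why* it works the way it does.

## 1. Physical model

OR-PAM records, per lateral position, a radio-frequency (RF) A-line: the
ultrasound transient generated by optical absorption in blood. The
information of interest is the A-line's *envelope*; the carrier phase
carries no vascular information. We recover the analytic-signal envelope
with the classic FFT method: multiply the spectrum by the Hilbert step
vector (2 on positive frequencies, 1 at DC and Nyquist, 0 on negatives)
and take the modulus of the inverse transform.

```{r envelope}
t   <- seq_len(256)
a   <- exp(-((t - 128)^2) / (2 * 30^2))       # true envelope
env <- hilbert_envelope(a * cos(2 * pi * 0.23 * t))
max(abs(env[50:206] - a[50:206]))              # edge-free interior error
```

The **maximum amplitude projection** (MAP) is the per-pixel maximum of the
envelope over depth; the **depth map** is the depth of that maximum
(shallowest sample on ties, `NA` below a noise floor). `denoise_median`
applies a reflect-padded median filter — reflection rather than zero
padding because MAP intensity does not fall to zero at the field-of-view
edge, and a zero border would bias edge pixels dark.

## 2. Segmentation

`segment_vessels` chains six steps; their order matters.

**Vesselness.** `vesselness_multiscale` is a Frangi-type ridge filter on
the scale-normalised Hessian ($\sigma^2 H$), with scales matched to vessel
radii (default $\sigma \in \{1, 2, 3, 4, 6, 8\}$ px). One deliberate departure
from the textbook formulation: the noise-scale parameter $\gamma$ (the
"structureness" normaliser) is computed **globally across all scales**
(half the maximum Frobenius norm over every scale) rather than per scale.
Per-scale $\gamma$ renormalises each scale to its own strongest response,
so a scale at which the image contains *no* structure of that size gets
its noise amplified to vessel-like scores; on a 256² image with a single
thin tube this produced thousands of spurious noise components at the
largest scale. A global $\gamma$ keeps all scales on one footing.
Derivative kernels are explicitly zero-sum (the vanishing moment lost to
kernel truncation is restored by subtracting the kernel mean), so a
constant image yields exactly zero vesselness.

**Adaptive threshold.** `adaptive_threshold` keeps pixels strictly above
their local mean (integral-image box filter, default 31 px block) plus an
offset. The input is mean-centred first so that integral-image round-off
cannot make a constant image compare "above" its own mean anywhere.

**FWHM refinement.** Vesselness + threshold finds vessel *cores*;
apparent width at that stage depends on contrast. `refine_mask_halfmax`
re-derives the boundary photometrically: a pixel belongs to a vessel if
its intensity exceeds background + `fraction` (default 0.5, i.e. FWHM) of
the local peak-to-background contrast, where the local peak is a grey
dilation (radius 12 px) and background a grey erosion (radius 24 px).
Because the phantom renders tubes with Gaussian profiles whose FWHM equals
the true diameter, the FWHM criterion recovers the true width by
construction — and on real Gaussian-beam OR-PAM data FWHM is the standard
width convention. Two guards make this robust:

* the refinement is confined to an *allow window* — the detected mask
  dilated by 12 px (equal to the peak radius, so the window always covers
  the widest vessel's half-max support);
* a **noise significance floor**: a pixel is kept only if its local
  contrast (peak − background) exceeds `noise_floor_sd` (default 10) times
  a robust noise estimate (`mad` of the pixels *outside* the allow window,
  i.e. background only). Without this, taking a disc maximum minus a disc
  minimum over pure noise yields a "contrast" of roughly 7 noise sigmas,
  and half of any noise patch passes the half-max test. Ten sigmas is the
  Rose visibility criterion (~5) with a factor-2 margin against the
  extreme-value inflation.

**Ordering.** Small-object cleanup runs **before** refinement and again
after. A single supra-threshold noise pixel, if left in the detection
mask, seeds an allow window in pure background and can grow into a speck;
removing sub-`min_object_px` (default 20) components first eliminates
those seeds, and the second pass removes anything the refinement itself
fragmented, then fills holes up to `fill_hole_px` (default 10).

**Skeleton and EDT.** `skeletonize` is Guo–Hall thinning (topology-
preserving, one-pixel-wide, implemented in C++ via Rcpp).
`distance_transform` computes the exact Euclidean distance transform
(EBImage's `distmap`) on a mask padded with a one-pixel background ring,
so the image border counts as background — a vessel leaving the field of
view should not get an artificially large radius. The test suite checks
the EDT against a brute-force nearest-background search.

## 3. Metrics

With pixel size $p$ (µm), skeleton $S$, mask $M$, EDT $E$:

* **PA signal** — mean amplitude. Default mode `upper_half` (mean of
  pixels at or above the median): the plain mean of a sparse vascular
  image is dominated by background, so a hemoglobin-related amplitude
  change (e.g. after absorber injection) is diluted roughly by vessel
  density. Averaging the upper half tracks the vascular compartment while
  staying segmentation-independent. `above_half_mean` is available as an
  alternative.
* **VD** = $|M| / N_{px}$; **PVD** = $|S| / N_{px}$ by default
  (`pvd_denominator = "image_pixels"`), so VD and PVD share a denominator
  and their ratio is the mean vessel width in pixels. The alternative
  normalisation (skeleton per mask pixel) is available via
  `metrics_config`.
* **VDI** = $\operatorname{mean}_{(i,j) \in S}(2E_{ij} - 1)\,p$. The
  $2E-1$ form is exact for odd-width rasterised bars (a 9 px bar reads
  exactly 90 µm at 10 µm/px) and carries a +1 px odd-width bias for
  continuous tubes, which we accept as the estimator's documented
  convention — the *ground truth* diameter is defined through the same
  estimator on the true mask/centreline, so pipeline validation compares
  like with like.
* **VC** — box-counting dimension: $-$slope of $\log N(s)$ vs $\log s$
  over box sizes $\{1,2,4,8,16,32\}$ (origin-anchored grid). Computed on
  the **skeleton** by default: the dimension of the filled mask mixes
  vessel *width* into what should be a topology/tortuosity measure, and
  saturates toward 2 for dense masks. A line scores 1, a filled square 2,
  and a depth-4 Sierpiński carpet gives the exact counts $8^k$ at sizes
  $3^k$ and dimension $\log 8 / \log 3 \approx 1.893$:

```{r fractal}
s <- make_fixture("sierpinski", params = list(depth = 4))
box_counts(s, 3^(0:4))
vessel_complexity(s, 3^(0:4))
```

## 4. Quantitative maps

`compute_quant_maps` evaluates diameter, density, PVD and complexity in a
sliding window (default 8×8 px, stride 1, reflect padding so every output
pixel has a full window). Each window value is *identical* to what the
metrics module returns on the cropped window — the maps are the metrics,
localised, not approximations. For complexity inside an 8 px window the
box ladder is restricted to powers of two up to the window size.

## 5. The phantom and its limits

`generate_vessel_tree` grows random branching trees (default 12 roots)
over four regions — control, normal, and two melanoma zones (quadrants
split at 0.45/0.55 of each axis). Rendering: each segment becomes a tube
with a Gaussian cross-profile of FWHM = 2r (matching a diffraction-limited
OR-PAM point spread), melanoma zones add a tumour background field, and
i.i.d. Gaussian noise (default σ = 0.02) is added on top.
`render_rf_volume` places a modulated carrier (0.25 of the sampling rate,
with an explicit Nyquist check) at each pixel's depth so the full
reconstruction path can be exercised.

Simplifications to keep in mind: 2-D tubes rather than 3-D cylinders
projected; noise is white (no speckle correlation); no depth-dependent
fluence or focal blurring; vessels do not overlap realistically at
crossings. These do not affect what the phantom is for — known-answer
validation of the numerics — but the phantom is not a simulator of
instrument physics.

`apply_pdt_effect` models staged therapy: a *kill set* of segments is
destroyed (descendants removed with their parents), survivors optionally
shrink, and tumour amplitude factors change. Kill sets for increasing
kill fractions are **nested** (shared uniform draws), so a larger dose
never resurrects a vessel — this makes dose-response curves monotone by
construction and testable as such.

## 6. The simulated study

`simulate_pdt_series` builds a four-timepoint experiment:
`pre_injection`, `post_RB` (photosensitiser injection: global amplitude
gain ×1.07, the absorber raises PA signal everywhere by a few percent),
`post_PDT1` (first melanoma zone treated), `post_PDT2` (second zone
treated). Design decisions:

* **Destroyed-vessel amplitude equals background** (`tumor_factor = 0.02`
  for the destroyed tumour field): a vessel whose blood is gone produces
  no hemoglobin signal. An earlier draft left a dim residue, which sat
  exactly at the detection threshold and made segmentation flicker
  between runs.
* **ROIs cover their whole zone, inset 2 px** rather than a centred
  fraction — a centred crop of a random tree can land on a near-empty
  patch, and percent changes on near-zero baselines are meaningless.
* Percent changes are reported **vs. the pre-injection value of the same
  ROI**, so each ROI is its own control; `summarize_mean_across_rois`
  gives the cross-ROI mean when a single per-metric number is wanted.
* Untargeted ROIs are *exactly* invariant across PDT timepoints up to the
  global gain: the simulator perturbs only targeted segments, so the
  control ROI's residual percent change measures pure pipeline noise
  (well under 1 % at 256²).

## 7. Numerical conventions

* Separable Gaussian convolution uses replicate padding, and pads the
  image itself when a truncated 4σ kernel exceeds the image size.
* TIFF stores samples in [0, 1]; quantitative images are written as
  32-bit float with a JSON sidecar holding the scale (and offset for
  signed RF volumes), so round trips are lossless to float precision.
* All randomness flows from a single integer seed per phantom/study;
  the CLI `timecourse` output is byte-deterministic for a given seed.
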