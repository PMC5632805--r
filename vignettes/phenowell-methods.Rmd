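---
title: "Methods: from plate images to growth statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plate images to growth statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenowell)
```

`phenowell` implements the analysis side of a high-throughput *in vitro*
well-plate bioassay: a camera photographs each 6-, 12- or 24-well plate
from above, and the projected green area of each seedling's rosette is the
measured growth trait. This vignette describes the models and procedures,
the parameters that matter, the synthetic benchmark that the tests rely
on, and the design choices made where the problem was genuinely open.

## Plate geometry

Plate coordinates are millimetres, origin at the top-left plate corner,
x right, y down; image pixels are indexed from the top-left with pixel
centres at half-integer coordinates. Built-in layouts use the ANSI/SLAS
127.76 × 85.48 mm footprint with the well grid centred on the plate
(24-well: 4 × 6, well radius 7.8 mm, pitch 19.3 mm; 12-well: 3 × 4,
r = 11 mm; 6-well: 2 × 3, r = 17.4 mm); all geometry is overridable via a
YAML layout file. Wells are numbered **column-wise** — down the first
column, then the next. Because the symmetric alternative (numbering from
another corner) cannot be distinguished from per-well results alone, the
origin is fixed by convention at the top-left well; it is a single,
documented choice rather than a configuration guess.

Four blue boundary marks sit just outside the plate corners. The first
mark is shifted 22 mm along the top edge: a deliberately asymmetric
("keyed") quadrilateral, so that the mark set determines the plate pose
uniquely and a 180° flip cannot masquerade as a valid registration.

## The image pipeline

**Lens correction.** The camera's radial distortion is modelled by a
single-coefficient division model about the image centre: a pixel at
distorted radius $r_d$ belongs at $r_u = r_d/(1 + k\,r_d^2)$. The model is
analytically invertible ($r_d$ solves a quadratic), which gives a
closed-form forward map for synthesis and a closed-form inverse for
correction; correction resamples by nearest neighbour. $k$ is
camera-specific (units px⁻²; a typical full-resolution value of 5 × 10⁻⁹
moves image corners by ~20 px) and is configuration, not estimation. The
coefficient must satisfy $4k r_\max^2 < 1$ over the frame or the model is
not invertible and the call errors.

**Registration.** Blue marks are segmented by an HSV band (hue 100–140 on
the 0–179 scale, saturation ≥ 80, value ≥ 60 by default), connected
components below `mark_min_area` (20 px) are discarded, and centroids are
ordered by angle about their mean. Candidate mark-to-template
correspondences enumerate subsets (when spurious blue blobs yield more
than four marks), all cyclic shifts, and reversed orders; each candidate
is fitted with a least-squares similarity transform (complex linear
regression, proper rotations only) and scored by normalised inverse RMS
residual. The score plays the role of a registration "probability": it is
a heuristic plausibility ranking, not a calibrated posterior.

**Segmentation.** A pixel is plant tissue iff hue ∈ [35, 90] (0–179
scale) AND saturation ≥ 60 AND value ∈ [40, 255] (0–255). The cut-offs
are deliberately simple — green rosettes on white agar are far from the
decision boundary — and fully configurable, since real cameras and media
differ. The only post-processing is a minimum connected-component filter
(default 5 px) to suppress isolated sensor noise; no morphology touches
the mask otherwise, so measured areas remain pure pixel counts.

**Validation and retry.** A registration is accepted only if at most
`outside_tolerance` green pixels (default 0, after the component filter)
fall outside every mapped well disc. Candidates are tried in score order
until one validates; if none does, the best-scoring candidate is used and
the measurement is flagged `valid = FALSE` for manual review. This is the
pipeline's safety net: a wrong pose almost always strands some rosette
outside the supposed wells.

**Measurement scale.** Per-well counts are taken in the corrected image
and multiplied by $(s_{\mathrm{ref}}/\hat s)^2$, where $\hat s$ is the
fitted scale (px/mm) and $s_{\mathrm{ref}}$ = `crop_px_per_mm` (default
15.26 px/mm, a 127.76 mm plate spanning 78% of a 2500 px frame). Areas
from images taken at slightly different camera heights are thereby
comparable, and reduced-resolution runs can set their own reference.
Registered crops (used for preview overlays) cover exactly the plate
rectangle at the same reference scale.

## The synthetic benchmark

The generator is first-class code, not a fixture: it renders what the
platform photographs and simulates what the biology does, with exact
ground truth for both.

**Scene.** White-grey tray, near-white agar inside the plate rectangle,
blue marks (with sub-millimetre placement jitter, default SD 0.1 mm),
and one rosette blob per well. Rosettes are lobed stars
$r \le c\,\rho(\theta)$, $\rho(\theta) \propto 1 + a\cos(\ell(\theta -
\phi))$ with 4–8 lobes and amplitude 0.2–0.35 — area-controllable shapes
with rosette-like outlines. The radial threshold $c$ is calibrated on the
canonical pixel grid so that the rendered pixel count at the identity pose
equals the requested area *exactly* (±1 px of floating-point boundary
effect); under other poses the count deviates only by boundary
rasterisation. Colours straddle the segmentation defaults on purpose
(green hue 120° ± jitter, saturation ≈ 0.6, value ≈ 0.55), so threshold
tests are informative. Rendering maps each output pixel through the
forward distortion and inverse pose, i.e. the synthetic image is the
*distorted* camera frame that the pipeline must first correct.

**Growth.** Each plant follows
$A(t) = A_0\,e^{r_{\mathrm{eff}} G(t)}\,\varepsilon(t)$ with
$r_{\mathrm{eff}}$ = baseline RGR × treatment factor, log-normal
observation noise, and an optional geometric age decay of the RGR
($G(t) = (d^t-1)/\ln d$). Defaults emulate unstressed 4-day-old
transplants imaged daily: $A_0 \sim N(250, 60^2)$ px (full-resolution
scale), baseline RGR 0.4 day⁻¹, constant with age ($d = 1$, matching the
observed log-linear growth over the 9-day assay), noise SD 0.08. Death is
a per-day Bernoulli hazard, absorbing, with area 0 afterwards — consistent
with how the pipeline sees a dead (fully chlorotic) plant. The bundled
`salt_stress_model()` reduces RGR by 20/30/56/84% for 50/75/100/150 mM
NaCl and gives the lethal dose a hazard of 0.125/day from day 4, i.e.
survival ≈ 67% at day 7 falling to ≈ 51% at day 9 — the senescence-driven
mortality pattern of severe salt stress. The age-decay variant
(baseline 0.51 day⁻¹, decay 0.93) reproduces both the ~20-fold 9-day area
increase and the ~2.4% mean green-area gain over 2-hour intervals in
8-day-old plants that quantifies the assay's short-interval sensitivity.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: leaf-level morphology and overlap, shadows,
specular highlights and condensation on lids, chlorosis (dying tissue
here jumps straight to background instead of passing through yellow),
plate-to-plate media colour variation, and any spatial correlation of
micro-climate across the growth area. Segmentation accuracy on real
images therefore still needs a one-off visual check of the preview
overlays; the synthetic benchmark validates geometry, bookkeeping and
statistics, not colour robustness.

## Growth and survival statistics

RGR uses the classical two-point formula
$(\ln A_2 - \ln A_1)/(t_2 - t_1)$; intervals touching a zero area yield
`NA` rather than an error, so deaths do not poison group summaries. The
default group RGR curve averages per-plant RGRs (each plant is its own
control for initial size); RGR of the group mean curve is available as an
option since both conventions appear in practice. Exponential fits are
ordinary least squares of $\ln A$ on $t$ over positive-area points (≥ 3
required), reporting Pearson's r of the linearised pairs and the
regression F-test p-value — "significance after linearisation". Quartiles
use linear interpolation between order statistics (`quantile` type 7,
the default of mainstream numeric stacks); the convention is fixed and
documented because published quartile tables depend on it. Survival at
day $d$ counts plants whose area stayed above the death threshold
(default 0 px, configurable) at every observation up to $d$; death is
absorbing by construction.

## Group comparison

Kruskal–Wallis (via `stats::kruskal.test`, mid-ranks and the standard tie
correction) compares treatments day by day; the degenerate all-equal case
returns H = 0, p = 1 instead of failing on the vanishing tie correction.
The Conover–Iman post-hoc compares mean ranks with the pooled rank
variance,
$t_{ij} = (\bar R_i - \bar R_j)\big/\sqrt{S^2\,\tfrac{N-1-H}{N-k}
(\tfrac1{n_i}+\tfrac1{n_j})}$, on $N-k$ degrees of freedom, with
$S^2 = (\sum r^2 - N(N+1)^2/4)/(N-1)$ handling ties. P-values are
**unadjusted by default** — the letter tables this mirrors show no sign of
multiplicity correction, and each day is tested separately — with Holm
(or any `p.adjust` method) one option away for the cautious. Letters use
the insert-and-absorb algorithm and are anchored to descending group
medians, so the best-growing group always carries "a"; sharing a letter is
exactly equivalent to a non-significant pairwise difference, a property
the tests verify exhaustively for up to five groups.

## Numerical choices and degenerate inputs

- Similarity fits are closed-form complex regressions; no iteration, no
  tolerance knobs. Candidate de-duplication rounds transform parameters
  to 10⁻³ before comparison.
- Score ties between candidate registrations are broken arbitrarily by
  sort order; the validation loop, not the score, carries the decision
  weight in ambiguous cases.
- Empty masks are valid everywhere (an empty plate measures all zeros);
  empty groups, zero-variance correlations, out-of-range well indices and
  malformed filenames raise informative errors.
- Measured areas are rounded to whole reference-scale pixels so tabular
  round-trips are lossless.

## Problem sizes in the test-suite

The suite renders at 640 × 512 px (the full platform geometry at ~3.9
px/mm) — a size chosen so the complete suite, including a 50-plate
end-to-end recovery benchmark, a 54-image workflow demo, and a
5000-replicate null calibration of the Kruskal–Wallis test, runs in a few
minutes; one full-resolution 2500 × 2000 render verifies the platform
image format. At the test scale the pipeline recovers per-well areas with
a median relative error well under 1% and a worst case under 5% across
randomised poses (scale 0.9–1.1, rotation ±5°, translation ±12 px,
varied distortion and noise).

## Known limitations

- One plant per well is assumed; merged rosettes from neighbouring wells
  are not split (wells are far enough apart that this arises only from
  gross mis-seeding).
- The registration template expects the keyed four-mark tray; trays with
  symmetric mark sets still work (the validation loop resolves the
  ambiguity when the well grid is asymmetric in the image) but lose the
  geometric guarantee, as the retry tests illustrate.
- Tabular output is CSV with a fixed column schema (`filename, date, x,
  y, area_1..n`), chosen for lossless round-trips and version control;
  spreadsheet users can open it directly.
- Survival uses a hard area threshold; a wilting plant whose area decays
  but never reaches the threshold counts as alive.
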