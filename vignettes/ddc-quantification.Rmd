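---
title: "Quantifying dilated deep capillaries on en face OCTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dilated deep capillaries on en face OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcquant)
```

## The measurement problem

Diabetic retinopathy remodels the deep capillary plexus: alongside the
normal fine mesh, dot-like (microaneurysm-like) and string-like
(dilated-segment) capillaries of supra-normal caliber appear. On an en
face OCTA angiogram of the deep layers these two populations differ most
reliably in *caliber*: the normal mesh is almost entirely at or below 6
pixels of width on a 1024 × 1024 grid covering a nominal 3 × 3 mm field,
while the dilated lesions are wider. `ddcquant` turns that observation
into a per-eye biomarker, the **DDC index**: the percentage of each
ETDRS-style sector occupied by vessel signal that survives a
caliber-selective morphological filter.

The pipeline is deterministic — no training, no per-image tuning — which
is what makes it auditable: every number is a pixel count.

## Pipeline stages and their parameters

### Binarization

The angiogram is first contrast-stretched: with saturation fraction
$s$ (default $0.0035$, i.e. 0.35 % of pixels allowed to clip at each
tail — the stock behavior of ImageJ's automatic brightness/contrast),
the intensity quantiles at $s$ and $1-s$ map linearly to 0 and 255.
Concretely, with $k = \lfloor s n \rfloor$, the lower bound is the
smallest intensity level remaining after discarding the $k$ darkest
pixels, and symmetrically for the upper bound. A constant image has no
dynamic range and is passed through unchanged (with a message); it then
fails thresholding with a degenerate-histogram error rather than
producing an arbitrary mask.

The stretched image is re-quantized to integer levels and thresholded by
the Kapur maximum-entropy criterion: choose $t$ maximizing
$H_{bg}(t) + H_{fg}(t)$, the Shannon entropies of the normalized
histogram restricted to levels $\le t$ and $> t$. Conventions that matter
and are fixed here: $0\log 0 = 0$; natural logarithms (the argmax is
base-invariant); candidate splits leave both classes nonempty; ties break
toward the smallest $t$; and foreground is *strictly above* $t$, so the
vessel class is always the brighter one. A global threshold is used
deliberately — bright non-vascular material (suspended scattering
particles in motion) is handled by the global statistics of the image,
not by local adaptation.

### Caliber filtering

Fine vessels are deleted by iterated binary erosion with ImageJ "Erode"
semantics: per pass, a foreground pixel becomes background iff at least
`neighbor_count` of its 8 neighbors are background. With the defaults
(3 iterations, count 1) this equals classical erosion by a 7 × 7 square
structuring element, so an axis-aligned stripe of width $w$ is removed
completely iff $w \le 2 \cdot \text{iterations} = 6$. That cutoff *is*
the biological selection: the normal mesh vanishes, dilated lesions keep
a core. Pixels beyond the border count as background by default
(foreground touching the edge erodes inward); the alternative
("foreground", ImageJ's pad-edges option) is available via
`erode_params()`. Two known geometric properties are documented rather
than corrected: a 45°-oriented vessel of perpendicular width $w$ has
Chebyshev thickness $w/\sqrt2$ and is removed at somewhat larger widths,
and vessel *crossings* locally exceed single-vessel caliber so branch
points are not always deleted.

### Sector geometry and magnification correction

Sector masks are built in physical units. Bennett's formula enters as a
pure isotropic rescale: relative to the reference axial length the
device assumes for its nominal field,
$\text{scale} = (AL - 1.82)/(AL_{ref} - 1.82)$, and the corrected pixel
pitch is `nominal_width_mm * scale / side_px`. The reference axial length
is not a device constant we can observe, so it is a configurable
parameter with default 24.2 mm (a standard emmetropic reference);
changing it rescales all sectors coherently. The fovea is assumed at the
exact image center — these scans are fovea-centered by acquisition — and
no fovea detection is attempted.

Masks use pixel-center membership with inner bounds inclusive and outer
bounds exclusive: center disc $d < 0.5$ mm, parafoveal annulus
$0.5 \le d < 1.25$ mm. Quadrants split the annulus along the two 45°
diagonals. Tie-break: pixels exactly on a diagonal belong to the
superior/inferior wedges (closed vertical, open horizontal wedges). On a
square grid an entire diagonal of pixel centers satisfies
$|dx| = |dy|$, so the vertical wedges are systematically larger than the
horizontal ones by exactly the tie count; the true grid symmetries —
superior = inferior and nasal = temporal counts — hold exactly, and the
tests assert precisely that. Laterality maps the horizontal wedges to
nasal/temporal: in standard fundus orientation the nasal retina is the
image's right half for OD and left half for OS, overridable by
`nasal_side_override` because export conventions vary.

Because the correction rescales the grid (not the image), a longer eye
has fewer pixels per retinal millimetre: sector *pixel* counts shrink as
axial length grows while sector *areas* in mm² stay fixed — an invariant
the tests check across AL ∈ {22, 24.2, 26} mm.

### The index

For each sector, `index = 100 · |DDC ∩ sector| / |sector|`. The
denominator is the whole sector area, not the pre-erosion vessel area:
the biomarker is a relative area of dilated signal, comparable across
eyes regardless of overall vessel density. The all-sectors value uses the
full 2.5 mm disc and is therefore the area-weighted mean of the five
sector indices. Indices are printed to three decimals (in percent) and
kept at full precision internally. Eligibility QC (signal strength ≥ 8,
axial length within [22, 26] mm, missing fields reported explicitly)
annotates results by default instead of dropping eyes, so cohort-level
exclusion remains reproducible.

## The phantom generator

There is no deposited image data for this pipeline, so the package
carries its own test substrate. `generate_phantom()` emulates exactly the
features the pipeline measures:

- a **normal mesh** of smoothed random-walk paths (persistent-heading
  control points, spline-densified) stroked at widths 2–5 px, grown until
  a target vessel fraction (default 0.2) is reached;
- **dot lesions**: ellipses with axis diameters 8–14 px, attached to mesh
  points at random orientation;
- **string lesions**: short smooth paths (30–80 px) stroked at widths
  8–12 px;
- intensities as class means (background 30, vessels 170, lesions 200)
  plus additive Gaussian noise (SD 12), clipped to [0, 255].

Strokes are rasterized as a 1-px centreline thickened to all pixels
within Euclidean distance $(w-1)/2$, so effective calibers are odd (an
even requested width rounds down by one); recorded lesion calibers are
the effective ones. Two design details keep the generator honest as a
ground-truth source:

- **Sub-threshold mesh by construction.** Individual strokes are ≤ 5 px,
  but overlapping strokes can form composite structures wider than the
  cutoff. A thinning step removes the 7 × 7 neighborhood of any mesh
  pixel that would survive the default erosion; by monotonicity of
  erosion one pass guarantees the lesion-free mesh erodes to nothing.
  This is what makes the lesion-free phantom a genuine false-positive
  control (index ≤ 0.01 %).
- **Single seeded generator.** All randomness flows from `spec$seed`
  through one RNG whose state is saved and restored, so phantoms and
  cohorts are bit-reproducible and never perturb the caller's RNG.

What the phantom deliberately does *not* model: decorrelation/speckle
statistics, projection artifacts, flow-dependent signal, 3-D structure,
or realistic vascular topology (no closed capillary loops, no perfusion
physiology). Passing tests on phantoms therefore demonstrate that the
*measurement chain* — thresholding, caliber selection, geometry,
counting — is correct under a controlled imaging model; they do not
certify performance on device images, where segmentation quality and
artifact handling dominate.

### Ground truth and what "recovery" means

The caliber filter reports the *eroded remnant* of a lesion, which is
necessarily smaller than the lesion's full footprint (a disc of radius
$r$ erodes to radius $r-3$). Parameter recovery is therefore defined
against the quantity the pipeline estimates: the index obtained by
running the caliber filter directly on the noise-free ground-truth vessel
mask. The pipeline (which additionally has to binarize the noisy image)
must match that reference within 10 % relative error. Monotonicity in
lesion burden is checked separately: across a 20-phantom dose–response
sweep (dot counts $2s$ and string counts $s$ for $s = 1..20$, spanning
none-to-severe burden around the synthetic cohort's DR range), the
pipeline index must rank-correlate with the raw ground-truth lesion
fraction at ρ ≥ 0.9. Raw lesion area and eroded remnant are *not*
rank-interchangeable at fixed burden — random caliber mixes decouple
them — which is why the sweep, not a set of identical-burden phantoms, is
the designed experiment.

## Statistical battery

The cohort-level tools mirror standard nonparametric reporting for this
kind of ophthalmic data: median (IQR) per sector per group with
Kruskal–Wallis omnibus p-values (tie-corrected, chi-square reference),
pairwise rank tests Bonferroni-corrected by the number of pairs,
two-sided Fisher's exact test, and ROC AUC. Conventions that differ
between software packages are pinned down:

- **Fisher two-sided rule**: probability-mass ordering (sum of
  same-margin tables with hypergeometric probability ≤ the observed
  table's), the dominant convention in standard statistics software.
- **Quartiles**: linear interpolation between order statistics
  (`quantile` type 7).
- **AUC**: the Mann–Whitney pair-counting identity (ties count half);
  the threshold-sweep ROC curve integrates to the same number by
  construction, and the tests require agreement to 1e-12.
- **DME rule**: CST strictly greater than 320 µm (male) / 305 µm
  (female); `decimal_to_logmar()` is $-\log_{10}(\text{VA})$.
- α = 0.05 throughout.

No mixed-effects adjustment is made for patients contributing two eyes;
cohort summaries treat eyes as independent, and this limitation is
inherited knowingly.

## Numerical choices and degenerate inputs

- Images deeper than 8 bits are linearly rescaled by their maximum on
  load; the contrast stretch renormalizes anyway.
- Resampling (e.g. a device-native 300 × 300 grid onto 1024 × 1024) is
  bilinear with pixel centers at $((i-0.5)/n)$ in unit-square
  coordinates — monotone and overshoot-free, so constants are exact and
  outputs stay within the input range. The device's true interpolation
  kernel is unknown; bilinear is the conventional assumption.
- Degenerate inputs fail loudly at a named stage: constant images raise
  a degenerate-histogram error, non-square rasters a geometry error,
  corrected fields narrower than 2.5 mm a geometry error, and batch
  processing records per-eye errors in an `error` column without
  aborting the cohort.

## Problem sizes

Module tests exercise the pipeline at 256–512 px grids; the end-to-end
recovery suite runs 20 phantoms plus 3 false-positive controls at the
full 1024 × 1024 analysis grid, and the geometry oracle runs at 1024².
The statistics oracles use exhaustive enumeration for all 2 × 2 tables
with total ≤ 20 and a 100,000-draw permutation reference for the
Kruskal–Wallis p-value.
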