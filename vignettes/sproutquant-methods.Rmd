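---
title: "Quantifying explant sprouting area: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying explant sprouting area: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutquant)
```

## The measurement problem

Organotypic sprouting assays (choroid explants, aortic rings) read out
angiogenic activity as the area covered by microvessels growing out of an
embedded tissue fragment. Two practical complications shape the method:

* the explant body itself occupies a large, variable area that must be
  excluded — and explant size does not predict sprouting, so it must be
  *subtracted*, never used as a denominator;
* absolute sprouting areas drift between independent experiments (tissue
  preparation, media, microscope settings), so treatment effects are only
  comparable after normalizing each sample to the mean of the control
  group *within the same batch*.

`sproutquant` implements the computerized pipeline (deterministic
magic-wand selection of the explant, deletion, thresholding of the
sprouts) together with the traditional manual readout (total outline minus
explant), the normalization, and the assay's standard statistics.

## Pipeline stages and their parameters

**Seeded region growing (`magic_wand`).** The user supplies one seed pixel
inside the explant. The selection is the maximal 8-connected region
containing the seed whose members differ from the *seed pixel's* intensity
by at most `tolerance_fraction` of the full dynamic range. Two deliberate
choices:

* *Fixed reference.* The reference is the seed value (optionally the 3×3
  median around it, `seed_median_3x3`), never a moving average of the
  growing region. A moving reference makes the result depend on traversal
  order; with a fixed window the region is a well-defined set and the
  flood fill merely enumerates it. The compiled breadth-first kernel is
  order-independent by construction and is cross-checked in the test suite
  against a brute-force flood fill.
* *Tolerance semantics.* Interactive wand tools variously interpret
  "tolerance 30" as absolute gray levels or as a percentage. We define it
  as a fraction of the dynamic range (default `0.30`, i.e. ±76.5 gray
  levels on 8 bits) because it is depth-invariant; a user who needs the
  absolute-gray-level behaviour can pass
  `tolerance_fraction = k / (2^bit_depth - 1)`.

Connectivity is 8-connected for region growth and 4-connected for the
border test in `fill_holes`, the conventional pairing that prevents
diagonal "leakage" of background into the filled region.

**Explant deletion (`delete_explant`).** Explant pixels are replaced by the
modal intensity of the remaining pixels (ties broken toward the lower gray
level). A zero fill would inject a spurious dark class into the histogram
and bias the subsequent automatic threshold; the background mode is the
least informative value available.

**Thresholding (`threshold_sprouts`).** Default is Otsu's criterion,
computed by exhaustive search over all `2^bit_depth - 1` candidate cuts of
the post-deletion histogram — deterministic, and cheap even at 16 bits.
The dark mask is `v <= t` (phase-contrast vessels are darker than the
background halo); `bright_objects` is the exact complement. When several
cuts achieve the same between-class variance (e.g. an image with two
isolated gray levels) the smallest is returned, a documented tie-break
that keeps the dark class minimal. Assays thresholded by eye are
reproduced with `threshold_method = "fixed"`.

**Background exclusion (`exclude_background`).** An optional keep-polygon
clears sprout-mask pixels outside it, replacing the interactive
free-selection step. Membership is decided at pixel centers by the
even-odd rule, with centers exactly on the boundary counted *inside* (the
inclusive convention makes an axis-aligned rectangle through centers keep
those pixels, and makes polygon areas commensurable with mask areas).
Vertices outside the canvas are clipped to it with a warning.

**Residual-overlap rule.** Whatever the threshold does, sprout pixels
falling inside the (hole-filled) explant mask are removed as the last
step, so the two masks are disjoint by construction.

**Manual variant (`manual_quantify`).** The traditional readout subtracts
the explant area from a total outline. Since no record states how such
outlines are drawn in practice, the package accepts an explicit polygon or
builds the convex hull of the segmented explant + sprouts
(`hull_outline`), which is what the cross-method comparisons in the test
suite use. The manual readout includes extracellular space and therefore
upper-bounds the computerized one on every sample — the qualitative
relationship the assay literature reports.

**Calibration.** Areas are `pixels × (c/1000)²` mm² for `c` µm per pixel
edge. Calibration is a required manifest column; no microscope default is
assumed (the CLI falls back to 1.0 µm/px with an explicit warning so
pixel-unit results remain usable).

## Statistics

Group summaries are mean ± SEM (`sd/√n`, undefined and reported `NA` at
n = 1). Two groups are compared with the pooled-variance two-tailed
unpaired t-test (`var_equal = FALSE` gives Welch's test); the degenerate
all-identical case returns p = 1 by convention. Three or more groups use
one-way fixed-effects ANOVA; two crossed factors use two-way ANOVA with
interaction and Type II sums of squares — the assay's designs are
near-balanced, where Type II is well defined without an ordering choice.
Pairwise comparisons are pooled t-tests with Bonferroni multiplication
over the pairs actually tested. Normality is assumed rather than tested,
as is standard for this assay; a caveat is emitted whenever a group has
fewer than 4 observations, where no test could detect non-normality
anyway.

## What the synthetic generator emulates

`generate_sample` paints, on a 192×192 8-bit canvas by default: a dark
rotated ellipse (the explant, gray level 30, semi-axis 22 px, aspect
0.85), thin darker filaments radiating outward (the sprouts, gray level
130, width 3 px, quadratic Bézier curves with per-sprout random curvature
and length jitter), a bright background (gray level 220), and i.i.d.
Gaussian read noise (σ = 4 by default) added after the ground-truth masks
are frozen. The RNG is fixed (Mersenne–Twister, inversion normals) and
every sample is bit-reproducible from its seed.

Intensity choices are load-bearing: the default 30 % wand window around an
explant seed spans ±76.5 gray levels, so sprouts (|130 − 30| = 100) and
background (|220 − 30| = 190) are excluded, mirroring the real assay where
the wand selects only the dark compact tissue. The generator refuses
configurations whose sprouts are not darker than the background, since the
thresholding polarity contract would be violated.

Filaments are rasterized as true tubes — a pixel is painted when its
center lies within `width/2` of the curve, by exact point-to-segment
distance — so painted area per unit length does not depend on filament
angle, and each curve is rescaled to its nominal *arc* length so curvature
does not change area either. Filament anchors sit on a ring whose radius
is an explicit parameter (default: explant radius + 2 px), which decouples
sprout painting from explant size; this is what makes the explant-size
independence property (±1.5× radius, < 1 % area change) expressible and
testable. Residual geometric variation between samples — angle and
curvature draws interacting with the pixel grid and occasional filament
overlaps — is below ~1 % SD of painted area.

`generate_dose_batch` arranges samples into the assay's standard
dose-response design: doses 0/10/50/250 with 8 samples per dose, dose 0
labeled `control`. Expected true sprout area follows a saturating Emax
curve `baseline · (1 + Emax · d/(d + EC50))` (defaults: baseline 1100 px,
EC50 = 50, Emax = +1 for stimulation, with Emax = −0.8 modeling an
anti-angiogenic compound); the Emax form is our design choice for a
bounded, monotone "dose-dependent" response. Biological variability is a
per-sample multiplicative lognormal factor with unit mean and CV 0.15 (and
it also switches the per-sprout length jitter on; a zero-CV model is fully
noise-free apart from the grid effects above). Per-sample target areas are
realized by scaling filament count and length with √factor, subtracting
the π(w/2)² end-cap overhead per filament, and clamping lengths to the
canvas with count compensating — realized ground-truth areas track targets
to within ~1 %.

What the generator does **not** emulate: phase-contrast halo ringing and
shading, anastomosis and branching of vessels, debris and pigmented
contamination, uneven illumination. Passing tests therefore demonstrate
correctness of the measurement pipeline on images with known truth and
controlled noise, not robustness to every real-world artifact; on real
images the seed point, tolerance, threshold choice and keep-polygon remain
the operator's responsibility.

## Problem sizes in the shipped tests

The test suite validates the wand against a brute-force oracle on 100
random images up to 20×20; recovery, ordering and size-independence
properties on 192×192 samples (exact recovery without noise, ±5 % at
σ = 4 over 20 replicates); and dose-response recovery on 100 replicate
batches (4 doses × 8 samples) for stimulation plus 20 for suppression,
requiring a Bonferroni-significant top-dose-vs-control comparison in ≥95 %
of replicates. The normalized dose estimates averaged over replicate
batches sit within a few percent of the model expectation; single batches
scatter around it with the ≈5 % standard error implied by CV 0.15 at
n = 8.

## Known limitations

* The wand's fixed-reference window can under-select explants with strong
  internal intensity gradients; `seed_median_3x3` helps with noisy seeds
  but not with gradients. Real deployments may need per-image tolerance.
* Otsu assumes a roughly bimodal post-deletion histogram; sparse sprouts
  on a textured background can defeat it (use a fixed threshold and the
  keep-polygon).
* The manual method's convex hull is a conservative automatic stand-in
  for a hand-drawn outline; it is intended for method comparison, not as
  a faithful reconstruction of any particular operator's tracing.
* Time-course designs are analyzed per day (each day a batch
  cross-section); there is no repeated-measures model.
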