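---
title: "Image-based damage scoring for seedling seed-box screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based damage scoring for seedling seed-box screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopperburn)
```

## The measurement problem

Bulk seedling seed-box tests expose rows or patches of many rice
varieties to planthoppers and rate each variety's damage by eye on the
0–9 Standard Evaluation System (SES) scale. Phloem feeders kill slowly
and chromatically: chlorophyll loss moves the canopy from green through
yellow toward the reddish-brown of hopperburn (brown planthopper,
*Nilaparvata lugens*) or a grey-straw colour (whitebacked planthopper,
*Sogatella furcifera*), and some of those transitions are hard for a
human rater to resolve. `hopperburn` replaces the subjective rating with
quantities computed from ordinary colour photographs of seedling
patches: mean red, green and blue reflectance of the foreground pixels,
derived colour coordinates, and vegetation indices, scored relative to a
susceptible check variety that anchors each test.

## From photograph to channel means

A patch photograph is segmented by colour range: a pixel is foreground
when its Euclidean distance in RGB space to the nearest colour of a seed
palette falls below a threshold (default 60 on the 0–255 scale). The
palette deliberately includes senescent straw, brown and
elevated-red/blue tones: dead seedlings must remain foreground, or every
index would be biased toward survivors. The threshold is a free
parameter exposed in configuration — the interactive tool it emulates
does not document a comparable setting — and an HSB-space variant is
available for sensitivity checks. Foreground pixels are reduced to
arithmetic channel means (`summarize_patch()`), which is the package's
fundamental record.

All subsequent colour arithmetic happens on proportions (mean / 255).
Ratio quantities (hue, saturation, normalized r, g, b, NGRDI, GDR, GLI,
VARI, DGCI) are unaffected by the rescaling; additive ones (chroma,
brightness, GMR, TGI) are reported on the 0–1 scale.

## Colour coordinates and indices

Hue uses the standard piecewise hexcone formula keyed on the largest
channel, with negative results wrapped into [0, 360). Achromatic inputs
have no hue; they are reported as hue 0 with an explicit `achromatic`
flag rather than silently contributing a fake 0°, and DGCI — the only
index that consumes hue — is missing for them. Saturation is
chroma/max; brightness is the channel maximum. Luminosity uses Rec.601
luma weights (0.299, 0.587, 0.114); it is carried as capture metadata
only and no index consumes it, because the histogram tools that report
"luminosity" use a weighted luma whose exact weights are not part of
any index definition here.

The indices are computed means-first: the index of the patch's mean
colour, not the mean of per-pixel indices. That mirrors the
histogram-mean workflow the package emulates; a per-pixel mode
(`per_pixel_index()`) exists for sensitivity analysis and its outputs
are labelled as such. Canonical published forms are the default:

* NGRDI = (G − R)/(G + R)
* VARI = (G − R)/(G + R − B)
* GLI = (2G − R − B)/(2G + R + B)
* TGI = −0.5·[190(R − G) − 120(R − B)]
* DGCI = [(H − 60)/60 + (1 − S) + (1 − V)]/3

Some circulating tabulations of GLI and TGI contain typographic
variants; `literal = TRUE` (or `--table1-literal` on the command line)
evaluates those variant strings side by side for auditing. The variant
VARI string parses to the same value as the canonical form, and the
variant DGCI string is not parseable at all, so the flag affects only
GLI and TGI. Degenerate denominators (GDR at R = 0, NGRDI at G + R = 0,
VARI at G + R = B) produce a missing value and a warning, never an
error: one black patch must not abort a screen.

## Time standardization and condition change

Replicate tests end on the day the susceptible check dies, so durations
vary (6–10 days). Sampling days are mapped to proportional time,
rounded to the nearest 0.1 with halves rounded up (the rounding
direction is a package choice; only "nearest 0.1" is inherited).
Relative damage is evaluated on final-day data only (proportional time
1.0), with split control arms pooled and a variety's sub-replicate
patches averaged within a tray.

Condition change for a variety under one infestation is
ΔIndex = Index(infested) − Index(control), computed within each
replicate and then averaged; pairing deltas by replicate preserves the
blocking the tray design implies, and was preferred over a delta of
grand means (both orders agree in expectation; the paired order has
smaller variance under replicate effects). The proportional condition
change is the variety's averaged delta divided by the check's, and its
reciprocal (`foldBetter`) expresses the same quantity as "n times
better at holding condition than the check"; both are emitted because
the ratio reads naturally in either direction. A check delta of exactly
zero leaves the ratios undefined (missing, with a warning). SES scores
band as 0–3 resistant, 4–6 moderately resistant, 7–9 susceptible.

## Permutation inference

The inferential layer is deliberately permutation-based rather than a
reimplementation of classical repeated-measures GLMs and Duncan/Tukey
post-hoc machinery:

* `permanova()` computes a pseudo-F from the Euclidean distance matrix
  of colour triplets, with p = (b + 1)/(B + 1) over free label
  permutations (default B = 999; the count is a default, not a
  reconstruction of any published analysis), or exact enumeration of
  all n! relabellings for n ≤ 8.
* `pairwise_permanova()` runs two-level tests per pair (statistic √F)
  with Holm adjustment by default.
* `many_to_one()` compares each variety's final-day values against the
  check by a two-sample permutation test on the mean difference,
  enumerating group assignments exhaustively when feasible, with Holm
  adjustment across varieties. A variety is flagged "less damaged" only
  when its adjusted p ≤ α and its mean lies on the better-condition
  side. Because the check is sown on seven patches per tray, it
  contributes ~21 final-day values; that replication is what gives the
  many-to-one comparisons their resolution at three replicates.
* `pcoa()` provides unconstrained principal coordinates on the same
  distance matrix in place of constrained (canonical) ordination — the
  visualization intent is preserved without canonical discriminant
  machinery, and this substitution is a documented deviation.
* Nested random-factor structure (variety within treatment) is
  simplified to crossed fixed factors tested separately under free
  permutation; exact nested permutation schemes are under-determined
  for this design and are out of scope.

All permutation p-values obey the (b + 1)/(B + 1) form and can never be
zero; seeded runs are exactly reproducible.

## The synthetic generator: a stated world

No public pixel-level dataset accompanies the screening protocol this
package implements, so the generator is a first-class, tested module
that states the world downstream stages are validated against:

* **Latent severity** follows a logistic in days,
  `plogis(rate·((1 − ρ)·m·t − midpoint))` with rate 1.2/day and
  midpoint 4, where ρ ∈ [0, 1] is the variety's resistance to the
  attacking species and m a lognormal replicate multiplier (sd 0.08).
  Control severity is identically zero. The logistic's early-flat/
  late-steep shape gives the test-termination rule a well-defined
  crossing; the replicate multiplier spreads durations over the 6–10
  day window.
* **Channels** are baseline + aging drift + severity · treatment shift
  + Gaussian noise, clamped to [0, 255]. The healthy baseline is
  (62, 108, 48); aging adds 1.2/day red and 0.8/day blue plus a
  mid-test green flush (Gaussian bump, amplitude 8) that reproduces the
  "greening" of non-infested controls. The brown planthopper shift at
  full severity is (+70, −40, +55) — strong red and blue gain — and the
  whitebacked shift (+40, −25, +50) retains proportionately more green,
  so final red is higher under brown planthopper, as the two species'
  distinct pathologies require.
* **Noise** is 3 intensity units per channel, doubled for the
  whitebacked arm: its between-replicate variability (most visible in
  hue) is characteristically larger.
* **Damage records** on the final day: SES score = round(9·severity,
  halves up), binomial dead counts above a severity threshold of 0.7,
  and dry weight 400·(1 − 0.6·severity) mg plus noise; weight loss is
  the control-minus-infested contrast.
* **Plate map**: 45-square trays, one tray per arm per replicate, the
  check on 7 squares; 38 test varieties + 7 check patches fill a tray
  exactly. A dropout probability (default 0) emulates varieties that
  fail to germinate.

None of these numbers is an estimate from data: magnitudes were chosen
once to reproduce the qualitative orderings the screening literature
describes (red/blue rising with damage, the control greening phase,
brown-vs-whitebacked red ordering, larger whitebacked variance) and are
documented as such. A green test therefore establishes that the
pipeline recovers structure *of this stated kind* — monotone severity,
resistance ordering, calibrated type-I error — not that it reproduces
any particular greenhouse dataset. Real images additionally contain
geometry (leaf shape, shadows, specularity), white-balance drift and
rater noise that the renderer's sinusoidal strokes and iid pixel jitter
do not emulate.

## Numerical choices

* Half-up rounding for the 0.1 time grid and the severity-to-score map,
  with a 1e-9 guard against binary-representation edge cases.
* Hue ties broken in channel order R, G, B (first maximum), matching
  the common hexcone convention.
* Permutation comparisons use a 1e-12 slack when counting
  `F_perm >= F_obs` so exact re-achievements of the observed statistic
  are never lost to floating-point noise.
* PCoA drops eigenvalues below a relative 1e-9 tolerance and reports
  the count of negative ones rather than correcting them (Euclidean
  inputs, the only ones produced internally, have none).
* The segmentation default threshold (60) and palette are free
  parameters of the emulation, exposed in configuration; rendered-patch
  benchmarks verify precision/recall ≥ 0.99 at these defaults.

## Known limitations

* Camera calibration, white balance, frame geometry and raw decoding
  are out of scope; inputs are assumed to be calibrated 8-bit RGB.
* Choice tests measure relative damage, not tolerance: herbivore
  pressure is uncontrolled per variety, so condition change relative to
  the check must not be read as a tolerance estimate.
* The many-to-one and PERMANOVA analogues are not the classical
  GLM/Duncan machinery; where those procedures' exact numbers matter,
  this package is not a drop-in replacement.
* The generator's parameters are qualitative calibrations; quantitative
  agreement with any specific greenhouse series is neither claimed nor
  testable from published material.
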