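---
title: "Decoding and analysing shear wave elastography clips of muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and analysing shear wave elastography clips of muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweclip)
```

## The measurement problem

Shear wave elastography estimates tissue stiffness by tracking the speed of
induced shear waves; for muscle the convention is to report shear wave
velocity (SWV, m/s), which rises with stiffness. Clinical scanners display
the estimate as a color map (the *elastogram*) blended over the greyscale
B-mode image, and export recordings as multiframe DICOM clips in which only
the rendered RGB pixels survive — the numeric stiffness field does not.
Quantitative analysis therefore has to invert the display: find the
overlay, undo the color coding, and handle the pixels that carry no
information (void, rendered grey) or exceed the reliable range (saturated,
here > 9.9 m/s on a < 10 m/s scale).

Two rates coexist in one clip: B-mode frames refresh at about 11 Hz, the
elastogram only at 1.2–2.0 Hz, so consecutive frames repeat the same
overlay until the next update. A 30-s clip at 1.6 Hz holds ~330 frames but
only 48 distinct elastograms. `sweclip` models this explicitly with a
half-open tick convention: elastogram $i$ (0-based) covers acquisition
times $t \in [\,i/r,\ (i+1)/r\,)$ at elastogram rate $r$. The recorded
range 24–54 elastograms per 20–30-s clip is consistent with a constant
rate for almost all settings ($30 \times 2.0 = 60 > 54$ suggests the
instrument's effective rate can drop within a clip; the generator uses a
constant rate, which covers the tested range).

## Color scale

Vendors do not publish their lookup tables (LUTs), so the package makes the
LUT an explicit, swappable object (`color_scale()`). The default is a
200-point table at 0.05 m/s spacing over $[0, 9.95]$ m/s along a
blue→cyan→green→yellow→red path. Decoding finds each colored pixel's
nearest control point in RGB space and refines by projecting onto the
segments to the neighbouring control points, interpolating the velocity
linearly. Two consequences matter:

* the encode→decode round trip is bounded by half the quantization step
  (0.025 m/s) by construction, and in practice is limited only by 8-bit
  rounding (~0.005 m/s);
* analysing real instrument data requires calibrating a LUT from the
  on-screen color bar and passing it as `control_points`; nothing else in
  the pipeline changes.

Colored and grey pixels are separated by chroma,
$\max(R,G,B)-\min(R,G,B)$, with a default cutoff of 8/255 — cheap,
monotone, and robust to mild blending. The scanner blends the overlay at
about 50 % opacity; by default the LUT is taken to represent the
*blended* (on-screen) colors, and a `unblend` argument can invert a stated
alpha over a stated background where those are known.

## Quality control and grid

The elastogram's upper 1 mm is discarded (boundary artifacts), rounding
*up* in pixels so none of the discarded strip survives
(`ceiling(1 mm / spacing)`), and the remainder is tiled with fourteen
4 mm × 4 mm squares (`round(4 mm / spacing)` px per side): row A on top,
A1–A7 left to right, row B beneath. The grid anchors at the top-left of
the retained region — the horizontal placement is otherwise arbitrary, so
one deterministic choice is documented and a `center` anchor is offered.

Per square and elastogram the package extracts maximum, mean and median
SWV, SD, IQR, the percentage of colored pixels, and the count and
percentage of saturated pixels. Saturated pixels *remain* in the
statistics: saturation is reported as its own quantity, not used as a
filter. Quantiles use linear interpolation between order statistics
(`quantile` type 7), the single convention used by both the implementation
and the brute-force oracle in the tests.

Both QC rules read "50 %" strictly:

* a square-frame with **< 50 %** colored pixels is excluded (exactly 50 %
  is retained);
* an elastogram with **> 50 %** of squares excluded is discarded — 7 of 14
  retains the frame, 8 discards it.

The per-square reading of the frame rule (excluding square-frames rather
than whole frames on a pooled count) follows from the rule being attached
to the per-square quality count; the pooled alternative can be emulated by
raising `colored_cutoff_pct`.

Aggregation is a two-stage median — per square, the temporal median over
the square's included frames; then the median over squares with any
included frame — followed by a median over the (up to three) repetitions
of a condition. Medians match the nonparametric treatment of skewed
stiffness data; the mean is available by argument at both stages. The two
ratio measures, longitudinal/transverse (anisotropy) and single-leg-stance
/baseline (activation response), are computed per participant and then
summarised — so a group's median ratio is the median of participant
ratios, not the ratio of group medians. The activation ratio's numerator
is the single-leg-stance value: values > 1 then mean stiffening with
activity, which keeps the sign of the indicator aligned with its
interpretation; the reciprocal is available via `direction`.

## Statistics

**Reliability.** `icc_3_3()` implements the average-measures intraclass
correlation under the two-way model with *absolute agreement*,
$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$
with the F-based 95 % CI (Satterthwaite df) and
$\mathrm{SEM} = s_\text{pooled}\sqrt{1-\mathrm{ICC}}$, where
$s_\text{pooled}$ is the root of the mean per-repetition variance across
subjects (the SEM's base SD is not standardised in the literature, so the
choice is recorded here). The SPSS menu label "two-way mixed, absolute
agreement, average measures" is often written ICC(3,3), which collides
with Shrout–Fleiss naming where model 3 is the *consistency* form; the
result's `model` string therefore records the exact formula, and
`type = "consistency"` gives $(MS_R - MS_E)/MS_R$.

**Group comparisons.** Kruskal–Wallis (tie-corrected H, $\chi^2_{k-1}$
approximation) as omnibus test at $\alpha = 0.05$, followed — for
significant omnibus results, strict $p < 0.05$ — by pairwise asymptotic
Wilcoxon rank-sum tests: rank-sum W, tie-corrected normal z, two-sided p.
No multiplicity correction is applied by default, mirroring common
reporting practice for these designs; Holm and Bonferroni are opt-in. At
tiny samples the asymptotic p-values differ visibly from the exact
permutation distribution (e.g. three groups of three: 0.027 asymptotic vs
0.004 exact); the tests treat the oracle comparison as an
approximation-quality bound, not an identity.

**Correlation.** Spearman's ρ with average ranks for ties and asymptotic
p. Interpretive bands on $|\rho|$: below_fair $[0, 0.25)$, fair
$[0.25, 0.50)$, moderate_to_good $[0.50, 0.75)$, good_to_excellent
$[0.75, 1]$ — boundaries assigned upward, a documented resolution of the
conventional but ambiguous wording "between 0.25 and 0.50".

**Planning.** `anova_power_n()` searches the smallest total $N$ whose
one-way fixed-effects F-test power (noncentrality $f^2 N$, df $k-1$ and
$N-k$) reaches the target. `wmw_power_n()` uses the asymptotic relative
efficiency route: solve the two-sample t size via the noncentral-t
distribution at $d$ (for a pairwise contrast within a design planned on
Cohen's $f$, $d = 2f$), inflate by $1/\mathrm{ARE}$ with
$\mathrm{ARE} = 3/\pi$ for normal parents, and round up to the smallest
even total. At $f = 0.48$, $\alpha = 0.05$, power 0.80 these give
$N = 45$ and $N = 38$.

## The phantom generator

`make_phantom_clip()` writes image-level phantoms — constant, gradient, or
lesion-patch SWV fields rendered through the same LUT into multiframe RGB
DICOM (explicit VR little endian; the package includes a minimal writer
and reader for exactly this profile, cross-checked against an independent
DICOM implementation in the tests). The phantom reproduces the features
that make real clips awkward: the 11 Hz / 1.2–2.0 Hz rate mismatch, void
pixels redrawn at every elastogram tick, an optional saturation patch
rendered at the top of the scale, 20/30-s durations, and physical pixel
spacing. Ground truth (exact fields, masks, tick indices) is returned
alongside the file and never re-derived from it.

Defaults are chosen once to mimic a plausible recording: 0.2 mm/px
spacing; a 70 × 150 px overlay (14 × 30 mm — comfortably above the
1 mm + 8 mm × 28 mm the grid needs); elastogram rate 1.6 Hz; noise SD
0.05 m/s (small relative to reported between-group differences of
0.1–1 m/s); void fraction 0.10, in line with the high data-inclusion rates
of longitudinal scanning. The cohort simulator draws trial values as group
median + participant offset (SD 0.20 m/s) + trial noise (SD 0.10 m/s),
with group × muscle × task × orientation medians seeded from published
reference values for the three-group knee-OA design (21/21/20
participants, baseline once and three repetitions otherwise, both
orientations: 20 trials per participant, 1240 in total).

What the phantoms deliberately do **not** model: acoustic physics, speckle
statistics, probe motion, tissue inhomogeneity beyond the planted field,
or a vendor's true (unpublished) LUT and blending. Passing the test suite
therefore demonstrates that the *computational* pipeline is correct given
a known color coding — not that any particular scanner's clips decode
correctly without LUT calibration.

## Numerical choices and degenerate inputs

* Velocities are clamped to the LUT range before encoding; decode errors
  are bounded by half the 0.05 m/s quantization step.
* A square with no valid pixel yields `NA` statistics and
  `colored_pct = 0`; a clip whose elastograms are all discarded yields an
  invalid trial with an explicit reason rather than an error.
* Missing repetitions propagate `NA` through `collapse_repetitions()`;
  ratios are defined only when both operands exist and are positive.
* Overlay detection requires at least one colored pixel and picks the
  largest connected component, making it invariant to appended all-grey
  frames and to small colored artifacts.
* All rectangles are 0-based half-open; square sizes in pixels derive from
  physical units by `round()`, the top discard by `ceiling()`.
* Test problem sizes are chosen to exercise every rule at desk scale: 20-
  and 30-s phantoms (220/330 frames), cohorts of 62, null-distribution
  checks at 2000 replicates, ICC recovery at n = 200 subjects.

## Known limitations

Real-scanner integration needs a calibrated LUT (sketch: sample the
on-screen color bar at known velocities and pass the table as
`control_points`); the DICOM i/o intentionally covers only the
uncompressed multiframe RGB profile the phantoms use; and reliability
tables printed with identical rows across conditions in source material
cannot be distinguished from transcription artifacts — reliability here is
validated against simulated variance components and an independent
implementation instead.
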