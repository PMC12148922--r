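# sweclip

Muscle stiffness around an osteoarthritic knee is usually assessed by
ultrasound shear wave elastography (SWE): the scanner superimposes a color
*elastogram* — a map of shear wave velocity (SWV, m/s; higher = stiffer) —
on the greyscale B-mode image. Exported clips interleave the two streams:
B-mode frames at ~11 Hz carrying an elastogram overlay that refreshes at
only 1.2–2.0 Hz, with void (uncolored) pixels where shear wave tracking
failed and saturated pixels beyond the reliable range (> 9.9 m/s on a
< 10 m/s scale).

`sweclip` turns such clips into analysis-ready stiffness tables, for
researchers studying muscle mechanics in knee osteoarthritis and related
conditions. The pipeline:

1. **Decode** — locate the overlay within the frames, collapse repeated
   frames to the distinct elastograms, and invert the color lookup table to
   per-pixel SWV with validity and saturation masks.
2. **Grid & QC** — discard the elastogram's top 1 mm, tile the rest with a
   2 × 7 grid of 4 mm × 4 mm squares (A1–A7, B1–B7), and extract per square
   and frame: max, mean, median SWV, SD, IQR, % colored pixels, and the
   count/% of saturated pixels. Square-frames with < 50 % colored pixels
   are excluded; an elastogram with > 50 % of squares excluded (≥ 8 of 14)
   is discarded.
3. **Aggregate** — two-stage median (per-square temporal median, then
   median over squares) to a trial value; median over repetitions to a
   condition value; plus two scale-free ratios: longitudinal/transverse SWV
   (muscle anisotropy) and single-leg-stance/baseline SWV (activation
   response).
4. **Statistics** — ICC(A,k) reliability (two-way, absolute agreement,
   average of k = 3, F-based CI) with SEM = pooled SD · √(1 − ICC);
   Kruskal–Wallis and pairwise asymptotic Wilcoxon group comparisons;
   Spearman correlations with interpretive bands; and a-priori sample
   sizes for the one-way ANOVA (noncentral-F search) and the
   Wilcoxon–Mann–Whitney test (ARE method, 3/π for normal parents).

Because vendor color tables are unpublished, the package ships a synthetic
phantom generator (`make_phantom_clip()`) that writes multiframe RGB DICOM
clips with a *known* SWV field, frame-rate mismatch, void patterns and
saturation patches, plus a three-group cohort simulator
(`simulate_cohort()`). Every stage of the pipeline is validated against
this exact ground truth.

## Worked example

```r
library(sweclip)

sc   <- color_scale()                      # 200-point blue-to-red LUT over [0, 10) m/s
spec <- phantom_spec(base_swv = 4.5, void_fraction = 0.1, duration_s = 20,
                     elasto_rate_hz = 1.6, noise_sd = 0.05, seed = 42)
clip <- make_phantom_clip(spec, file.path(tempdir(), "demo.dcm"), sc)
res  <- analyze_clip(clip$path, sc)
res$summary[c("trial_swv", "frames_total", "frames_retained", "inclusion_pct", "valid")]
#>   trial_swv frames_total frames_retained inclusion_pct valid
#> 1       4.5           32              32           100 TRUE
```

The 20-s clip holds 220 B-mode frames but only 32 distinct elastograms
(20 s × 1.6 Hz, 11 Hz frames sharing each overlay until the next tick);
all 32 pass QC and the two-stage median recovers the phantom's 4.5 m/s
field exactly.

Group comparison on a simulated cohort (gastrocnemius medialis,
single-leg stance, longitudinal plane):

```r
cohort <- simulate_cohort(cohort_spec(seed = 7))
tab    <- build_cohort_table(cohort[c("participant_id", "group", "muscle",
                                      "task", "orientation", "repetition", "swv")])
sls    <- subset(tab, task == "single_leg_stance" & orientation == "longitudinal" &
                      muscle == "gastrocnemius_medialis")
groups <- split(sls$swv, sls$group)
kruskal_wallis(groups)$statistic
#> 25.91                      # H, p < 1e-4: the three groups differ
pairwise_wilcoxon(groups)
#>   group1      group2            w     z  p_value
#> 1 knee_OA     old_control      73 -3.51 0.000443
#> 2 knee_OA     young_control    66 -3.87 0.000108
#> 3 old_control young_control    66 -3.87 0.000108
```

The negative z for knee_OA vs. both control groups reflects the simulated
stiffness deficit of the OA group under load. Study planning:

```r
anova_power_n(effect_f = 0.48)   # 45  (k = 3, alpha = 0.05, power = 0.80)
wmw_power_n(effect_f = 0.48)     # 38  (d = 2f = 0.96, ARE = 3/pi)
```

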