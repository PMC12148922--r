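Package: sweclip
Title: Shear Wave Elastography Clip Analysis for Muscle Stiffness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiframe ultrasound shear wave
    elastography (SWE) clips of skeletal muscle. Locates the color
    elastogram overlay within B-mode frame stacks, decodes overlay colors
    to shear wave velocity with validity and saturation flags, segments
    the elastogram into a 2x7 grid of 4 mm squares with frame- and
    square-level quality control, aggregates per-square statistics into
    trial- and participant-level stiffness values, and computes the
    longitudinal-to-transverse anisotropy ratio and the single-leg-
    stance-to-baseline activation ratio. Includes reliability (two-way
    mixed, absolute-agreement average-measures intraclass correlation
    with standard error of measurement), nonparametric group comparisons
    (Kruskal-Wallis, pairwise asymptotic Wilcoxon), Spearman correlation
    with interpretive bands, and a-priori sample-size calculations for
    the one-way ANOVA and the Wilcoxon-Mann-Whitney test. A synthetic
    phantom-clip and cohort generator with exact ground truth makes the
    whole pipeline testable without any instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
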