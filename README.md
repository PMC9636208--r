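# fibroCPA

Automated quantification of liver fibrosis on picrosirius red (PSR) stained
whole-slide images, for preclinical hepatology groups who need a continuous,
operator-independent fibrosis endpoint next to hydroxyproline assays and
histological staging.

Fibrosis is reported as the **collagen proportionate area (CPA)** — the
percentage of the delineated tissue area occupied by stained collagen. The
segmentation is the optical-density / SVD stain-separation pipeline:

1. per-channel absorbance `OD_c = log10(I0_c / max(I_c, eps))`, with `I0`
   estimated as a high percentile of the slide (clean glass);
2. tissue delineation by thresholding `||OD||_2`, with µm-specified
   morphological cleanup so 20X (0.452 µm/px) and 40X (0.226 µm/px) scans
   behave identically;
3. singular value decomposition of the uncentered OD vectors of tissue
   pixels (accumulated as a 3×3 Gram matrix in one pass);
4. projection of every pixel on the **third singular vector** `v3` — the
   least-variance axis of the tissue OD cloud, on which the sirius-red
   collagen contrast loads — and a single global threshold;
5. `CPA = 100 * collagen_px / tissue_px`, averaged per animal over its
   sections.

The pipeline is a pure function of the pixels and the configuration:
repeated runs are bit-identical (standard error of the collagen pixel count
over 5 runs is exactly 0), and results do not depend on the processing tile
size.

Because no real slides ship with the package, a **synthetic PSR generator**
(`make_slide()`, `make_cohort()`) produces slides with exact ground-truth
masks — septal (CCl4-like) or perisinusoidal ("chicken-wire") patterns,
picric-yellow parenchyma, red collagen, realistic texture, optics and sensor
noise — plus whole cohorts with CPA-linked hydroxyproline values and Ishak /
modified Ishak / NASH CRN stage labels. The validation statistics are
included: Spearman correlation, Fisher z, Steiger's one-sided Z for
comparing two dependent correlations that share the staging variable, and
the 20X-vs-40X regression. See `vignette("fibrocpa-methods")` for the model,
assumptions and numerical choices.

## Worked example

```r
library(fibroCPA)

slide <- make_slide(slide_gen_params(width_px = 1024, height_px = 1024,
                                     pattern = "septal", target_cpa = 10,
                                     seed = 42))
slide
#> <synthetic_slide> 1024 x 1024 px, 0.452 um/px, pattern septal, true CPA 10.006%

seg <- segment_slide(slide$image)
compute_cpa(seg, "demo")
#> <cpa_measurement> demo: 9.9860% (52357 / 524303 px)

rep5 <- repeatability_check(slide$image, n_runs = 5)
rep5$counts; rep5$se
#> [1] 52357 52357 52357 52357 52357
#> [1] 0
```

The true CPA of the generated slide is 10.006% (an exact mask pixel ratio);
the automated pipeline recovers 9.986%, an error of 0.02 percentage points,
and all five repeat runs return the identical collagen pixel count.

Comparing how strongly a staging score correlates with CPA versus with
hydroxyproline, on the same 35 animals (correlations share the score and are
therefore dependent):

```r
compare_dependent_correlations(r12 = 0.96, r13 = 0.81, r23 = 0.8266, n = 35)
#> <dependent_correlation_comparison> steiger_dependent: Z = 4.4194,
#>   p(greater) = 4.949e-06 (r12 = 0.960, r13 = 0.810, r23 = 0.827, n = 35)
```

CPA correlates significantly more strongly with the score than the
biochemical assay does.

## Command line

```sh
Rscript inst/cli/fibrocpa.R simulate cohort --output study --seed 1
Rscript inst/cli/fibrocpa.R segment study --output study_seg
Rscript inst/cli/fibrocpa.R analyze --sections study_seg/sections.csv \
    --metadata study/metadata.csv --output study_stats
Rscript inst/cli/fibrocpa.R validate
```

`segment` writes one CSV row per slide (pixel counts, CPA, singular values,
I0) plus a manifest with config snapshot and input checksums; `analyze`
writes the per-animal table and the correlation report (Spearman r of each
staging system with CPA and with HYP, Steiger Z, one-sided p).

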