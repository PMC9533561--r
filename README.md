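# immuneband

Spatial quantification of the tumor immune microenvironment from
segmented-cell tables, built for paired primary / liver-metastasis
colorectal cancer cohorts profiled by multiplex immunofluorescence.

Commercial mIF pipelines (inForm-style) export one row per segmented cell:
position, tumor/stroma compartment, and called positivity for each panel
marker (here CD8, Foxp3, CD68, CD163, CD20, CD11c, CD66b, CD56, PD-L1,
IFN-γ, Ki67, VEGFR-2). `immuneband` turns those tables into regional
immune statistics:

- **Boundary + banding** — the tumor boundary of each 20× field is
  estimated from tumor-compartment cells (raster, morphological closing,
  contour extraction) and every cell and pixel of tissue is assigned by
  exact signed Euclidean distance *d* to that boundary:
  TC (tumor center) for *d* < 0, TF (invasive front) for 0 ≤ *d* < 150 µm,
  PT (peritumor) for *d* ≥ 150 µm.
- **Densities** — each phenotype is reported as cells/mm² of regional
  tissue area, pooled over a lesion's 3–5 fields (Σcount / Σarea).
- **Macrophage colocalization subtypes** — CD68⁺CD163⁺, CD68⁺CD163⁻ and
  CD68⁻CD163⁺ cells, which partition the CD68/CD163-positive population.
- **Immunophenotypes** — each lesion is classified inflamed / excluded /
  desert from its CD8 densities: inflamed if TC density ≥ *t*, excluded if
  TC < *t* ≤ TF, desert otherwise (*t* defaults to the cohort median CD8
  TC density and is reported with every call).
- **Comparison battery** — two-sided Wilcoxon tests with exact small-sample
  null distributions: signed-rank for paired contrasts (TF vs TC and PT vs
  TF within lesions; primary vs metastasis within patients, per region and
  pooled) and rank-sum for clinical subgroups (1 vs >1 metastases,
  diameter < 3 vs ≥ 3 cm).

No cohort of this kind is public, so the package includes a synthetic
generator (`synth_config()` / `simulate_cohort()`) that emulates the full
study design — 17 patients, paired lesions, 3–5 fields each, disc tumors,
a 150 µm immune band, configurable per-region marker intensities and
CD68/CD163 joint states — together with ground truth for recovery testing.

## Worked example

```r
library(immuneband)

co  <- simulate_cohort(synth_config(seed = 101))   # 17 paired patients
res <- run_pipeline(co$samples, co$clinical)
res
#> <pipeline_result> 34 lesions, 1632 density rows; battery: 115/180 comparisons significant at alpha = 0.05

subset(res$battery, marker == "CD8" & stratum == "TF_vs_TC")
#>  lesion_type        test method  n statistic         p mean_a mean_b
#>      primary signed_rank  exact 17       153 1.526e-05  132.9  48.75
#>   metastasis signed_rank  exact 17       153 1.526e-05  131.9  75.14
```

All 17 primary lesions show denser CD8 infiltration at the invasive front
than in the tumor center (W = 153 is the maximum possible rank sum, so the
exact two-sided p is 2/2¹⁷ ≈ 1.5 × 10⁻⁵; mean 132.9 vs 48.8 cells/mm²) —
the generator plants a 3× front-to-center gradient and the pipeline
recovers it. The macrophage landscape (median cells/mm² across patients):

```r
round(res$heatmap, 1)
#>               CD68+CD163+ CD68+CD163- CD68-CD163+
#> primary.TC           16.6        26.4        14.3
#> metastasis.TC        19.9        29.6        21.8
#> primary.TF           47.8        79.5        30.4
#> metastasis.TF        30.3        62.7        37.0
#> primary.PT           13.9        29.2        14.9
#> metastasis.PT        38.5        21.7        43.5
```

The metastasis peritumor is dominated by CD163⁺ subtypes (43.5 vs
14.9 cells/mm² for CD68⁻CD163⁺), while CD68⁺CD163⁻ cells prevail around
primaries. Per-lesion immunophenotypes report the threshold they used:

```r
head(res$immunotypes, 4)
#>  patient_id lesion_type    label  d_tc  d_tf threshold
#>         P01     primary excluded 45.80 107.5     61.95
#>         P01  metastasis inflamed 70.84 125.6     61.95
#>         P02     primary excluded 31.96 100.1     61.95
#>         P02  metastasis inflamed 66.05  99.8     61.95
```

A shell front-end with `simulate` / `run` / `compare` subcommands lives in
`inst/cli/immuneband.R`; all outputs are tidy delimited text with a JSON
provenance record.

## Scope

The pipeline starts at the segmented-cell table: image acquisition,
spectral unmixing, segmentation and positivity thresholding are upstream
and out of scope, as are survival modelling and intensity-based scores.
See `vignettes/spatial-immune-quantification.Rmd` for the model details,
parameter choices and limitations.
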