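# imcmyo

Quantitative analysis of imaging mass cytometry (IMC) pseudoimages of
skeletal muscle sections — from multi-channel 16-bit OME-TIFF stacks and
QuPath GeoJSON regions of interest to region/stroma/fiber-level marker
metrics, cell and capillary counts, fibrotic-focus comparisons and
cross-marker correlation statistics. Written for myology groups analyzing
dystrophic muscle (e.g. Becker muscular dystrophy) with Hyperion-class
instruments, where each 1 µm² pixel holds raw ion counts per metal-tagged
antibody.

## What it computes

For a marker channel $c$ with threshold $t_c$ and a region $R$:

- positive fraction $\;100\cdot|\{p \in R : v_c(p) \ge t_c\}| / |R|\;$ (%),
  mean intensity, and positive-signal mean intensity;
- muscle fibers segmented from the laminin channel by a deterministic
  smooth → threshold (Otsu) → seeded-watershed pipeline with
  full-width-half-maximum outline recovery; stroma is the exact complement
  of the fiber labels within the ROI;
- nucleus-gated cell counts (CD56 satellite cells, CD68/CD206 macrophage
  subsets), CD31 capillaries vs large vessels by size partition, and
  object densities per mm²;
- a per-fiber table of cross-sectional area (CSA, µm²) and marker
  positivity under the area rules "≥ 10% of fiber area positive" (5% for
  CTGF);
- CSA summaries (mean ± SD, relative-frequency histogram, ECDF) and the
  statistical battery: Shapiro–Wilk, unpaired t-tests (Welch default,
  p ≤ 0.05), two-sample Kolmogorov–Smirnov, and Spearman correlation
  families with Bonferroni correction ($p_{adj} = \min(1, m\,p)$).

A synthetic muscle-section generator (Voronoi fiber mosaic, patchily
widened endomysial stroma, planted vessels/cells/fat, Poisson count noise)
provides ground truth for every stage, with disease-stage presets
`control`, `mild`, `moderate`, `advanced_fibrosis`, `advanced_fat`.

## Worked example

```r
library(imcmyo)

# a synthetic five-stage cohort, two 300x300 um sections per stage
cohort <- generate_cohort(n_per_group = 2, base_seed = 1)
res <- run_full_cohort(cohort)

aggregate(cbind(stroma_pct, capillary_density_mm2, n_m2) ~ group,
          res$sample_summary, mean)
#>               group stroma_pct capillary_density_mm2 n_m2
#> 1 advanced_fat        70.18                  88.89  18.0
#> 2 advanced_fibrosis   55.90                 127.78  13.0
#> 3 control             26.36                 333.33   1.0
#> 4 mild                35.43                 266.67   4.0
#> 5 moderate            43.50                 194.44   8.0

res$ks_control_vs_dystrophic
#> $D
#> [1] 0.196
#> $p
#> [1] 0.144
```

Measured stroma rises monotonically across the severity spectrum while
capillary density falls and CD206+ (M2) counts rise — the section-level
signature of fibro-fatty replacement recovered from the synthetic ground
truth. The KS line compares the pooled control vs dystrophic fiber CSA
distributions (D = sup ECDF difference).

`write_results(res, "out/")` emits the tidy bundle: `roi_metrics.csv`,
`fibers.csv`, `objects.csv`, `sample_summary.csv`, `csa_summary.csv`,
`correlations.csv`, `region_comparison.csv`, `run_log.txt`.

File-based runs use a YAML config (paths to stacks, the panel CSV, GeoJSON
ROIs, thresholds CSV or `auto:otsu`) through `run_quantify()` /
`run_full()`, or the thin CLI at `inst/scripts/imcmyo-cli.R`
(`synth`, `quantify`, `run-all` subcommands).

## Package layout

- `R/` — panel/stack IO, ROI geometry, quantification, segmentation,
  fiber analysis, statistics, synthetic generator, pipeline orchestration
- `inst/extdata/panel_default.csv` — the default 17-channel marker panel
- `vignettes/imc-muscle-quantification.Rmd` — models, conventions,
  parameter rationale and limitations
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
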