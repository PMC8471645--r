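# maskrepro

Test–retest reproducibility analysis for 3D segmentation shape features.

When the same patient is scanned twice within days, the prostate gland has
not changed — so any disagreement between morphological features extracted
from the two segmentations measures the (ir)reproducibility of the
segmentation itself. `maskrepro` implements the full analysis chain for
such paired two-scan designs, for a whole gland (WP) split into the
peripheral zone (PZ) and the remaining zones (non-PZ), segmented by a
manual reference and any number of automatic methods. It is aimed at
researchers evaluating whether automatic (e.g. CNN-based) prostate
segmentation is reproducible enough to feed radiomics features — above all
gland volume, and the PSA density derived from it — into longitudinal
clinical use.

The package provides:

* **I/O and regions** — NIfTI-1 label maps (0 = background, 1 = PZ,
  2 = non-PZ), canonical slice × row × column axis handling, WP by merging,
  non-PZ by subtraction, and a composition loader for methods that predict
  WP and PZ independently.
* **Post-processing** — retain the largest 3D connected component at
  6/18/26-connectivity, applied per zone.
* **14 shape features** in physical units, computed from a watertight
  triangle mesh (marching tetrahedra on a Gaussian-smoothed field, Taubin
  smoothing) and from voxel-coordinate moments: mesh volume, voxel volume,
  surface area, surface-area-to-volume ratio, sphericity, major/minor/least
  axis lengths, elongation, flatness, and maximum 3D and per-plane 2D
  diameters.
* **Agreement statistics** — Dice similarity coefficient; two-way random
  single-score intraclass correlation, with n subjects and k repeated
  scans and row/column/error mean squares MSR, MSC, MSE:

  ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)),

  with F-based 95% confidence intervals; CI-overlap significance between
  methods; paired Wilcoxon signed-rank tests with Benjamini–Hochberg
  correction; Spearman correlation; Bland–Altman bias and limits of
  agreement; and a seeded permutation test (random re-exclusion, 1000
  runs, "< 50/1000" rule) for whether quality-score-based cohort
  filtering genuinely improves the ICC.
* **A synthetic paired-cohort generator** emulating the two-scan study
  design (62 subjects, 3 mm slices, probe compression of scan 2, graded
  per-method boundary noise, spurious components, gross failures, quality
  scores), so the whole pipeline runs and is tested without clinical data.

## Worked example

```r
library(maskrepro)

# a small two-method cohort at the study's voxel geometry
cfg <- synthetic_config(n_subjects = 8,
                        method_noise = c(manual = 0.5, vnet = 1.8),
                        seed = 7)
cohort <- generate_cohort(cfg, file.path(tempdir(), "demo-cohort"))
report <- run_analysis(cohort$manifest_path, qc_threshold = 85,
                       qc_runs = 200, seed = 7)

subset(report$icc, feature == "voxel_volume")
#>    region method_id      feature       icc    ci_low   ci_high n
#> 61     WP    manual voxel_volume 0.9978957 0.9895303 0.9995784 8
#> 62     PZ    manual voxel_volume 0.9963524 0.9236008 0.9994084 8
#> 63  nonPZ    manual voxel_volume 0.9964396 0.9839290 0.9992727 8
#> 64     WP      vnet voxel_volume 0.9534925 0.7992531 0.9903954 8
#> 65     PZ      vnet voxel_volume 0.9596846 0.8120047 0.9918122 8
#> 66  nonPZ      vnet voxel_volume 0.9440011 0.7660751 0.9883463 8
```

Each row is the inter-scan reproducibility of the segmented volume for one
region and method: the manual reference reproduces volume almost perfectly
(ICC ≈ 0.996–0.998), while the noisy simulated method ("vnet", 1.8 mm RMS
boundary error) drops to ICC ≈ 0.94–0.96 with visibly wider confidence
intervals. The report also contains the between-scan volume comparison —

```r
subset(report$volume_comparison, region == "WP")
#>   region method_id n percent_median_difference wilcoxon_p      bh_q
#> 1     WP    manual 8                 -0.376168  0.9453125 0.9453125
#> 4     WP      vnet 8                  2.076146  0.5468750 0.9453125
```

— where `percent_median_difference` is the median of
100·(scan2 − scan1)/scan1 per subject (here a fraction of a percent for
the manual reference, with non-significant Wilcoxon/BH p-values at n = 8),
and the DSC summary against the manual reference:

```r
report$dsc_summary
#>   region method_id scan_id    median        iqr
#> 1  nonPZ      vnet   scan1 0.9058943 0.01935249
#> 2     PZ      vnet   scan1 0.7757054 0.06032234
#> 3     WP      vnet   scan1 0.9076254 0.01594010
#> ...
```

The thin-shell PZ is, as expected, the hardest region (median DSC ≈ 0.78
versus ≈ 0.91 for the whole gland). `compare_methods(report)` adds the
"how many of the 14 features are comparable to manual" summary based on
CI overlap, and `write_report(report, dir)` writes every table as CSV plus
a JSON provenance record.

A command-line wrapper with `simulate` / `postprocess` / `features` /
`analyze` subcommands is installed at `inst/cli/maskrepro`.

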