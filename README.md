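# marrowvar

Longitudinal analysis of bone-marrow heterogeneity from proton density fat
fraction (PDFF) MRI in mouse models of myelofibrosis (MF).

## The problem

Healthy distal tibia marrow in the mouse is fat-rich (mean PDFF around 50%)
and spatially heterogeneous: fat cells and hematopoietic cells are
interleaved, so voxel PDFF values spread widely. As MF progresses,
malignant hematopoietic cells replace marrow fat: the distal PDFF mean
falls toward zero and — the signal this package quantifies — the *variance*
of voxel PDFF values collapses, because the marrow becomes uniformly
cellular. Tracking that variance gives a registration-free middle ground
between whole-ROI means (which mask heterogeneity) and parametric response
mapping (which needs exact voxel co-registration across scans).

## The method

For each scan the pipeline:

1. computes the **axial mean trajectory** — per-slice mean PDFF along the
   tibia — and splits the marrow ROI into proximal (hematopoietic,
   low-PDFF), transition, and distal zones with a plateau-fraction rule
   (smoothed trajectory crossing `L_p + f (L_d − L_p)` at `f = 0.25` and
   `0.75`); only the distal zone is analysed;
2. scores heterogeneity as the **trimmed voxel variance**: with distal
   voxel values `x_1..x_n`, threshold `t = Q_0.90(x)` (linear
   interpolation), retained set `R = {x_i ≤ x_i ≤ t}`, score
   `s² = Var(R)` (sample convention, units percent²) — one number per
   mouse per scan day;
3. runs group inference on the resulting cohort table: two-group
   **permutation tests** on the difference in means
   (`p = (1+b)/(1+B)` Monte Carlo, exact enumeration when feasible),
   **PCA** with a centroid-distance label-permutation separation p-value,
   per-mouse least-squares lines of score over day combined into group
   lines, quartile (violin) summaries, and a responder/diseased
   classification rule (responder: spleen volume falls to ≤ 50% of
   baseline; diseased: spleen growth plus declining distal PDFF).

A synthetic phantom module generates tibia volumes (scaled-Beta voxel law
parameterised by mean and variance, proximal/transition/distal zone
structure) and whole longitudinal cohorts — healthy, nonresponder, and
responder disease courses with post-irradiation day-0 variance inflation,
scheduled dropout and spleen trajectories — so the entire pipeline runs
and is tested with no MRI data. The published per-mouse variance table is
bundled as `inst/extdata/table1_variances.csv` (15 healthy mice; 17 + 12
MF mice over days 0/64/69/74 and 0/55/77/93; cells missing in print yield
no record).

## Worked example

```r
library(marrowvar)
tab <- load_table1_fixture()
res <- run_pipeline(list(mode = "fixture", out_dir = "results/table1",
                         seed = 1, n_perm = 10000))
res$permutation$disease_vs_healthy$p_value
#> [1] 0.00039996
res$permutation$disease1_vs_disease2$p_value
#> [1] 0.7421258
res$group_lines
#>     group      slope intercept n_fits
#>  disease1 -1.9258576 138.95385     17
#>  disease2 -0.8347463  82.94071     12
#>   healthy  0.0000000  51.60000     15
```

Reading: pooled day-0 disease variances (29 values, irradiated baseline
marrow) exceed healthy variances (15 values) — one-sided permutation
p ≈ 0.0004, a clear group difference — while the two disease cohorts are
indistinguishable over all scans (two-sided p ≈ 0.74), justifying pooling
them. Group lines show the disease signature: high day-0 intercept with a
negative slope as variance collapses, against a flat healthy reference
near 49–52 percent².

The numbered scripts under `analysis/` run the complete study:
`01_table1_statistics.R` (inference on the bundled table),
`02_simulate_cohorts.R` (simulate and score a 49-mouse phantom study),
`03_simulated_inference.R` (inference + classification on the phantoms,
recovering all 29 nonresponders as diseased and all 5 responders from
their spleen trajectories). Outputs are written under `results/`.

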