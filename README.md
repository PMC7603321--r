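# wmtopo

Graph-theoretical analysis of **white-matter (WM) functional connectomes**
for case-control neuroimaging studies, with a focus on small-world topology
as a candidate neuromarker of depression severity and diagnosis.

Resting-state BOLD signals inside white matter carry reproducible functional
organization. This package implements the full analysis chain used to ask
whether that organization is disrupted in a patient group:

1. **Parcellation** — a group-level WM voxel mask is randomly subdivided
   into N contiguous, size-balanced nodes by seeded region growing
   (N = 128 by default), always growing the currently smallest parcel.
2. **Connectivity** — node-averaged time series give a Pearson correlation
   matrix per subject, Fisher r-to-z transformed
   (`z = atanh(r)`), with zero diagonal.
3. **Topology** — each matrix is proportionally thresholded at sparsities
   `0.10, 0.11, …, 0.30`; at each sparsity the weighted clustering
   coefficient `Cp` and characteristic path length `Lp` (edge length
   `1/w`) are normalized by degree-preserving Maslov–Sneppen null networks:

   γ = Cp / Cp_rand,  λ = Lp / Lp_rand,  σ = γ / λ

   and each curve is summarized by its trapezoidal **AUC**, giving three
   per-subject features (`gamma_auc`, `lambda_auc`, `sigma_auc`).
   σ > 1 with γ > 1 and λ ≈ 1 is the small-world signature.
4. **Statistics** — covariate-adjusted (age, sex, education, mean framewise
   displacement) group comparisons routed between a pooled t-test and the
   Mann–Whitney U test by a normality check, Bonferroni-corrected over the
   three planned comparisons; Pearson correlation of the features with
   symptom severity (HAMD) in patients.
5. **Machine learning** — 5-fold cross-validated linear SVR predicting
   severity from the three features, and a class-imbalance-robust ensemble
   of three sigmoid-kernel SVMs (each trained on 80% of patients plus an
   equal number of controls) classifying an independent replication sample
   by majority vote.

A built-in **synthetic cohort generator** (`simulate_cohort()`) produces
weighted small-world subject networks with a planted patient shift toward
topological randomization, planted negative clustering–severity coupling,
realistic connectivity estimation noise and matched phenotypes — so the
whole pipeline runs, and is tested, without any external imaging data.
Optionally it renders networks as voxel time series on a toy mask to
exercise the parcellation and extraction stages.

## Worked example

Simulate a 91-patient / 100-control cohort of 64-node networks, compute
topology features (3 nulls per sparsity), and run the group and severity
analyses:

```r
library(wmtopo)

spec   <- cohort_spec(n_patients = 91, n_controls = 100, n_nodes = 64,
                      rng_seed = 1)
cohort <- simulate_cohort(spec)
topo   <- cohort_topology(cohort$networks, n_nulls = 3, seed = 1)
head(topo, 3)
#> # A tibble: 3 × 4
#>   subject_id gamma_auc lambda_auc sigma_auc
#>   <chr>          <dbl>      <dbl>     <dbl>
#> 1 s001           0.206      0.199     0.208
#> 2 s002           0.207      0.199     0.208
#> 3 s003           0.220      0.202     0.217

compare_topology(topo, cohort$phenotypes) |>
  dplyr::select(metric, test_used, statistic, p_bonferroni, estimate)
#> # A tibble: 3 × 5
#>   metric     test_used      statistic p_bonferroni estimate
#>   <chr>      <chr>              <dbl>        <dbl>    <dbl>
#> 1 gamma_auc  mann_whitney_u      1589     2.58e-14 -0.0444
#> 2 lambda_auc mann_whitney_u      3501     1.80e- 2 -0.00291
#> 3 sigma_auc  mann_whitney_u      1497     3.74e-15 -0.0396
```

Patients show strongly reduced normalized clustering (γ) and
small-worldness (σ) — negative `estimate` at p ≈ 1e-14 — while the
normalized path length (λ) effect is two orders of magnitude smaller and
only borderline at this sample size: the "shift toward randomization"
pattern. The planted negative clustering–severity coupling is recovered in
patients, and severity is predictable out of fold:

```r
correlate_with_symptoms(topo, cohort$phenotypes)
#> # A tibble: 3 × 5
#>   metric          r    p_raw p_bonferroni     n
#>   <chr>       <dbl>    <dbl>        <dbl> <int>
#> 1 gamma_auc  -0.395 0.000107     0.000322    91
#> 2 lambda_auc -0.379 0.000215     0.000644    91
#> 3 sigma_auc  -0.382 0.000185     0.000555    91

svr_predict_cv(dplyr::inner_join(topo, cohort$phenotypes,
                                 by = "subject_id"), seed = 1)
#> 5-fold CV SVR (91 subjects): observed-vs-predicted r = 0.334, p = 0.00121
```

`autoplot()` on the SVR
fit, `plot_topology_comparison()` and `plot_sparsity_curves()` draw the
standard figures; `tidy()`/`glance()` return the per-subject and summary
tables. `run_pipeline(pipeline_config(...))` executes all stages (including
replication-sample classification and the group × sample interaction ANOVA)
and writes stage CSVs plus a provenance manifest.

## Notes

* Analysis conventions (Onnela weighted clustering on max-normalized
  weights, signed-rank negative-edge policy, exclusion of unreachable pairs
  from Lp, min(U1, U2) reporting) are documented and switchable; see the
  methods vignette `vignettes/wm-connectome-topology.Rmd`.
* Masks and label maps read/write as NIfTI (`read_mask_nifti()`,
  `write_labels_nifti()`, …); matrices as TSV; phenotypes and results as
  CSV.
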