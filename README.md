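# netprog

Network-based discovery and evaluation of multi-omic prognostic
subnetworks for cancer survival analysis.

## What it does

Single molecular features rarely predict tumor survival well: prognostic
signal is weak, spread across interacting genes, and split between data
types (mRNA expression, copy number, promoter methylation). `netprog`
integrates the three levels over a protein–protein interaction network:

1. **Screening** — every (gene, modality) feature is tested against
   overall survival in an age-adjusted Cox proportional-hazards model
   (1-df likelihood-ratio test, raw *p* < 0.05); per gene, methylation is
   collapsed to its most survival-associated probe.
2. **Heat scoring** — per gene, the screened-in modality p-values are
   combined by Fisher's method, `score = -2 * sum(log p_m)`; genes with a
   positive score are the survival-related set.
3. **Subnetwork discovery** — insulated heat diffusion
   `F = beta * (I - (1 - beta) W)^-1` spreads the scores over the
   interactome; the exchanged-heat matrix `E_ij = F_ij * h_j` is
   thresholded at a permutation-calibrated `delta`, and strongly connected
   components of at least 4 genes are the candidate subnetworks, each with
   an empirical size-class p-value from heat permutations.
4. **Prognostic evaluation** — each subnetwork's multi-omic profile is
   scored by Monte-Carlo cross-validation (100 random 80/20 splits,
   elastic-net-penalized Cox per split, Harrell's C-index on the held-out
   patients); the median C is compared against a survival-permutation
   null. Models pass with median C > 0.5 and permutation *p* < 0.05.
5. **Risk scoring** — features selected in more than 5 of the 100 splits
   enter a final multivariable Cox fit; the subnetwork risk score
   `snRS_i = sum_f coef_f * x_fi` splits the cohort at its median into
   high/low risk groups, compared by Kaplan–Meier/log-rank and by
   clinically adjusted Cox models.
6. **Stratification** — the stability-selected features of all models with
   median C > 0.5 are pooled and patients are clustered by consensus
   non-negative matrix factorization (default two strata), with a survival
   comparison between strata.

A seeded synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
produces interactomes with planted dense modules and matched multi-omic +
Weibull proportional-hazards survival data, so the entire pipeline is
testable without access to patient-level data.

## Worked example

```r
library(netprog)

cfg <- sim_config(n_genes = 60, n_modules = 1, module_size = 6,
                  n_patients = 150, effect_log_hr = 1.0, seed = 5)
sim <- simulate_cohort(cfg)

acfg <- analysis_config(n_cv_splits = 10, n_permutations = 20,
                        n_perm_splits = 5, n_discovery_perms = 20,
                        n_delta_perms = 10, nmf_runs = 10, seed = 3)
res <- run_pipeline(sim$dataset, sim$network, acfg, out_dir = "netprog_out")

res$subnetworks
#> <subnetwork_set> 1 subnetwork(s), delta = 0.0862
#> # A tibble: 1 × 5
#>   id     size genes     n_edges size_class_p
#>   <chr> <int> <list>      <dbl>        <dbl>
#> 1 sub_1     7 <chr [7]>      15       0.0476

tibble::as_tibble(res$models)
#> # A tibble: 1 × 6
#>   subnetwork  size median_c permutation_p passed  rank
#>   <chr>      <int>    <dbl>         <dbl> <lgl>  <int>
#> 1 sub_1          7    0.816        0.0476 TRUE       1

glance(res$risk$stratification)
#> # A tibble: 1 × 7
#>   n_high n_low cutoff logrank_p    hr ci_low ci_high
#>    <int> <int>  <dbl>     <dbl> <dbl>  <dbl>   <dbl>
#> 1     75    75  0.187  3.08e-20  6.43   4.14    9.98
```

The discovered 7-gene subnetwork contains the entire planted 6-gene
module (plus one hot background gene): its profile ranks survival on
held-out patients far above chance (median C = 0.82 vs 0.5), the
permutation test puts that at the smallest achievable add-one p (1/21),
and the resulting risk score separates the cohort into groups with a
hazard ratio of 6.4 (log-rank p ≈ 3e-20). Stage tables (screening
statistics, gene heats, subnetwork memberships, per-split C-indexes, snRS
assignments, cluster labels) are written under `netprog_out/`.

A command-line shell with subcommands
`simulate | screen | score | discover | evaluate | risk | stratify |
run-all` is installed at `inst/exec/netprog`.

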