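---
title: "Network-based subnetwork discovery for survival prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based subnetwork discovery for survival prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprog)
```

## The problem

Tumor cohorts profiled on several molecular levels — mRNA expression,
copy-number variation (CNV), promoter DNA methylation — rarely yield single
genes that predict overall survival robustly: effects are small, spread
across correlated genes, and split between data types. `netprog` implements
a network-based alternative: it scores every gene by the joint survival
association of its molecular features, diffuses those scores over a
protein–protein interaction (PPI) network so that connected groups of
moderately associated genes reinforce each other, extracts "hot"
subnetworks, and then treats each subnetwork's multi-omic profile as a
candidate prognostic signature whose predictive power is measured by
cross-validated concordance against a permutation null. The retained
signatures yield a per-patient risk score and a survival-oriented
stratification of the cohort.

## The model, stage by stage

### Per-feature screening

For every feature $x$ (one gene in one modality; one probe for
methylation), we fit an age-adjusted Cox proportional-hazards model

$$\lambda(t \mid x, a) = \lambda_0(t)\, e^{\beta x + \gamma a},$$

with Efron handling of tied event times, and test $\beta = 0$ by the 1-df
likelihood-ratio test against the age-only model. Features with
$p < \alpha$ (default $0.05$, uncorrected — the screening is deliberately
liberal because the network stage supplies the multiplicity control through
its own permutation null) are "survival-related". Features are
z-standardized before fitting so coefficients are comparable across
modalities in the downstream penalized fits. Genes with several methylation
probes keep only the probe with the smallest screening p-value (ties broken
by the lexicographically smallest probe id): the screening statistic itself
is the measure of "most associated with survival", which avoids defining a
separate correlation against censored times.

### Gene heat

Per gene, the screened-in modality p-values are combined by Fisher's
method,

$$\mathrm{score}(g) = -2 \sum_{m} \ln p_m, \qquad
  m \in \{\text{mRNA}, \text{CNV}, \text{methylation}\},$$

summing over at most one p-value per modality. A gene with no screened-in
feature scores 0. Genes with positive score form the survival-related gene
set. Only selected p-values enter the sum: an unselected (large) p-value is
treated as absence of evidence, not negative evidence.

### Insulated diffusion and subnetwork extraction

With $A$ the adjacency of the PPI network and
$W_{ij} = A_{ij}/\deg(j)$ the column-stochastic walk matrix, the insulated
diffusion matrix is

$$F = \beta\,(I - (1-\beta) W)^{-1},$$

a random walk with restart probability $\beta$ (default 0.4, the
conventional choice for PPI networks; configurable). $F$ is computed by a
linear solve per connected component, never by a full explicit inverse, and
isolated nodes are given a self-transition so $F$ stays column-stochastic.
The exchanged heat $E_{ij} = F_{ij} h_j$ is the heat that gene $i$ receives
from source $j$; since columns of $F$ sum to one, $\sum_i E_{ij} = h_j$
(heat is conserved), a property the test suite asserts directly.

Thresholding ($E_{ij} > \delta$ defines the arc $j \to i$) gives a directed
graph whose strongly connected components of at least
`min_subnetwork_size` (default 4) genes are the candidate subnetworks.

### Choosing the threshold

$\delta$ has no published value, so the package calibrates it from heat
permutations: heats are shuffled over the network genes, and for each
permuted exchanged-heat matrix we find the smallest $\delta$ at which the
largest strongly connected component falls below `delta_size_cap` nodes;
the median over the ensemble is used. The cap defaults to 3 — permuted
heats may retain nothing larger than a single exchanged edge — so that at
the chosen threshold no chance component comes anywhere near the
reportable size of 4. We examined looser caps (component sizes up to 10
under permutation): they place $\delta$ inside the regime where background
genes that pass screening by chance and happen to border a hot region are
absorbed into its component, diluting a planted module with as many
background genes as members. With the tight cap the planted module is
recovered essentially clean, which is the behavior the discovery stage is
for. The cap, like $\delta$ itself, is configurable.

Discovered subnetworks get an empirical size-class p-value from a second
round of heat permutations: $p(s)$ is the add-one fraction of permutations
showing at least as many components of size $\ge s$ as observed.

### Prognostic evaluation

Each subnetwork's profile — the screened-in features of its member genes,
z-standardized — is evaluated by Monte-Carlo cross-validation: 100 random
80/20 train/test splits (both configurable); per split an elastic-net
penalized Cox model (mixing 0.5; penalty strength by inner 5-fold
partial-likelihood cross-validation over a 50-step path) is trained and its
linear predictor is scored on the held-out patients by Harrell's
concordance index. The median test C over splits is the subnetwork's
predictive value. The elastic net is used as a feature-selection step; when
the inner CV prefers the empty end of the path, the fit steps down to the
largest penalty admitting at least one feature, so every split contributes
a feature set (as the stability counts below require) and a non-degenerate
test statistic. Splits with no event in train or test are redrawn.

Harrell's C counts ordered pairs $(i, j)$ in which $i$ is established as
the earlier event ($t_i < t_j$ with $i$ observed, or $t_i = t_j$ with $i$
observed and $j$ censored): the pair is concordant when the earlier event
carries the higher predicted risk, tied predictions count one half, and
tied event times with both events observed are not comparable. C is 1 for
perfect ranking, 0.5 at chance.

Significance comes from jointly permuting the $(t, e)$ pairs across
patients and re-running the cross-validation on each permuted outcome
(by default with a reduced budget of 20 splits per permutation, a
fidelity/runtime trade-off; set `n_perm_splits = n_cv_splits` for full
fidelity, and use equal budgets when studying the null, where
exchangeability between the observed and permuted runs matters). The
add-one empirical p-value is
$p = (\#\{\text{permuted median} \ge \text{observed}\} + 1)/(B + 1)$.
Models pass the filter when median C $> 0.5$ and $p < 0.05$, and are ranked
by median C (ties: smaller p first, then id).

The genome-wide baseline comparator applies univariate-Cox pre-selection at
$p < 0.05$ *inside* each training split (avoiding test-set leakage; the
alternative of pre-selecting once on the full cohort is optimistic) and
then the identical penalized fit, for any subset of the three modalities.

### Risk scores and stratification

Features selected in strictly more than `stability_min_count` (default 5)
of the splits enter the final unpenalized multivariable Cox fit on the full
cohort; its coefficients weight the subnetwork risk score
$\mathrm{snRS}_i = \sum_f \hat\beta_f\, x_{fi}$. Collinear or non-convergent
fits fall back to a barely penalized ridge ($\lambda = 10^{-4}$), reported
on the model object. The cohort is split at the median snRS (ties go to the
low-risk group — deterministic and conservative), compared by Kaplan–Meier
curves, the log-rank test, and a Cox hazard ratio of high vs low, and the
snRS is re-examined as a continuous covariate in a multivariable Cox model
with age, stage (dichotomized III/IV vs I/II), lymph-node count, and tumor
weight. For external cohorts measured on mRNA only, `snrs(..., mrna_only =
TRUE)` applies the mRNA coefficients as trained, with no refitting or
renormalization — a documented limitation, since dropped modalities shift
the score's location but not the within-cohort ranking that the median
split uses.

Finally, the stability-selected features of all models with median
C $> 0.5$ are pooled (deduplicated), each feature is min–max scaled to
$[0,1]$ (the simplest rank-preserving map into the non-negative domain —
mRNA z-scores and CNV scores can be negative), and patients are clustered
by consensus non-negative matrix factorization: `nmf_runs` random restarts
of rank-`nmf_k` multiplicative-update NMF (Frobenius objective, 200
iterations), each labeling patients by their dominant factor; the consensus
matrix of co-clustering frequencies is cut by average-linkage hierarchical
clustering into `nmf_k` strata (default 2), whose survival is compared by
log-rank and pairwise hazard ratios.

## The synthetic cohort generator

Real multi-omic survival cohorts cannot ship with a package, so `netprog`
includes a generator whose outputs exercise every pipeline stage:

* **Network**: `n_genes` nodes; disjoint planted modules of `module_size`
  genes with within-module edge probability `p_in` (default 0.8) against a
  sparse background (`p_out`, default 0.01) — a dense community in a sparse
  interactome.
* **Features**: mRNA and CNV as independent standard Gaussians; methylation
  as the logistic transform of a gene-level Gaussian latent observed through
  1–3 noisy probes per gene (so beta-values stay in $[0,1]$ and the
  probe-collapse rule is exercised). Effects are specified on the latent
  scale.
* **Survival**: Weibull proportional hazards (shape 1.2, scale 5 time
  units), with linear predictor
  $\eta_i = \sum \beta_{g,m}\, \tilde x_{g,m,i}$ over the planted active
  features (default log-HR 0.7 per SD each). The Weibull baseline is
  PH-compatible and closed-form invertible, which keeps the generator exact
  and fast.
* **Censoring**: independent exponential, with the rate solved numerically
  against the realized event times so the achieved censoring fraction
  matches the target (default 0.3).
* **Clinical covariates**: age, stage, lymph-node count, tumor weight drawn
  independently of survival (so the age adjustment and the clinical
  adjustment table have known null behavior).

Everything derives from one master seed through named substreams, so any
stage can be re-run independently and the whole pipeline is bit-for-bit
reproducible.

What the generator does *not* emulate: platform artifacts and batch
effects, correlated co-expression structure beyond the planted modules,
mutation or miRNA features, and informative censoring. Passing tests on
this substrate therefore demonstrate the pipeline's statistical and
algorithmic correctness under its own model assumptions, not performance on
any real tumor cohort.

## Numerical and design choices

* **Cox fits** go through the `survival` package (Efron ties throughout);
  the per-feature screening calls the underlying fitter directly and is
  asserted identical to `coxph()` in the tests.
* **Penalized fits** go through `glmnet`; fold assignments are drawn from
  the seeded substream so inner CV is reproducible.
* **Empirical p-values** always use the add-one estimator
  $(k+1)/(B+1)$, which cannot return 0.
* **p = 0 heat inputs** are floored at the smallest positive double before
  the log.
* **Degenerate inputs**: constant features are flagged and excluded from
  selection rather than erroring the stage; empty screening results, empty
  subnetwork lists, and models with no stability-selected feature are valid
  empty outcomes (with warnings), and the pipeline records skipped stages
  in its run summary.
* **Tie rules** are fixed and documented: probe collapse by smallest p then
  probe id; model ranking by median C, then permutation p, then id; median
  snRS ties to the low-risk group.
* **Problem sizes in the tests**: the property suites use cohorts of
  40–400 patients and networks of 15–300 genes, the planted-recovery suite
  uses 50 replicates of the 300-gene / 8-gene-module / 400-patient
  configuration, and null-calibration suites use 200 replicate seeds with
  reduced split budgets — sizes at which every distributional claim is
  testable in minutes while matching the cohort scale the method targets.

## Known limitations

* Harrell's C (not Uno's) is used; under heavy censoring it is mildly
  optimistic, but it is the estimator the evaluation framework is defined
  with.
* The permutation test with unequal split budgets (observed vs permuted) is
  slightly conservative under the null; equal budgets restore exactness.
* The NMF rank is fixed by configuration (default 2); the package does not
  attempt to choose `k` from the data.
* Cross-network "sharing" of subnetworks is reported descriptively as gene
  overlap with a Jaccard threshold (default 0.5); no consensus across
  thresholds or networks is attempted.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 120, module_size = 8, n_patients = 200,
                  effect_log_hr = 0.9, seed = 1)
sim <- simulate_cohort(cfg)

acfg <- analysis_config(n_cv_splits = 25, n_permutations = 20,
                        n_discovery_perms = 50, seed = 1)
res <- run_pipeline(sim$dataset, sim$network, acfg, out_dir = "netprog_out")

res$subnetworks          # discovered modules with size-class p-values
res$models               # ranked prognostic models
glance(res$risk$stratification)  # log-rank p, HR of the median split
```
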