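---
title: "Methods: weighted connectomes, sex differences, and memory mediation"
author: "memconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectomes, sex differences, and memory mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memconn)
```

## What the package computes

`memconn` implements a complete analysis chain for weighted structural brain
networks built from probabilistic tractography, aimed at one scientific
question: do males and females differ in whole-brain network organisation,
and does that difference carry part of the well-replicated female advantage
in episodic free recall?

The chain is:

1. **Connectome construction.** For each subject, a directed streamline
   count matrix over `R` anatomical parcels (82 = Desikan-Killiany cortical
   + subcortical, or 162 = Destrieux + subcortical) is converted to
   connection probabilities by dividing each row by that seed's number of
   valid streamlines (the *waytotal*), and symmetrized by averaging the
   i-to-j and j-to-i probabilities. A population-level mask removes edges
   whose across-subject `mean + 2 sd` falls below a connectivity of 0.01;
   masked edges are removed in every subject so the edge set is consistent.
2. **Graph metrics**, computed from first principles on the weighted
   matrix: node strength `s_i = sum_j w_ij` (global value: mean over
   nodes); weighted shortest paths with edge length `1/w` (Dijkstra per
   source); characteristic path length (mean finite distance over ordered
   pairs); global efficiency (mean inverse distance); and weighted
   transitivity with geometric-mean (Onnela) triangle intensity after
   max-weight normalisation,
   `T = sum_i 2 t_i / sum_i k_i (k_i - 1)` with
   `t_i = 1/2 sum_{j,h} (w'_ij w'_ih w'_jh)^{1/3}`. The node-level analogue
   `C_i = 2 t_i / (k_i (k_i - 1))` is the clustering coefficient.
3. **Inference.** Covariate-adjusted linear models with Type-II F tests
   (age and intracranial volume as covariates for connectome outcomes; age
   and recall room for memory outcomes); Cohen's *d* reconstructed from the
   model *t* value, `d = t (n1 + n2) / (sqrt(n1 n2) sqrt(df))`, so *d*
   inherits every covariate adjustment; random-intercept REML mixed models
   for the subject-by-valence recall table; partial Pearson correlations;
   and a node-level clustering scan Bonferroni-corrected by the node count.
4. **Mediation.** Sex (female = 0 / male = 1) as exposure, weighted
   transitivity as mediator, total (or positive-picture) recall as outcome.
   Mediator and outcome are residualized on age, recall room and ICV, all
   variables are standardized, and the paths a (sex to mediator), b
   (mediator to outcome given sex), c (total) and c' (direct) are
   standardized regression coefficients, so the indirect effect `a * b`
   and all paths live on the correlation (r) scale. Inference for `a * b`
   and the mediation ratio `(a * b)/c'` uses a bias-corrected and
   accelerated (BCa) bootstrap.

## The synthetic cohort generator

The original cohort (655 healthy young adults, 60% female) cannot be
shipped, so the package includes a generator whose *population statistics*
match the study's printed effect structure. It is first-class, tested code:
every downstream stage is validated by recovering the configured parameters
from generated cohorts.

**Covariates.** Sex is Bernoulli(0.60 female); ages are truncated normals
on [18, 35] with sex-specific means/SDs (22.62/3.32 female, 23.26/3.46
male); ICV is drawn from sex-conditional normals whose separation is solved
from the target point-biserial correlation (default -0.69, female coded
high; with the study's within-sex SDs this lands the male mean near the
printed 17.64 against 15.14 for females — the study never states the unit,
so the simulation simply mirrors the printed scale). Recall room is split
50/50; hormonal-contraceptive use and menstrual-cycle phase are drawn at
the study's observed female proportions and carried as factors only — no
hormonal effect on networks is simulated, because none was found.

**Networks: one latent clustering dial.** A fixed block-modular template
`W0` (7 modules for 82 nodes; strong within-module edges, moderate
between-module edges, plus a weak/absent tail of between-module
connections that the population mask later removes) is paired with a
triangle-enriched companion `T0`, obtained by multiplying core edges by
their normalized two-step walk support and compressing with a cube root
(the scale of geometric-mean triangle intensity). Each subject mixes the
two: `W_i = clip((1 - lambda_i) W0 + lambda_i T0)`, with multiplicative
log-normal edge noise (sd 0.05), and directed streamline tallies are
Binomial(waytotal = 5000, W_i[j, k]) per ordered parcel pair. Transitivity
of the mix is numerically increasing in the dial, so
`lambda_i = lambda0 + beta_sex * male_i + beta_age * z(age_i) + eps_i`
realizes a *global* transitivity difference. This is deliberate: the
study-level effect is a whole-brain difference, and node-level
concentration is left emergent rather than painted onto specific parcels.

**Memory.** Each valence category has 24 pictures; recall counts are
Binomial(24, p) with a logit-linear predictor carrying valence intercepts
(negative and positive recalled better than neutral), a female advantage
largest for positive pictures, a recall-room improvement, a transitivity
term `gamma_t * z(T)`, and a subject random ability (logit sd 0.45) that
gives the mixed model a genuine random intercept. Binomial counts keep
recall bounded in [0, 24] by construction.

**Calibration.** Four quantities are targets: the ICV-adjusted
standardized sex difference in transitivity (d = 0.42, male higher), the
age-transitivity correlation (-0.23), the transitivity-memory partial
correlation (-0.12), and the between-subject transitivity SD (0.0025, the
scale of the study's printed group SDs). `calibrate_effects()` first runs
a full tally-level pilot at the cohort's own size — edge noise, Binomial
tallies, population mask, transitivity — with dial values spread like a
real cohort's, and fits a quadratic `h(lambda)` for the observed
transitivity plus a residual "measurement" SD. It then solves
`(beta_sex, beta_age, sigma_eps)` on cheap metric-level pilots (default
400,000 subjects) with common random numbers by a multiplicative fixed
point, and finds `gamma_t` by a secant search on the target partial
correlation. Infeasible targets (e.g. measurement noise exceeding the
requested between-subject SD) fail loudly with diagnostics. The
metric-level generation mode (`generate_cohort(..., level = "metric")`)
draws observed transitivity directly from `h(lambda)` plus measurement
noise — this is what makes 5,000-replicate type-I studies affordable — and
shares covariates and recall with the tally mode under the same seed.

**What the generator does not emulate.** Spatial geometry of tracts,
parcel-specific effects (node-level hits in a generated cohort are sampling
noise), valence/arousal ratings at item level, the true (unknown) edge
covariance structure of human connectomes, and the absolute transitivity
level: the synthetic template is sparser than the real connectome, so
generated transitivity sits near 0.43 rather than the study's 0.765. All
calibrated quantities are *relative* (standardized differences and
correlations), which is also why passing recovery tests shows estimator
correctness under the configured structure, not fidelity of any single
simulated brain.

## Numerical and design choices

- **Distance mapping.** The weight-to-length map is `l = 1/w`, the standard
  convention of the network-neuroscience toolbox literature; disconnected
  pairs are excluded from the path-length mean and flagged
  (`connected = FALSE`) rather than raising an error, since masking can in
  principle disconnect a matrix.
- **Transitivity variant.** Geometric-mean (Onnela) triangle intensity with
  max-weight normalisation. The printed magnitudes of the original analysis
  cannot disambiguate the exact library variant used there; the choice is
  isolated in `weighted_clustering()` so an arithmetic-mean (Barrat-style)
  variant could be swapped in.
- **Mask boundary.** "Below 0.01" is read strictly, so an edge whose
  criterion equals the threshold is kept; the criterion uses the sample
  (n - 1) SD.
- **Type-II sums of squares** for the F tests (the convention of the car
  package used for the original models); Type III is available as an
  argument. For mixed models the denominator df follow nlme's inner/outer
  (between/within subject) convention, which reproduces the published
  F(1, ~650)/F(2, ~1308) df layout; `anova` type is "sequential" by
  default with "marginal" as the switch.
- **d from t.** `d = t (n1 + n2)/(sqrt(n1 n2) sqrt(df))`: with F = 27.11,
  groups 264/391 and df 651 this reproduces the published d = 0.42 exactly
  to two decimals, which is the reason this variant (rather than
  `t sqrt(1/n1 + 1/n2)`, giving 0.41) is used.
- **Mediation bootstrap.** Subjects are resampled; residualization is done
  once on the full sample by default, matching the residual-based setup of
  the original analysis, with `reresidualize = TRUE` available to redo the
  covariate adjustment inside every draw. Bias correction uses
  `z0 = qnorm(P(boot < estimate))` (clamped with a warning in degenerate
  cases), acceleration uses the jackknife skewness formula, and interval
  endpoints interpolate order statistics on the normal-quantile scale, so
  the implementation agrees with `boot::boot.ci(type = "bca")` to numerical
  precision on identical draws. Default B = 10000, the study's setting;
  tests run at reduced B with fixed seeds.
- **Ratio instability.** The mediation ratio `(a b)/c'` is reported as `NA`
  with a warning when the direct effect is numerically zero.
- **Seeding.** Every stage derives a fixed substream from one master seed
  (all derived seeds stay below 2^31), so `run_pipeline()` reruns
  bit-identically and stages can be re-run in isolation.

## Problem sizes used in the tests

The suite validates the full chain at sizes chosen to keep the statistics
meaningful: oracle equivalence (Dijkstra vs Floyd-Warshall, matrix-power
transitivity vs exhaustive triangle loops) on 100+ random graphs of up to
12 nodes at 1e-10 tolerance; type-I error of the sex F test over 5,000
null-generator replicates at the published alpha = 0.0125; parameter
recovery over 50 tally-level replicate cohorts at the study size n = 655
(d, age and memory correlations, and the indirect effect each compared to
target within two Monte-Carlo standard errors); and 95% BCa coverage over
200 replicates at B = 2000 within three percentage points. Most unit tests
run on a reduced 28-node parcellation with a proportionally larger target
transitivity SD (0.012), since a sparser parcellation has fewer triangles
and hence noisier transitivity.

## Known limitations

- The generator realizes the configured effect structure through a single
  latent dial; it cannot be used to study node-level localisation, edge-level
  topology effects, or parcellation comparisons beyond node count.
- Real tractography weights can behave non-probabilistically when target
  masks overlap; inputs are clamped to [0, 1].
- The mediation machinery is a single-mediator linear analysis; no
  exposure-mediator interaction, sensitivity analysis, or multiple
  mediators.
- REML fitting relies on nlme; denominator-df conventions other than
  inner/outer (e.g. Satterthwaite) are out of scope.

## A minimal run

```{r example, eval = FALSE}
config <- cohort_config(n_subjects = 655, seed = 1)
result <- run_pipeline(config, seed = 1, B = 10000,
                       output_dir = "memconn_report")
print(result)
```

The report directory contains the subject-level metric table, the tidy
model table (term, F, df, p, d-or-r, significance at alpha = 0.0125), the
node-level scan with its Bonferroni threshold, the mediation summaries for
total and positive-picture recall, and boxplot/age-association figures
when ggplot2 is available.
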