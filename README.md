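# memconn

Structural-connectome analysis of sex differences in brain network
organisation and their mediation of episodic memory performance.

`memconn` is for researchers working with probabilistic-tractography
connectomes who want a tested, reproducible pipeline from raw streamline
tallies to the statistical claims: weighted network construction,
population-level edge masking, whole-brain graph metrics, covariate-adjusted
group contrasts, and bootstrap mediation analysis. Because imaging cohorts
usually cannot be redistributed, the package ships a calibrated synthetic
cohort generator that reproduces the statistical structure of a large
(n = 655, 60% female) young-adult study, so the entire chain is testable by
parameter recovery.

## The model in brief

Per subject, a directed streamline count matrix over R anatomical parcels is
turned into connection probabilities P_ij = N_ij / waytotal_i, symmetrized
as C_ij = (P_ij + P_ji)/2, and masked at the population level: edges with
mean(C_ij) + 2 sd(C_ij) < 0.01 across subjects are removed everywhere. Four
whole-brain measures are computed on the weighted graph:

- graph strength: s_i = Σ_j C_ij (global: mean over nodes),
- characteristic path length: mean shortest-path distance with edge length
  1/C_ij,
- global efficiency: mean inverse shortest-path distance,
- weighted transitivity: T = Σ_i 2 t_i / Σ_i k_i(k_i − 1), with
  geometric-mean triangle intensity t_i = ½ Σ_{j,h} (ŵ_ij ŵ_ih ŵ_jh)^{1/3}
  after max-weight normalisation; node level: clustering coefficient
  C_i = 2 t_i / (k_i(k_i − 1)).

Sex differences are tested with linear models (Type-II F tests; age and ICV
as covariates) and expressed as Cohen's d reconstructed from the model t
value, d = t(n1+n2)/(√(n1·n2)·√df), so d inherits all covariate
adjustments. Memory (free recall of 24 pictures per valence category) is
analysed with random-intercept REML mixed models. Mediation of the
sex→memory effect by weighted transitivity uses residualized, standardized
variables (paths on the r scale; indirect effect a·b) with bias-corrected
and accelerated (BCa) bootstrap intervals at 95–99.5%.

## Worked example

```r
library(memconn)

config <- cohort_config(seed = 1)        # n = 655, 82 nodes, d = 0.42, ...
calib  <- calibrate_effects(config)      # ~30 s: tunes the generator
cohort <- generate_cohort(config, calib, seed = 1, level = "tally")

conns  <- build_connectomes(cohort$tallies)
mask   <- build_population_mask(conns)   # theta = 0.01, k_sd = 2
print(mask)
#> population_mask: 2058 / 3321 edges kept (theta = 0.01, k_sd = 2, n = 655)

masked <- lapply(conns, apply_mask, mask = mask)
tv     <- sapply(masked, function(m) weighted_clustering(m)$transitivity)

fit <- fit_ols(tv ~ sex + age + icv, cbind(cohort$subjects, tv = tv))
print(fit)
#> ols_result (n = 655, Type-2 F tests)
#>  term        F df1 df2         p    d_or_r
#>   sex 36.03116   1 651 3.226e-09  0.480845
#>   age 36.61997   1 651 2.423e-09 -0.230773
#>   icv  0.02843   1 651 8.662e-01  0.006608
```

The sex row says: adjusted for age and ICV, males have higher weighted
transitivity in this particular generated cohort, F(1, 651) = 36.0, Cohen's
d = 0.48 (positive = male-higher; the configured population target is
d = 0.42, and single cohorts scatter around it with SE ≈ 0.08). The age row
recovers the configured negative age association (r = −0.23). The mediation
stage then asks how much of the female recall advantage runs through the
network difference:

```r
med <- run_mediation(cohort$subjects, tv, outcome = "all", B = 10000, seed = 1)
print(med)
#> mediation_result (n = 655, B = 10000)
#>   a = 0.161, b = -0.098, c = -0.065, c' = -0.049
#>   indirect (a*b) = -0.016, ratio indirect/direct = 0.320
#>   indirect 95.0% BCa CI: [-0.0349, -0.0035] *
#>   indirect 99.0% BCa CI: [-0.0421, -0.0006] *
#>   indirect 99.5% BCa CI: [-0.0438, 0.0008]
#>   ratio 95.0% BCa CI: [-0.6292, 15.1304]
#>   ...
```

With male = 1 coding, a > 0 (males higher transitivity), b < 0 (higher
transitivity, worse recall), so the indirect effect a·b ≈ −0.02 on the r
scale: the network difference transmits a male disadvantage in recall —
equivalently, part of the female advantage — and its 95% and 99% BCa
intervals exclude zero (the published analysis reports the same quantity as
r = 0.02 in magnitude). The wide ratio interval shows why the mediation
ratio (a·b)/c′ is reported with bootstrap intervals rather than alone: it
is unstable when the direct effect is small.

One call runs everything (simulation, connectomes, metrics, all models,
node-level Bonferroni scan, both mediations) and writes a plain-text report:

```r
res <- run_pipeline(cohort_config(seed = 1), seed = 1, B = 10000,
                    output_dir = "memconn_report")
```

A thin CLI wrapper with the same surface lives at `inst/cli/memconn.R`
(`Rscript memconn.R run-all --seed 1 --out report`).

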