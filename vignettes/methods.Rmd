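---
title: "Methods: association meta-analysis and BMI mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association meta-analysis and BMI mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamediate)
```

## Scope and model

`metamediate` implements a multi-cohort analysis chain for paired blood
transcriptome (microarray intensities) and metabolome (targeted LC-MS/MS
amino acid and acylcarnitine concentrations) data, and a mediation analysis
of their joint effects on body mass index (BMI):

1. **Study-wise pre-processing.** Metabolites: removal of measurements whose
   natural-log value exceeds mean + 5 SD of the log-transformed positive
   values (zeros, i.e. values below the detection limit, are excluded from
   the threshold computation only and never flagged), rank-based inverse
   normal transformation (INT), and empirical-Bayes location/scale batch
   adjustment. Expression: log2, quantile normalisation, empirical-Bayes
   batch adjustment, removal of probes present in at most 5% of samples or
   Bonferroni-significantly associated with batch, removal of samples whose
   Euclidean distance from the feature-wise median sample exceeds
   median + 4 IQR of the distance distribution, and probe-to-gene mapping
   through a user-supplied table.
2. **Per-study association scan.** For each metabolite, every probe is
   regressed by OLS on the metabolite plus six covariates (age, sex, fasting
   hours, hematocrit, neutrophil %, monocyte %). Residual variances are
   shrunk by an empirical-Bayes scaled-F prior (the log-F moment estimator
   with digamma/trigamma inversion), giving moderated t statistics on
   augmented degrees of freedom.
3. **Random-effects meta-analysis.** Probe-metabolite pairs present in at
   least two studies are pooled by DerSimonian-Laird: fixed-effect weights
   $w_i = 1/\mathrm{se}_i^2$, Cochran's $Q$, the method-of-moments
   $\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$,
   random-effects weights $1/(\mathrm{se}_i^2+\hat\tau^2)$, and
   $I^2 = \max\{0, (Q-(k-1))/Q\}$.
4. **Hierarchical FDR.** Benjamini-Hochberg within each family (metabolites
   for associations, exposures for mediations), then BH across families on
   each family's smallest adjusted p. A record is significant when both its
   local adjusted p and its family's global adjusted p are at or below the
   level (default 5%).
5. **Mediation.** For each eligible transcript-metabolite pair the five
   regressions (log-BMI ~ metabolite; log-BMI ~ expression;
   metabolite ~ expression; expression ~ metabolite;
   log-BMI ~ metabolite + expression), each with covariates, are fitted per
   study by plain OLS and pooled by DerSimonian-Laird. The indirect effect
   is the product of coefficients $\beta_\mathrm{mediation} = \alpha\beta$
   ($\alpha$: exposure on mediator; $\beta$: mediator on log-BMI given the
   exposure). Its p-value compares $z_\alpha z_\beta$ against the null
   distribution of the product of two independent standard normals (density
   $K_0(|u|)/\pi$). Confidence intervals are Monte-Carlo quantiles of
   $ab$ with $a \sim N(\hat\alpha, \mathrm{se}_\alpha^2)$,
   $b \sim N(\hat\beta, \mathrm{se}_\beta^2)$. The proportion mediated
   $\mathrm{PM} = \alpha\beta/(\alpha\beta+\tau')$ classifies directions:
   a significant mediation with $\mathrm{PM}\ge 0.2$ whose reverse has
   $\mathrm{PM}\le 0.2$ is a strong unidirectional mediation; both
   directions significant with $\mathrm{PM}\ge0.2$ is strong bi-directional;
   other significant mediations are weak.
6. **Networks and power.** Bipartite hub-gene/metabolite association
   networks (edges filtered by explained variance, default 0.5%),
   metabolite-metabolite links from Pearson correlations of standardised
   effect profiles ($|r|\ge0.9$), PM-filterable directed mediation networks,
   and a minimum-detectable-$R^2$ calculator,
   $R^2_{\min} = \lambda/(n+\lambda)$ with
   $\lambda = (z_{1-\alpha/2}+z_{\mathrm{power}})^2$.

Eligibility for a mediation test follows the usual causal-triangle
requirements: the exposure must have a significant total effect on log-BMI
or at least a significant direct effect (the latter case is flagged
`partial_only`, since only partial mediation is then assessable). Pairs with
a significant exposure-by-mediator interaction on log-BMI are removed before
testing, because the product-of-coefficients decomposition is invalid under
interaction. BMI and diabetes status are never used as covariates in these
models — adjusting for the outcome (or a near-collinear proxy) would absorb
the very effects under study.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| FDR level `q` | 0.05 | level of both hierarchical BH stages |
| `pm_cut` | 0.2 | PM threshold separating strong from weak mediations |
| `outlier_sd` | 5 | log-scale SD multiplier for metabolite upper outliers |
| `min_rate` | 0.05 | probe presence-rate threshold |
| `iqr_mult` | 4 | sample distance filter multiplier |
| `min_explained_variance` | 0.005 | association network edge filter (r²) |
| `mc_reps` | 1e5 | Monte-Carlo CI draws (>= 1e4 enforced with a warning) |
| `alpha` (power) | 2e-8 | genome-wide level, 0.05 / 2.5 million tests |

## Synthetic data generator

`generate_multistudy()` emulates the multi-cohort design so that every
stage is testable without external data: several analysis groups of unequal
size (default 1000/600/350), two technical batches per group with additive
shifts (SD 0.3) and multiplicative scales (log-SD 0.1) applied per
batch-feature on the log scale, six covariates with realistic marginals and
small effects on log-BMI, and feature latents with unit marginal variance
sharing a covariate-loading budget of 0.1 (confounding that the covariate
adjustment removes). Metabolites are log-normal and left-censored to zero at
a configurable rate (default 5%), reproducing the skew and excess zeros the
pre-processing rules target; expression latents map to positive
microarray-like intensities via `2^x`. BMI is `exp(linear predictor +
noise)` with residual SD 0.15 on the log scale — a realistic coefficient of
variation around a median of 27 kg/m² — so log-BMI is exactly linear in
exposures, mediators and covariates. Planted triangles draw per-study
effects as the triangle effect plus `Normal(0, heterogeneity_sd)` (default
0.02), giving genuine random-effects heterogeneity.

What the generator does **not** emulate: genotype/kinship structure,
vendor control probes, raw spectra, realistic probe-level correlation
structure (co-expression), or missingness beyond detection-limit zeros.
Passing tests therefore demonstrate the correctness of the statistical
machinery under its stated model, not robustness to every artefact of real
cohort data.

## Numerical choices

* **INT offset.** Blom (3/8) with average ranks for ties; zeros are retained
  through INT (ranked lowest), only the upper-outlier step excludes them.
  A constant vector transforms to all zeros with a warning.
* **Sample distance rule.** "Distance larger than four times the IQR from
  the median" is read as `median(d) + 4*IQR(d)` on the distance
  distribution; the absolute variant (`d > 4*IQR`) is available via
  `rule = "absolute"`.
* **Probe presence fallback.** When detection flags are absent, presence is
  intensity above the 5th percentile of the study-wide intensity
  distribution (all probes pooled; a per-probe percentile would make every
  probe 95% present by construction).
* **Moderation.** The trigamma inversion uses Newton iteration to 1e-10
  relative tolerance; when the observed log-variance dispersion does not
  exceed its chi-square expectation the prior degrees of freedom are
  infinite and all variances collapse to their mean.
* **Product-normal CDF.** The tail integral of the Bessel-`K0` density is
  evaluated by adaptive quadrature from `|x|` to infinity (relative
  tolerance 1e-12), avoiding the logarithmic singularity at 0 entirely and
  guaranteeing `F(x) + F(-x) = 1` by construction; for `|x| > 700` the tail
  underflows and is 0.
* **Meta-analysis.** DerSimonian-Laird was chosen as the random-effects
  estimator (REML available in `metafor` for cross-checking); the pooled
  p-value uses the normal reference, standard for DL. `I^2` is computed from
  `Q` and truncated at zero.
* **Moderated vs raw SEs.** Moderated SEs feed the association
  meta-analysis (`run_study_associations(moderated = TRUE)` default),
  consistent with the empirical-Bayes scan; the five mediation regressions
  use plain OLS, as is conventional for mediation triangles.
* **PM.** Returned unclipped; values outside [0, 1] (sign pathologies) are
  flagged, not altered, and a zero total effect yields `NA` with an
  `undefined` flag. Classification compares the signed PM against the
  cutoff exactly.
* **Hierarchical FDR decision rule.** The two-stage adjustment is combined
  by conjunction (local AND global at level q); the Benjamini-Bogomolov
  level-adjusted variant is available via `variant = "bb"`.
* **Wilcoxon subset comparison.** Heterogeneity (`I^2`) comparisons between
  catalogues use the pairs shared by both; effect correlations use the
  union of pairs significant in either (switchable to all shared pairs).

## Validation design and problem sizes

The replicated validation suites use deliberately small feature counts
(4 probes x 4 metabolites) and three studies of n = 1500, which makes one
recovery replicate cheap while keeping per-coefficient sampling error
(~0.015 pooled) far below the planted effects:

* `replicate_triangle_recovery()` (200 replicates): Monte-Carlo CI coverage
  of the planted indirect effect and direction-classification recovery.
  The planted triangle is identical in every study
  (`heterogeneity_sd = 0`): the covered quantity is the common indirect
  effect. With between-study heterogeneity and only three studies,
  DerSimonian-Laird `tau^2` is noisy and the CI undercovers the population
  effect (about 0.83 at `heterogeneity_sd = 0.02` in our experiments) — a
  known small-k limitation of the estimator, not of the implementation; the
  argument is exposed so users can reproduce this behaviour.
* `replicate_interaction_filter()` (100 replicates): removal power for a
  planted interaction of 0.5 and the null removal rate of
  interaction-free pairs.
* `replicate_null_fdr()` (500 replicates of 50 families x 200 tests):
  mean false discovery proportion under the global null.
* `prodnorm_null_calibration()` (1e4 null triangles): the product test is
  conservative near the null centre, so rejection rates at or slightly
  below the nominal 5% are the expected behaviour.

Quantile normalisation is disabled inside the small-feature validation
replicates (and only there): with a handful of probes the common quantile
grid has too little resolution and would destroy between-sample signal.
This is a property of quantile normalisation at degenerate feature counts,
not of the pipeline at genome scale.

## Known limitations

* The minimum-detectable-variance calculator reproduces published design
  values at three of five sample sizes after rounding; at n = 935 and
  n = 3145 the normal-approximation solution differs by about 0.1
  percentage points from values computed with commercial power software,
  which uses its own exact-F and rounding conventions. The exact
  noncentral-F path (`exact = TRUE`) agrees with the normal approximation
  to < 0.1 pp for n >= 2000.
* Mediation classifications are statements about conditional correlation
  structure; the causal order is assumed, not tested, and alternative
  orders (e.g. BMI affecting expression) can produce the same joint
  distribution.
* Complete mediation (absence of a direct effect) is not tested; the
  pipeline focuses on partial mediation.
* Kinship/relatedness adjustment and vendor control-probe QC are out of
  scope; inputs are assumed to come from unrelated individuals after
  study-specific QC.

## A small worked run

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_per_study = c(300, 300, 300), n_probes = 30, n_metabolites = 6,
  triangle_specs = list(
    true_triangle("transcript", "probe_0001", "met_001", 0.5, 0.2, 0.1)),
  seed = 42)
datasets <- generate_multistudy(cfg)
run <- run_config(output_dir = "results_run", seed = 42, mc_reps = 1e4)
manifest <- run_pipeline(run, datasets = datasets)
```

The output directory then holds the per-study association records, the
meta-analysis catalogue, interaction records, the classified mediation
table, GraphML/JSON networks, the power table, a QC report, a run log with
all filter counts, and a checksummed manifest; reruns with the same seed are
byte-identical.
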