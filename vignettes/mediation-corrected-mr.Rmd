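---
title: "Mediation-corrected instrument selection for MR of dietary intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation-corrected instrument selection for MR of dietary intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curmr)
```

## The problem

Genome-wide association studies of reported food intake recover hundreds of
variants, but a variant associated with, say, milk-fat choice need not act
on food preference at all: its association may be entirely mediated through
body mass index, blood lipids, blood pressure, education or disease status,
any of which alters what people eat — or what they report eating. Used as
Mendelian randomization (MR) instruments, such mediated variants violate the
exclusion restriction and re-introduce exactly the confounding and reverse
causation that MR is meant to remove. `curmr` implements a correction and
classification scheme that separates variants with a *direct* effect on the
food trait from those whose association is mediated, and restricts MR to
the direct ones.

## The model

### Mediator model and corrected effects

For a focal food trait, a set of candidate mediator traits (health
determinants with public GWAS summary statistics) is screened by forward
stepwise multivariable MR (`fit_prior()`). The retained mediators carry
causal effects $\theta_k$ on the focal trait, estimated by weighted
multiple regression without intercept of the focal per-variant effects on
the mediator effect matrix at the mediators' instruments (weights
$1/\mathrm{se}^2$).

Each variant's *prior mediated effect* is the linear combination

$$\mu_j = \sum_k \theta_k\, b_{kj},$$

where $b_{kj}$ is variant $j$'s effect on mediator $k$. The corrected
effect subtracts it:

$$\beta^{\mathrm{corr}}_j = \beta^{\mathrm{obs}}_j - \mu_j,
\qquad
\mathrm{se}^2_{\mathrm{corr}} = \mathrm{se}^2_{\mathrm{obs}}
 + \sum_k\left(\theta_k^2\,\mathrm{se}^2_{b_{kj}}
 + b_{kj}^2\,\mathrm{se}^2_{\theta_k}\right).$$

Additive subtraction is the central modelling decision: it makes the
corrected effect interpretable as the residual direct path, propagates
variance upward only (the corrected SE can never shrink below the observed
one), and yields the defining identity $\mu_j = 0 \Rightarrow
\mathrm{CUR}_j = 1$ exactly. The variance propagation treats the mediator
betas and the $\theta_k$ as independent; correlation induced by sample
overlap between the focal and mediator GWAS is ignored by default
(`project_effects()` exposes an error-covariance hook for the analogous
problem across food traits).

### The corrected-to-uncorrected ratio (CUR)

$$\mathrm{CUR}_j = \beta^{\mathrm{corr}}_j / \beta^{\mathrm{obs}}_j.$$

A variant whose association is not mediated keeps
$\mathrm{CUR} \approx 1$; mediation drags CUR away from 1 (towards 0 when
the whole association is mediated, negative when the correction flips the
sign). `classify_cur()` labels a variant **non-mediated** iff CUR lies in
$1 \pm w$ with default half-width $w = 0.05$, and **uncertain** otherwise.
Three deliberate choices:

* the window applies to the *signed* CUR, so sign flips are always
  uncertain;
* variants with $|\beta^{\mathrm{obs}}| < 2\,\mathrm{se}_{\mathrm{obs}}$
  are uncertain regardless of CUR — a ratio of two noise-dominated numbers
  carries no information, and CUR is only interpreted at
  genome-wide-significant variants anyway;
* a missing mediator estimate makes a variant not-correctable (uncertain
  with a reason) rather than silently imputed as zero.

### Stepwise mediator selection

The selection criterion is predictive, not merely associative: a candidate
enters only if (a) its multivariable effect is significant after Bonferroni
correction over the candidate pool (default entry level 0.05), and (b) it
improves the K-fold cross-validated prediction of the focal z-scores,
measured as the mean held-out correlation between prior and observed
z-scores, with $\theta$ refit in each fold excluding the held-out
instruments. The correlation is used *signed*: a prior that anti-correlates
out of sample is not predictive, and a squared summary would reward chance
entries (it is non-negative by construction). Under a pure-null candidate
pool this keeps the null model in well over 95% of replicates while a
mediator with a genuine effect of 0.3 SD enters essentially always. The
`prior_r2` reported with the model — the squared correlation between prior
and observed z-scores genome-wide — is the fraction of the trait's
association signal attributable to mediation.

## MR estimators

All estimators are implemented from their defining formulas and
cross-checked in the test suite against independent routes
(closed-form weighted least squares, Monte-Carlo delta method, parametric
constructions):

* **IVW**: fixed-effect weighted regression through the origin; the
  random-effects flavour is *multiplicative* (SE inflated by
  $\sqrt{Q/(n-1)}$ when above 1), matching the fixed/random dichotomy used
  in two-sample MR summary practice; `mode = "auto"` switches at
  heterogeneity $p < 0.05$. One instrument falls back to the Wald ratio.
* **MR-Egger**: weighted regression with free intercept after orienting all
  exposure betas positive (the standard InSIDE convention); multiplicative
  SE inflation; the intercept tests directional pleiotropy.
* **Weighted median**: inverse-variance-weighted median of the per-variant
  ratios with the usual interpolation; SE by parametric bootstrap (the
  caller's RNG stream is saved and restored).
* **MR-RAPS**: maximum adjusted profile likelihood for the ratio under an
  errors-in-variables model with multiplicative overdispersion (the plain,
  non-robust loss). In the error-free-exposure limit the point estimate
  equals IVW. The SE comes from the observed information, with the
  overdispersion floored at 1 so it never deflates below the fixed-effect
  SE.
* **Radial outliers**: per-variant contributions to the radial Q with
  modified second-order weights, compared to $\chi^2_1$, Bonferroni over
  the current instrument count at $\alpha = 0.05$, iterated to
  convergence.
* **Stepwise heterogeneity pruning**: removes the largest-Q instrument
  while the global Cochran Q p-value is below 0.05.
* All Wald-type inference uses the normal approximation.

The reverse-direction screen (health on food) applies stepwise
heterogeneity pruning and the *switch rule*: when the Egger intercept
differs from zero at $p < 0.05$ the Egger estimate replaces IVW. The
forward analysis (food on health) instead reports Egger, weighted median
and RAPS as sensitivity analyses alongside radial-cleaned IVW — the two
directions deliberately follow different protocols.

## Dietary-pattern (PC) traits

Food traits are clustered on their (corrected) genetic-correlation matrix
by agglomerative merging of the most-correlated pair, with negatively keyed
items reversed into their cluster. The flat grouping applies a simplified
reliability rule: a merge is kept only if the merged cluster's
standardized alpha is at least the larger of its children's. This is an
item-clustering *stand-in*: the contract is recovering the grouping on
separable matrices, not replicating any published implementation's
tie-breaking.

For each group the leading eigenvector of the genetic-correlation submatrix
(unit norm, sign fixed by a reference trait) defines the pattern trait;
only the first component is retained, with explained share
$\lambda_1/\sum\lambda$. Per-variant effects project as the
loading-weighted linear combination, with independent-error SE propagation
by default. Projecting the original and the corrected effects separately
yields a projected CUR, so pattern traits are filtered exactly like single
foods. Loadings are applied to per-SD effects without re-standardization by
trait heritabilities; the projection is linear, so identity on singleton
groups and scale equivariance hold exactly. Estimated correlation matrices
that are slightly indefinite are repaired by eigenvalue clipping and
rescaling to a unit diagonal (tolerance 1e-8); matrices whose most negative
eigenvalue exceeds 5% of the largest are rejected as invalid.

## The synthetic-data generator

### Single-food structural system (`sim_config()` / `simulate_cohort()`)

Individual-level cohorts follow a linear structural equation model with
three variant classes — `Gy` acting directly on the food trait Y, `Gx` on
a causally connected trait X, `Gu` on a confounder U — and simultaneous
effects X→Y and Y→X. The bidirectional system is solved through its
*reduced form* rather than by iteration, so the generated data are exact
and the implied marginal effects have closed forms (carried in the truth
table and verified against the individual-level scans in the tests).
Genotypes are independent Binomial(2, maf) draws; the observed trait is
$Y_o = \sqrt{r}\,Y_t + \sqrt{1-r}\,\varepsilon$ with test-retest
reliability $r$, which keeps unit variance and makes replicate
questionnaire measurements correlate at $r$.

Default study conditions, chosen once as representative of this setting:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 100,000 | biobank-scale single GWAS |
| `n_gy`, `var_gy` | 50, 0.10 | food-trait SNP heritability is modest, spread over tens of loci |
| `n_gx`, `var_gx` | 50, 0.35 | health determinants contribute a few large-effect loci, so mediated signals are visible in the food GWAS |
| `maf_range` | (0.05, 0.5) | common variants |
| `retest_r` | 0.7 | typical short food-frequency-questionnaire test-retest reliability |
| CUR window | 0.05 | the 1 ± 0.05 classification window |
| instrument selection | p < 5e-8, r² < 0.001 | conventional two-sample MR practice |
| food-trait discovery | p < 1e-8 | 5e-8 Bonferroni-corrected over 5 independent food groups |

A fast path (`simulate_sumstats()`) draws summary statistics directly from
the asymptotic sampling distribution of the per-variant regression
estimates, independently across traits — i.e. an idealized two-sample
design. The individual-level path is the ground truth; the fast path exists
for large replication grids and is calibrated against it in the tests.

### Multi-trait studies (`study_config()` / `simulate_study()`)

Pipeline-level simulations use an acyclic topology: confounder U → health
mediators → foods → outcomes. Every trait is represented internally as a
linear combination of independent primitives (centered dosages plus one
noise primitive per trait), so trait variances are exactly 1 and true
standardized effects are exact by construction. Questionnaire noise is
applied to the foods as above. Summary statistics are again drawn per trait
in independent samples.

What the generator deliberately does *not* emulate — and hence what passing
tests do not establish about real data: linkage disequilibrium (an optional
compound-symmetry block mode exists only to exercise the pruner; default
variants are independent), sample overlap between the focal and mediator
GWAS (error correlations are zero by design, matching the correction's
independence assumption rather than stress-testing it), allele-frequency
and effect-size architectures of real cohorts, binary traits and their
log-odds scale, and population stratification. Estimated genetic
correlations in `run_study()` are proxied by correlations of corrected
z-scores across the simulated variant panel, which is adequate for
separable structures but is not an LD-score-regression estimate.

## Numerical choices and degenerate inputs

* LD pruning is greedy by ascending p with ties broken by variant id, so
  results are deterministic; every LD-connected component keeps its
  smallest-p variant.
* Palindromic (A/T, C/G) variants are kept only when both allele
  frequencies are available and both are farther than 0.08 from 0.5
  (frequencies on opposite sides trigger a flip); variants with missing
  frequency always fail this check. Complement-coded records are treated
  as mismatches — no strand inference.
* `beta_xy * beta_yx = 1` makes the simultaneous system singular and is a
  configuration error; monomorphic variants are dropped from scans with a
  message; an all-flagged radial step, pruning below two instruments, a
  rank-deficient multivariable design and an empty harmonization
  intersection are errors, not silent results.
* p-values are floored at the smallest positive double so that q-value
  computation never sees an exact zero.
* Storey's estimator uses the lambda grid 0.05–0.95 (step 0.05) with a
  df-3 smoothing spline evaluated at the largest lambda, clamped to
  (1/m, 1]; below 20 p-values it falls back to Benjamini–Hochberg with a
  warning.
* Seeds: every simulator takes an explicit seed and is bit-reproducible;
  `run_study()` derives all per-pair bootstrap seeds from the pipeline
  seed.

## Problem sizes used in the checks

The packaged checks run the calibration grid at n = 100,000 individuals
with 50 + 50 variants across two grid cells; the confounded-null comparison
at 200 replicates of the asymptotic generator; estimator oracles at 1,000
instances/replicates; coverage at 400 replicates; and the full-null
false-discovery calibration at 500 reduced-scale pipeline replicates
(4 food × 5 outcome pairs each). These sizes were chosen so each property
is measured with Monte-Carlo error well inside its acceptance band.

## A worked example

```{r example}
cfg <- sim_config(n_individuals = 50000, n_gy = 30, n_gx = 30,
                  beta_xy = 0.3, seed = 42)
cohort <- simulate_cohort(cfg)
food <- gwas_scan(cohort, "Yo")
health <- gwas_scan(cohort, "X")

model <- fit_prior(food, list(health = health))
model

corrected <- correct_effects(food, model, list(health = health))
summary(corrected)
```

The mediated variants (those acting through the health trait) fall outside
the CUR window and are excluded from the instrument set that
`forward_mr()` uses in `cur_filtered` mode.

## Known limitations

The correction subtracts a point estimate of the mediated path; it is not a
posterior and carries no shrinkage, so weakly estimated mediator effects
propagate into wide corrected SEs rather than being regularized away.
Sample overlap between focal and mediator GWAS biases the prior's SE
decomposition. The classification threshold trades sensitivity against
specificity and degrades as reverse causation (Y→X) grows, since direct
variants then genuinely act on the mediator too — under strong
bidirectionality the CUR distributions of direct and mediated variants
overlap and no window separates them cleanly. Binary-outcome support is
limited to carrying the log-OR scale tag through the pipeline; no
liability-scale conversion is attempted.
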