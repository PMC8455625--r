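---
title: "Methods: elastic-net drug-response signatures and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-net drug-response signatures and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsig)
```

## Overview

`pharmsig` trains per-drug elastic-net signatures of treatment response
from cell-line mutation and expression data restricted to a cancer-gene
panel, locks them, and applies them without modification to independent
cohorts. This vignette records the modelling assumptions, the tunable
parameters and their defaults, the numerical choices, what the synthetic
cohorts emulate, and the known limitations. It states no empirical result
beyond what the package's tests and acceptance script themselves compute.

## Feature representation

**Mutation channel.** A gene/sample pair is coded 1 iff at least one call
affects the protein-coding product: missense, nonsense, frameshift,
in-frame indel, or splice-site (splice-site variants are included as
coding-affecting, standard somatic-filtering practice). Silent, intronic,
intergenic, UTR and other non-coding calls never set the bit, and
duplicate calls collapse by OR, so the channel is invariant to call
multiplicity. Samples present in the expression data but absent from the
call table are treated as wild-type (all zeros) — absence of a call is
absence of a mutation under this coding.

**Expression channel.** `log2(FPKM + 1)`, then median scaling. The
pseudo-count of 1 keeps zero FPKM finite and is configurable
(`pseudo_count`). "Scaled to the median of the cohort" is implemented as
*per-gene* median centering by default: each gene's median across the
cohort's samples becomes 0, which makes the feature dimensionless and
comparable across platforms — the property that cross-cohort transfer of
locked coefficients relies on, since any gene-wise location shift between
platforms (library preparation, quantification pipeline) is removed by
each cohort's own centering. A cohort-global mode (one median subtracted
from the whole matrix) is provided for sensitivity analysis
(`mode = "global"`); it preserves between-gene level differences but does
not neutralize gene-specific platform shifts.

**Assembly.** Features are named `<GENE>:expr` and `<GENE>:mut`, ordered
by the panel with the expression channel first per gene. A gene missing
from one channel simply contributes no column there. Gene symbols are
upper-cased everywhere for cross-file matching. Panels from multiple
platforms are harmonized by intersection ordered by the first panel
(`harmonize_panel()`).

## Training

For each drug the package minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i\beta)^2 +
  \lambda\left(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right)$$

with the response the per-drug Z-scored IC50.

* **Grid.** $\alpha \in \{0.1, 0.325, 0.55, 0.775, 1.0\}$ spans the
  lasso–ridge continuum; per $\alpha$, 100 log-spaced $\lambda$ values
  from $\lambda_{\max} = \max_j |\langle x_j^{std}, y-\bar y\rangle| /
  (n\,\max(\alpha, 0.001))$ down to $10^{-4}\lambda_{\max}$. At
  $\lambda \ge \lambda_{\max}$ (for $\alpha > 0$) every coefficient is
  exactly zero, so the path starts at the null model.
* **Cross-validation.** 10-fold; fold membership is a seed-keyed shuffle
  of `1:n` split round-robin, hence a pure function of `(seed, n)` — no
  stratification, as the target is continuous. Selection is by mean
  squared CV error; ties break toward larger $\lambda$, then larger
  $\alpha$, preferring the sparser model.
* **Standardization.** Features are standardized internally to zero mean
  and unit population variance; binary mutation features are standardized
  identically (no special casing), which makes $\lambda$ comparable
  across features. Coefficients are back-transformed to the original
  feature scale before locking and serialization.
* **Solver.** Coordinate descent is delegated to glmnet. glmnet's
  gaussian path internally rescales the response by its population
  standard deviation, which leaves the L1 penalty at the requested
  strength but inflates the ridge penalty by $1/\mathrm{sd}(y)$; the
  package compensates exactly by requesting
  $(\alpha/k,\; \lambda k)$ with $k = \alpha + (1-\alpha)\,\mathrm{sd}(y)$,
  so the optimum returned is the objective stated above. The tests verify
  this against the ridge closed form $(X^TX/n + \lambda I)^{-1}X^Ty/n$ at
  $\alpha = 0$ (tolerance $10^{-6}$) and against the single-predictor
  soft-threshold $\mathrm{sign}(\rho)\max(|\rho| - \lambda, 0)$ at
  $\alpha = 1$ (tolerance $10^{-8}$). Because glmnet requires at least
  two columns, single-feature problems are padded with a zero column
  whose coefficient is provably zero. Convergence threshold is
  $10^{-12}$.
* **Degenerate inputs.** A constant response yields the intercept-only
  model with a warning (penalized optimum regardless of $\lambda$);
  fewer than `2 * n_folds` usable samples is an error; constant features
  receive coefficient zero. Drugs failing preconditions in
  `fit_all_drugs()` are reported in a warning and in
  `attr(, "failures")`, never silently dropped.

A fitted model is **locked**: `predict_scores()` and `write_model_set()`
refuse unlocked models, and applying a locked model to a new cohort uses
name-based feature alignment so column order is irrelevant. Features
absent from the cohort contribute 0 under the default `zero_fill` policy
— the neutral value under both encodings (cohort median for centered
expression, wild-type for mutation) — with the per-drug filled count
reported; `missing_policy = "error"` lists the absent features instead.
Model sets serialize to a long-format TSV (drug, term, coefficient; the
intercept as `"(Intercept)"`) with a header block carrying the shared
feature namespace and per-drug $\alpha$, $\lambda$ and seed at 17
significant digits, making the write/read round trip exact; exact-zero
coefficients are omitted from the file and restored from the namespace.

## Validation statistics

* **External correlation.** Per drug, Pearson correlation between the
  predicted score and −AUC (higher AUC accompanies lower IC50, so a
  well-calibrated score correlates positively with −AUC). The two-sided
  p-value uses $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df and the 95% CI
  the Fisher z transform; drugs with fewer than 3 pairs are skipped with
  a warning; BH adjustment is applied across all tested drugs.
* **Group comparisons.** Welch's unequal-variance t-test (the default
  unpaired test in standard statistical environments), two-sided. The
  zero-variance equal-mean edge returns $t = 0$, $p = 1$. Direction is
  `marker_more_sensitive` when the marker-positive group has the lower
  mean score.
* **Interaction test.** Maximum-likelihood logistic regression
  `response ~ treatment + score + treatment:score` via IRLS (tolerance
  $10^{-8}$, max 100 iterations), Wald p-values per term (a
  likelihood-ratio p is available via `lr_test = TRUE`). Separation is
  detected by re-expressing the coefficients on the standardized-score
  scale (an exact reparametrization) and failing when any magnitude
  exceeds 15, or when all fitted probabilities collapse to 0/1; both are
  diagnostic errors rather than silent estimates. Sample sizes below 20
  warn. A significant interaction is what distinguishes a *predictive*
  biomarker (modifying the effect of a specific treatment) from a
  prognostic one.

## Biomarker predicates

Indications are loaded from a YAML config (one entry per indication)
rather than hard-coded; the shipped
`extdata/synthetic_biomarker_config.yaml` is a synthetic example keyed to
the generator's panel. Rules: mutated gene set, wild-type gene set (the
exact complement), specific protein changes (`V600E`-style, `p.` prefix
stripped on both sides), expression strictly above a within-cohort
quantile (ties fall in the negative group — relevant only for discrete
data), and boolean annotation flags (receptor status, promoter
methylation, fusion calls consumed as flags; fusion *calling* is out of
scope). Verdicts are a pure function of (observed direction, p,
thresholds): `concordant` / `discordant` below the significance
threshold (default 0.05) depending on direction, `borderline` for
matching direction with $0.05 \le p < 0.10$, else `non_significant`.
The borderline band is motivated by near-threshold indication results
being worth flagging rather than discarding.

## Discovery scan

Per (drug, gene) pair: OLS of the drug's scores on mutation status plus
a tumor-site factor (one-hot against the lexicographically first level;
the mutation t statistic is invariant to the reference choice, which the
tests verify). Genes enter at pan-cancer mutation frequency
$\ge$ `min_mutation_freq` (default 0.05; implemented inclusively, which
differs from a strict ">5%" reading only for genes at exactly the
threshold); drugs may be restricted to a named allowlist. Ranking is by
signed t ascending — most negative, i.e. most sensitizing, first — with
an `abs_t` option for two-sided discovery; ties break lexicographically
by (drug, gene) for reproducibility. The top selection takes
$\lceil \text{fraction} \cdot K \rceil$ pairs, guaranteeing non-empty
output for small $K$. No multiple-testing adjustment enters the ranking;
BH-adjusted p-values are reported alongside for context. Rank-deficient
pairs (mutation aliased with a site) are skipped with the reason
recorded, not fabricated. The per-pair simple-model choice (one OLS per
pair rather than a joint multi-mutation model) keeps each t statistic
interpretable as that mutation's marginal, site-adjusted association.

## Synthetic cohorts: what they emulate

The generators encode the statistical structure the pipeline assumes and
are the package's study conditions; their defaults are fixed, not tuning
knobs.

* **Training cohort** (default n = 500 samples, 60 panel genes, 10
  drugs): per-gene Bernoulli mutations (rates drawn once per config on
  \[0.1, 0.4\]), log-normal FPKM (log2 means on \[2, 8\], SDs on
  \[0.5, 1.5\]), and per drug a sparse linear truth — 5 nonzero
  coefficients with magnitudes on \[0.5, 1.5\] and random signs over the
  feature space *as the preprocessing module computes it* — plus Gaussian
  noise ($\sigma = 0.5$), then per-drug Z-scoring. Decoy silent and
  intronic calls are always emitted so the consequence filter is
  exercised by default. The stored truth includes the Z-scoring center
  and scale, so planted coefficients are comparable to fitted ones as
  $\beta / \text{scale}$.
* **External cohort**: same truth, new samples, per-gene shifts added to
  the expression means (the platform effect median centering must
  remove), response as AUC = a monotone decreasing transform of the true
  predictor plus noise, clipped to \[0, 1\].
* **Clinical cohort**: Bernoulli treatment, binary response from
  `logit⁻¹(b0 + bT·T + bs·s + bts·T·s)`, percent response emitted
  consistently with the binary endpoint under the 50% threshold
  convention (responders 51–100%).

They do **not** emulate copy-number, fusions, methylation, tumor-type
specific expression programs, gene–gene correlation structure, or
missingness patterns of real cohorts — so passing tests demonstrate the
pipeline's statistical machinery (recovery, calibration, transfer under
location shifts), not performance on real tumors.

## Problem sizes and runtime choices

The test suite and acceptance script use sizes chosen to make the
statistical properties sharp while keeping a full run inexpensive:
closed-form solver checks at n = 20; planted-recovery at n = 500 with
60 features; cross-cohort validation with 10 drugs trained on 500
samples and validated on 300; interaction calibration over 1000 null
replicates at n = 200 and recovery over 200 replicates at n = 400; the
discovery scan over 100 planted seeds at n = 300 and 60 null seeds.

## Known limitations

* Coefficient-level agreement with any previously published signature
  table is not expected: the tuning grid and CV metric are this
  package's documented choices, and regularized solutions are sensitive
  to both.
* The AUC dialect must be declared (`auc_percent`) when response tables
  arrive on a 0–100 scale; the \[0, 1\] scale is the default contract.
* The interaction model contains exactly the three terms named above;
  additional clinical covariates are out of scope.
* Duplicate gene symbols in expression input are rejected rather than
  aggregated — resolving multi-mapped symbols is upstream work.
* Confidence intervals for correlations are reported as (low, high);
  published tables sometimes print the bracket in the opposite order.
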