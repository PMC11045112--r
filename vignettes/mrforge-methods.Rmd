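---
title: "Two-sample Mendelian randomization with mrforge: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrforge)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (say, circulating
alanine aminotransferase) on an outcome (say, essential hypertension)
from GWAS summary statistics alone. A variant is a valid instrument if
it (1) associates with the exposure, (2) is independent of confounders,
and (3) affects the outcome only through the exposure. Assumption 2 is
untestable from summary data and is documented rather than coded;
assumptions 1 and 3 are what the machinery in this package selects for
and probes.

The two-sample design takes the per-SNP exposure associations
$(\hat\beta_{Xj}, se_{Xj})$ and outcome associations
$(\hat\beta_{Yj}, se_{Yj})$ from *different* GWAS cohorts, which avoids
sample-overlap bias and is the setting every estimator here assumes.

## Instrument selection

`selectInstruments()` runs a fixed stage order; reordering changes
results, so the order is part of the contract and each stage's SNP
counts are logged:

1. **Genome-wide significance**: keep SNPs with $p < 5\times10^{-8}$
   (strict; exactly $5\times10^{-8}$ is not significant).
2. **LD clumping**: sort ascending by p (ties broken by SNP id so the
   result is row-order invariant), accept a SNP iff its $r^2$ with every
   accepted SNP is $< 0.01$. The LD table is user input — the package
   computes no LD — and a pair absent from it counts as $r^2 = 0$,
   which is conservative for clumping (keeps SNPs) and strict for proxy
   search (no proxy without evidence). No positional window is applied;
   users who want one encode it in the LD table.
3. **Proxy substitution**: an instrument missing from the outcome data
   is replaced by the outcome-present SNP with the highest $r^2 > 0.8$
   (ties: smaller p, then lexicographic id). The proxy's *own* alleles
   and effects are used downstream — no allele-phase imputation, since
   the original SNP has no outcome record by definition.
4. **MAF/palindrome filter**: drop SNPs with minor allele frequency
   strictly below 0.01 (exactly 0.01 is kept) and all A/T or C/G
   (strand-ambiguous) pairs, regardless of frequency. Missing EAF is an
   error here, never silently imputed.
5. **Weak instruments**: per-SNP $r^2 = 2\,maf(1-maf)\beta^2$ (valid
   for standardized traits) and $F = (n-2)\,r^2/(1-r^2)$; SNPs with
   $F < 10$ are excluded ($F = 10$ exactly is retained). The per-SNP
   univariable form of $F$ is used because exclusion is applied per
   instrument. At biobank scale this filter is non-binding.

## Harmonization

`harmonize()` aligns outcome effects to the exposure's effect allele:
direct match kept; swapped alleles negate $\beta_Y$ and reflect EAF;
strand complementing is attempted only when direct and swapped matching
both fail (avoiding silent double flips); anything else is dropped with
a reason code. Palindromic SNPs were removed upstream; one that slips
through is dropped, never frequency-resolved. An EAF disagreement above
0.2 after alignment warns (possible strand/build mismatch) but does not
remove, since no such filter is part of the analysis plan. Harmonization
is idempotent, and negating all outcome effects while swapping outcome
allele labels leaves every downstream estimate unchanged.

## Estimators

All p-values and confidence intervals use the normal reference
distribution, the summary-data MR convention. For binary outcomes
effects are log odds ratios and estimates carry
$OR = e^{\hat\theta}$ with exponentiated CI endpoints.

* **Wald ratio** (one SNP): $\hat\theta = \hat\beta_Y/\hat\beta_X$ with
  first-order delta SE $se_Y/|\hat\beta_X|$. Ignoring the exposure-side
  noise is standard once $F \ge 10$; it is the reason Cochran's Q runs
  slightly above its degrees of freedom on strong-effect data (the
  residual truly has variance $se_Y^2 + \theta^2 se_X^2$).
* **IVW**: origin-constrained weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ with weights $1/se_Y^2$,
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$. The fixed-effect SE is
  $(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$; the multiplicative
  random-effects (MRE) model multiplies it by $\sqrt{Q/(J-1)}$,
  **floored at 1** so overdispersion can widen but never narrow the
  interval. The floor is a conservative convention we adopt explicitly;
  it guarantees MRE p-values are never smaller than fixed-effect ones.
* **MR-Egger**: weighted regression with intercept after re-signing
  each SNP so $\hat\beta_X \ge 0$ — required for the intercept's
  identifiability; the fit is invariant to per-SNP sign conventions.
  The intercept estimates the average directional pleiotropic effect
  and its p-value is the pleiotropy test. Both SEs are scaled by
  $\max(1, \sqrt{Q'/(J-2)})$; the unscaled values are recoverable via
  the `seMultiplier` attribute, so both conventions are reportable.
* **Weighted median**: per-SNP ratios ordered under weights
  $w_j = (\hat\beta_{Xj}/se_{Yj})^2$ (the first-order inverse variance
  of the ratio); the estimate interpolates the ratio at standardized
  cumulative weight 0.5, and is consistent when valid instruments carry
  at least half the weight. The SE comes from a parametric bootstrap
  (resampling $\hat\beta_X, \hat\beta_Y$ from their sampling normals)
  with an explicit seed; rows are sorted by SNP id first so the
  bootstrap is row-order invariant.
* **Multivariable IVW**: weighted multiple regression of
  $\hat\beta_Y$ on the $K$ exposure-beta columns, no intercept, SEs
  from the weighted normal equations inflated by
  $\max(1,\sqrt{Q/(J-K)})$. Rank deficiency raises a collinearity error
  naming the offending exposures. Instrument selection for the
  multivariable pipeline uses union-then-clump (every SNP significant
  for at least one exposure, clumped on its best p across exposures);
  per-exposure intersection is a possible alternative we did not adopt
  because it discards instruments the joint model can use.

## Sensitivity and validity machinery

* **Cochran's Q** at the IVW estimate, $\chi^2_{J-1}$ reference. When
  its p-value falls below 0.05 the pipeline reports the MRE model as
  primary — the threshold is a choice (configurable via `hetPval`),
  since the switch rule itself names no level.
* **Leave-one-out**, flagging any SNP whose removal changes the
  estimate's sign or moves its p across 0.05.
* **MR-PRESSO**: observed
  $RSS = \sum_j w_j(\hat\beta_{Yj} - \hat\theta_{-j}\hat\beta_{Xj})^2$
  with leave-one-out IVW estimates $\hat\theta_{-j}$; the null
  distribution comes from parametric simulation under the fitted model.
  Per-SNP terms give the outlier test, flagged at Bonferroni
  $0.05/J$ (the per-SNP level is our choice). With outliers removed,
  the distortion statistic
  $100(\hat\theta_{raw}-\hat\theta_{corr})/|\hat\theta_{corr}|$ (the
  absolute-value denominator keeps the percentage interpretable for
  negative estimates) is referred to re-estimates with random
  same-sized subsets removed. Empirical p-values use the add-one
  convention $(k+1)/(n_{sim}+1)$ so they are never exactly zero, and
  the simulation is seeded and row-order invariant.
* **Steiger directionality**: total instrument $r^2$ on exposure vs
  outcome, compared through Fisher's z. For binary outcomes the
  observed-scale $r^2$, $2\,maf(1-maf)\beta^2\,cf(1-cf)$, is used —
  simpler than a liability-scale conversion, and flagged so users know
  the convention. A tie fails the direction check. Missing EAF or n is
  a hard error because failed directions must be excluded, not skipped.
* **Power**: non-centrality approximation $NCP = n\,r^2\,\beta^2$
  (times $cf(1-cf)$ for binary outcomes),
  $power = 1-\Phi(z_{1-\alpha/2}-\sqrt{NCP}) +
  \Phi(-z_{1-\alpha/2}-\sqrt{NCP})$, verified against a Monte-Carlo
  Wald test rather than against any web calculator. The assumed effect
  size is an explicit input — it is never inferred from the data being
  tested.
* **FDR**: Benjamini–Hochberg over the primary p-value of every
  reported result in one run. The family definition is configurable
  (`fdrScope` label) and logged because reasonable families differ
  (per-direction, per-trait-group, global); BH rather than BY is the
  default, BY being stricter than the analysis plan requires.

### Verdicts

`runPair()` labels each direction `reported`, `excluded_steiger`
(instruments explain more outcome than exposure variance — likely
reverse causation), `excluded_pleiotropy` (the Egger intercept remains
significant at `alpha` *after* MR-PRESSO outlier removal, i.e.
pleiotropy that removal could not eliminate), or `not_estimable` (no
eligible instruments). Steiger exclusion takes precedence. Note the
pleiotropy gate falsely excludes about 5% of truly clean pairs — the
price of any 0.05-level gate — which is why simulation summaries in our
tests condition on `reported`.

## The synthetic generator

No public consortium download is small enough to test against, so the
package carries a generator whose defaults *are* the study conditions
used throughout the test suite, chosen once:

| parameter | default | why |
|---|---|---|
| `nSnps` | 50 | typical post-clumping instrument count |
| `nExposure`, `nOutcome` | 200,000 | biobank-scale GWAS |
| `exposureH2` | 0.10 | mid-range of reported instrument $r^2$ totals for liver-enzyme-like traits |
| `pleiotropySd` | 0.05 | direct effects comparable to typical SNP effects, so invalid instruments matter but do not dominate |
| `mafRange` | (0.05, 0.5) | common variants, matching post-QC GWAS panels |
| `ldBlockSize` | 1 | instruments post-clumping are independent |

Per-SNP true exposure effects $\gamma_j$ are rescaled so
$\sum_j 2p_j(1-p_j)\gamma_j^2$ equals `exposureH2` exactly. Effect
alleles are reported as the exposure-increasing allele (the per-allele
sign being arbitrary labelling), so $\gamma_j \ge 0$; this makes
half-normal "directional" direct effects genuinely directional relative
to the instruments, which is what makes the Egger intercept test and
the IVW-vs-weighted-median bias ordering meaningful. Estimated effects
are truths plus $N(0, se^2)$ noise with the standardized-trait SE
$1/\sqrt{2p(1-p)n}$; binary outcomes are simulated directly on the
log-odds scale with the $1/\sqrt{cf(1-cf)}$ variance inflation — no
liability threshold, because the estimators only ever see $(\beta, se)$.
LD affects the LD table only (block-diagonal AR(1)), not the sampled
estimates, matching the post-clumping independence the $r^2<0.01$
filter enforces.

What the generator does **not** emulate — and hence what passing tests
cannot vouch for on real data: population stratification, sample
overlap between the two GWAS, assortative mating, winner's-curse-free
discovery (selection on significance does induce mild winner's curse in
pipeline runs, visible as slight attenuation), LD-correlated effect
estimates, and allele-frequency mismatch between cohorts.

## Problem sizes and numerical conventions

The simulation tests use 200–1000 replicates of 50-SNP studies —
enough that Monte-Carlo error (three binomial SEs around nominal rates)
separates pass from fail, small enough to run routinely. Exact
identities are asserted at $10^{-12}$ or machine precision; oracle
equivalence (explicit normal equations, literal greedy-rule replay,
exhaustive allele enumeration) at $10^{-10}$ relative error. All
stochastic operations take explicit integer seeds, restore the caller's
RNG state, and produce byte-identical reports on identical inputs.

Boundary conventions, collected in one place: significance is strict
(`<`), clumping is strict (`<`), proxy LD is strict (`>`), MAF removal
is strict (`<`, so 0.01 is kept), F exclusion is strict (`<`, so 10 is
retained), Steiger ties fail. Every one of these is tested on both
sides of its boundary.

## Known limitations

Wald-ratio SEs ignore exposure-side uncertainty (first-order delta);
Cochran's Q inherits the same approximation. The MRE floor at 1 makes
random-effects intervals conservative, never anticonservative. Binary
Steiger $r^2$ is observed-scale, not liability-scale. No correlated-
instrument (generalized) IVW, mode-based estimators, MR-RAPS, or I² —
deliberately outside scope. Real-data headline estimates from the
consortium GWAS this design mirrors require multi-gigabyte inputs and
are not reproducible here; everything the package claims is claimed via
parameter recovery on its own generator.
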