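---
title: "Partitioning maternal variance with pedigreed animal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal variance with pedigreed animal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matherit)
```

## The model and its assumptions

For a maternally influenced trait recorded once per animal, `matherit`
fits three nested linear mixed models. All three share fixed effects
(here generation and hatch, reference-coded with an explicit intercept —
any full-rank coding gives identical variance components) and an
independent residual. They differ in how much of the dam's contribution
is modelled:

* **M1**: `y = Xb + Zu + e`, with `var(u) = A σ²a`. Everything the dam
  does beyond transmitting genes is absorbed by `e` (and, upward-biased,
  by `σ²a`).
* **M2**: adds the maternal genetic effect `d` of each record's dam,
  `var(u, d) = G0 ⊗ A` with
  `G0 = [[σ²a, σam], [σam, σ²m]]`. The direct–maternal covariance `σam`
  is always estimated, never pinned at zero: antagonistic (negative)
  covariances are common and forcing them to zero redistributes variance
  incorrectly.
* **M3**: further adds a permanent environmental effect of the dam,
  `var(pe) = I σ²pe`, one level per dam with progeny records.

`A` is the numerator relationship matrix. It is built from the renumbered
pedigree by the tabular method; its sparse inverse is assembled directly
by Henderson's rules with Mendelian-sampling variances adjusted for
parental inbreeding (Meuwissen–Luo coefficients). Unknown parents are
treated as unrelated, non-inbred base animals; no phantom-parent grouping
is attempted because the data this package targets carry no grouping
structure. A flag (`use_inbreeding = FALSE`) reproduces the
no-inbreeding simplification for cross-checks against software that
ignores it; inbreeding is accounted for by default since closed,
full-sib-mated lines are precisely where it accumulates. The dense form
of `A` is refused above a configurable cap (default 5000 animals); the
sampler itself only ever touches the sparse inverse.

Records whose dam is unknown have no defined maternal link: they are kept
under M1 but excluded (with a logged count) under M2/M3. Because this can
change the record set, `select_best()` refuses to compare DIC values
across fits with different record counts.

## Ratios and the phenotypic-variance convention

Per retained draw,

```
σ²p    = σ²a + σ²m + σam + σ²pe + σ²e
h²_add = σ²a / σ²p,  h²_mat = σ²m / σ²p,  c²_mpe = σ²pe / σ²p
```

The direct–maternal covariance **is included** in `σ²p`. Back-calculating
published variance-component tables for this model class reproduces their
printed heritabilities only under this convention (e.g. components
27.26, 5.87, −9.52, 1.71, 60.11 give 27.26/85.43 = 0.32); the exclusive
convention is available behind `include_cov = FALSE`. Ratios are computed
draw by draw and then summarised; the ratio of posterior means is also
attached for table cross-checks (the two agree to about two decimals on
well-mixed chains). Draws with non-positive `σ²p` (possible in principle
with a large negative covariance) are excluded from ratio summaries and
counted.

## The sampler

Each Gibbs round sweeps the mixed-model unknowns one at a time
(single-site) from their normal full conditionals using the sparse
coefficient structure `W'W + σ²e Λ`, where `Λ` carries `A⁻¹ ⊗ G0⁻¹` for
`(u, d)` and `I/σ²pe` for `pe`; variances then update from their
conjugate full conditionals — scaled inverse chi-square for scalar
components (`u'A⁻¹u` with `q` degrees of freedom, `pe'pe` with the dam
count, `e'e` with the record count) and a 2×2 inverse-Wishart for `G0`
with scale `[[u'A⁻¹u, u'A⁻¹d], [·, d'A⁻¹d]]` plus the prior scale.
Single-site sweeps are memory-light and adequate at the population sizes
this package targets (a few thousand animals); block updates are out of
scope.

Numerical choices:

* **Reproducibility.** Every random number — including the
  inverse-Wishart draws, generated by Bartlett decomposition — comes from
  R's own RNG, so `set.seed()` makes whole chains bitwise reproducible.
  Randomness is consumed in a fixed order per round: location effects in
  column order, then the genetic (co)variance, then `σ²pe`, then `σ²e`,
  then (bivariate only) the residual matrix.
* **Starting values.** Variances start at the sample phenotypic variance
  split evenly across fitted components; `σam` starts at 0; location
  effects at 0.
* **Degenerate draws.** If an inverse-Wishart scale matrix is numerically
  indefinite the sampler retries with a small ridge a bounded number of
  times, then aborts; a diverging residual variance (beyond 10¹² times
  its start) aborts with the iteration index.
* **HPDI.** The 95% highest-posterior-density interval is the shortest
  contiguous interval over the sorted draws containing `ceil(0.95 N)` of
  them, ties broken toward the lower start index. It is never wider than
  the equal-tailed interval. `coda::HPDinterval` (which can differ by one
  order statistic) is used as an independent cross-check in the tests.
* **Diagnostics.** Geweke z compares the first 10% against the last 50%
  of the chain with spectral-density variance estimates; effective sample
  size comes from the integrated autocorrelation time. Both are computed
  by `coda`, the standard implementation.

**Priors.** The default is minimally informative and conjugate: degrees
of freedom `dimension + 1` (2 for scalars, 3 for the 2×2 `G0`) and scale
set so each component's prior guess is half the phenotypic variance split
evenly across the fitted components. This keeps every posterior proper
while being swamped by a few hundred records. A `flat_priors = TRUE`
switch zeroes both df and scale. One visible consequence of the proper
default: the diagonal inverse-Wishart scale keeps posterior correlations
off the ±1 boundary, so degenerate checks (a trait correlated with
itself) are run under a near-flat prior where the posterior mean exceeds
0.999.

**Bivariate runs** fit a two-trait direct-additive model with 2×2 genetic
and residual covariance matrices, both inverse-Wishart. Animals recorded
for one trait only contribute through the pedigree; their missing record
is imputed each round from the conditional residual distribution (data
augmentation), and rows missing both traits are dropped. The trait pair
is canonicalised internally (sorted by name) and mapped back on output,
which makes "exchange the trait labels" an exact transpose of the draws
under the same seed — a symmetry a literal per-label sampling order could
not deliver.

## Model choice by DIC

The deviance recorded per retained draw is the conditional one,
`−2 log N(y | Xb + Zu + Wd + Mpe, I σ²e)`, i.e. conditioned on the
sampled random effects — the form a residual-based sampler can evaluate
at every draw. `DIC = 2 D̄ − D(θ̄)` with the plug-in at the posterior
means of the location effects and of `σ²e` (means, not medians). The
marginal-deviance variant would penalise random effects differently and
give different absolute values; since the variant used for published
absolute DICs in this model class is typically unstated, absolute values
are not comparison targets here — only the ranking, which is what model
selection consumes. Ties closer than 0.5 DIC go to the simpler model and
are flagged. A negative effective-parameter count is reported with a
warning rather than an error: it is a recognised Monte-Carlo artefact on
short chains.

## What the synthetic generator does and does not emulate

`simulate_population()` reproduces the statistical design the models
assume: a base population of unrelated founders, hierarchical sire–dam
matings (default 50 sires × 250 dams at 1:5), discrete generations
(default 3) whose parents are drawn from the previous generation,
hatches (default 5) assigned uniformly within generation, and phenotypes
built effect by effect — founder `(u, d)` from `N(0, G0)`, offspring from
the mid-parent average plus a Mendelian-sampling deviate shrunk by
parental inbreeding `0.5 (1 − (F_s + F_d)/2) G0`, dam-level `pe`, fixed
generation and hatch steps, and residual noise. Fixed-effect steps
default to evenly spaced values spanning ±0.5 phenotypic SD so that a
model ignoring them is detectably wrong. The truth manifest stores every
sampled effect so recovery error can be computed without re-simulation.
`apply_missingness()` thins records per trait and can blank whole
generations, mimicking late-cycle traits recorded in fewer generations.

Deliberately not emulated: selection of parents (real closed lines are
often under index selection, which erodes variance across generations and
would bias recovery tests; parents are drawn at random), sexed offspring
(all progeny are treated as recordable females), repeated records,
overlapping generations, and dominance or genotype-by-environment
structure. Passing tests on these simulations therefore demonstrates that
the estimation machinery is correct under the model's own assumptions —
not that any real population satisfies those assumptions.

## Validation design and scales

The test suite checks, at sizes chosen to keep a full run around a
minute: exact arithmetic against published variance-component tables;
`A⁻¹A = I` to 1e-8 on dozens of random pedigrees (against dense
inversion); bitwise chain reproducibility; HPDI coverage of the
generating values of all components of M1–M3 (8 replicates per model,
12 sires × 60 dams × 3 generations, ~360 records, 4000-round chains)
pooled at the 85% level; DIC ranking of a maternal model above M1 in at
least 80% of replicates under strong maternal signal (`h²_mat = 0.3`);
bivariate recovery of `r_g = 0.8`, `r_e = 0.3` within ±0.1 at ~1050
records per trait under a study-like 1:5 design; and diagnostic
calibration on chains of known dependence (i.i.d. and AR(1) with
coefficient 0.9). Production analyses should use the long-chain defaults
(200 000 rounds, 2000 burn-in, thinning 50); the shortened chains in the
tests are enough for the interval-coverage properties being asserted
because the posteriors at those data sizes are wide.

One honest caveat surfaced by validation: with weakly informative family
structures (few progeny per dam, shallow pedigrees) the posterior mean of
`r_g` is noticeably attenuated toward zero even though the sampler is
exact — verified by matching an independent blocked reference sampler to
three decimals. That is a property of the posterior, not a bug; designs
with larger families concentrate the posterior near the generating value.

## Known limitations

Univariate chains store only variance components and deviance, not
location-effect traces. The bivariate model fits direct additive effects
only (no maternal terms), matching its role of estimating genetic
correlations. DIC is the conditional variant; WAIC and cross-validated
criteria are out of scope. Dense `A` is capped; genomic (marker-based)
relationship matrices and single-step methods are out of scope.
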