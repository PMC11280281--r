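# matherit

Bayesian variance partitioning for maternally influenced traits in
pedigreed populations.

In species where the dam shapes her offspring's phenotype beyond the genes
she transmits — egg size and early growth in poultry, birth weight in
mammals — a trait's variance is not just "genetic plus residual". The dam
contributes a heritable *maternal genetic* effect `d` (which may covary,
often negatively, with the animal's own breeding value `u`) and a
non-genetic *maternal permanent environmental* effect `pe` shared by all
her progeny. Ignoring these components inflates direct heritability
estimates and misdirects selection. `matherit` is for quantitative
geneticists and breeders who want to partition that variance properly from
pedigree and phenotype data.

## The models

Three nested animal models are fitted per trait:

| Model | Equation | Random terms |
|-------|----------|--------------|
| M1 | `y = Xb + Zu + e` | direct additive |
| M2 | `y = Xb + Zu + Wd + e` | + maternal genetic, with cov(u, d) |
| M3 | `y = Xb + Zu + Wd + Mpe + e` | + maternal permanent environment |

with `var(u, d) = G0 ⊗ A` (A the numerator relationship matrix built from
the pedigree with inbreeding), `var(pe) = I σ²pe`, `var(e) = I σ²e`, and
`G0 = [[σ²a, σam], [σam, σ²m]]`. Posteriors are drawn by a compiled
single-site Gibbs sampler (scaled-inverse-chi-square and inverse-Wishart
full conditionals for the variances), models are compared by DIC, and
results are reported as posterior means, SDs and 95% highest posterior
density intervals of the variance components and the derived ratios

```
σ²p = σ²a + σ²m + σam + σ²pe + σ²e
h²_add = σ²a/σ²p    h²_mat = σ²m/σ²p    c²_mpe = σ²pe/σ²p
```

Bivariate runs estimate posterior additive-genetic and environmental
correlations between trait pairs. A synthetic-population generator
(hierarchical sire–dam matings, discrete generations, hatches,
user-specified true components including negative direct–maternal
covariance) stands in for confidential flock data and backs the test
suite.

## Worked example

Simulate a flock (12 sires × 60 dams mated 1:5, 3 generations, true
components σ²a = 40, σ²m = 20, σam = −10, σ²pe = 10, σ²e = 60), fit all
three models, compare by DIC and summarise the best:

```r
library(matherit)

cfg <- sim_config(n_sires = 12, n_dams = 60, n_generations = 3,
                  progeny_per_dam = 2, sigma2_a = 40, sigma2_m = 20,
                  sigma_am = -10, sigma2_pe = 10, sigma2_e = 60, seed = 2024)
sim <- simulate_population(cfg)

fits <- lapply(c("M1", "M2", "M3"), function(m)
  run_chain(sim$records, sim$pedigree, m,
            n_iter = 20000, burn_in = 2000, thin = 10, seed = 7))

(cmp <- dplyr::bind_rows(lapply(fits, dic)))
#> # A tibble: 3 × 7
#>   model trait n_records  dbar d_at_mean    pd   dic
#> 1 M1    trait       360 2599.     2515.  84.5 2684.
#> 2 M2    trait       360 2537.     2421. 116.  2652.
#> 3 M3    trait       360 2533.     2412. 121.  2654.
select_best(cmp)
#> [1] "M2"

tidy(fits[[3]])
#> # A tibble: 9 × 5
#>   parameter      mean      sd hpdi_low hpdi_high
#> 1 sigma2_a     21.4   12.8      4.83      46.8
#> 2 sigma2_m     17.6    8.86     3.80      34.9
#> 3 sigma_am     -3.70   8.53   -21.9       8.72
#> 4 sigma2_pe    13.4    6.31     3.01      25.5
#> 5 sigma2_e     66.9    9.72    47.5      86.0
#> 6 sigma2_p    116.     9.47    98.0     135.
#> 7 h2_additive   0.184  0.105    0.0435    0.400
#> 8 h2_maternal   0.152  0.0728   0.0392    0.298
#> 9 c2_mpe        0.116  0.0519   0.0273    0.216
```

Both maternal models beat M1 by ~30 DIC points, and every true component
falls inside its 95% HPDI — at this deliberately small scale the
posteriors are wide, which is exactly the spread the HPDIs quantify.
`autoplot(fits[[3]])` draws the traces; `chain_diagnostics()` reports
effective sample sizes, Geweke z-scores and lag autocorrelations;
`run_bivariate_chain()` gives genetic/environmental correlations for trait
pairs; `cmd_simulate()` / `cmd_fit()` / `cmd_correlate()` drive the same
pipeline from yaml configs and CSV files (see `inst/cli/matherit.R` for a
shell entry point).

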