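# fidherit

Quantitative genetics of the fear of humans. `fidherit` estimates the
heritability of flight initiation distance (FID) — the distance at which a
bird flees an approaching human — in pedigreed wild populations sampled
across urban and rural habitats, the way it is done for long-term studies of
territorial birds (e.g. burrowing owls) where both parent–offspring
regressions and a pedigree-based animal model are feasible.

## What it computes

For log-transformed FID (natural log of meters):

- **Parent–offspring regression heritability.** With full-sib broods
  averaged to avoid pseudo-replication, the midparent–midoffspring slope
  estimates h² directly; single-parent regressions estimate h² as twice the
  slope, corrected for phenotypic assortative mating by

  h² = 2b / (1 + r),

  where r is the phenotypic correlation between mates (assortative mating
  inflates single-parent regressions by (1 + r) but leaves the midparent
  regression unbiased).

- **z-score comparison of estimates**: z = (xᵢ − xⱼ)/√(SEᵢ² + SEⱼ²) with
  two-sided normal p-values, for comparing heritabilities between habitats
  or methods.

- **A Bayesian animal model** y = Xβ + Za + e with a ~ N(0, A σ²_A),
  e ~ N(0, I σ²_R), fitted by a Gibbs sampler written for this package:
  fixed effects (habitat, sex) from their Gaussian full conditional, all
  breeding values jointly through a sparse Cholesky of the mixed-model
  equations built on the pedigree's A⁻¹ (Henderson's rules with inbreeding),
  and scaled inverse-chi-square draws for the variance components
  (inverse-Wishart prior V = 1, ν = 0.02 by default). Heritability is
  reported per draw as h² = σ²_A/(σ²_A + σ²_R) with posterior mean, mode and
  95% highest-posterior-density interval.

- **A synthetic-study generator** that emulates the sampling design such
  analyses face: a ~1,200-individual three-generation pedigree split across
  urban and rural habitats, log-FID with h² = 0.43 on unit phenotypic
  variance, urban effect −0.42, female effect +0.06, phenotypic mate
  correlation 0.78, and natal-habitat philopatry. Every stage of the package
  is tested end-to-end against this generator's known truth.

## Worked example

```r
library(fidherit)

study <- simulate_fid_study(sim_config(seed = 42))
study
#> <fid_study> 1157 individuals (655 urban / 502 rural), 3 generations, true h2 = 0.43

po_heritability(study$pedigree, study$phenotypes)
#> # A tibble: 9 × 7
#>   method    habitat    h2     se     n        p correction_r
#>   <chr>     <chr>   <dbl>  <dbl> <int>    <dbl>        <dbl>
#> 1 midparent rural   0.457 0.0635   139 3.79e-11       NA
#> 2 midparent urban   0.388 0.0694   162 9.67e- 8       NA
#> 3 midparent all     0.456 0.0467   301 9.84e-20       NA
#> 4 father    rural   0.520 0.0781   139 5.99e-10        0.755
#> 5 father    urban   0.374 0.0792   162 4.92e- 6        0.766
#> 6 father    all     0.480 0.0554   301 2.65e-16        0.769
#> 7 mother    rural   0.408 0.0624   139 1.13e- 9        0.755
#> 8 mother    urban   0.398 0.0706   162 7.78e- 8        0.766
#> 9 mother    all     0.433 0.0465   301 2.54e-18        0.769

fit <- fit_animal_model(study$phenotypes, study$pedigree,
                        desk_schedule(seed = 7))
glance(fit)
#> # A tibble: 1 × 8
#>   h2_mean h2_mode h2_conf_low h2_conf_high ess_h2 n_draws n_obs n_pedigree
#>     <dbl>   <dbl>       <dbl>        <dbl>  <dbl>   <int> <int>      <int>
#> 1   0.395   0.383       0.320        0.472   895.     900  1157       1157
```

The regression table reads: with ~300 broods the midparent slope recovers
the generating h² = 0.43 to within sampling error (0.456 ± 0.047); the
mother–offspring estimate, after division by (1 + r) with the mate
correlation estimated from the data (r ≈ 0.77), lands at 0.433. The animal
model partitions the same phenotypes against the full pedigree: posterior
mean h² 0.395 with 95% HPD [0.32, 0.47] covering the truth, and the fixed
effects recover the urban (−0.42) and sex (+0.06) contrasts (see
`tidy(fit)`).

Published comparison tables can be checked directly from printed estimates:

```r
rural <- tibble::tibble(method = "midparent", habitat = "rural", h2 = 0.69, se = 0.22)
urban <- tibble::tibble(method = "midparent", habitat = "urban", h2 = 0.39, se = 0.14)
z_compare(rural, urban)
#> # A tibble: 1 × 5
#>   pair                                  z     p z_reported p_reported
#>   <chr>                             <dbl> <dbl>      <dbl>      <dbl>
#> 1 midparent/rural vs midparent/urban 1.15 0.250       1.15     0.2501
```

File-based workflows use `read_pedigree_file()` (TSV: id, sire, dam, sex,
habitat; `0`/empty/`NA` mark unknown parents), `read_phenotypes()` (CSV:
id, fid_m, with repeated measures averaged on the meter scale before the
log transform), and `read_parent_offspring()` for long-format family tables
of raw parent/offspring FIDs.

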