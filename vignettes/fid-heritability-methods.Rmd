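---
title: "Estimating the heritability of flight initiation distance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heritability of flight initiation distance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Flight initiation distance (FID) — how close a human can approach before a
bird flees — is a repeatable, individual-level measure of fear of humans.
When a wild population is monitored long enough to know who bred with whom,
two classical quantitative-genetic routes to its heritability open up:
parent–offspring regression and the pedigree-based animal model. This
vignette documents the models `fidherit` implements, the numerical choices
behind them, and what the synthetic-data generator used for testing does
and does not emulate.

## The response variable

All analyses work on the natural logarithm of FID in meters. FID
distributions are strongly right-skewed and effects are closer to additive
on the log scale. The base of the logarithm is a pure convention here:
regression slopes of log on log are base-invariant, and variance ratios are
unaffected by linear rescaling. When an individual was measured more than
once, measures are averaged **on the meter scale first** and logged after
(`read_phenotypes()`); the mean of the raw distances is the quantity that
field protocols describe, and the high within-individual repeatability of
FID makes the choice numerically minor but it is applied and tested
explicitly.

## Parent–offspring regressions

Offspring are grouped into full-sib broods and each brood contributes its
mean log-FID once (`build_po_dataset()`), avoiding pseudo-replication from
large broods; broods are unweighted in the regression regardless of size,
which matches the averaging convention of field studies (a weighted variant
would change SEs, not expectations). The midparent–midoffspring slope
estimates h² directly. Single-parent slopes are doubled, and because mates
are phenotypically correlated (assortative mating), divided by (1 + r):

- `midparent_h2()`: h² = b. Phenotypic assortative mating inflates the
  variance of midparent values and the parent–offspring covariance by the
  same (1 + r) factor, so no correction applies.
- `single_parent_h2()`: h² = 2b/(1 + r). The standard error is scaled by
  the same 2/(1 + r) factor, because the estimator is a linear function of
  the slope; treating the correction as known (rather than propagating the
  sampling error of r itself) mirrors how such corrections are reported.
- `mate_correlation()` is the Pearson correlation of mate log-FIDs;
  `mate_correlations()` stratifies it by the habitat in which the pair
  bred.

Habitat-stratified estimates filter broods by the natal habitat of the
offspring: under philopatry this is also where the offspring will be
measured and breed, so the stratum reflects the habitat in which the
parent–offspring resemblance is expressed.

Estimates are compared with z = (xᵢ − xⱼ)/√(SEᵢ² + SEⱼ²) and a two-sided
normal p (`z_compare()`). Published tables of such comparisons round z to
two decimals and report the p of the rounded z; both the raw and the
reported pair are exposed (`z`, `p`, `z_reported`, `p_reported`), and no
multiple-testing adjustment is applied, matching how raw pairwise
comparisons are reported in this literature.

## Pedigree machinery

`validate_pedigree()` topologically sorts individuals (parents first,
input order preserved among ties) and enforces structural soundness:
unique ids, no self-parentage or cycles, parents present or explicitly
unknown (`0`/empty/`NA`), sexes consistent with parental roles. Founders
are treated as an unrelated, non-inbred base population — nothing in a
field pedigree identifies founder relatedness — and individuals with one
known parent are supported, as happens when an unringed mate is identified
through shared offspring.

The additive relationship matrix A is built densely by the recursive
tabular method (`additive_relationship_matrix()`); at the scale of such
studies (a few thousand individuals) the dense build is trivial, and the
inbreeding coefficients F = diag(A) − 1 come for free. The sampler never
uses dense A: `a_inverse()` assembles A⁻¹ sparsely by Henderson's rules
with Mendelian-sampling variances d = 0.5 − 0.25(F_sire + F_dam) (3/4 − F/4
with one known parent, 1 for founders), which stays scalable and exact
under inbreeding. Tests verify A against an independently coded recursive
kinship oracle to 1e-12 and A⁻¹A = I to 1e-8.

## The animal model

The model is y = Xβ + Za + e with a ~ N(0, A σ²_A) and e ~ N(0, I σ²_R);
h² = σ²_A/(σ²_A + σ²_R). Fixed effects are an intercept, habitat
(urban-vs-rural indicator) and sex (female-vs-male indicator); year is
deliberately *not* a term, because FID is highly repeatable across an
individual's lifespan and a year term would absorb no structure by design.

The Gibbs sampler (`fit_animal_model()`) draws:

1. β from its Gaussian full conditional (flat improper prior);
2. all breeding values **jointly** from the mixed-model-equation
   conditional, N(C⁻¹Z'(y − Xβ)/σ²_R · σ²_R, σ²_R C⁻¹) with
   C = Z'Z + (σ²_R/σ²_A) A⁻¹, via a sparse Cholesky whose symbolic
   analysis is computed once and numerically updated each iteration.
   Joint (single-block) sampling was chosen over single-site updates for
   mixing: the stationary distribution is identical, but autocorrelation
   at this pedigree scale is drastically lower (stored draws have
   near-nominal effective sample size);
3. σ²_A from a scaled inverse-chi-square with df ν + q and scale
   (a'A⁻¹a + νV)/(ν + q), and σ²_R analogously from the residuals.

The prior (V = 1, ν = 0.02) is a univariate inverse-Wishart — i.e. scaled
inverse-chi-square — applied independently to each variance component, the
parameterisation convention of the MCMC mixed-model packages used in this
field; at ν = 0.02 it is effectively uninformative, and a sensitivity test
verifies that posterior-mean h² moves by < 0.05 across prior scales
V ∈ {0.5, 1, 2}. Unphenotyped pedigree members are retained and simply
receive breeding values; all pedigree links contribute information.

Summaries (`summarize_posterior()`, `tidy()`, `glance()`) report the
posterior mean and the kernel-density mode of h² — published point
estimates in this area are rarely labelled as one or the other, so both
are exposed — with a 95% highest-posterior-density interval (shortest
interval on the sorted draws; an equal-tailed quantile interval is
available by flag). Fixed effects are flagged significant when their
interval excludes zero. Chain quality is diagnosed by Geyer's
initial-positive-sequence effective sample size (`effective_sample_size()`),
which is conservative and requires no spectral fitting; a constant chain
is reported as degenerate with a warning rather than an arbitrary number.

The default schedule is 1,000,000 iterations with 10,000 burn-in and
thinning 200, the schedule appropriate for a final analysis;
`desk_schedule()` (50,000/5,000/50) is what the package's own simulation
experiments and calibration runs use, and at the ~1,200-individual scale
it yields ~900 stored draws with effective sample sizes near the draw
count, entirely adequate for means and 95% intervals.

## The synthetic-study generator

`simulate_fid_study()` generates pedigree, breeding values and phenotypes
jointly, generation by generation, because mate choice is phenotypic.
Defaults define the reference design used throughout the tests: 140
founders per habitat and ~1,200 individuals over 3 generations; log-FID
with total phenotypic variance 1.0, h² = 0.43, urban effect −0.42, female
effect +0.06, intercept 3.4 (a rural male at ~30 m); mate correlation
0.78; full natal-habitat philopatry. The behavioural parameters are the
contrasts and correlations such urban/rural FID studies report; total
phenotypic variance is not separately reported in that literature, so it
is fixed at 1.0 and left as a configuration knob (only variance *ratios*
matter for h²).

Mechanics and their rationale:

- **Assortative mating** (`assign_mates_assortative()`): monogamous
  rank-matching of females' phenotypes against a male latent value
  correlated ρ = r with male phenotype. For Gaussian phenotypes the
  realised Pearson correlation between mates is within Monte-Carlo error
  of the target (verified at r = 0 and 0.78 and in the r → 1 rank-sorted
  limit). Mating acts on the *phenotype*, not the breeding value, because
  mate correlations are measured phenotypically in the field.
- **Transmission** (`simulate_breeding_values()`): additive-infinitesimal;
  offspring receive the parental mean plus Mendelian sampling noise with
  variance 0.5·V_A·(1 − 0.5(F_s + F_d)). Parental inbreeding is tracked
  through the growing relationship matrix only for pedigrees deeper than
  three layers; with unrelated founders, parents of any three-layer design
  provably have F = 0, so the default design skips that bookkeeping.
- **Brood sizes** are Poisson (mean 2.8, capped at 8) — a neutral choice
  where field distributions are unspecified; **sexes** are assigned 1:1;
  **philopatry** settles offspring in the natal habitat with probability 1
  by default, reflecting the strong natal-habitat fidelity reported for
  urban/rural owl populations, and is a free parameter.
- Everything is deterministic given `seed`.

What the generator does **not** emulate: overlapping generations and age
structure, survival and dispersal, extra-pair paternity (the analysis
assumes social parents are genetic parents, defensible for genetically
monogamous territorial species but an assumption nonetheless), maternal
and other non-additive variance, and habitat differences in variance.
Passing recovery tests on this generator therefore demonstrates that the
estimators are correctly implemented and calibrated under the additive
model — not that real FID heritability is free of non-genetic inflation
(shared habitat, parental effects), which pedigree data of this shape
cannot fully separate.

Note one subtlety the recovery experiments rely on: with phenotypic
assortative mating, the additive variance of later generations exceeds the
founder V_A (positive gametic-phase disequilibrium), yet the animal model
with the complete pedigree consistently recovers the *base-population*
parameters — mate choice based on observed phenotypes is ignorable in the
likelihood when the data used for selection are analysed. The calibration
experiments therefore compare posterior h² against the founder value 0.43.

## Problem sizes used in the packaged experiments

The packaged tests run: oracle equivalence on 100 random pedigrees of up
to 30 individuals; a dense-likelihood-grid cross-check of the Gibbs
posterior mode on a ~60-individual pedigree (profile MLE over
h² ∈ {0.01, …, 0.99}); 20 replicates of the full ~1,200-individual design
with 50,000-iteration chains for parameter recovery (mean posterior-mean
h² within ±0.05 of 0.43, ≥ 17/20 HPD coverage, habitat effect within
±0.05 of −0.42); and 100-seed calibration of the midparent estimator at
h² ∈ {0, 0.6, 1} with ~400 broods per habitat stratum. These sizes were
chosen as the smallest designs at which the binding tolerances are
comfortably inside Monte-Carlo error.

The calibration runs stratify by habitat, for the same reason the field
analyses do: in a pooled two-habitat regression the habitat effect is
shared between parents and offspring (philopatry) and contributes
p(1 − p)·β² of brood-level covariance, inflating the pooled slope by up to
~0.05 when heritability is low. This is a property of the pooled design —
visible in the package's own simulations — not of the estimator;
within-habitat estimates are free of it.

## Known limitations

- The regression SE correction divides by (1 + r) treating r as known;
  the sampling error of r is not propagated.
- The kernel-density posterior mode is boundary-biased when mass piles
  near h² = 0; for weak-signal data the posterior mean and interval are
  the more stable summaries (both are reported).
- Habitat assignment of a brood uses majority natal habitat; under partial
  philopatry a brood split across habitats is assigned to its majority
  habitat rather than being divided.
- The animal model assumes homoscedastic residuals across habitats and a
  single trait; repeated measures are collapsed before modelling rather
  than fitted with a permanent-environment effect.
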