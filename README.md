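# spermsel

Phenotypic selection on ejaculate traits in a wild population, measured
from sperm-cell tracks and SNP genotypes.

`spermsel` is for evolutionary biologists quantifying postcopulatory
sexual selection: it takes the raw materials of a mark–recapture sperm
competition study — per-cell swimming tracks, a biallelic SNP genotype
panel for adults and offspring, and per-male morphology/count tables —
and carries them through to Lande–Arnold selection differentials and
gradients with a nonparametric fitness surface. A synthetic-population
generator with known generative parameters makes the whole chain testable
without any field data.

## The model at the core

For standardized traits **z** (mean 0, SD 1) and relative fitness
*w* = *n*/*n̄* (offspring count over the population mean):

- *s*ⱼ — univariate linear selection differential, the OLS slope of
  *w* on *z*ⱼ; identical to cov(*w*, *z*ⱼ) for standardized traits.
- *c*ⱼ — univariate quadratic differential: 2 × the quadratic
  coefficient of *w* ~ *z*ⱼ + *z*ⱼ², SE doubled likewise.
- **β** — multivariate linear gradients, from the multiple regression of
  *w* on all six traits (direct selection, holding other traits fixed).
- **γ** — quadratic (diagonal, doubled) and correlational (off-diagonal,
  not doubled) gradients from the full second-order regression, under the
  surface parameterization *w* = α + **β**ᵀ**z** + ½ **z**ᵀ**γ z**.

Significance comes from log-link quasi-Poisson GLMs on the raw counts
(dispersion by Pearson χ²/df), because count fitness is skewed and
overdispersed. The fitness surface for sperm count is a penalized cubic
spline whose basis dimension K is chosen by generalized cross-validation.

Parentage — the fitness input — is assigned per offspring as the
maximum-likelihood dam–sire trio over all candidate pairs, with a
symmetric per-allele genotyping-error model, missing-locus handling, and
acceptance controlled at an estimated false discovery rate against a
Monte-Carlo null of unrelated trios.

## Worked example

Simulate a population at the study conditions (171 males, six correlated
sperm traits, negative linear −0.17 and quadratic −0.16 selection on
sperm count, overdispersion 3) and re-estimate the selection surface:

```r
library(spermsel)
cfg   <- sim_config(seed = 7)
study <- simulate_study(cfg)
est   <- selection_analysis(study$phenotypes, study$offspring_counts)
print(est)
#> Selection analysis on 171 males, 6 traits
#>              trait       s   s_se       c   c_se     beta beta_se
#> 1      sperm_count -0.2095 0.0708 -0.2461 0.1118 -0.20100  0.0766
#> 2         velocity -0.0838 0.0723  0.0355 0.1022  0.15099  0.1017
#> 3        linearity -0.1646 0.0715  0.1036 0.0959 -0.20830  0.0959
#> ...
p <- est$p_linear
p$p[p$term == "sperm_count"]
#> [1] 0.0105
```

The sperm-count differential (−0.21 ± 0.07 for this seed) recovers the
generative negative selection and the quasi-Poisson test flags it
(p ≈ 0.01), while the four morphology/velocity traits carry no generative
selection — their estimates scatter around zero at SE ≈ 0.07–0.10.
The γ diagonal for sperm count (−0.29 for this seed) is the doubled
quadratic coefficient: concave selection, males near or slightly below
the trait mean doing best. The fitness surface makes that visible:

```r
sf <- select_k(est$z[, "sperm_count"], est$w)   # K chosen by GCV
print(sf)
#> <surface_fit: K = 3 chosen by GCV from {3,4,5,6,7,8,9,10}, edf = 2.79>
plot_fitness_surface(sf, est$z[, "sperm_count"], est$w)
```

The numbered scripts under `analysis/` run the full chain — simulate,
kinematics from tracks, parentage, selection, surface — writing each
stage's tables under `results/run/` and a run report aggregating them
(`make_report()`).

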