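---
title: "Measuring phenotypic selection on ejaculate traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phenotypic selection on ejaculate traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

In promiscuous species, a male's reproductive success is decided partly
after mating, when ejaculates from different males compete for
fertilization. Which ejaculate traits this postcopulatory selection
targets — how many sperm a male transfers, how fast and how straight they
swim, how the cell is built — is a multivariate question: sperm traits are
phenotypically correlated, so selection on one trait drags others along,
and fitness may depend on trait combinations.

`spermsel` implements the complete measurement chain used to answer this
question in a wild lizard population:

1. **Kinematics** — per-cell swimming metrics from manually tracked
   coordinates (`compute_vapi()`, `compute_linearity()`,
   `summarize_male()`), plus hemocytometer count scaling and a bootstrap
   precision analysis.
2. **Parentage** — offspring-to-dam-sire trio assignment from a biallelic
   SNP panel under a genotyping-error model with false-discovery-rate
   control (`assign_parentage()`), and per-adult offspring/mate tallies
   (`tally_fitness()`).
3. **Selection analysis** — Lande–Arnold selection differentials and
   gradients on standardized traits with relative fitness
   (`univariate_differentials()`, `multivariate_gradients()`), with
   significance from quasi-Poisson GLMs (`significance_glm()`).
4. **Fitness surface** — a GCV-selected penalized cubic spline of relative
   fitness on standardized sperm count (`select_k()`).
5. **Synthetic data** — a generator with known generative parameters
   (`sim_config()`, `simulate_study()`) so that every stage above is
   testable end to end without field data.

The numbered scripts under `analysis/` run these stages in order on a
synthetic population and write their tables under `results/`.

# The selection model

Traits are variance-standardized (sample SD, $n-1$ denominator; the
default of R's `scale()`); relative fitness is
$w_i = n_i / \bar n$ for offspring count $n_i$, so $\bar w = 1$.

* Univariate linear differential: $s_j$ is the OLS slope of
  $w \sim z_j$. For standardized traits $s_j \equiv \mathrm{cov}(w, z_j)$,
  an identity the tests verify to numerical precision.
* Univariate quadratic differential: $c_j$ is **twice** the quadratic
  coefficient of $w \sim z_j + z_j^2$, its SE doubled likewise.
* Multivariate gradients: $\beta$ from $w \sim z_1 + \dots + z_6$;
  $\gamma$ from the full second-order model (all linear, squared and
  pairwise cross-product terms), with $\gamma_{ii}$ twice the squared-term
  coefficient and $\gamma_{ij}$ the cross-product coefficient **not**
  doubled. The doubling convention follows the standard correction for
  quadratic selection estimates: the fitness surface is parameterized
  $w = \alpha + \beta^\top z + \tfrac12 z^\top \gamma z$, so the
  regression coefficient on $z_j^2$ estimates $\gamma_{jj}/2$, while the
  coefficient on $z_i z_j$ already estimates $\gamma_{ij}$.

Because offspring counts are skewed and overdispersed, point estimates
come from OLS (the quantities the selection-gradient literature is built
on) while *significance* comes from a log-link Poisson model with
dispersion estimated by Pearson $\chi^2/\mathrm{df}$ (the quasi-Poisson
model) on the raw counts. The response is the integer count, not $w$:
quasi-Poisson variance is defined for counts, and under a log link the
normalization by $\bar n$ is absorbed by the intercept, leaving slopes and
their tests unchanged. Multicollinearity is reported as VIFs
($1/(1-R^2_k)$ per term, both designs) and trait relationships as partial
correlations from the inverse correlation matrix, with $t$-tests on
$n - k$ degrees of freedom.

p-values are two-sided and uncorrected for multiplicity, matching the
standard reporting of selection tables.

# The fitness surface

`fit_penalized_spline()` builds a B-spline basis of dimension $K$ on
equally spaced knots (cubic for $K \ge 4$; $K = 3$ falls back to a
quadratic basis, since a cubic basis needs at least four functions),
penalizes second differences of the coefficients, and minimizes
$\mathrm{GCV}(\lambda) = n\,\mathrm{RSS}/(n - \mathrm{tr}\,H)^2$ by
golden-section search on $\log_{10}\lambda \in [-8, 8]$. `select_k()`
repeats this for $K = 3..10$ and keeps the $K$ with the smallest GCV
(ties to the smaller $K$). The literature often calls $K$ itself "the
smoothing parameter"; here $K$ is the basis dimension and $\lambda$ the
smoothing intensity, optimized internally for every $K$ — this matches the
convention of the standard GAM machinery while keeping the $K$-selection
narrative. The tests cross-check the hand-rolled fit against `mgcv` with a
P-spline basis.

The 95% band is the pointwise frequentist
$\pm 1.96\,\mathrm{SE}$ from the penalized-fit covariance
$(B^\top B + \lambda P)^{-1} B^\top B (B^\top B + \lambda P)^{-1}
\hat\sigma^2$; a Bayesian band would be wider near the boundary but was
not needed for the qualitative display. Fitting uses Gaussian loss on $w$
(the usual GAM-of-relative-fitness display), not the count likelihood.
Binned means use rank-based bins of near-equal size; tied predictor
values are kept together in the lower bin so bins never split identical
phenotypes.

# Kinematics definitions and defaults

* **VAPi** — the track is smoothed twice with centered moving averages
  (defaults `window_vap = 5`, `window_extra = 5` frames) and the smoothed
  path length is divided by elapsed time. The extra pass is the
  low-framerate variant of classical VAP; the original plugin's windows
  are not published, so both are parameters and are recorded in the
  output. Endpoints use shrinking *centered* windows — no data are
  invented beyond the track, and straight tracks are reproduced exactly
  for any window.
* **Linearity** — by default LIN $= 100 \cdot$ (net displacement /
  point-to-point path length), the standard CASA definition of "percent
  forward progression"; `method = "STR"` (net velocity over VAP) is
  offered because the verbal definition is ambiguous between the two.
* **Motility screen** — cells with total path length under 5 µm are
  flagged immobile; the field protocol excluded immobile/stuck cells
  without a numeric rule, so the threshold is a configurable default.
* Tracks need ≥ 45 frames and 15 usable cells per male (both
  configurable); shorter samples are flagged for exclusion, mirroring the
  field protocol's exclusion of males that could not be measured.
* Time is derived from frame index / fps when absolute stamps are absent.
* `resampling_precision()` bootstraps per-male means at sizes 2–15 with
  10,000 resamples per size and averages the SD across males; at size
  $k$ from $n$ cells the expected value is
  $\sigma\sqrt{(n-1)/n}/\sqrt{k}$, which the tests verify by exhaustive
  enumeration at $n = 3, k = 2$.

# Parentage model

Trio likelihoods follow the standard SNP-parentage construction: at each
locus, the probability of the three observed genotypes under (i)
Mendelian transmission from the pair with Hardy–Weinberg parental
genotypes, versus (ii) three unrelated Hardy–Weinberg draws, both under a
symmetric per-allele misread applied independently to each allele
(default rate 0.005, i.e. a 1% per-genotype error). The LOD is the summed
log10 ratio over loci with all three calls present. Allele frequencies
are estimated from genotyped adults with missing entries ignored;
monomorphic loci are dropped with a warning.

The assignment stage is a re-implementation of the *contract* of the
standard trio-assignment tools, not a port: the best dam–sire pair per
offspring is found by exhaustive search (after a pairwise
opposing-homozygote pre-filter, cap 10 by default, which removes
essentially all non-relatives at 215 loci), and acceptance is controlled
against a Monte-Carlo null of simulated unrelated trios drawn at the
estimated allele frequencies under the same error and missingness. The
estimated FDR at a cutoff is (number of offspring × null tail
probability) / (calls accepted), with the add-one convention
$(k+1)/(n+1)$ for the tail so the estimate is never exactly zero — a
threshold of 0 therefore accepts nothing, the conservative degenerate
behaviour. Equal-LOD ties for the best pair leave the offspring
unassigned. Completeness filters: offspring with > 50% missing loci are
dropped; adults with > 50 missing loci leave the candidate pool.

# The synthetic population

The generator's defaults are the study conditions: 171 phenotyped males,
465 females, the six-trait phenotypic correlation structure measured in
the wild population (`anole_trait_correlation()`), a 215-locus panel with
0.5% per-allele error and 10% missing calls, and selection acting only on
sperm count (linear −0.17, quadratic −0.16 on the standardized scale).
Where the study does not state a value, defaults were chosen once as
field-realistic and not revisited:

* trait means/SDs (count 1.5×10⁶ ± 6×10⁵ cells; VAPi 45 ± 10 µm/s;
  linearity 75 ± 10%; head 12 ± 0.8 µm; midpiece 4 ± 0.5 µm; flagellum
  70 ± 4 µm) — magnitudes typical of anole sperm measurements; they are
  irrelevant to the selection analysis, which standardizes;
* mean offspring per male 3.86 (the study's assignments per genotyped
  sire) with dispersion 3 — the offspring-count distribution is not
  reported, so the variance inflation is a modelling choice; it is a
  config parameter, and the dispersion-sensitivity of SEs is tested;
* dams-per-sire negative binomial with mean 3.85 and size 2, truncated to
  the number of offspring — reproduces the reported mean mate count with
  a plausible maximum (~16) at the study's male population size;
* allele frequencies uniform on (0.2, 0.8) — an informative genotyping
  panel, as marker panels for parentage are designed to be.

Offspring counts are drawn with
$\log \mu = \log m + \beta^\top z + \tfrac12 z^\top \gamma z$ and
variance $\phi \mu$ (negative binomial with size $\mu/(\phi-1)$; Poisson
at $\phi = 1$). The log link keeps counts positive and makes the
generative model conjugate with the quasi-Poisson testing machinery.

**The estimand gap.** With a log-link generative surface the OLS
Lande–Arnold coefficients do not converge to the generative $(\beta,
\gamma)$ exactly. For Gaussian $z \sim N(0, \Sigma)$, fitness-weighting
tilts the trait distribution to another Gaussian with covariance
$C = (\Sigma^{-1} - \gamma)^{-1}$ and mean $Cb$, giving large-sample
limits $s = Cb$, $\beta = \Sigma^{-1}Cb$ and a quadratic-regression limit
$\Sigma^{-1}(C - \Sigma + \mu\mu^\top)\Sigma^{-1}$ (`la_estimands()`).
At the default magnitudes the linear gradient limit is ≈ −0.147 (a
second-order gap of ≈ 0.02 from −0.17) and the quadratic limit is
≈ −0.116 (a gap of ≈ 0.04 from −0.16). `recovery_experiment()` reports
both comparisons; its replicate means agree with these analytic limits,
which is the sharper correctness check. This is a property of log-link
fitness surfaces, not an estimator defect — on a *linear* fitness surface
the same estimators are exactly unbiased, as the covariance-identity
tests show.

Cell tracks are correlated random walks with fixed step length
$v/\mathrm{fps}$ and von-Mises turning angles (Best–Fisher sampler,
hand-implemented since no circular-statistics package is a dependency).
The concentration is calibrated by inverting the Kareiva–Shigesada
mean-squared-displacement formula so the *root-mean-square* straightness
matches the requested linearity; realized mean linearity runs somewhat
below the request (RMS ≥ mean), which the tests bound rather than pin
down. The calibration range is capped at mean resultant length
$1 - 10^{-4}$ (the MSD formula cancels catastrophically nearer 1);
requests ≥ 99.95% produce an exactly straight path.

## What the generator does and does not emulate

It reproduces: the trait correlation structure, overdispersed
offspring-count fitness under a known selection surface, Mendelian
genotype transmission with per-allele error and missingness, promiscuous
mating with a realistic mate-count distribution, and tracking jitter on
cell paths. It does **not** emulate: temporal change in ejaculate traits
across a breeding season, linkage or departures from Hardy–Weinberg,
population structure among adults, incomplete sampling of parents (every
true parent is genotyped, unlike the field study where many offspring had
an ungenotyped parent), or measurement error in morphology. Passing
recovery tests therefore demonstrate that the *estimators and pipeline*
are correct under the stated model, not that field inference is immune to
those unmodelled features.

# Numerical choices

* All least-squares fits go through R's QR-based `lm`; rank deficiency
  aborts with the collinear columns named. The full quadratic model has
  27 terms and needs $n \gtrsim 30$; at the study's $n = 171$ it is well
  conditioned.
* VIFs come from inversion of the design correlation matrix (exactly
  $1/(1-R^2_k)$), with a column-wise fallback reporting `Inf` under
  perfect collinearity.
* Golden-section GCV search uses tolerance $10^{-6}$ on
  $\log_{10}\lambda$; the optimality audit in the tests checks the
  optimum against bracketing values.
* Seeds: every stochastic function takes an explicit seed and
  restores the caller's RNG state; pipeline stages derive their seeds by
  hashing the master seed with the stage name, so a stage is reproducible
  in isolation and stages are mutually independent.
* Determinism: identical configuration (including seed) gives
  byte-identical outputs; the pipeline manifest records md5 checksums so
  any number is traceable to a seed and config.

# Problem sizes

The shipped experiments use 500 replicate populations of 171 males for
gradient recovery, 2000 for the type-I-error calibration, and a
~1000-offspring population on the 215-locus panel for parentage recovery
— sizes at which Monte-Carlo error is far below the effects being
checked while the whole suite stays quick on a single core.

# Known limitations

* The FDR calibration uses a per-trio null; it does not model the
  best-of-many-pairs selection effect beyond multiplying the tail by the
  number of offspring, which is conservative for sparse candidate sets
  but approximate in general. Numerical agreement with the published
  trio-assignment software on real data is not claimed.
* The exact smoothing algorithm of the original tracking plugin is
  unpublished; VAPi window choices shift absolute velocities slightly
  (never the straight-line case) and are therefore parameters.
* The surface CI is pointwise; simultaneous coverage over the grid is
  lower.
* Selection estimates are phenotypic; nothing here separates genetic from
  environmental covariance with fitness.
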