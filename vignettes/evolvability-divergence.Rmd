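---
title: "Evolvability and the divergence of plant populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolvability and the divergence of plant populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(qgdiverge)
```

## The scientific question

Standing additive genetic variation within populations is the fuel for the
response to selection. If genetic architecture constrains evolution, trait
combinations with more genetic variation should have diverged more among
populations, and populations should have diverged preferentially along
directions of high evolvability. `qgdiverge` implements the statistical
machinery to test these predictions on databases that pair within-population
evolvability estimates with among-population divergence of trait means.

All quantities live on the proportional scale, which makes them comparable
across traits and species:

* **Evolvability** of a trait is the mean-scaled additive genetic variance
  $e = I_A = V_A/\bar{x}^2$: the expected proportional response to an
  episode of unit-strength selection. For a mean-scaled G-matrix
  $\mathbf{G}$ and a unit direction $\mathbf{v}$, the evolvability along
  $\mathbf{v}$ is $e(\mathbf{v}) = \mathbf{v}^\top \mathbf{G}\mathbf{v}$,
  and the **conditional evolvability** — the response available when
  selection holds all orthogonal trait combinations constant — is
  $c(\mathbf{v}) = (\mathbf{v}^\top \mathbf{G}^{-1}\mathbf{v})^{-1}$, with
  $c(\mathbf{v}) \le e(\mathbf{v})$ and equality exactly at eigenvectors.
* **Divergence** of a trait is $d$, the variance of natural-log-transformed
  population means; multivariately, $\mathbf{D}$ is the covariance matrix
  of log population means and $d(\mathbf{v}) = \mathbf{v}^\top \mathbf{D}
  \mathbf{v}$. Assuming normal log means, the expected absolute log
  deviation of a population from the grand mean is the folded-normal mean
  $\sqrt{2d/\pi}$, and $d_P = \exp\!\sqrt{2d/\pi}$ expresses divergence as
  the proportional factor by which an average population differs from the
  grand mean.

The slope of log $d$ on log $e$ is the quantity that discriminates
macroevolutionary models: neutral divergence predicts slope 1 (with
$d/e = t/N_e$), while optimum tracking under an Ornstein–Uhlenbeck moving
optimum with weak selection predicts slopes between 0.5 and 1.

## The univariate meta-regression

`run_univariate()` assembles one row per divergence study × trait, pairing
each divergence estimate with the mean evolvability estimate for the
species–trait combination, and fits

$$\log d_{ij} = \beta_0 + \beta_e \log e_{ij} + \beta_n \log n_{pop,j}
  + \beta_g \log dist_j + a_{sp(i)} + b_j + s_j \log e_{ij} +
  \varepsilon_{ij}$$

with random intercepts for species ($a$) and divergence study ($b$), an
uncorrelated random slope per study ($s_j$, whose SD measures slope
heterogeneity), and residual variance $\sigma^2 / w_{ij}$. The weights are
the inverse measurement-error variance of each $d$: the sampling variance
of an among-population variance over $n$ populations is
$\sigma^2_m(d) = 2d^2/(n+2)$, which the delta method transfers to the
constant $2/(n+2)$ on the log scale; the default weights are therefore
$(n_{pop}+2)/2$. Covariates are log-transformed and mean-centered, so the
intercept is the expected log divergence at average covariate values.
Models are fit by maximum likelihood (through `lme4`) whenever AIC
comparisons across fixed-effect structures are requested; moderator models
add a trait-category, mating-system, or environment main effect plus its
interaction with log evolvability, and $\Delta AIC = AIC_{complex} -
AIC_{baseline}$ is reported with $|\Delta AIC| > 2$ read as a detectable
difference.

### Attenuation correction

Evolvability enters the regression as an estimate, and estimation error in
a predictor biases its slope toward zero by the reliability
$1 - V_{me}/V$. The predictor used is the **mean** of the $m$ repeated
estimates per species–trait, so the package computes $V_{me}$ as the mean
of (within species–trait variance of log estimates)$/m$ — the error
variance of the quantity actually regressed on — and $V$ as the variance
of the log mean estimates across rows. The corrected slope divides the raw
slope (and its SE) by the reliability; `attenuation_correct()` refuses the
correction when $V_{me} \ge V$ rather than extrapolating from pure noise.
The coarser reading of $V_{me}$ as the raw within-group variance is
available via `vme_method = "within"`, but it overcorrects whenever
$m > 1$ and fails slope-recovery simulations, so it is not the default.

### Marginal and conditional r²

`r2_nakagawa()` partitions variance as fixed / random / residual:
$r^2_M = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$ and
$r^2_C$ adds $\sigma^2_r$ to the numerator. The random-slope contribution
is evaluated at the observed covariate distribution
($\tau^2 \cdot \mathrm{mean}(z^2)$ for an uncorrelated slope on $z$), and
the weighted residual variance is summarized as
$\sigma^2 \cdot \mathrm{mean}(1/w_i)$.

## The multivariate case analyses

A "case" pairs a G-matrix with a D-matrix over the same $k \ge 3$ traits.
`case_regression()` regresses $\log d(\mathbf{v})$ on $\log e(\mathbf{v})$
by OLS across a direction set: the original trait axes (reducing to the
matrix diagonals, i.e. the univariate analysis), or the eigenvectors of
G, D, or P. Eigenvectors maximize the spread of evolvability and
divergence and are orthogonal, but the choice matters because estimation
error biases the comparison in opposite directions: sampling error
inflates the leading eigenvalue of whichever matrix defines the
directions, so D-direction slopes are biased **up** and G-direction slopes
**down**, with P-directions (phenotypic matrix, error independent of both)
in between. The package's Monte-Carlo machinery reproduces this ordering
on synthetic ensembles, mirroring the empirical pattern.

Uncertainty: `resample_G()` emulates the sampling distribution of an
estimated G by drawing `n_families` observations from
$MVN(\mathbf{1}, \mathbf{G})$ per iteration (1,000 by default) and taking
the sample covariance; `resample_D()` uses the equivalent construction
with `n_pops` draws (a Wishart with $n_{pop}-1$ effective degrees of
freedom, elementwise unbiased — an approximation documented for the
common situation where only a point estimate of D is available). The SE of
a case slope is the SD over randomly paired (G, D) draws, with directions
recomputed from the drawn matrix so that direction-choice error propagates
(`fixed_directions = TRUE` provides the sensitivity toggle); the number of
pairings defaults to 1,000 and is configurable. Grand slopes per direction
set come from `meta_slope()`: an inverse-variance-weighted mixed model
with random intercepts for species and D-matrix identity.

## Evolvability along observed divergence vectors

For a focal population carrying a G-matrix, the divergence vector to
another population is $\Delta = \log \bar{x}_{target} - \log
\bar{x}_{focal}$; its unit direction is where evolution actually went, and
its Euclidean norm is used as the divergence magnitude $d(\Delta)$ (the
norm, rather than the mean absolute element, is adopted as the natural
multivariate magnitude; it is also what makes the triangle inequality and
rotation invariance hold). `vector_evolvabilities()` evaluates
$e(\Delta)$ and $c(\Delta)$ on the unit vector and forms ratios against
the matrix summaries $\bar{e} = \mathrm{tr}(\mathbf{G})/k$ and $\bar{c}$.
`above_average_summary()` reports the fraction of populations above
average (counted per record; a population appearing under several
G-matrices contributes one record each) and error-weighed mean log ratios
whose sampling variances come from the same G-resampling draws. Display
scaling for summary panels (`minmax_scale()`) maps $\bar{e} \to 0$,
$e_{max} \to +1$, $e_{min} \to -1$, linearly on each side.

$\bar{e} = \mathrm{tr}(\mathbf{G})/k$ is exact (the mean of
$e(\mathbf{v})$ over uniform directions); no closed form is as simple for
$\bar{c}$, which is computed by seeded Monte Carlo over uniform random
unit directions (10,000 by default; the Monte-Carlo SE is negligible
relative to the matrix sampling error this feeds into). When a matrix
subset of traits is supplied, $\bar{e}$ is the trace mean of the supplied
matrix — the natural reading when the matrix defines the trait space under
study.

## The synthetic-data generator

`simulate_database()` generates complete databases with known ground
truth, emulating the hierarchical structure of the empirical literature:
species → divergence studies → populations → traits, with trait-category,
mating-system, and environment labels and geographic coordinates. Defaults
(in `sim_config()`) describe the study conditions the package is validated
under:

* 16 species × 3 studies (48 divergence studies, the scale of the
  empirical database), 5 traits per species, 5–12 populations per study;
* true G-matrices are Wishart draws (df = 3k) around a compound-symmetric
  correlation (ρ = 0.3), rescaled to a mean evolvability of 0.005 — the
  typical magnitude of mean-scaled additive variance in plants;
* **neutral** divergence: log population means drawn with among-population
  covariance $(t/N_e)\,\mathbf{G}$, so the true log–log slope is 1 and
  $d/e = t/N_e$ (default 1) along every direction. The **OU** alternative
  emulates optimum tracking by its stationary covariance: shared
  eigenvectors with G and eigenvalues $\lambda_i^s$ (trace preserved),
  giving a true G-direction slope of $s \in [0.5, 1]$. The OU process is
  represented by its stationary among-population covariance rather than
  explicit time integration, since only the stationary predictions are
  analyzed;
* population means carry sampling noise of log-scale variance
  $\mathrm{diag}(\mathbf{G})/h^2/n_{ind}$ ($h^2 = 0.3$, 100 individuals
  per population);
* evolvability estimates are mean-one log-normal perturbations of the true
  diagonal (SD 0.3, 3 repeats per species–trait), generating the
  attenuation the univariate pipeline must undo;
* estimated matrices (G from `n_families` = 60 draws, P = G/h² from the
  pooled individuals) are exposed to the pipeline unless
  `exact_matrices = TRUE`, which bypasses estimation noise for analytical
  checks.

Geographic coordinates are cosmetic covariate generators (no
isolation-by-distance genetics), and the default world has no
trait-category effect on divergence (`category_effects = c(floral = 1,
vegetative = 1)`), i.e. a pure neutral world; category offsets are
exercised explicitly where a Fig.-1-style contrast is wanted:

```{r category-world}
db <- simulate_database(sim_config(
  n_species = 8, studies_per_species = 2,
  category_effects = c(floral = 1, vegetative = 4), seed = 11))
run_patterns(db, bootstrap_reps = 500, seed = 1)$summaries$trait_category
```

What passing tests on these worlds do **not** show about real data: the
generator draws species independently (no phylogeny), assumes populations
within a study are exchangeable (no gene flow, no spatial structure tied
to the coordinates), uses log-normal estimate noise and normal log means,
and shares one true G across a species' studies. Real databases violate
all of these to some degree; the validation demonstrates that the
estimators recover truth when their assumptions hold, not that the
assumptions hold in nature.

## Numerical choices

* Variance denominators are $n-1$ throughout (unbiased sample estimators).
* Eigenvector signs follow the largest-magnitude-coefficient-positive rule
  so outputs are reproducible.
* Near-singular G-matrices (reciprocal condition number below 1e-12,
  configurable) are a hard error in conditional evolvability: a silent
  pseudo-inverse would bias $c$ downward invisibly; reduce the trait set
  instead.
* Direction vectors are auto-normalized, with a warning when the input
  length deviates from 1 by more than 1e-8.
* Matrix CSVs are validated for symmetry (tolerance 1e-8 on read);
  asymmetries within tolerance are averaged and reported.
* Directions with non-positive projected variance (possible for estimated
  matrices) are dropped from case regressions with a logged count; slope
  SEs error out if more than half the Monte-Carlo pairings degenerate.
* Multivariate D estimation uses complete cases; incomplete populations
  are an error by default, listwise-dropped (with a message) on request.
* Species and study random intercepts are crossed (study identifiers are
  unique across species, making crossed and nested equivalent here);
  ecotype-assigned populations are treated as ordinary populations.
* Studies without a usable geographic distance lose their rows by default
  (`distance_policy = "drop"`) rather than entering as log(0);
  median imputation is the alternative.

## Validation problem sizes

The test suite validates slope recovery on 100 independent neutral worlds
of 200 studies each (the corrected slope's 95% CI covers 1 in well over
90% of replicates, and the mean $d/e$ diagnostic sits within 0.1 of 1);
the estimation-noise bias ordering (D > P > G grand slopes) on a 30-case
ensemble; brute-force cofactor/OLS oracles at $k \le 3$ to 1e-10; and
G-resampling unbiasedness with its leading-eigenvalue bias at 10,000
draws. These sizes were chosen to make the Monte-Carlo checks decisive at
desk scale; `scripts/acceptance.R` re-runs the same computations from a
command-line seed.

## Known limitations

* The headline numbers of the empirical literature depend on a compiled
  database of hundreds of published estimates; the package validates its
  machinery on synthetic ground truth instead of re-deriving those
  numbers.
* Bayesian error-corrected estimation of G and D from individual-level
  data is out of scope; matrices are inputs, with the simple sample
  covariance provided for D.
* No phylogenetic mixed models: species enter as exchangeable random
  intercepts.
* Conditional evolvability is computed against the full supplied G-matrix;
  scenarios conditioning on trait subsets are not implemented.
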