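---
title: "Genomic prediction for Striga resistance breeding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for Striga resistance breeding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strigaGS)
```

## The breeding problem

*Striga hermonthica* is an obligate root parasite of maize that can destroy
most of a crop in infested fields of sub-Saharan Africa. Resistance is
polygenic, and phenotyping requires artificially infested nurseries whose
area is scarce, so only a small fraction of candidate doubled-haploid (DH)
lines can ever be testcrossed and field-scored. Genomic selection offers a
way out: phenotype a modest training set of testcrosses under infestation,
genotype the whole DH population, and predict breeding values for the lines
that never reach the field. `strigaGS` implements that analysis chain end to
end: trait derivation from plot records, mixed-model analysis of
alpha-lattice trials, a genomic relationship matrix (GRM) from dominant
markers, a Bayesian reaction-norm genotype-by-environment (G×E) model
fitted by Gibbs sampling, and the CV0/CV1/CV2 sparse-testing
cross-validation schemes.

## Derived traits

Plots are scored for emerged *Striga* plants at 8, 10 and 12 weeks after
planting (WAP), for *Striga* damage on a 1 (healthy) to 9 (scorched) scale
at 10 and 12 WAP, and for ear weight and grain moisture.

* **AUSNPC** — the area under the *Striga* number progress curve — is the
  trapezoid-rule integral of the emerged counts over time,
  $\sum_i \tfrac{y_i + y_{i-1}}{2}(t_i - t_{i-1})$. Scoring dates given in
  WAP are converted to days at 7 days/week, so the 8/10/12 WAP schedule
  becomes 56/70/84 days. The quantity has units of count·days; field
  reports sometimes label it in m² because counts are taken on a fixed plot
  area — the number is the same, only the label differs, so the package
  reports the formula's value and leaves labelling to the user.
* **SDR** is the arithmetic mean of the two damage ratings.
* **Grain yield** converts plot ear weight to t/ha assuming an 80%
  shelling fraction and adjusting to 12.5% moisture, on a default plot of
  4 m × 0.75 m = 3 m² (configurable).

## Trial mixed models

Single-site analysis of an alpha-lattice trial uses
$y = \mu + G_i + R_j + B_{k(j)} + \varepsilon$, with replicates and
incomplete blocks nested in replicates random. Across sites,
$y = \mu + G_i + E_j + R_{k(j)} + B_{l(jk)} + GE_{ij} + \varepsilon$ with
environment fixed and everything else random. Each trait is fitted twice:
genotype random for variance components and BLUPs, genotype fixed for the
BLUEs that feed genomic prediction. REML fitting is delegated to `lme4`,
the standard tool for exactly these models; the package's own tests verify
that on balanced designs the REML components coincide with the closed-form
expected-mean-squares ANOVA estimators to 1e-4 relative error.

Two conventions needed a decision the trial description leaves open:

* **Testers.** Each DH line is crossed to two testers. Tester enters both
  fits as a fixed effect and a line's value is its effect averaged over
  testers; no line×tester interaction is modelled, matching how two-tester
  testcross means are normally collapsed to a line value.
* **BLUEs for prediction.** The reaction-norm model carries its own
  environment effects, so the package computes BLUEs per environment
  (single-site model) and stacks one value per line × environment. An
  across-site BLUE path is also available but is not the default.

Broad-sense heritability on an entry-mean basis is
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_\varepsilon / R)$ for a single
environment and
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E +
\sigma^2_\varepsilon/(ER))$ across $E$ environments with $R$ replicates.
The LSD at $\alpha = 0.05$ is $t_{0.975,\nu}\sqrt{2\hat\sigma^2_\varepsilon/(RE)}$
and is reported for completeness only.

```{r herit}
heritability_across(variance_components(181.61, 520.38, sigma2_GE = 32.99,
                                        n_environments = 3, n_replicates = 2))
```

## Markers and the relationship kernel

rAmpSeq tags are dominant: a line either carries a sequence tag (1) or not
(0), and the two presence/absence classes play the allele roles. QC drops
monomorphic/zero-variance tags and tags whose minor-class frequency is
below 0.05. Missing calls are mean-imputed per marker (variance-neutral
under standardization); no imputation model is attempted. Columns are then
centred and scaled to unit **population** variance, and the kernel is the
VanRaden-style cross-product $G = SS^{\top}/p$. Under population-variance
scaling $\operatorname{mean}(\operatorname{diag}(G)) = 1$ exactly, the
GBLUP convention that makes the genomic variance parameter directly
comparable to a genetic variance. $G$ is kept as computed — positive
semidefinite but possibly singular; a ridge is only ever added where an
explicit inverse is required (closed-form checks), never to the stored
kernel.

## The reaction-norm G×E model

The prediction model for the stacked line×environment values is

$$y = Z_E\beta_E + Z_g g + u + e,$$

with $\beta_E \sim N(0, \sigma^2_E I)$ (environments enter as a "dummy"
location effect — no environmental covariates),
$g \sim N(0, \sigma^2_g G)$ over **all** lines, phenotyped or not,
$u \sim N(0, \sigma^2_{g\times E}\, (Z_g G Z_g^{\top}) \circ
(Z_E Z_E^{\top}))$, and $e \sim N(0, \sigma^2_e I)$. The environment effect
is sampled as a random effect with its own variance exactly as its prior is
written, not as a fixed effect.

### Sampler design

`fit_gibbs()` works on the complete grid of all kernel lines × all
environments, in environment-major order. On that grid the interaction
kernel is block-diagonal with one copy of $G$ per environment, so a single
eigendecomposition $G = U D U^{\top}$ (computed once, cached in the design,
shared across cross-validation folds) serves every block. Each Gaussian
block is re-parameterized on the scaled eigenvectors, where its full
conditional is **diagonal**: an iteration costs a few dense matrix–vector
products, $O(L^2)$ after the decomposition. Cells without a phenotype —
unphenotyped lines, masked hold-outs, untested environments — are imputed
from their current conditional each sweep (data augmentation), which is
also what keeps the grid balanced and the conditionals diagonal. Eigenvalues
below `1e-8` of the largest are dropped, so rank-deficient kernels
(clones, more lines than markers) are handled exactly.

Variances get scaled-inverse-χ² full conditionals. Priors follow the usual
Bayesian-GBLUP software convention: `df_prior = 5` for every variance, scale
set so the prior mode is `R2_error = 0.5` of the sample phenotypic variance
for the residual, with the other half split equally over the environment,
genomic and interaction blocks. The schedule defaults to 30,000 iterations,
15,000 burn-in, thinning 10 — 1,500 retained draws (the count is floored
when the schedule does not divide evenly). The chain is fully reproducible
from its seed; a diverging variance draw aborts with the iteration index.

GEBVs are posterior means: unphenotyped lines are carried inside $G$ during
sampling (joint approach) rather than kriged afterwards, so their draws come
from the exact joint full conditional. The across-environment GEBV is
$\hat\mu + \overline{\beta_E} + \hat g + \bar u$; per-environment values
substitute the specific environment's effect and interaction.

## Cross-validation

* **CV0** — leave one environment out entirely (one fold per environment):
  accuracy of predicting tested lines in an untested environment. The
  held-out environment's $\beta_E$ and $u$ have no data, so its prediction
  is effectively $\hat\mu + \hat g$ — the model's conditional mean for a
  new environment.
* **CV1** — 20% of lines masked in *all* environments per fold: accuracy
  for brand-new lines.
* **CV2** — 20% of line×environment cells masked uniformly per fold, with
  a repair step guaranteeing every line keeps at least one observed
  environment: the sparse-testing scenario.

Accuracy is the raw Pearson correlation between observed and predicted
values on the held-out cells, computed per environment within each fold and
averaged over folds (pooling across folds would mix fold-specific
calibrations). The across-environment summary is the pair-count-weighted
mean of the per-environment accuracies; the weighting rule behind published
"weighted r" columns is rarely stated, and pair-count weights are the
natural convex choice — the weight rule is exposed in
`weighted_across_r()`. Folds contributing fewer than 3 pairs in an
environment are skipped there with a warning.

## The synthetic-data generator

`simulate_markers()` draws each marker's presence frequency uniformly from
the configured minor-class range (or its complement) and enforces it
exactly by permutation fill. `simulate_trial()` generates one plot per
line × tester × environment × replicate from the across-site model used
for analysis. Design choices:

* Marker effects at the causal loci are rescaled so the realized variance
  of line main values equals `var_genetic` **exactly** — recovery tests
  then measure estimator behaviour, not the generator's sampling noise.
* G×E deviations are genomic: within each environment they are drawn from
  $N(0, \texttt{var\_gxe}\, G)$, independently across environments. This is
  the interaction structure the reaction-norm model assumes; drawing them
  iid across lines instead would make the fitted interaction variance
  estimate `var_gxe · mean(1/d)` (with `d` the kernel eigenvalues) rather
  than `var_gxe`.
* Testers are fixed additive offsets (SD $=\sqrt{\texttt{var\_genetic}}/2$);
  no line×tester interaction, consistent with collapsing testcross pairs.
* Count-like traits are `round(pmax(0, latent))` of the Gaussian latent —
  raw *Striga* counts are analysed with Gaussian models after a normality
  check, so the generator produces near-Gaussian counts; `trait_kind`
  leaves the choice to the user rather than guessing an unstated
  transformation.

Defaults mirror a realistic screening campaign: 606 lines, 5,000 dominant
markers with minor-class frequency in (0.05, 0.5], 3 locations × 2
replicates × 2 testers, incomplete blocks of 4, variance components at the
magnitudes seen for emerged-count traits (σ²_G = 80, σ²_GE = 23,
σ²_ε = 323), and 300 causal markers ("many genes of small effect").
Environment, replicate and block variances (40/10/20) are not reported for
such trials and were set once at magnitudes typical of lattice trials
(moderate relative to error). `simulate_striga_dataset()` wraps this into a
deposited-style multi-trait table (counts at three dates, two ratings, ear
weight + moisture) sharing one field layout and marker panel, with
per-trait variances at published across-site magnitudes and nuisance
variances scaled in proportion to each trait's error variance.

What the generator deliberately does **not** emulate: linkage
disequilibrium, family/pedigree structure among DH lines, selection,
location-specific error variances, *Striga* population dynamics, or
line×tester interaction. Passing tests therefore demonstrate correctness of
the estimators under the models' own assumptions, not robustness to every
feature of real field data — real maize panels have strong family structure
that typically makes genomic prediction *easier* than under this
generator's iid-marker panels.

## Validation design and problem sizes

The test suite checks every computational path against an independent
oracle: the GRM against a brute-force double loop, AUSNPC against numerical
trapezoid integration on 1,000 random series, balanced-design REML against
closed-form ANOVA estimators, and the Gibbs sampler with frozen variances
against the closed-form GBLUP solution (and, during development, against a
brute-force numerically integrated exact posterior on a tiny instance).
Stochastic end-to-end checks use 300-line, 3-environment experiments at a
reduced 3,000-iteration schedule: variance-component recovery averages
posterior means over 20 generator seeds, and the cross-validation ordering
check (CV2 > CV1 > 0 on a trait with entry-mean H² ≈ 0.6; accuracy centred
on 0 for pure noise) uses 10 folds. The recovery experiment uses a 600-tag
panel (p/L = 2): separating σ²_g×E from σ²_e at one observation per cell is
informative only through the kernel's eigenvalue dispersion, and a p ≫ L
panel (G ≈ I) would make the interaction variance unidentifiable regardless
of the sampler.

## Known limitations

* **Interaction-variance identifiability.** With a single value per
  line×environment cell, σ²_g×E and σ²_e are separated only by the kernel's
  eigenvalue spread. The df = 5 prior with mode at (1−R2)/3 of the
  phenotypic variance — roughly twice a typical interaction variance —
  therefore pulls the posterior mean of σ²_g×E upward noticeably (about
  +30% at the recovery-test conditions, while σ²_g and σ²_e recover within
  5–10%). This is a property of the model and prior at this design, not of
  the implementation (which matches the exact posterior); with replicated
  cells or weaker priors the pull shrinks. Predictions are much less
  affected than the variance decomposition.
* Heritability is broad-sense on an entry-mean basis; no standard errors
  for variance components and no significance testing are provided.
* No spatial (row–column/AR1) modelling, no heterogeneous per-environment
  error variances, no multi-trait model, no marker-effect models (Bayes
  A/B/Cπ), no environmental covariates.
* MCMC convergence is not adaptively tested; the schedule is fixed and the
  user is expected to scale it to the problem.
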