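# strigaGS

Genomic prediction for *Striga* resistance breeding in tropical maize.

*Striga hermonthica* is a parasitic weed that can take 20–100% of the maize
crop in infested regions of sub-Saharan Africa. Because resistance
phenotyping requires artificially infested nurseries of limited area, only
a small training set of doubled-haploid (DH) testcross hybrids can be
field-scored; the rest of the population must be selected on genomic
estimated breeding values (GEBVs). `strigaGS` implements that analysis end
to end:

* **Trait derivation** — area under the *Striga* number progress curve
  (AUSNPC, trapezoid rule over emerged counts at 8/10/12 weeks after
  planting), average damage rating (SDR, 1–9 scale), and grain yield from
  ear weight (80% shelling, adjusted to 12.5% moisture).
* **Trial mixed models** — single-site
  `y = mu + G + R + B(R) + e` and across-site
  `y = mu + G + E + R(E) + B(ER) + GE + e` alpha-lattice models fitted by
  REML (via lme4), giving BLUEs, BLUPs, variance components and broad-sense
  heritability `H^2 = s2G / (s2G + s2GE/E + s2e/(E*R))`.
* **Genomic relationship matrix** — dominant presence/absence markers are
  QC-filtered (monomorphic and minor-class frequency < 0.05 removed),
  column-standardized, and combined as `G = S S' / p` (VanRaden-style;
  mean diagonal exactly 1).
* **Reaction-norm G×E model** — `y = ZE betaE + Zg g + u + e` with
  `g ~ N(0, s2g G)` over all lines (tested and untested) and
  `u ~ N(0, s2gxE (Zg G Zg') # (ZE ZE'))`, fitted by a Gibbs sampler with
  eigendecomposition-based block updates and data augmentation for
  unobserved cells (default schedule 30,000 iterations, 15,000 burn-in,
  thinning 10).
* **Sparse-testing cross-validation** — CV0 (leave one environment out),
  CV1 (new lines) and CV2 (lines untested in some environments), with
  per-environment and pair-count-weighted across-environment Pearson
  accuracy.
* **Synthetic trials** — a generator for dominant marker panels and
  multi-location alpha-lattice testcross trials with user-set variance
  components, so the whole chain is testable with known truth.

See `vignettes/striga-genomic-prediction.Rmd` for the models, priors,
numerical choices and limitations.

## Worked example

Simulate a 150-line, 3-location screening campaign, analyse one trait, and
predict GEBVs for 50 lines that were never phenotyped:

```r
library(strigaGS)

cfg <- sim_config(n_lines = 150, n_markers = 1500, n_environments = 3,
                  n_replicates = 2, block_size = 4, n_testers = 2, seed = 42)
ds   <- simulate_striga_dataset(cfg)
phen <- derive_traits(ds$phenotypes)

fit_across_sites(phen, "str10wap")
#> Trait summary:str10wap
#>   sigma2_G = 55.06 sigma2_GE = 20.06 sigma2_error = 258.1
#>   H2 = 0.526  LSD05 = 18.2  (150 lines)
```

The genotypic variance, G×E variance and entry-mean heritability
(`H2 = 0.53` here) tell you whether selection on this trait is worthwhile
before any genomics. Now the genomic step:

```r
grm   <- compute_grm(impute_markers(qc_markers(ds$markers)))
blues <- blues_by_environment(phen, "str10wap")
trn   <- sort(unique(blues$line))[1:100]           # 100 phenotyped lines

des  <- build_design(blues[blues$line %in% trn, ], grm)
fit  <- fit_gibbs(des, iterations = 6000, burn_in = 3000, thin = 10, seed = 42)
gebv <- predict_gebv(fit, des)
head(gebv[, 1:4], 4)
#>     line set      g_main     gebv
#> 1 DH0001 TRN -13.2729111 14.79715
#> 2 DH0002 TRN   0.7606773 31.67450
#> 3 DH0003 TRN  -0.7432701 30.11136
#> 4 DH0004 TRN  -1.1079398 29.35469
```

`g_main` is a line's genomic main effect (deviation from the population
mean; for an emerged-*Striga* count, negative is good — DH0001 supports ~13
fewer parasites), `gebv` its predicted trait value averaged over
environments. The 50 unphenotyped lines (`set == "TST"`) get GEBVs through
the relationship matrix alone, and their distribution matches the training
set (means 30.7 vs 30.6 here), as expected when both sets come from one
population. Sparse-testing accuracy:

```r
run_cv(blues[blues$line %in% trn, ], grm, "CV2", n_folds = 10,
       seed = 42, iterations = 3000, burn_in = 1500, thin = 10)
#> Cross-validation accuracy (CV2, 10 folds)
#>    E1    E2    E3
#> 0.520 0.443 0.504
#> Across environments (weighted r): 0.487
```

An across-environment accuracy near 0.5 for a trait with `H2 ≈ 0.5` means
masked line×environment cells are predicted about as well as the trait's
repeatability allows — the sparse-testing regime works. `run_pipeline()`
wraps all of the above (plus CV0/CV1 and multi-trait reports) behind one
seeded, fully reproducible configuration.

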