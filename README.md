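# smokesig

Smoking changes the circulating metabolome, and some of those changes sit on
the causal path to type 2 diabetes. **smokesig** implements the full
inference chain connecting the three, for epidemiologists and biostatisticians
who want the analyses as tested, reusable functions rather than one-off
scripts:

1. **Metabolome-wide screen** — per-metabolite linear models of smoking
   status (current/former/never) adjusted for lifestyle covariates, with an
   *effective number of tests* correction: the significance level is
   `0.05 / m_eff`, where `m_eff` is the number of principal components
   explaining >99% of metabolite variance.
2. **Mendelian randomization confirmation** — two-sample MR per screened
   metabolite using smoking-initiation instruments: allele harmonization,
   Wald ratios `b_Y / b_X`, inverse-variance-weighted pooling (identical to
   zero-intercept weighted least squares), Cochran-Q heterogeneity, and
   MR-PRESSO simulation-based pleiotropy detection with outlier-corrected
   re-estimation. A metabolite is confirmed when screen and MR agree in
   direction and MR p < 0.05.
3. **Metabolic signature** — residualize confirmed metabolites on
   covariates, fit an elastic net for current-vs-never smoking with
   10-fold CV over an (alpha, lambda) grid, score any cohort as the weighted
   residual sum, and validate by the smoking semi-partial R² at baseline,
   repeat assessment, an external cohort (pure coefficient transfer), and
   internal–external cross-validation across assessment centers.
4. **Survival** — Cox models on the *attained-age* time scale with delayed
   entry (left truncation), baseline hazard stratified on entry-age bands ×
   sex, Efron ties.
5. **Mediation** — natural direct/indirect effects of smoking on diabetes
   through the signature via a weighted marginal structural Cox model
   (data expansion + mediator density-ratio weights), with
   `proportion mediated = log HR_NIE / log HR_total` and participant-level
   bootstrap CIs.
6. **Gene–environment interaction** — weighted-allele genetic risk scores
   with quintile categories (low / intermediate / high), joint 3×2 hazard
   ratio tables, additive interaction as
   `RERI = HR11 − HR10 − HR01 + 1` with a delta-method CI, and a
   multiplicative-interaction likelihood-ratio test.

Because the biobank cohorts these methods target are access-restricted, the
package includes a seeded synthetic cohort generator
(`cohort_config()` / `simulate_cohort()`) with the full statistical
structure the pipeline assumes — confounded three-level smoking, a
latent-factor metabolome with factor-aligned smoking effects, GRS genotypes,
and left-truncated Weibull survival with either log-linear or exact
cell-planted hazards — so every stage is testable against known truth.

## Worked example

```r
library(smokesig)
report <- run_pipeline(config = cohort_config(), seed = 1)
report
```

```
<pipeline_report> (seed 1)
  cohort: 18070 analysed (20000 generated), 461 events
  screen: m_eff = 66 (alpha 7.58e-04); 149 selected; 122 confirmed by MR; 64 in signature
  signature R2 by smoking: baseline 6.73%, repeat 1.21%, external 6.12%
  IECV R2 range: 5.45% - 6.90%
  HR current vs never: 1.83 (1.39-2.41)
  HR per SD signature: 1.20 (1.09-1.31)
  mediation: total 1.79, NDE 1.61, NIE 1.11, mediated 17.8%
  RERI (high GRS): 0.64 (-0.33-1.61); multiplicative LRT p = 0.647
```

Reading this: of 249 metabolites, 66 principal components explain >99% of
the variance, so the screen threshold is 0.05/66; 149 metabolites pass it
and 122 are direction-consistent and significant in MR; the elastic net
keeps 64 of them. Smoking explains ~7% of the signature's variance at
baseline, less at the repeat visit (smoking effects partially reverse after
quitting), and a comparable share in a transfer-scored external cohort.
Current smokers have ~1.8× the diabetes hazard of never smokers; weighting
the expanded data by the mediator density ratio splits that into a direct
HR of 1.61 and an indirect (through-signature) HR of 1.11. The proportion
mediated through the *learned* signature is noisy at ~460 events and
attenuated relative to the generator's true-mediator path (38% of the
excess log-hazard): the fitted score measures the true signature with
error, and classical measurement error in a mediator shifts part of the
indirect effect into the direct effect. The mediation test suite therefore
checks recovery against the true mediator, where the estimator is
unbiased. The additive interaction between a high genetic risk score and a
high signature is positive but imprecise at this cohort size, with no
evidence of multiplicative interaction.

Each stage is also exposed directly (`screen_metabolites()`, `mr_ivw()`,
`mr_presso()`, `build_signature()`, `compute_signature()`, `fit_cox()`,
`natural_effects()`, `joint_interaction()`, ...), takes a data frame first
and returns tibbles or objects with `tidy()` / `glance()` / `autoplot()`
methods, so results chain with the pipe. See the methods vignette
(`vignettes/smoking-metabolome-diabetes.Rmd`) for the models, assumptions
and design choices.

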