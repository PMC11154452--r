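# busulfanpk

Population pharmacokinetics of twice-daily intravenous busulfan in
(mostly pediatric) hematopoietic stem cell transplantation.

Busulfan conditioning targets a narrow cumulative exposure window
(cAUC 45–70 mg·h/L for reduced-intensity, 80–100 mg·h/L for myeloablative
regimens), while clearance varies widely between children *and decreases
over the first days of therapy*. This package implements the full analysis
pipeline for that problem:

- a **structural model**: one-compartment superposition of intravenous
  infusions in which the elimination rate constant declines exponentially
  over therapy time,
  `k*(t) = k (1 + d_k (1 − exp(−κ_k t)))`,
  applied per dosing interval as the exact time-average `k′` at the
  interval midpoint (`k_inst()`, `k_avg()`, `concentration()`);
- **covariate functions** (`bsa()`, `tbw()`, `ffm()`, `fmat()`,
  `derive_covariates()`): body surface area, total body water, fat-free
  mass and the sigmoid maturation function of postmenstrual age
  `F_mat = 1/(1 + (PMA/46)^−2.3)`;
- **non-compartmental analysis** per measured dosing interval (`nca()`):
  log-linear terminal slope, trapezoidal AUC/AUMC with tail extrapolation,
  C_max, CL = dose/AUC, V, t½, MRT;
- a **SAEM engine** for nonlinear mixed-effects estimation (`fit_saem()`),
  with importance-sampling `-2LL` (`loglik_is()`), empirical Bayes
  estimates and shrinkage;
- the **model-building workflow** (`build_basic_model()`,
  `forward_select()`, `backward_eliminate()`, `test_comedication()`) with
  the study thresholds (Δ-2LL 3.84 to enter, 6.63 to stay, minimum effect
  0.1, shrinkage cap 0.4, 24 h co-medication window);
- **diagnostics**: `icwres()`, `npde()`, `vpc()`, `bootstrap_fit()`,
  `train_test_split()`, `covariate_stripped_cl()`, `dose_linearity()`,
  `simulate_cl_trend()`, plus `autoplot()`/`plot_*()` graphics;
- a **synthetic cohort generator** (`simulate_cohort()`) emulating the
  study design — 124 mostly pediatric subjects, twice-daily 3 h/4 h
  infusions, exposure-targeted dosing with therapeutic drug monitoring,
  rich sampling after morning infusions — so every stage is testable
  without confidential patient data.

The fitted study parameters ship as `bu_final_model()`: typical
V = 11.7 L and k = 0.365 1/h at the reference covariates (TBW 10 L,
albumin 30 g/L, 3 h infusions), TBW on V (effect 0.931) and k (−0.189),
maturation and albumin on k, ALL reducing k by ~19%, HLH/XLP amplifying
the time decline from −0.167 to −0.312, κ_k = exp(−2.965) (half-life of
the change ≈ 13.4 h), additive residual SD 0.076 mg/L.

## Worked example

```r
library(busulfanpk)

# a study-like synthetic cohort, fully reproducible from the seed
cohort <- simulate_cohort(bu_cohort_spec(n_subjects = 124), seed = 1)
ds <- cohort$dataset
ds
#> <bu_dataset> 124 subjects, 812 doses, 2184 observations
#> provenance: synthetic cohort (simulate_cohort)

# non-compartmental exposure per measured interval
head(nca(ds), 3)
#> # A tibble: 3 × 15
#>   subject_id interval  dose     k   auc  aumc  cmax    cl     v t_half   mrt
#> 1 S001              2  53.3 0.268  9.77  51.1  1.76  5.46  20.4   2.59  5.23
#> 2 S001              4  69.1 0.265 14.3   77.5  2.54  4.83  18.3   2.62  5.42
#> 3 S002              1 126.  0.345  8.81  42.6  2.06 14.3   41.5   2.01  4.84

# fit the final covariate model by SAEM (reduced iterations shown)
fit <- fit_saem(ds, bu_final_model_spec(),
                saem_settings(n_explore = 600, n_smooth = 100, seed = 1))
round(fit$theta[c("lnV_0", "lnk_0", "dk_0", "lnkappa")], 3)
#>   lnV_0   lnk_0    dk_0 lnkappa
#>   2.496  -1.034  -0.189  -3.187

exp(fit$theta[["lnV_0"]])   # typical distribution volume, L
#> [1] 12.14
100 * -fit$theta[["dk_0"]]  # average % reduction of k (and CL) at steady state
#> [1] 18.9
```

The interpretation: the engine recovers the simulating model on this
cohort — a typical subject distributes busulfan in ~12 L, eliminates with
k ≈ 0.36/h, and loses roughly a fifth of clearance over the first 2–3 days
(half-life of the change ≈ 13–17 h) — which is why repeated exposure
measurement and dose adjustment stay necessary.

The time trend of clearance implied by the model, with population bands:

```r
autoplot(simulate_cl_trend(bu_final_model(), n = 100000, horizon = 72))
```

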