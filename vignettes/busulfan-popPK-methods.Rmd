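---
title: "Methods: population pharmacokinetics of twice-daily intravenous busulfan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of twice-daily intravenous busulfan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(busulfanpk)
```

# The problem

Busulfan-based conditioning before hematopoietic stem cell transplantation
targets a narrow cumulative exposure window (cAUC 45–70 mg·h/L for
reduced-intensity, 80–100 mg·h/L for myeloablative regimens). In children
the pharmacokinetics are highly variable between patients — and between
doses of the same patient: clearance typically *falls* over the first days
of therapy. This package implements a complete population-PK workflow for
twice-daily intravenous busulfan: a structural model with a time-varying
elimination rate constant, covariate/maturation functions,
non-compartmental exposure estimation, SAEM-based mixed-effects fitting
with stepwise covariate selection, model diagnostics, and a synthetic
cohort generator that emulates the therapeutic-drug-monitoring (TDM) study
design, so that the whole pipeline is testable without confidential
clinical data.

# Structural model

Plasma concentration is the superposition of all past infusions of a
one-compartment model with distribution volume $V$:

$$C(t) = \sum_{j} \frac{R_{0,j}}{k'(t)\,V}
  \left(1-e^{-k'(t)\,t_{\mathrm{inf}}}\right) e^{-k'(t)\,t_{\mathrm{el}}},$$

where $R_{0,j}$ is the infusion rate of dose $j$, $t_\mathrm{inf}$ the
elapsed infusion time (capped at the infusion duration, 3 h or 4 h) and
$t_\mathrm{el}$ the time since that infusion ended. The elimination rate
constant declines exponentially over therapy time with amplitude $d_k$
(typically negative) and rate $\kappa_k$:

$$k^*(t) = k\,\bigl(1 + d_k(1 - e^{-\kappa_k t})\bigr).$$

Within a dosing interval the model uses a constant rate — the exact time
average of $k^*$ evaluated at the interval midpoint $t_\mathrm{mid}$:

$$k'(t) = k(1+d_k) + k\,d_k\,\frac{e^{-\kappa_k t_\mathrm{mid}}-1}
  {\kappa_k\,t_\mathrm{mid}},$$

so that $k'$ can change between, but not within, dosing intervals. This
deliberately prevents the time trend from mimicking a second compartment.
The average is implemented as the exact integral of $k^*$ (the two limits
$k'(0)=k$ and $k'(\infty)=k(1+d_k)$ pin it down); `k_avg()` is tested
against numeric quadrature at $10^{-10}$. Interval membership is half-open:
an observation at exactly the next infusion start belongs to the next
interval. The final interval of a schedule (no successor) uses its start
plus half the subject's median inter-dose gap as $t_\mathrm{mid}$ (6 h
under 12-hourly dosing) — a choice the data cannot distinguish from nearby
alternatives, made once and kept configurable through `bu_schedule()`.

# Covariates

Body-size and maturation covariates are computed by `derive_covariates()`:
body surface area $\sqrt{HW/3600}$, total body water
$\exp(-2.952 + 0.551\ln W + 0.796\ln H + 0.008\,\mathrm{age} -
0.047\,\mathrm{female})$, sexed fat-free mass, and the sigmoid maturation
function of postmenstrual age $F_\mathrm{mat} = 1/(1+(\mathrm{PMA}/46)^{-2.3})$
(0.5 at 46 weeks, 0.85 at 98 weeks). Postmenstrual age adds a fixed 40
gestational weeks to postnatal age; years are converted at 52.1775
weeks/year (the mean calendar year — the source protocol did not state a
conversion, so this is fixed here and documented). Continuous covariates
enter the model centered on rounded population-typical references (TBW
10 L, albumin 30 g/L, infusion duration 3 h); missing values are replaced
by the reference, i.e. their centered term is zero, with a warning.

The packaged final model (`bu_final_model()`) carries the fitted fixed
effects, diagonal random-effect variances on $\ln V$, $\ln k$ and $d_k$
($\kappa_k$ has none — its shrinkage exceeded 0.6 when tried), the additive
residual SD $\sigma = 0.076$ mg/L (interpreted here as mg/L; the units were
not stated with the estimate), and the bootstrap confidence intervals.

# Estimation: SAEM

`fit_saem()` implements stochastic approximation EM. The individual vector
$\phi_i = (\ln V_i, \ln k_i, d_{k,i})$ follows
$\phi_i = X_i\theta + \eta_i$, $\eta_i \sim N(0, \mathrm{diag}\,\Omega^2)$,
with an additive residual error model (a proportional model was rejected in
this application). Each iteration:

1. **Simulation.** Random effects are refreshed by Metropolis–Hastings — an
   independent proposal from the prior plus componentwise random walks
   whose scales adapt toward ~40% acceptance. Draws violating
   $1 + d_k > 0$ are rejected.
2. **Stochastic approximation.** Sufficient statistics ($\phi$, $\phi^2$,
   residual sum of squares) are updated with step size 1 during the
   exploration phase and $1/\mathrm{iter}$ during smoothing.
3. **Maximization.** Fixed effects of parameters with random effects are
   weighted-least-squares solutions of the $\phi$ statistics; variances and
   $\sigma^2$ have closed forms, annealed during exploration (at most a 5%
   decrease per iteration) to avoid premature collapse.

Parameters *without* inter-individual variability ($\ln\kappa_k$ and any
co-medication effect) are handled the standard way for SAEM: they are
sampled per subject like the others but with a fictive variance that is
kept moderate during exploration and collapsed during smoothing, and their
fixed effect is the mean of the sampled values. Because the likelihood is
nearly flat along a $(d_k,\kappa_k)$ ridge at this sampling design, a
damped local profile step (a one-dimensional residual-sum-of-squares
minimization within ±0.3, weight 0.3) accelerates travel along the ridge;
without it the pair converges an order of magnitude more slowly.

Start values follow the study protocol: $\ln V = 2.5$, $\ln k = -1$,
$d_k = 0$, $\ln\kappa_k = \ln(\ln 2/24)$ (a 24 h half-life of the change),
optionally perturbed within ±1 for replicate runs; bootstrap refits use the
fixed starts. Iteration counts are 2000/300 (exploration/smoothing) for
final fits and 600/100 during model building; `-2LL` is computed by
importance sampling (`loglik_is()`) with a scaled Student-t proposal around
each subject's conditional mean. Likelihood comparisons of nested models
use a common seed so that Monte-Carlo error partially cancels. Empirical
Bayes estimates are conditional means from continued sampling at the final
estimates; shrinkage is $1-\mathrm{var}(\hat\eta)/\Omega^2$.

Parameter uncertainty is reported through the nonparametric bootstrap
(`bootstrap_fit()`, subject-level resampling, percentile intervals), which
is the authoritative interval source here; no asymptotic standard errors
are computed for fits.

# Model building

`build_basic_model()` compares static against dynamic elimination (3 added
parameters, $\chi^2_3$ critical value 7.82). `forward_select()` is greedy:
per round, every remaining candidate is added singly, and the best is kept
only if it lowers `-2LL` by more than 3.84 ($\chi^2_1$, p = 0.05) *and* its
maximal effect across the observed covariate range is at least 0.1 on the
log scale (~10%). Alternative body-size metrics compete for the same slot
and leave the pool together. `backward_eliminate()` removes each covariate
singly and keeps it only if removal raises `-2LL` by more than 6.63
(p = 0.01). Co-medication effects are fixed effects active for dosing
intervals whose infusion started within 24 h after an administration
(`test_comedication()`), with the same inclusion criteria. Ties in `-2LL`
at equal degrees of freedom resolve by candidate order, which is the
documented order of `bu_candidate_covariates()`.

# Non-compartmental analysis

`nca()` estimates, per measured dosing interval: the elimination rate
constant as the negative log-linear slope of the descending phase (all
samples strictly after the interval's observed $C_\mathrm{max}$; at least
3 by default — the descending-phase definition is standard practice, the
source protocol does not define it); AUC and AUMC by linear trapezoids
(the unqualified "trapezoidal method" is read as linear). The first
interval is extrapolated to infinity with a mono-exponential tail whose
rate comes from the last three samples (the AUMC tail is
$C(t_n)t_n/k_n + C(t_n)/k_n^2$, reading the printed "t" as $t_n$);
subsequent intervals integrate between infusion starts under a
steady-state assumption, log-linearly extrapolating the endpoint when the
last sample comes early. Clearance is dose/AUC, $V$ = dose/(AUC·k),
half-life $\ln 2/k$, MRT = AUMC/AUC with interval-relative times.

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions, fixed before any
fitting: 124 subjects; 72% male; ages 0.2–27 y log-uniform with 18% under
1 y; disease mix ALL 10%, AML 10%, CGD 26%, HLH/XLP 11%,
hemoglobinopathies 10%, PID 11%, metabolic 6%, neuroblastoma 5%, other
11%; albumin uniform 19–50 g/L; hematocrit 0.17–0.41; leukocytes
log-uniform 0.16–20.9 G/L; infusion duration 3 h (65%) or 4 h (the earlier
study arm, 35%). Weight and height come from a coarse built-in
growth-by-age table with correlated lognormal scatter — deliberately not
an external growth standard; it only needs to induce the realistic
W–H–age–TBW correlation structure. Heights are not reported for the study
population, so this component is a stated approximation.

Dosing is 12-hourly; the first dose targets an AUC of 10.5 mg·h/L (the
midpoint of the 9–12 window) using the population-predicted clearance, and
the number of doses (4–10) is set so the planned cumulative AUC lands in
the regimen window. Morning/evening start is randomized 50/50 (the study
found no effect of dose parity); only morning doses are sampled, at
pre-dose and 0/30/60/120/240/360 min after infusion end; the number of
measured doses is drawn with median 3 (capped by available mornings).
With TDM enabled, after each measured interval the remaining doses are
rescaled by the non-compartmental AUC toward the cumulative target — at
the full design this reproduces the study's totals (~2400 concentrations,
median 3 measured doses).

Simulated concentrations add $N(0,\sigma)$ noise and truncate at zero.
Truncation creates ties at zero among pre-dose samples; the npde
computation therefore uses smoothed ranks with randomized tie-breaking.

**What the generator does not emulate:** assay error structure beyond
additive noise, within-day clinical sampling deviations, correlated
comorbidity patterns, real co-medication schedules (timestamps are planted
by tests as needed), and genetic covariates. Passing tests therefore show
the pipeline is correct *under the stated model*, not that the model is
true of any particular clinic's data.

# Diagnostics

`icwres()` gives conditional individual weighted residuals;
`npde()` normalized prediction distribution errors (decorrelation by
simulated mean/Cholesky covariance per subject, smoothed ranks);
`vpc()` a visual predictive check at raw sampling times (no binning),
flagging time points with fewer than 5 observations;
`covariate_stripped_cl()` re-fits without chosen covariates and compares
subject-level to population-predicted clearance (two-sided Student's t for
the ALL contrast, OLS slope for albumin); `dose_linearity()` relates
dose-normalized AUC of the third/fifth/seventh interval to the first,
excluding even-numbered measured doses; `simulate_cl_trend()` samples
$d_k \sim N(\hat d_k, \Omega_{d_k})$ and
$\kappa_k \sim N(\hat\kappa_k, \mathrm{SE}\cdot\sqrt{n})$ (negative draws
rejected and redrawn — the model requires $\kappa_k>0$ and the source is
silent on the point) to band the relative clearance trajectory
$1 + d_k(1-e^{-\kappa_k t})$.

A practical caveat found while validating: **self-simulation diagnostics
require non-adaptive designs.** Under TDM the realized doses depend on the
realized residuals, so re-simulating with fixed doses but fresh random
effects is not exchangeable with the observed data, and VPC coverage
degrades even when the model is exactly true. Calibration checks in the
test suite therefore simulate cohorts with `tdm = FALSE`; diagnostics on
TDM data remain useful but conservative.

# Numerical choices and problem sizes

Tolerances: the structural model matches closed forms at $10^{-6}$
relative and the averaged rate constant matches quadrature at $10^{-10}$;
NCA recovers clearance within 5% at the study sampling schedule (the
discretization bound of linear trapezoids there). Degenerate inputs are
rejected with informative errors (all-zero concentrations, fewer than 2
subjects, non-positive durations); intervals failing NCA point rules are
reported rather than fatal.

The stochastic test suite and the acceptance script use scaled problem
sizes chosen once: parameter-recovery checks fit 4–6 cohorts of 124
subjects at 1000 exploration / 150 smoothing iterations (reduced from the
2000/300 final-fit protocol, enough for the slow-converging
$(d_k,\kappa_k)$ pair); null-data selection calibration uses 4 seeds with
two candidate covariates; planted-structure recovery uses 2 replicates at
150/40 iterations. At these sizes the Monte-Carlo error of the
importance-sampling `-2LL` is a few units, which is why the
covariate-selection checks assert recovery of the dominant structure
(the strongest planted effects, no decoys) rather than the complete
covariate set in every replicate — mirroring the original analysis, where
a 75%-training subset likewise failed to confirm the weakest covariate.

# Known limitations

Random effects are diagonal (per-parameter variances only); no
inter-occasion random effects — occasion-to-occasion change is carried
entirely by the deterministic $k'(t)$ trend; a two-compartment structural
model is out of scope (it was tested and rejected in the source analysis);
`-2LL` values are Monte-Carlo estimates and small differences between
non-nested models should not be over-read; fit standard errors are not
reported (use the bootstrap).
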