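# kinclust

Model-based classification of longitudinal biomarker trajectories with
two-compartment kinetic models and a Classification-EM algorithm.

## The problem

After curettage of a hydatidiform mole, women are monitored with repeated
hCG measurements; in most, hCG falls in two exponential phases, but
residual trophoblastic tissue can keep producing hormone and progress to
gestational trophoblastic neoplasia (GTN).  With only 2–6 irregularly
timed measurements per woman in the first 21 days, single values or
simple rules are unreliable.  `kinclust` classifies whole trajectories:
the cohort is modeled as `G` latent groups, each with a *typical
trajectory* given by the plasma compartment of the kinetic system

```
mu1'(t) = -(k12 + k10) mu1(t) + k21 mu2(t) + r(t)
mu2'(t) =   k12 mu1(t) - k21 mu2(t)
```

with `mu1(0) = mu10`, `mu2(0) = 0` and residual production `r(t) = 0`,
`A`, or `A*t`.  The transfer/elimination constants `k12, k21, k10` are
shared by all groups (normal physiology); `mu10` and `A` are
group-specific, with `A = 0` pinned in the lowest group.  Measurements
are Gaussian on the log scale.  Parameters and hard group assignments
`z` are estimated jointly by maximizing the classification
log-likelihood

```
l_c(Y; alpha, pi, z) = sum_i sum_g z_ig log( pi_g f_g(Y_i; alpha_g) )
```

with the CEM algorithm (E-step posteriors, C-step argmax, constrained
Levenberg–Marquardt M-step), initialized by a stochastic-EM chain.  The
group with the highest trajectory level is read as predictive of GTN,
and the resulting test is evaluated by stratified k-fold
cross-validation.  An unconstrained bi-exponential model
(`c e^{a t} + c2 e^{a2 t}` per group) is included as the non-biological
competitor, and a synthetic-cohort generator plus simulation harness
validate estimation and classification end to end.

Intended users: biostatisticians modeling sparse longitudinal biomarkers
for diagnosis (hCG after mole evacuation, PSA after prostatectomy, and
similar settings).

## Worked example

```r
library(kinclust)

## a synthetic 300-subject cohort from the frozen canonical scenario
scenario <- canonical_scenario(n_subjects = 300)
cohort   <- simulate_cohort(scenario, seed = 1)
cohort
#> <cohort> 300 subjects, 1057 measurements (per subject: median 3, range 2-6)
#>   labeled; disease prevalence 7.3%

## fit the 4-group compartment model with constant residual production
fit <- cem_fit(cohort, scenario$spec,
               fit_config(seed = 1, n_restarts = 12, n_successful_chains = 2))
fit
#> <cem_fit> compartment, G = 4 (converged in 4 iterations)
#>   l_c = -1519.15  loglik = -1500.34  BIC = 3080.5  AIC = 3028.7  ICL = 3118.1
#>   group sizes (ascending trajectory level): 25-137-121-17

round(fit$structure$kinetics, 3)
#>   k12   k21   k10
#> 0.817 0.312 0.722

## the top-level group is the disease prediction
accuracy(classify_disease(fit), cohort$labels)
#> <accuracy> tp=13 fp=4 fn=9 tn=274
#>   sensitivity 59.1%  specificity 98.6%  PPV 76.5%  NPV 96.8%  classification rate 95.7%
```

The fitted kinetic constants sit near the generating values
(0.7, 0.25, 0.6 per day), the four recovered group sizes track the
generating mixture, and the top-group rule keeps specificity and NPV
high — the qualitative profile this classification is designed for
(sensitivity is limited at this noise level because the two highest
groups overlap).  `stratified_kfold_cv()` gives the
cross-validated version of the same metrics; `select_models()` fits the
whole candidate grid (G = 2–4, constant/linear production, shared or
per-group variance, plus the bi-exponential competitor) and tabulates
log-likelihood, BIC/AIC/ICL and accuracy per candidate;
`run_sensitivity()` checks stability against perturbed initial
classifications.

A thin command-line front-end is installed at
`inst/cli/kinclust.R` (`fit`, `select`, `cv`, `simulate`,
`sensitivity` subcommands).

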