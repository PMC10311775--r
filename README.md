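# rehabdyn

Hierarchical Bayesian dynamic modelling of upper-extremity motor outcomes
during and after rehabilitation in chronic stroke.

## The problem and the model

Clinicians planning motor therapy after stroke need long-term forecasts of a
patient's outcome under a given training schedule, with honest uncertainty.
`rehabdyn` implements a three-level hierarchical Bayesian dynamic model of
the Motor Activity Log (MAL, a 0–5 self-reported quality-of-movement score)
observed repeatedly over weeks.

**Level 1 (within-subject dynamics).** A latent motor memory `x` evolves
weekly under retention, supervised training and self-training:

    x[t+1] = alpha * x[t] + beta * u[t]      if u[t] > 0   (training week)
    x[t+1] = alpha * x[t] + gamma * m[t]     otherwise     (self-training)

    m[t]   = 10 / (1 + exp(-0.2 * x[t])) - 5

where `u[t]` is the training dose delivered that week (hours), `alpha` in
(0, 1) is the retention rate (values near 1 mean little forgetting),
`beta >= 0` the learning rate, and `gamma >= 0` the self-training rate that
feeds the predicted MAL `m` back into memory during rest weeks.  The
fixed-slope sigmoid keeps every predicted MAL inside the instrument's 0–5
range.  There is no process noise; observed MAL values follow a Student-t
around `m[t]` with shared scale `sigma_mal` and degrees of freedom `nu` to
absorb outlying self-reports.

**Level 2 (between subjects).** `logit(alpha_i) ~ N(theta_alpha,
sigma_alpha)`, `beta_i` and `gamma_i` are truncated-normal, and the initial
memory is regressed on the baseline MAL, `x0_i ~ N(k * MAL_ini_i,
sigma_ini)`, all truncated to nonnegative values.

**Level 3 (population).** Weakly-informative hyper-priors: normal on the
location parameters (`theta_alpha ~ N(2, 1)` encodes a median retention
near 0.86), inverse-gamma on the scales, a truncated normal on `k`, and
`nu ~ Gamma(2, 0.1)`.

Around the model the package provides synthetic DOSE-like (four dose arms
over three training bouts, 14 assessments) and EXCITE-like (immediate vs
one-year-delayed 60 h, 9 assessments) trial generators, an adaptive
Metropolis-within-Gibbs sampler written in C++ (see the methods vignette),
rank-normalised split R-hat / bulk–tail ESS / prior–posterior overlap
diagnostics, WAIC and Pareto-smoothed importance-sampling LOO model
comparison, leave-one-subject-out forecast evaluation with Bayesian
forecasting RMSE and permutation tests, and the dose efficacy, efficiency,
decay and self-training threshold analyses.

## Worked example

```r
library(rehabdyn)

## a small synthetic DOSE-like cohort (8 subjects, 2 per dose arm)
coh <- simulate_cohort(trial_design("dose", n_subjects = 8), seed = 3)
fit <- hbdm(coh, chains = 2, iter = 30000, warmup = 6000, thin = 12, seed = 1)
fit
```

```
Hierarchical Bayesian dynamic MAL model
  structure: dynamic full
  subjects: 8   weekly grid: 0 .. 37   observations: 112
  chains: 2   kept draws/chain: 2000 (iter 30000, warmup 6000, thin 12)
  sampler: rehabdyn adaptive MwG 1.0.0   seed: 1   elapsed: 38.2s
  max rank-normalised split R-hat: 1.019

Population-level posterior (median [95% CI]):
  theta_alpha     2.292 [   1.389,    3.267]
  sigma_alpha     0.517 [   0.244,    1.123]
  theta_beta     -0.758 [  -2.208,    0.051]
  sigma_beta      0.403 [   0.215,    0.718]
  theta_gamma    -0.613 [  -2.221,    0.354]
  sigma_gamma     0.408 [   0.209,    0.830]
  k               3.066 [   2.635,    3.454]
  sigma_ini       0.843 [   0.427,    1.683]
  sigma_mal       0.247 [   0.206,    0.291]
  nu             20.381 [   5.945,   60.055]
```

The population block says the typical retention rate is `plogis(2.29)`
≈ 0.91 per week in this cohort, the baseline MAL maps to initial memory
with slope ≈ 3.1, and the measurement scale is ~0.25 MAL points.
Per-subject estimates and fit quality:

```r
head(coef(fit), 3)
#   subject_id     alpha       beta     gamma       x0
# 1        S01 0.9131844 0.08203974 0.1617514 3.054245
# 2        S02 0.9028159 0.07285840 0.1203785 7.417796
# 3        S03 0.9248100 0.19756674 0.1682871 5.743462

f <- fitted(fit)
point_rmse(f$fitted, f$mal_obs)
# [1] 0.2302942        # ~5% of the 0-5 MAL range
plot(fit)              # trajectories with 95% credible bands
```

A counterfactual dosing question — what if subject S01 had received 22 h of
training every week from week 2 on?

```r
predict(fit, subjects = "S01", schedule_hours = rep(c(0, 22), c(2, 36)))
```

Forecasting a "new" patient from baseline only, with the full cohort as
prior information:

```r
scen <- forecast_scenarios(coh$design)
fc <- loso_forecast(coh, "S01", scen$baseline_only, seed = 1)
fc$bf_rmse          # per-week Bayesian forecasting RMSE
```

Model criticism and comparison:

```r
diagnostics_report(fit)
fit0 <- hbdm(coh, model = hbdm_model("no_learning"),
             chains = 2, iter = 3000, warmup = 1500, seed = 1)
compare_models(full = fit, no_learning = fit0)
```

A command-line wrapper for the same pipeline is installed at
`system.file("cli", "rehabdyn.R", package = "rehabdyn")` with subcommands
`simulate`, `fit`, `compare`, `forecast`, `evaluate` and `report`.

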