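# iiwbias

Quantifying the bias introduced into inverse-intensity weighted GEEs
(IIW-GEEs) when subjects with **no follow-up assessments** are dropped from
a longitudinal analysis with irregular, outcome-dependent assessment times.

## The problem

Longitudinal outcomes are often observed only when a patient is assessed,
and assessment frequency may depend on disease severity.  IIW-GEEs handle
this: an Andersen–Gill proportional-intensity model

λᵢ(t) = λ₀(t) · exp{Zᵢ(t) γ₀}

is fitted to the assessment process, and the marginal outcome model
E{Yᵢ(t) | Xᵢ(t)} = Xᵢ(t) β₀ is estimated from the working-independence
estimating equation with each observed assessment weighted by
exp{−Zᵢ(t) γ̂}.  Because subjects with Nᵢ(τ) = 0 contribute no terms to the
outcome estimating equation, dropping them cannot change β̂ *for a fixed
γ̂* — but it does change γ̂: their at-risk intervals vanish from the
partial-likelihood risk sets while the events all remain, and that bias in
γ̂^FU (the "follow-up only" estimate, versus γ̂^EV from everyone)
propagates into the weights, β̂, and derived estimands such as the area
under the mean trajectory, AUC = ∫₀^τ μ(t) dt — the average disease burden.

The package provides

- `simulate_cohort()` — cohorts whose assessment intensity depends on the
  last observed outcome, under a declining-mean and a constant-mean
  mechanism (disease-activity-score scale, Gaussian trajectories with
  random intercept/slope and an exponential-correlation residual with
  nugget);
- `iiwgee()` — the flagship fit (counting process → intensity fit under
  the `"EV"` or `"FU"` inclusion scheme → inverse-intensity weights →
  weighted GEE → AUC), with `print`, `summary`, `coef`, `vcov`,
  `predict`, `fitted`, `residuals`, `plot` methods; the pieces
  (`build_counting_process()`, `fit_intensity()`, `compute_weights()`,
  `solve_iiw_gee()`, `auc_from_beta()`) are exported individually;
- `gamma_bias_closed_form()`, `s_moments()`, `no_followup_prob()`,
  `beta_bias_first_order()`, `bias_curve()` — the analytic bias theory for
  time-invariant intensity covariates (Bernoulli, standard Normal,
  Gamma(1,1)), both the exact population limit and its first-order Taylor
  form;
- `run_scenario()` / `run_grid()` / `calibrate_lambda0()` — the Monte
  Carlo experiment harness comparing the EV and FU schemes;
- a command-line interface (`run_cli()`, installed script
  `inst/scripts/iiwbias`) with `simulate`, `fit-intensity`, `fit-gee`,
  `bias-theory`, and `experiment` subcommands reading/writing plain CSV
  with provenance headers.

## Worked example

```r
library(iiwbias)
coh <- simulate_cohort(400, outcome_spec(1), visit_spec(), seed = 42)
coh
#> Simulated cohort: 400 subjects, 1086 follow-up assessments
#>   zero-follow-up subjects: 22 (5.5%)
#>   lambda0 = 0.5, gamma0 = 0.5, tau = 2, seed = 42

summary(iiwgee(coh, scheme = "EV"))
#> Scheme EV: 400 subjects (22 with no follow-up), 1086 assessments, tau = 2
#>
#> Assessment-intensity model (log intensity ratios):
#>   Estimate     SE
#> z   0.4112 0.1061
#>
#> Outcome model (cluster-robust SEs, weights fixed):
#>             Estimate Robust SE      z Pr(>|z|)
#> (Intercept)   3.3989    0.4573 7.4323        0
#> X1            3.9005    0.4228 9.2258        0
#> X2           10.6212    2.4109 4.4054        0
#>
#> AUC over [0, 2]: 12.5895 (SE 0.1701)
```

The intensity coefficient (≈0.41) estimates how strongly the log of the
last observed outcome drives assessment frequency (truth 0.5 here); the
outcome coefficients recover the simulated declining trajectory
(truth 3.3, 4, 10.5), and the AUC estimates the true average burden
`true_auc(2, 1)` = 12.42152.  Refitting with `scheme = "FU"` drops the 22
zero-follow-up subjects from the intensity fit and shifts γ̂ to 0.4095 —
this cohort's realisation of the omission effect.

The analytic counterpart, for a time-invariant Bernoulli(0.5) covariate at
γ₀ = 0.5 and Λ₀ = λ₀τ = 1:

```r
gamma_bias_closed_form("bernoulli", gamma0 = 0.5, lambda0 = 0.5, tau = 2)
#> [1] -0.245116      # exact population limit of gamma-hat(FU) minus gamma0
bias_curve("lambda0", "bernoulli", grid = c(0.1, 0.5, 0.9))   # |bias| falls
```

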