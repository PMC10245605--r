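# covadjust

Power and sample-size simulation for covariate-adjusted time-to-event
randomized trials.

## What problem this solves, and for whom

Adjusting the primary Cox analysis of a randomized trial for a
prespecified baseline prognostic covariate sharpens the treatment-effect
estimate, which can be converted into a smaller trial at the same target
power. For continuous outcomes the saving is the classical
Fleiss relation $N_{adj} = N_0\,(1 - r^2)$; for time-to-event outcomes
there is no closed form, and the saving depends jointly on the covariate's
prognostic strength (its C-index $C$) and on the cumulative incidence
$\Lambda$ of events by end of follow-up. `covadjust` is for trial
statisticians and methodologists who want to quantify that saving for a
planned design by direct simulation, and to predict it from data at the
design stage via survival $R^2$ measures.

The package simulates two-arm trials from a Weibull proportional-hazards
model with hazard multiplier

$$h_i(z) = \theta^z \exp(\kappa + \beta x_i), \qquad
T_i = (-\log U_i / h_i)^{1/w},$$

with exponential drop-out at rate $d$ and administrative censoring at the
follow-up horizon. The auxiliary parameters $(\kappa, \beta)$ are
calibrated so the control arm attains prespecified $(\Lambda, C)$ — by
default $C$ is Harrell's C as it would be estimated under the trial's own
censoring, computed analytically by quadrature. Monte-Carlo power curves
for the unadjusted and covariate-adjusted Wald tests then locate the
sample sizes $N_0$ and $N_{adj}$ at 80% power, giving the observed
reduction $R^2_{obs} = 1 - N_{adj}/N_0$. Around this core the package
provides:

* a panel of eight survival $R^2$ measures (Cox-Snell and per-event
  likelihood-ratio forms, prognostic-index variance ratios, the
  Royston–Sauerbrei $D$-based measures, and an explained-randomness
  information-gain measure) with the generalized Fleiss prediction
  $N_{adj} = N_0 (1 - R^2_{CS})$;
* eligibility-broadening experiments comparing restricted vs broad
  enrollment, with and without adjustment, at matched event counts;
* semi-synthetic trial simulation from a fitted Cox model with Breslow
  baseline (stratified randomization, step-function inversion), plus a
  synthetic generator for an HCC-like cohort with a continuous prognostic
  score (5-year incidence ≈ 0.49, clinical C-index ≈ 0.65 rising to
  ≈ 0.70 with the score);
* a grid orchestrator with deterministic per-point seeding and resumable
  CSV persistence.

## Worked example

```r
library(covadjust)

sc  <- trial_scenario(theta = 0.7, Lambda_target = 0.9, C_target = 0.65,
                      w = 1.5, d = 0.01)
cal <- calibrate_scenario(sc)
cal
#> Calibrated: kappa = -1.370539, beta = 0.587312
#>   achieved Lambda = 0.900000 (gap 8.97e-13), C = 0.650000 (gap 2.08e-14)

res <- run_reduction(cal, reps = 2000, seed = 1)
res
#> N0 = 426, Nadj = 300, R2_obs = 29.6% (2000 reps per probe)
```

A trial with a covariate of C-index 0.65 in a setting where 90% of
control patients would have an event by 5 years needs 426 patients
unadjusted but only 300 adjusted — a 29.6% reduction. The design-stage
prediction from the Cox-Snell measure:

```r
m <- average_r2(cal, reps = 200, n = 1000, seed = 3)
fleiss_predict(res$N0, m[["r2_cs"]])
#> [1] 334        # r2_cs = 0.218: close to, and conservative for, Nadj = 300
```

The same machinery runs the semi-synthetic workflow:

```r
tab <- generate_surrogate_cohort(328, seed = 5)   # synthetic HCC-like cohort
run_semisynthetic_reduction(tab, theta = 0.72, reps = 1500, seed = 2)
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "covadjust", package = "covadjust")`) with
subcommands `calibrate`, `simulate`, `power`, `reduction`, `r2`,
`surrogate`, `semisynthetic` and `grid`.

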