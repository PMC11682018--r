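# lstema

Latent state–trait reliability of ambulatory cognitive tasks.

`lstema` quantifies how well smartphone-administered cognitive control
tasks — the color Stroop task and the go/no-go task — measure *within-person
fluctuation* when they are embedded in ecological momentary assessment
(EMA) designs with several prompts per day over days or weeks. It is aimed
at researchers who want to know, before relating momentary cognitive
performance to momentary context, mood, or behavior, whether their task
scores carry enough systematic state variance to make such analyses
meaningful.

## The model

Each task score (Stroop incongruent error rate, Stroop RT interference,
go/no-go commission rate, go/no-go mean correct go RT) is measured twice
per prompt via two parallel task blocks. The two block indicators
*Y*<sub>itn</sub> (indicator *i*, occasion *t*, person *n*) follow a
first-order autoregressive latent state–trait model:

```
Y[i,t,n] = xi[n] + OCC[t,n] + beta * time[t] + eps[i,t,n]
OCC[1,n] = zeta[1,n],   OCC[t,n] = phi * OCC[t-1,n] + zeta[t,n]
```

with person trait `xi ~ N(mu, var_trait)`, occasion factor `OCC` shared by
both blocks, innovations `zeta ~ N(0, var_state)`, a linear trait trend
`beta`, and indicator errors `eps ~ N(0, var_error)`. The six parameters
are estimated by maximum marginal likelihood (a sequential state-space
filter that marginalizes missed prompts), and decomposed into:

- **overall reliability** `Rel = (var_trait + var_occ) / var_total`
- **common consistency** `Con = var_trait / var_total` (trait share)
- **occasion specificity** `Spe = var_state / var_total` (state-residual share)
- **within-subject reliability** `Rel_within = var_occ / (var_occ + var_error)`

where `var_occ = var_state * (1 + phi^2 + phi^4 + phi^6 + phi^8)`
approximates the occasion-factor variance by its four-lag accumulation and
`var_total = var_trait + var_occ + var_error`.

Around the model, the package provides the full analysis chain:

- `simulate_scores()` / `simulate_trials()` — synthetic EMA data with
  exactly this latent structure, at block-score level (exact) or raw trial
  level (block aggregates track the latent states), including
  questionnaire/context streams and plantable careless responding;
- `filter_trials()` / `score_blocks()` — trial validity rules (RT < 150 ms
  invalid, RT from correct trials only, at least 10 valid trials per block
  and condition) and block scoring;
- `flag_fast_prompts()` / `longstring()` / `apply_exclusions()` — the three
  careless-responding screens (sub-second mean item time; longest identical
  response run above mean + 3 SD; task error rate above mean + 3 SD) plus
  the minimum-of-5-complete-assessments rule;
- `fit_dsem()` / `compute_indices()` — estimation and the four indices,
  with `tidy()`, `glance()`, `autoplot()` methods;
- `estimate_components()` / `rc()` / `rc_by_trialcount()` / `rc_by_day()` —
  generalizability-theory reliability of change
  `R_c = sigma2_pt / (sigma2_pt + sigma2_e / m)` over the two blocks,
  its curve against trials per block, and its per-day trajectory;
- `within_between_corr()` / `fit_context_model()` — within/between Pearson
  decomposition for convergent validity and multilevel context models with
  the within-subject variance explained by fixed effects;
- `run_pipeline()` — the whole chain on a config or on your own tables.

## Worked example

Simulate a two-week EMA study (40 subjects, 4 prompts/day, ~51%
compliance) at the package's default calibration and fit the go/no-go RT:

```r
library(lstema)

cfg <- ema_config(n_subjects = 40, n_days = 14, seed = 42)
sim <- simulate_scores(cfg)
fit <- fit_dsem(sim$blocks, "gng_rt")
fit
#> AR(1) latent state-trait model fit -- gng_rt
#>   subjects: 40  occasions: 56  logLik: -9459.3306
#>          mu_trait var_trait   beta    phi var_state var_error
#> estimate 282.6933  389.8949 0.0559 0.1844  320.8104   94.0067
#> se         3.3646   90.7675 0.0397 0.0492   16.2543    3.9803
#> indices:
#>    var_occ var_occ_stationary var_total    rel    con    spe rel_within
#> 1 332.0968           332.0968  815.9984 0.8848 0.4778 0.3932     0.7794
```

Read: of the total go/no-go RT variance, 48% is trait (common
consistency), 39% is occasion-specific state variance, and 78% of the
within-person variance is systematic — fluctuations in this score are
measured reliably. The generalizability-theory reliability of change over
the two blocks agrees:

```r
vc <- estimate_components(sim$blocks, "gng_rt")
rc(vc)
#> [1] 0.875224
```

and the two error rates correlate at both levels, as expected for two
inhibition tasks:

```r
occ <- sim$blocks |>
  dplyr::group_by(subject_id, occasion_index) |>
  dplyr::summarise(dplyr::across(c(stroop_er, gng_er), mean), .groups = "drop")
within_between_corr(occ, "stroop_er", "gng_er")
#>   r_between  r_within    p_between     p_within n_subjects n_observations
#> 1 0.5252315 0.1550343 0.0005015947 3.172468e-07         40           1116
```

`autoplot()` on a `dsem_fit`, an `rc_curve`, or an `rc_daily` object draws
the variance decomposition, the reliability-by-test-length curve, and the
per-day reliability trajectory.

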