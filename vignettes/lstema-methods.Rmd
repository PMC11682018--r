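---
title: "Measuring within-person fluctuation of cognitive control in EMA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring within-person fluctuation of cognitive control in EMA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstema)
```

## The problem

Ambulatory (EMA) administrations of cognitive control tasks promise to
relate *momentary* inhibition ability to momentary context and behavior.
Whether that promise can be kept depends on a property classical
reliability does not capture: how much of the occasion-to-occasion
variation in a task score is systematic state variance rather than
measurement noise. `lstema` implements a latent state–trait analysis of
two such tasks — the color Stroop task (incongruent error rate, ER, and
the congruent–incongruent RT interference, RT-Diff) and the go/no-go task
(commission rate on no-go trials and mean correct go RT) — measured in
two parallel blocks per prompt, several prompts per day, over two weeks.

## The latent model

For each score separately, the two block indicators at occasion $t$ of
person $n$ are modeled as

$$Y_{itn} = \xi_n + OCC_{tn} + \beta\,time_t + \epsilon_{itn}, \qquad i = 1,2$$

$$OCC_{1n} = \zeta_{1n}, \qquad OCC_{tn} = \varphi\,OCC_{t-1,n} + \zeta_{tn}$$

with trait $\xi_n \sim N(\mu, \sigma^2_\xi)$ constant over the study,
a latent occasion factor $OCC_{tn}$ shared by both blocks and following
an AR(1) process with innovations $\zeta_{tn} \sim N(0, \sigma^2_\zeta)$,
a linear trait trend $\beta$ capturing practice or fatigue, and
indicator-specific errors $\epsilon_{itn} \sim N(0, \sigma^2_\epsilon)$.
Innovation and error variances are constant over occasions and
indicators; loadings are fixed at one. The time regressor is the 0-based
scheduled prompt index, so $\mu$ is the expected score at the first
occasion.

Assumptions worth spelling out: fluctuation shared by the two blocks of a
prompt is interpreted as state, and disagreement between them as error —
any environmental event that disturbs only one of the two blocks inflates
apparent error variance; the AR(1) slope and all variances are shared
across persons; missing prompts are missing completely at random.

### Variance decomposition

With a stable autoregression, the occasion-factor variance accumulates
geometrically. We approximate it by its four-lag truncation

$$\mathrm{Var}(OCC) \approx \sigma^2_\zeta\,(1 + \varphi^2 + \varphi^4 + \varphi^6 + \varphi^8)
  = \sigma^2_\zeta\,\frac{1 - \varphi^{10}}{1 - \varphi^2},$$

report the exact stationary value $\sigma^2_\zeta/(1-\varphi^2)$ alongside
for sensitivity, and define, with
$\mathrm{Var}(Y) = \sigma^2_\xi + \mathrm{Var}(OCC) + \sigma^2_\epsilon$:

- overall reliability $Rel = (\sigma^2_\xi + \mathrm{Var}(OCC)) / \mathrm{Var}(Y)$,
- common consistency $Con = \sigma^2_\xi / \mathrm{Var}(Y)$,
- occasion specificity $Spe = \sigma^2_\zeta / \mathrm{Var}(Y)$,
- within-subject reliability $Rel_{within} = \mathrm{Var}(OCC) / (\mathrm{Var}(OCC) + \sigma^2_\epsilon)$.

Note that $Con + Spe \le Rel$, with equality exactly at $\varphi = 0$:
the occasion factor carries the autoregressive carry-over of earlier
innovations in addition to the current one. The identity $Rel = Con +
Spe$ sometimes quoted for state–trait decompositions holds only in the
non-autoregressive special case, so `compute_indices()` reports all
quantities without asserting it. Occasion specificity deliberately counts
only the *current* innovation — purely situational influence — while
$Rel_{within}$ counts the whole systematic within-person variance
including carry-over. All four indices are invariant to rescaling the
score's measurement unit.

### Estimation

`fit_dsem()` maximizes the marginal likelihood. Internally the model is a
two-dimensional linear-Gaussian state space (trait, occasion factor), and
the likelihood is evaluated by a Kalman filter that is vectorized across
subjects and processes the two indicators of an occasion sequentially;
missed prompts are marginalized by skipping their update, never imputed.
The filter is exact: the test suite verifies agreement with a direct
joint multivariate-normal evaluation of the same model (built
independently from the covariance closed form, `dsem_covariance()`) to
ten decimal places.

Numerical choices:

- variances are optimized on the log scale and $\varphi$ through
  $\tanh$, enforcing positivity and $|\varphi| < 1$ without constrained
  optimization;
- starting values are method-of-moments (person-mean variance for the
  trait, half the block-difference variance for error), combined with a
  fixed grid of autoregression starts ($\varphi_0 \in \{0, 0.3, 0.6\}$);
  BFGS from each start, best likelihood wins. The procedure is fully
  deterministic given the data;
- standard errors come from the numerical observed information on the
  transformed scale, delta-method-mapped back. At a variance boundary
  (true variance 0) the log-scale estimate diverges to $-\infty$,
  the variance estimate to 0, and its SE is not interpretable — the
  recovery tests cover this case;
- the occasion process is started (`OCC[1] = zeta[1]`), not
  stationary-initialized; `stationary = TRUE` switches both the
  generator and the filter to the stationary alternative;
- subjects contribute only if they have at least `min_occasions = 5`
  occasions with both blocks observed.

## Reliability of change

Complementing the model-based indices, `estimate_components()` and `rc()`
implement the generalizability-theory reliability of change over the $m =
2$ parallel blocks,

$$R_c = \frac{\sigma^2_{p\cdot t}}{\sigma^2_{p\cdot t} + \sigma^2_\epsilon / m},$$

from the two-way random-effects decomposition
$Y = \mu + person + person{\times}occasion + residual$. REML (via
`lme4`) is the primary estimator because EMA data are unbalanced by
missed prompts; on balanced complete data a closed-form expected-mean-
squares estimator is available as a cross-check and the two agree.
Negative method-of-moments components are truncated at zero (raw values
kept in an attribute). `rc_by_trialcount()` recomputes scores from the
first $n$ trials of each relevant condition in presentation order and
re-estimates the components *per n* — the literal reading of asking how
reliability grows with test length. `rc_by_day()` estimates the
components within each day's occasions; under positive autocorrelation
adjacent occasions are similar, so within-day systematic variance — and
hence per-day $R_c$ — is expected to sit below the pooled value even for
a perfectly stable measure.

## Scoring and screening rules

Trial validity: RTs below 150 ms are invalid (strict inequality; a
150 ms trial is valid); RT aggregates use correct, valid trials only;
each block contributes a score only if every relevant condition has at
least 10 valid trials. Practice trials are expected to be absent or
flagged and are dropped. Conventions the literature leaves open, fixed
here and exposed as switches: RT-Diff uses means, not medians; Stroop
non-responses count as errors by default (`stroop_nonresponse =
"missing"` drops them); go-trial omissions are not commissions — they
contribute neither to the no-go error rate nor an RT.

Careless-responding screens, applied in a fixed order: (1) prompts whose
mean questionnaire item time is below 1 s are removed entirely; (2)
prompts with a Stroop-block longstring (longest identical-response run)
above mean + 3 SD are removed; (3) occasions whose occasion-level task ER
exceeds mean + 3 SD lose that task's scores; (4) subjects with fewer than
5 complete assessments (both tasks valid on both blocks) are excluded
from model fitting. The 3 SD moments are computed once, pooled across
subjects, on the dataset remaining after rule (1), and are frozen into
the screening report, which records every flagged unit — re-screening
with the reported thresholds is idempotent, and every removal can be
reconstructed from the report. Two caveats are inherent to 3 SD rules and
documented rather than hidden: on a finite clean sample they flag a small
number of chance outliers (the longstring statistic is discrete and
skewed), and whether the original convention pooled the moments per
study, per subject, or otherwise is not standardized — pooled-per-study
is used and recorded.

## Validity and context analyses

`within_between_corr()` splits a correlation into a between part (Pearson
correlation of unweighted per-subject means) and a within part (Pearson
correlation of person-mean-centered observations pooled over prompts),
with $t$-based two-sided p-values on $N-2$ and $n_{obs}-N-1$ degrees of
freedom. With one observation per subject the between part reduces to the
ordinary Pearson correlation and the within part is undefined.

`fit_context_model()` regresses a task score on beep number (categorical,
first beep as reference), being alone, being outdoors, and tiredness,
with a random intercept per subject (REML). Continuous variables are
within-subject centered and then divided by the pooled (sample) SD of the
centered values — the only reading of "grand-mean standardized after
centering" that yields unit-variance inputs. The within-subject variance
explained is the marginal-$R^2$-style ratio
$\mathrm{Var}(X\hat\beta) / (\mathrm{Var}(X\hat\beta) + \hat\sigma^2_{resid})$
applied to the within-centered outcome; the exact construction is
recorded in the result's metadata because "within-subject variance
explained" is not a uniquely defined quantity. Correlations are reported
with raw p-values; no multiplicity correction is applied.

## The synthetic-data generator

`simulate_scores()` draws block indicators directly from the model
equations — the exact setting for estimator validation.
`simulate_trials()` generates raw trials whose block aggregates track the
same latent structure: error-rate scores live on the logit scale at trial
level (incongruent-error and commission probabilities are the inverse
logit of trait + occasion factor + trend, so block proportions are
unbiased for the latent level), and correct-trial RTs are lognormal with
means equal to the latent RT states. A single RNG stream per dataset is
split into per-subject sub-streams, so results are byte-identical under a
fixed seed and the first $k$ subjects are unchanged when the subject
count grows.

Defaults describe the study conditions the package targets: 70 subjects,
14 days with four prompts (56 scheduled occasions), 51% prompt
compliance (missing completely at random), Stroop blocks of 24 + 24
trials with a 1200 ms deadline, go/no-go blocks of 80 go + 20 no-go
trials with a 650 ms deadline. The per-score model parameters are
calibrated from descriptive levels typical of smartphone administrations
of these tasks — score means and between-person SDs (Stroop ER ≈ .19 ±
.06, RT-Diff ≈ 56 ± 36 ms, go/no-go ER ≈ .34 ± .16, go RT ≈ 288 ±
21 ms) together with variance shares giving moderate consistency for all
scores, low occasion specificity and poor within-subject reliability for
the Stroop scores, and moderate-to-high values for the go/no-go scores.
`params_from_shares()` solves the implied $(\sigma^2_\xi, \sigma^2_\zeta,
\sigma^2_\epsilon, \varphi)$ under the package's own index formulas; the
resulting $\varphi$ is small for the go/no-go scores and large for
RT-Diff, where almost all systematic within-person variance is
carry-over. Small linear trends emulate practice (RT-Diff declining) and
fatigue (go/no-go scores creeping up). The two error-rate scores share
trait ($r = .6$) and innovation ($r = .3$) variance, so the convergent-
validity analyses see realistic attenuated observed correlations
(between ≈ .5, within ≈ .1). Context covariates shift every score's
innovations by a configurable small amount, and the questionnaire stream
is weakly coupled to the go/no-go error latents.

What trial-level mode does *not* reproduce exactly: the block-score error
variance is induced by trial sampling noise (binomial for ERs, lognormal
means for RTs) at the configured trial counts rather than set to the
calibrated $\sigma^2_\epsilon$ — how block-level noise splits into trial
noise versus state variance is not an identified quantity at score level,
so it is exposed as a knob (`rt_trial_sd_*`, trial counts) instead of
asserted. Also absent, deliberately: circadian RT structure, nonlinear
practice curves, post-error slowing, and device timing jitter. Passing
tests on these synthetic data therefore demonstrate correctness of the
estimators and rules under the model's own assumptions, not robustness of
the model to real-data violations of them.

A configurable fraction of prompts is generated as careless — sub-second
item times, a single repeated Stroop response (which yields both a
maximal longstring and an incongruent ER near .75), and a .9 commission
rate — so the screening rules can be exercised with known ground truth.

## Problem sizes used by the test suite

Estimator recovery runs 100 replications at 70 subjects × 56 occasions ×
2 indicators (median estimates within 10% of each true variance, median
$\varphi$ error ≤ .05, implied indices within .03); the likelihood oracle
is checked on 50 random small instances (≤ 5 subjects, ≤ 6 occasions) at
10⁻⁸; variance-component recovery uses 200 subjects × 20 occasions; the
per-day reliability trend check runs 50 replications of a stationary
14-day design and requires a Kendall trend test to be non-significant in
at least 90% of them. Everything runs single-threaded in a few minutes.

## Known limitations

- One score per model: no joint multivariate fit across the four scores,
  no random (person-specific) $\varphi$ or $\beta$.
- The estimator is frequentist ML; a Bayesian backend could be added
  behind the same interface but is not included.
- The trial-to-latent link in trial-level simulation is a modeling
  convenience (logit-additive for ERs, additive in ms for RTs), not an
  empirically validated trial model.
- Standard errors for variance parameters near zero are unreliable, as
  in any boundary ML problem.
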