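#' DSEM parameter set for one task score
#'
#' Bundles the six parameters of the first-order autoregressive latent
#' state-trait model for a single score: the trait mean and variance, the
#' linear time trend, the autoregressive slope of the occasion process, the
#' innovation variance, and the measurement-error variance (shared by the two
#' block indicators).
#'
#' @param mu_trait Trait mean at the first occasion (score units).
#' @param var_trait Between-person trait variance (score units squared).
#' @param beta Linear trend per occasion (score units per occasion); the time
#'   regressor is the 0-based scheduled occasion index, so `mu_trait` is the
#'   expected score at the first occasion.
#' @param phi Autoregressive slope of the latent occasion process,
#'   `abs(phi) < 1`.
#' @param var_state Innovation (state-residual) variance, constant over
#'   occasions (score units squared).
#' @param var_error Measurement-error variance, equal for both block
#'   indicators and constant over occasions (score units squared).
#'
#' @return An object of class `dsem_params` (a named list).
#' @examples
#' dsem_params(var_trait = 1, phi = 0.3, var_state = 0.5, var_error = 0.5)
#' @export
dsem_params <- function(mu_trait = 0, var_trait = 1, beta = 0, phi = 0,
                        var_state = 1, var_error = 1) {
  p <- list(mu_trait = mu_trait, var_trait = var_trait, beta = beta,
            phi = phi, var_state = var_state, var_error = var_error)
  validate_dsem_params(p)
  structure(p, class = "dsem_params")
}

validate_dsem_params <- function(p) {
  for (f in c("mu_trait", "var_trait", "beta", "phi", "var_state", "var_error")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", f, "` must be a single finite number", call. = FALSE)
    }
  }
  for (f in c("var_trait", "var_state", "var_error")) {
    if (p[[f]] < 0) stop("`", f, "` must be non-negative", call. = FALSE)
  }
  if (abs(p$phi) >= 1) stop("`phi` must satisfy abs(phi) < 1", call. = FALSE)
  invisible(p)
}

#' @export
print.dsem_params <- function(x, ...) {
  cat("<dsem_params>\n")
  print(unlist(x))
  invisible(x)
}

# Solve for phi such that var_state * (1 + phi^2 + ... + phi^8) = var_occ.
solve_phi_from_occ <- function(var_occ, var_state) {
  ratio <- var_occ / var_state
  if (ratio <= 1) return(0)
  if (ratio >= 5) stop("var_occ/var_state ratio not attainable with abs(phi) < 1 under the 4-lag truncation")
  uniroot(function(phi) sum(phi^(2 * (0:4))) - ratio,
          interval = c(0, 0.999), tol = 1e-10)$root
}

# Back out dsem_params from a descriptive calibration: score mean, the
# between-person SD of person means, and the three variance shares
# (common consistency, occasion specificity, within-subject reliability).
params_from_shares <- function(mu, sd_between, con, spe, rel_within, beta = 0) {
  var_trait <- sd_between^2
  var_total <- var_trait / con
  var_state <- spe * var_total
  var_occ <- rel_within * (1 - con) * var_total
  var_error <- (1 - rel_within) * (1 - con) * var_total
  phi <- solve_phi_from_occ(var_occ, var_state)
  dsem_params(mu_trait = mu, var_trait = var_trait, beta = beta, phi = phi,
              var_state = var_state, var_error = var_error)
}

#' Default score-level model parameters
#'
#' One `dsem_params` set per task score, calibrated so that the marginal
#' moments mirror a two-week, four-prompts-per-day smartphone study of the
#' color Stroop and go/no-go tasks: score means and between-person SDs at
#' descriptive levels typical for such designs, and variance shares giving
#' moderate common consistency, modest-to-moderate occasion specificity, and
#' within-subject reliability that is poor for the Stroop scores and good for
#' the go/no-go scores. Error rates are proportions in `[0, 1]`; reaction
#' times are in milliseconds.
#'
#' @return Named list of [dsem_params()] for `stroop_er`, `stroop_rtdiff`,
#'   `gng_er`, `gng_rt`.
#' @export
default_score_params <- function() {
  list(
    stroop_er     = params_from_shares(0.191, 0.059, con = 0.513, spe = 0.111,
                                       rel_within = 0.315, beta = 0),
    stroop_rtdiff = params_from_shares(55.8, 35.8, con = 0.376, spe = 0.014,
                                       rel_within = 0.081, beta = -0.2),
    gng_er        = params_from_shares(0.343, 0.159, con = 0.685, spe = 0.161,
                                       rel_within = 0.576, beta = 3e-4),
    gng_rt        = params_from_shares(287.6, 20.5, con = 0.497, spe = 0.372,
                                       rel_within = 0.763, beta = 0.1)
  )
}

#' Synthetic EMA study configuration
#'
#' Defines an ecological momentary assessment study design and the latent
#' model that the synthetic generator emulates. Defaults describe a
#' main-study-scale design: 70 participants, 14 days with four prompts per
#' day (56 scheduled occasions), roughly 51% prompt compliance, Stroop blocks
#' of 24 congruent + 24 incongruent trials, and go/no-go blocks of 80 go +
#' 20 no-go trials.
#'
#' @param n_subjects Number of participants.
#' @param n_days Number of EMA days.
#' @param prompts_per_day Scheduled prompts (beeps) per day.
#' @param compliance_rate Probability that a scheduled prompt is answered.
#' @param seed Integer seed for the dataset-level RNG stream; per-subject
#'   sub-streams are derived from it so that the first `k` subjects are
#'   reproduced when `n_subjects` grows.
#' @param scores Named list of [dsem_params()], one per score; see
#'   [default_score_params()].
#' @param stroop_congruent,stroop_incongruent Stroop trials per block and
#'   condition.
#' @param gng_go,gng_nogo Go/no-go trials per block and condition.
#' @param max_rt_stroop,max_rt_gng Response deadlines in ms.
#' @param base_rt_stroop Mean correct congruent Stroop RT in ms.
#' @param rt_trial_sd_stroop,rt_trial_sd_gng Trial-level SD of correct RTs in
#'   ms. In trial-level data the block-score error variance is induced by
#'   this trial noise and the trial counts rather than set directly.
#' @param congruent_error_rate Error probability on congruent Stroop trials.
#' @param stroop_nonresponse_rate,go_omission_rate Probabilities of giving no
#'   response before the deadline.
#' @param anticipation_rate Probability of an anticipatory (< 150 ms)
#'   response, exercising the trial validity filter.
#' @param careless_fraction Fraction of answered prompts generated as
#'   careless (sub-second questionnaire item times, a single repeated Stroop
#'   response, extreme error rates) to exercise the screening rules.
#' @param context_coef Named numeric vector of effects of the standardized
#'   context covariates (`beep`, `alone`, `outdoors`, `tiredness`) on every
#'   score's occasion process, in units of that score's innovation SD.
#' @param selfreport_within,selfreport_between Target within- and
#'   between-person coupling of the self-report stream with the go/no-go
#'   error latents.
#' @param er_trait_cor,er_state_cor Latent correlation between the Stroop
#'   and go/no-go error-rate traits and between their occasion innovations,
#'   emulating convergent validity of the two inhibition tasks. Observed
#'   score correlations are attenuated below these latent values by
#'   measurement error.
#' @param stationary Logical; start the occasion process from its stationary
#'   distribution instead of `OCC[1] = zeta[1]`.
#'
#' @return An object of class `ema_config` (a named list).
#' @examples
#' cfg <- ema_config(n_subjects = 5, n_days = 2, seed = 1)
#' @export
ema_config <- function(n_subjects = 70, n_days = 14, prompts_per_day = 4,
                       compliance_rate = 0.51, seed = 1,
                       scores = default_score_params(),
                       stroop_congruent = 24, stroop_incongruent = 24,
                       gng_go = 80, gng_nogo = 20,
                       max_rt_stroop = 1200, max_rt_gng = 650,
                       base_rt_stroop = 700,
                       rt_trial_sd_stroop = 120, rt_trial_sd_gng = 60,
                       congruent_error_rate = 0.02,
                       stroop_nonresponse_rate = 0.02,
                       go_omission_rate = 0.03,
                       anticipation_rate = 0.01,
                       careless_fraction = 0,
                       context_coef = c(beep = 0.05, alone = 0.1,
                                        outdoors = 0.05, tiredness = 0.1),
                       selfreport_within = 0.1, selfreport_between = 0.3,
                       er_trait_cor = 0.6, er_state_cor = 0.3,
                       stationary = FALSE) {
  cfg <- list(
    n_subjects = n_subjects, n_days = n_days, prompts_per_day = prompts_per_day,
    compliance_rate = compliance_rate, seed = seed, scores = scores,
    stroop_congruent = stroop_congruent, stroop_incongruent = stroop_incongruent,
    gng_go = gng_go, gng_nogo = gng_nogo,
    max_rt_stroop = max_rt_stroop, max_rt_gng = max_rt_gng,
    base_rt_stroop = base_rt_stroop,
    rt_trial_sd_stroop = rt_trial_sd_stroop, rt_trial_sd_gng = rt_trial_sd_gng,
    congruent_error_rate = congruent_error_rate,
    stroop_nonresponse_rate = stroop_nonresponse_rate,
    go_omission_rate = go_omission_rate,
    anticipation_rate = anticipation_rate,
    careless_fraction = careless_fraction,
    context_coef = context_coef,
    selfreport_within = selfreport_within,
    selfreport_between = selfreport_between,
    er_trait_cor = er_trait_cor, er_state_cor = er_state_cor,
    stationary = stationary
  )
  validate_ema_config(cfg)
  structure(cfg, class = "ema_config")
}

validate_ema_config <- function(cfg) {
  for (f in c("n_subjects", "n_days", "prompts_per_day")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop("`", f, "` must be a positive integer", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$compliance_rate) || cfg$compliance_rate < 0 ||
      cfg$compliance_rate > 1) {
    stop("`compliance_rate` must be in [0, 1]", call. = FALSE)
  }
  for (f in c("stroop_congruent", "stroop_incongruent", "gng_go", "gng_nogo")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop("`", f, "` must be a positive trial count", call. = FALSE)
    }
  }
  for (f in c("careless_fraction", "congruent_error_rate",
              "stroop_nonresponse_rate", "go_omission_rate",
              "anticipation_rate")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  for (f in c("er_trait_cor", "er_state_cor")) {
    if (!is.numeric(cfg[[f]]) || abs(cfg[[f]]) > 1) {
      stop("`", f, "` must be a correlation in [-1, 1]", call. = FALSE)
    }
  }
  if (!is.list(cfg$scores) || is.null(names(cfg$scores)) ||
      any(!nzchar(names(cfg$scores)))) {
    stop("`scores` must be a named list of dsem_params", call. = FALSE)
  }
  for (nm in names(cfg$scores)) validate_dsem_params(cfg$scores[[nm]])
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' The YAML mirrors the arguments of [ema_config()]; the `scores` block maps
#' score names to the six model parameters.
#'
#' @param path Path to a YAML file.
#' @return An `ema_config`.
#' @export
read_ema_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scores)) {
    raw$scores <- lapply(raw$scores, function(p) do.call(dsem_params, p))
  }
  if (!is.null(raw$context_coef)) raw$context_coef <- unlist(raw$context_coef)
  do.call(ema_config, raw)
}

# Total scheduled occasions in a design.
n_occasions <- function(cfg) cfg$n_days * cfg$prompts_per_day

# Prefix-stable per-subject seeds derived from the dataset seed.
subject_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
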