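# Small design used across tests: one generic score with known parameters.
single_score_config <- function(n_subjects = 20, n_days = 4,
                                prompts_per_day = 4, compliance_rate = 1,
                                seed = 1, mu = 0, var_trait = 1, beta = 0,
                                phi = 0.3, var_state = 0.5, var_error = 0.5,
                                stationary = FALSE) {
  ema_config(
    n_subjects = n_subjects, n_days = n_days,
    prompts_per_day = prompts_per_day, compliance_rate = compliance_rate,
    seed = seed, stationary = stationary,
    scores = list(y = dsem_params(mu_trait = mu, var_trait = var_trait,
                                  beta = beta, phi = phi,
                                  var_state = var_state,
                                  var_error = var_error))
  )
}

tiny_trial_config <- function(seed = 1, ...) {
  ema_config(n_subjects = 3, n_days = 2, prompts_per_day = 2,
             compliance_rate = 1, seed = seed,
             stroop_congruent = 12, stroop_incongruent = 12,
             gng_go = 28, gng_nogo = 12, ...)
}

# Direct enumeration of the model-implied covariance between two indicator
# observations, independent of dsem_covariance(): expands
# OCC_t = sum_{j<=t} phi^(t-j) zeta_j term by term.
oracle_cov_entry <- function(p, t1, t2, same_indicator) {
  occ <- 0
  for (j in seq_len(min(t1, t2))) {
    occ <- occ + p$phi^(t1 - j) * p$phi^(t2 - j) * p$var_state
  }
  p$var_trait + occ + (same_indicator && t1 == t2) * p$var_error
}

# Joint-Gaussian log-likelihood oracle via mvtnorm on long block data.
oracle_loglik <- function(params, data, score, T) {
  mc <- dsem_covariance(params, T)
  sum(vapply(split(data, data$subject_id), function(d) {
    idx <- 2 * (d$occasion_index - 1) + d$block
    keep <- !is.na(d[[score]])
    if (!any(keep)) return(0)
    o <- sort(idx[keep])
    y <- d[[score]][keep][order(idx[keep])]
    mvtnorm::dmvnorm(y, mc$mean[o], mc$cov[o, o, drop = FALSE], log = TRUE)
  }, numeric(1)))
}

# Balanced two-way person x occasion draws with known variance components.
simulate_gt_blocks <- function(n_subjects, n_occasions, m = 2,
                               sigma2_person = 1, sigma2_pt = 0.5,
                               sigma2_error = 0.5, seed = 1) {
  set.seed(seed)
  pe <- rnorm(n_subjects, 0, sqrt(sigma2_person))
  pt_ <- matrix(rnorm(n_subjects * n_occasions, 0, sqrt(sigma2_pt)),
                n_subjects, n_occasions)
  tidyr::expand_grid(subject_id = seq_len(n_subjects),
                     occasion_index = seq_len(n_occasions),
                     block = seq_len(m)) |>
    dplyr::mutate(
      day = (occasion_index - 1) %/% 4 + 1,
      y = pe[subject_id] + pt_[cbind(subject_id, occasion_index)] +
        rnorm(dplyr::n(), 0, sqrt(sigma2_error)))
}

make_stroop_trials <- function(subject_id = 1, occasion_index = 1, block = 1,
                               rt_con = numeric(), rt_inc = numeric(),
                               correct_con = TRUE, correct_inc = TRUE) {
  tibble::tibble(
    subject_id = subject_id, occasion_index = occasion_index, block = block,
    task = "stroop",
    condition = rep(c("congruent", "incongruent"),
                    c(length(rt_con), length(rt_inc))),
    rt_ms = c(rt_con, rt_inc),
    correct = c(rep_len(correct_con, length(rt_con)),
                rep_len(correct_inc, length(rt_inc))),
    response_code = "red"
  ) |>
    dplyr::mutate(trial = dplyr::row_number())
}
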