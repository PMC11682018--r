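#' @title Synthetic EMA data generators
#' @description
#' Two generators emulate the latent structure assumed by the state-trait
#' model: [simulate_scores()] draws block-score indicators directly from the
#' model equations (exact, for estimator checks), while [simulate_trials()]
#' draws raw task trials whose block aggregates track the same latent
#' states (approximate, for exercising scoring and screening).
#' @name simulate
NULL

# Trait and innovation draws for one subject and one score.
draw_latents <- function(p, T, stationary = FALSE) {
  xi <- rnorm(1, p$mu_trait, sqrt(p$var_trait))
  zeta <- rnorm(T, 0, sqrt(p$var_state))
  if (stationary && abs(p$phi) < 1 && p$var_state > 0) {
    zeta[1] <- rnorm(1, 0, sqrt(p$var_state / (1 - p$phi^2)))
  }
  list(xi = xi, zeta = zeta)
}

zeta_sds <- function(p, T, stationary) {
  s <- rep(sqrt(p$var_state), T)
  if (stationary && p$var_state > 0) s[1] <- sqrt(p$var_state / (1 - p$phi^2))
  s
}

# Correlate the error-rate latents of the two tasks: replaces the go/no-go
# draws by a mixture preserving their marginals. `a`, `b` are centered
# draws with SD vectors `sa`, `sb`.
mix_correlated <- function(a, b, sa, sb, rho) {
  az <- ifelse(sa > 0, a / sa, 0)
  bz <- ifelse(sb > 0, b / sb, 0)
  sb * (rho * az + sqrt(1 - rho^2) * bz)
}

couple_er_latents <- function(lat, config, T) {
  if (!all(c("stroop_er", "gng_er") %in% names(lat))) return(lat)
  rt <- config$er_trait_cor
  rs <- config$er_state_cor
  if (rt == 0 && rs == 0) return(lat)
  pa <- lat$stroop_er$p
  pb <- lat$gng_er$p
  lat$gng_er$xi <- pb$mu_trait + mix_correlated(
    lat$stroop_er$xi - pa$mu_trait, lat$gng_er$xi - pb$mu_trait,
    sqrt(pa$var_trait), sqrt(pb$var_trait), rt)
  lat$gng_er$zeta <- mix_correlated(
    lat$stroop_er$zeta, lat$gng_er$zeta,
    zeta_sds(pa, T, config$stationary), zeta_sds(pb, T, config$stationary), rs)
  lat
}

# Latent process for one subject and one score. `shift` (length T) is added
# to the innovations (context effects enter here).
simulate_latents_one <- function(p, T, stationary = FALSE, shift = NULL) {
  l <- draw_latents(p, T, stationary)
  zeta <- l$zeta + if (is.null(shift)) 0 else shift
  occ <- as.numeric(stats::filter(zeta, p$phi, method = "recursive"))
  list(xi = l$xi, occ = occ, zeta = zeta)
}

occasion_grid <- function(cfg) {
  T <- n_occasions(cfg)
  tibble::tibble(
    occasion_index = seq_len(T),
    day = (seq_len(T) - 1L) %/% cfg$prompts_per_day + 1L,
    beep = (seq_len(T) - 1L) %% cfg$prompts_per_day + 1L
  )
}

#' Simulate block-score indicators from the latent model
#'
#' Draws, for every subject and scheduled occasion, two parallel block
#' indicators per score as `trait + occasion factor + trend + error` with
#' independent errors of equal variance. Non-answered prompts are emitted
#' with missing indicators but keep their occasion index, so the scheduled
#' grid stays intact. The latent draws are returned for recovery tests.
#'
#' @param config An [ema_config()].
#' @return A list with `blocks` (one row per subject x occasion x block;
#'   one column per score plus validity flags) and `latents` (one row per
#'   subject x occasion x score with `xi`, `occ`, `zeta`, `complied`).
#' @examples
#' sim <- simulate_scores(ema_config(n_subjects = 4, n_days = 2, seed = 1))
#' head(sim$blocks)
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "ema_config"))
  validate_ema_config(config)
  T <- n_occasions(config)
  grid <- occasion_grid(config)
  seeds <- subject_seeds(config$seed, config$n_subjects)
  score_names <- names(config$scores)

  per_subject <- purrr::map(seq_len(config$n_subjects), function(s) {
    set.seed(seeds[s])
    complied <- rbinom(T, 1L, config$compliance_rate) == 1L
    lat <- purrr::map(setNames(score_names, score_names), function(nm) {
      p <- config$scores[[nm]]
      l <- draw_latents(p, T, config$stationary)
      l$p <- p
      l$e1 <- rnorm(T, 0, sqrt(p$var_error))
      l$e2 <- rnorm(T, 0, sqrt(p$var_error))
      l
    })
    lat <- couple_er_latents(lat, config, T)
    lat <- purrr::map(lat, function(l) {
      p <- l$p
      l$occ <- as.numeric(stats::filter(l$zeta, p$phi, method = "recursive"))
      trend <- p$beta * (seq_len(T) - 1)
      y1 <- l$xi + l$occ + trend + l$e1
      y2 <- l$xi + l$occ + trend + l$e2
      y1[!complied] <- NA_real_
      y2[!complied] <- NA_real_
      l$y <- c(y1, y2)
      l
    })
    blocks <- tibble::tibble(subject_id = s,
                             occasion_index = rep(seq_len(T), 2),
                             block = rep(1:2, each = T))
    for (nm in score_names) blocks[[nm]] <- lat[[nm]]$y
    latents <- tibble::tibble(
      subject_id = s,
      score = rep(score_names, each = T),
      occasion_index = rep(seq_len(T), length(score_names)),
      xi = unlist(purrr::map(lat, ~ rep(.x$xi, T)), use.names = FALSE),
      occ = unlist(purrr::map(lat, "occ"), use.names = FALSE),
      zeta = unlist(purrr::map(lat, "zeta"), use.names = FALSE),
      complied = rep(complied, length(score_names)))
    list(blocks = blocks, latents = latents)
  })

  blocks <- dplyr::bind_rows(purrr::map(per_subject, "blocks")) |>
    dplyr::left_join(grid, by = "occasion_index") |>
    dplyr::relocate("day", "beep", .after = "occasion_index") |>
    dplyr::arrange(.data$subject_id, .data$occasion_index, .data$block)
  has_stroop <- any(c("stroop_er", "stroop_rtdiff") %in% names(blocks))
  has_gng <- any(c("gng_er", "gng_rt") %in% names(blocks))
  obs <- !is.na(blocks[[score_names[1]]])
  if (has_stroop) blocks$valid_stroop <- obs
  if (has_gng) blocks$valid_gng <- obs
  latents <- dplyr::bind_rows(purrr::map(per_subject, "latents")) |>
    dplyr::arrange(.data$subject_id, .data$score, .data$occasion_index)
  list(blocks = blocks, latents = latents)
}

# Lognormal draws with a given mean (ms) and SD (ms).
rlnorm_mean <- function(n, mean, sd) {
  mean <- pmax(mean, 1)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Map proportion-scale ER params to the logit scale (delta method).
logit_scale_params <- function(p) {
  f <- 1 / (p$mu_trait * (1 - p$mu_trait))
  dsem_params(mu_trait = qlogis(p$mu_trait), var_trait = p$var_trait * f^2,
              beta = p$beta * f, phi = p$phi,
              var_state = p$var_state * f^2, var_error = p$var_error * f^2)
}

stroop_colors <- c("red", "blue", "green", "yellow")

simulate_stroop_block <- function(cfg, block, er_p, rtdiff, careless) {
  n_c <- cfg$stroop_congruent
  n_i <- cfg$stroop_incongruent
  n <- n_c + n_i
  condition <- sample(rep(c("congruent", "incongruent"), c(n_c, n_i)))
  font <- sample(stroop_colors, n, replace = TRUE)
  if (careless) {
    correct <- font == "red"
    rt <- runif(n, 250, 450)
    code <- rep("red", n)
  } else {
    p_err <- ifelse(condition == "incongruent", er_p, cfg$congruent_error_rate)
    correct <- rbinom(n, 1L, 1 - p_err) == 1L
    mean_rt <- ifelse(condition == "incongruent",
                      cfg$base_rt_stroop + rtdiff, cfg$base_rt_stroop)
    rt <- rlnorm_mean(n, mean_rt, cfg$rt_trial_sd_stroop)
    rt <- pmin(rt, cfg$max_rt_stroop - 1)
    anticip <- runif(n) < cfg$anticipation_rate
    rt[anticip] <- runif(sum(anticip), 50, 149)
    code <- ifelse(correct, font,
                   vapply(font, function(f) sample(setdiff(stroop_colors, f), 1),
                          character(1)))
    nonresp <- runif(n) < cfg$stroop_nonresponse_rate
    rt[nonresp] <- NA_real_
    correct[nonresp] <- FALSE
    code[nonresp] <- NA_character_
  }
  tibble::tibble(task = "stroop", block = block, trial = seq_len(n),
                 condition = condition, rt_ms = rt, correct = correct,
                 response_code = code)
}

simulate_gng_block <- function(cfg, block, er_p, go_rt, careless) {
  n_g <- cfg$gng_go
  n_n <- cfg$gng_nogo
  n <- n_g + n_n
  condition <- sample(rep(c("go", "nogo"), c(n_g, n_n)))
  p_comm <- if (careless) 0.9 else er_p
  is_go <- condition == "go"
  responded <- logical(n)
  responded[is_go] <- runif(n_g) >= cfg$go_omission_rate
  responded[!is_go] <- runif(n_n) < p_comm
  rt <- rep(NA_real_, n)
  rt[responded] <- rlnorm_mean(sum(responded), go_rt, cfg$rt_trial_sd_gng)
  rt[responded] <- pmin(rt[responded], cfg$max_rt_gng - 1)
  if (!careless) {
    anticip <- responded & runif(n) < cfg$anticipation_rate
    rt[anticip] <- runif(sum(anticip), 50, 149)
  }
  correct <- ifelse(is_go, responded, !responded)
  code <- ifelse(responded, "tap", "none")
  tibble::tibble(task = "gng", block = block, trial = seq_len(n),
                 condition = condition, rt_ms = rt, correct = correct,
                 response_code = code)
}

#' Simulate trial-level EMA task data
#'
#' Generates raw Stroop and go/no-go trials whose block aggregates follow
#' the configured latent structure: incongruent-error and no-go commission
#' probabilities are an inverse-logit of `trait + occasion factor + trend`
#' on the logit scale, and correct-trial reaction times are lognormal with
#' means tracking the latent RT states, so expected block scores equal the
#' latent values. A questionnaire stream (item values and per-item
#' completion times) and a context stream (beep, alone, outdoors,
#' tiredness) accompany each answered prompt; an optional fraction of
#' prompts is generated as careless to exercise the screening rules.
#'
#' @param config An [ema_config()].
#' @return A list with tibbles `trials`, `questionnaire`, `context`, and
#'   `latents` (per-occasion latent values of the four scores, plus
#'   `complied` and `careless` flags).
#' @examples
#' sim <- simulate_trials(ema_config(n_subjects = 2, n_days = 1, seed = 1))
#' dplyr::count(sim$trials, task, condition)
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "ema_config"))
  validate_ema_config(config)
  needed <- c("stroop_er", "stroop_rtdiff", "gng_er", "gng_rt")
  missing_scores <- setdiff(needed, names(config$scores))
  if (length(missing_scores)) {
    stop("`scores` must contain parameters for: ",
         paste(missing_scores, collapse = ", "), call. = FALSE)
  }
  T <- n_occasions(config)
  grid <- occasion_grid(config)
  seeds <- subject_seeds(config$seed, config$n_subjects)
  link_params <- list(
    stroop_er = logit_scale_params(config$scores$stroop_er),
    stroop_rtdiff = config$scores$stroop_rtdiff,
    gng_er = logit_scale_params(config$scores$gng_er),
    gng_rt = config$scores$gng_rt
  )
  cc <- config$context_coef

  per_subject <- purrr::map(seq_len(config$n_subjects), function(s) {
    set.seed(seeds[s])
    complied <- rbinom(T, 1L, config$compliance_rate) == 1L
    careless <- complied & rbinom(T, 1L, config$careless_fraction) == 1L
    alone <- rbinom(T, 1L, 0.35)
    outdoors <- rbinom(T, 1L, 0.10)
    tired_z <- rnorm(T)
    tiredness <- pmin(pmax(round(47.5 + 20 * tired_z), 0), 100)
    beep_z <- as.numeric(scale(grid$beep)[, 1])
    if (any(!is.finite(beep_z))) beep_z <- rep(0, T)
    ctx_z <- cc[["beep"]] * beep_z +
      cc[["alone"]] * (alone - 0.35) / sqrt(0.35 * 0.65) +
      cc[["outdoors"]] * (outdoors - 0.10) / sqrt(0.10 * 0.90) +
      cc[["tiredness"]] * tired_z
    lat <- purrr::map(link_params, function(p) {
      l <- draw_latents(p, T, config$stationary)
      l$p <- p
      l
    })
    lat <- couple_er_latents(lat, config, T)
    lat <- purrr::map(lat, function(l) {
      p <- l$p
      zeta <- l$zeta + sqrt(p$var_state) * ctx_z
      l$zeta <- zeta
      l$occ <- as.numeric(stats::filter(zeta, p$phi, method = "recursive"))
      l$level <- l$xi + l$occ + p$beta * (seq_len(T) - 1)
      l
    })
    er_p <- plogis(lat$stroop_er$level)
    comm_p <- plogis(lat$gng_er$level)
    rtdiff <- lat$stroop_rtdiff$level
    go_rt <- pmax(lat$gng_rt$level, 160)

    occ_trials <- purrr::map(which(complied), function(t) {
      dplyr::bind_rows(
        simulate_stroop_block(config, 1L, er_p[t], rtdiff[t], careless[t]),
        simulate_stroop_block(config, 2L, er_p[t], rtdiff[t], careless[t]),
        simulate_gng_block(config, 1L, comm_p[t], go_rt[t], careless[t]),
        simulate_gng_block(config, 2L, comm_p[t], go_rt[t], careless[t])
      ) |>
        dplyr::mutate(occasion_index = t, .before = 1)
    })
    trials <- dplyr::bind_rows(occ_trials)

    items <- c(paste0("webexec_", 1:6), "selfdiscipline", "willpower")
    b_z <- (lat$gng_er$xi - link_params$gng_er$mu_trait) /
      max(sqrt(link_params$gng_er$var_trait), 1e-12)
    w_z <- lat$gng_er$occ / max(sqrt(link_params$gng_er$var_state), 1e-12)
    questionnaire <- purrr::map(which(complied), function(t) {
      val <- pmin(pmax(round(
        25 + 15 * (config$selfreport_between * b_z +
                     config$selfreport_within * w_z[t]) +
          rnorm(length(items), 0, 8)), 0), 100)
      time_s <- if (careless[t]) runif(length(items), 0.3, 0.9) else
        rlnorm_mean(length(items), 3000, 1500) / 1000
      tibble::tibble(occasion_index = t, item = items, value = val,
                     item_time_s = time_s)
    }) |> dplyr::bind_rows()

    context <- tibble::tibble(
      occasion_index = seq_len(T), alone = alone, outdoors = outdoors,
      tiredness = tiredness
    )[complied, ]

    latents <- dplyr::bind_rows(purrr::imap(lat, function(l, nm) {
      tibble::tibble(score = nm, occasion_index = seq_len(T), xi = l$xi,
                     occ = l$occ, zeta = l$zeta, level = l$level)
    })) |>
      dplyr::mutate(complied = complied[.data$occasion_index],
                    careless = careless[.data$occasion_index])

    lapply(list(trials = trials, questionnaire = questionnaire,
                context = context, latents = latents),
           function(d) dplyr::mutate(d, subject_id = s, .before = 1))
  })

  out <- purrr::map(c("trials", "questionnaire", "context", "latents"),
                    function(nm) {
                      dplyr::bind_rows(purrr::map(per_subject, nm)) |>
                        dplyr::left_join(grid, by = "occasion_index") |>
                        dplyr::relocate("day", "beep", .after = "occasion_index")
                    })
  names(out) <- c("trials", "questionnaire", "context", "latents")
  out
}
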