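#' Variance components of the two-way person x occasion design
#'
#' Decomposes block scores `Y[p, t, b]` into person, person-by-occasion,
#' and residual components, `Y = mu + person + person:occasion + residual`.
#' The primary estimator is restricted maximum likelihood via a random-
#' effects model; on balanced complete data a closed-form expected-mean-
#' squares (method-of-moments) estimator is available and agrees with REML.
#' Negative method-of-moments estimates are truncated at zero with a
#' warning (the raw values are kept in the `"untruncated"` attribute).
#'
#' @param data Long block tibble with `subject_id`, `occasion_index`,
#'   `block`, and the score column; missing scores are dropped.
#' @param score Name of the score column.
#' @param method `"reml"` (default, handles unbalanced data) or `"mom"`
#'   (balanced data only).
#' @return A one-row tibble of class `variance_components` with
#'   `sigma2_person`, `sigma2_person_time`, `sigma2_error`, `m` (number of
#'   block replicates), `n_subjects`, `n_occasions`.
#' @examples
#' sim <- simulate_scores(ema_config(n_subjects = 12, n_days = 3, seed = 2))
#' vc <- estimate_components(sim$blocks, "gng_er")
#' rc(vc)
#' @export
estimate_components <- function(data, score, method = c("reml", "mom")) {
  method <- match.arg(method)
  check_columns(data, c("subject_id", "occasion_index", "block", score), "data")
  d <- data[!is.na(data[[score]]),
            c("subject_id", "occasion_index", "block", score)]
  names(d)[4] <- "y"
  if (length(unique(d$subject_id)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  cell_sizes <- dplyr::count(d, .data$subject_id, .data$occasion_index)
  if (all(cell_sizes$n < 2)) {
    stop("all subject-occasion cells have a single block; ",
         "person x occasion and error variance are not separable",
         call. = FALSE)
  }
  m <- length(unique(d$block))
  n_subj <- length(unique(d$subject_id))
  n_occ <- length(unique(d$occasion_index))

  if (method == "mom") {
    occ_per_subj <- dplyr::count(cell_sizes, .data$subject_id)
    if (length(unique(cell_sizes$n)) > 1 ||
        length(unique(occ_per_subj$n)) > 1) {
      stop("method = \"mom\" requires balanced complete data", call. = FALSE)
    }
    T0 <- n_occ
    cell <- dplyr::summarise(
      dplyr::group_by(d, .data$subject_id, .data$occasion_index),
      cell_mean = mean(.data$y),
      cell_ss = sum((.data$y - mean(.data$y))^2),
      .groups = "drop")
    pers <- dplyr::summarise(
      dplyr::group_by(cell, .data$subject_id),
      p_mean = mean(.data$cell_mean),
      p_ss = sum((.data$cell_mean - mean(.data$cell_mean))^2),
      .groups = "drop")
    mse <- sum(cell$cell_ss) / (n_subj * T0 * (m - 1))
    ms_cwp <- m * sum(pers$p_ss) / (n_subj * (T0 - 1))
    ms_p <- m * T0 * var(pers$p_mean)
    raw <- c(person = (ms_p - ms_cwp) / (m * T0),
             person_time = (ms_cwp - mse) / m,
             error = mse)
  } else {
    d$cell <- interaction(d$subject_id, d$occasion_index, drop = TRUE)
    fit <- lme4::lmer(
      y ~ 1 + (1 | subject_id) + (1 | cell), data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    raw <- c(person = vc$vcov[vc$grp == "subject_id"],
             person_time = vc$vcov[vc$grp == "cell"],
             error = stats::sigma(fit)^2)
  }
  comp <- pmax(raw, 0)
  if (any(raw < 0)) {
    warning("negative variance component estimate truncated at 0 (",
            paste(names(raw)[raw < 0], round(raw[raw < 0], 6),
                  collapse = ", "), ")")
  }
  out <- tibble::tibble(sigma2_person = comp[["person"]],
                        sigma2_person_time = comp[["person_time"]],
                        sigma2_error = comp[["error"]], m = m,
                        n_subjects = n_subj, n_occasions = n_occ)
  attr(out, "untruncated") <- raw
  attr(out, "method") <- method
  class(out) <- c("variance_components", class(out))
  out
}

#' Reliability of change
#'
#' The generalizability-theory within-subject reliability
#' `R_c = sigma2_pt / (sigma2_pt + sigma2_e / m)`: the proportion of
#' within-person block-mean variance that reflects shared occasion-to-
#' occasion fluctuation rather than disagreement between the `m` parallel
#' blocks.
#'
#' @param components A `variance_components` row from
#'   [estimate_components()], or any list/tibble with `sigma2_person_time`,
#'   `sigma2_error`, `m`.
#' @return Scalar in `[0, 1]`, or `NA` with a warning when the denominator
#'   is zero.
#' @examples
#' rc(list(sigma2_person_time = 1, sigma2_error = 1, m = 2))
#' @export
rc <- function(components) {
  s_pt <- components$sigma2_person_time
  s_e <- components$sigma2_error
  m <- components$m
  den <- s_pt + s_e / m
  if (!is.finite(den) || den == 0) {
    warning("zero within-person variance; R_c undefined")
    return(NA_real_)
  }
  s_pt / den
}

#' Within-subject reliability as a function of test length
#'
#' Recomputes block scores using only the first `n` trials of each relevant
#' condition (in presentation order), re-estimates the variance components,
#' and evaluates [rc()] for each `n` on a grid — the basis of
#' reliability-versus-trial-count curves. The relevant conditions are
#' `incongruent` (Stroop ER), both Stroop conditions (RT-Diff), `nogo`
#' (go/no-go ER), and `go` (go/no-go RT); `n` runs up to the smallest block
#' count of the score's conditions.
#'
#' @param trials Trial tibble with presentation order column `trial`.
#' @param scores Character vector of scores to evaluate.
#' @param step Grid step for the trials-per-condition counts.
#' @param method Passed to [estimate_components()].
#' @return A tibble of class `rc_curve`: `score`, `n_per_condition`, `rc`,
#'   `sigma2_person_time`, `sigma2_error`.
#' @export
rc_by_trialcount <- function(trials,
                             scores = c("stroop_er", "stroop_rtdiff",
                                        "gng_er", "gng_rt"),
                             step = 2, method = "reml") {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  check_columns(trials, c("task", "condition", "trial"), "trials")
  conds <- list(stroop_er = "incongruent",
                stroop_rtdiff = c("congruent", "incongruent"),
                gng_er = "nogo", gng_rt = "go")
  counts <- dplyr::count(trials, .data$subject_id, .data$occasion_index,
                         .data$task, .data$block, .data$condition)
  rows <- purrr::map(intersect(scores, names(conds)), function(sc) {
    n_max <- min(counts$n[counts$condition %in% conds[[sc]]])
    grid <- seq(step, n_max, by = step)
    task <- if (grepl("^stroop", sc)) "stroop" else "gng"
    purrr::map(grid, function(n) {
      bl <- score_blocks(trials[trials$task == task, ], n_per_condition = n)
      vc <- tryCatch(estimate_components(bl, sc, method = method),
                     error = function(e) NULL)
      if (is.null(vc)) return(NULL)
      tibble::tibble(score = sc, n_per_condition = n, rc = rc(vc),
                     sigma2_person_time = vc$sigma2_person_time,
                     sigma2_error = vc$sigma2_error)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rc_curve", class(out))
  out
}

#' Within-subject reliability per study day
#'
#' Estimates the variance components and [rc()] separately within each
#' day's occasions, to check whether measurement of within-person
#' fluctuation degrades or improves over the study.
#'
#' @param blocks Scored blocks with a `day` column.
#' @param score Name of the score column.
#' @param method Passed to [estimate_components()].
#' @return A tibble of class `rc_daily`: `day`, `rc`, components, and the
#'   numbers of subjects/occasions used. Days on which no subject has two
#'   or more observed occasions are skipped with a warning.
#' @export
rc_by_day <- function(blocks, score, method = "reml") {
  check_columns(blocks, c("day", "subject_id", "occasion_index", "block",
                          score), "blocks")
  days <- sort(unique(blocks$day))
  rows <- purrr::map(days, function(d) {
    bd <- blocks[blocks$day == d & !is.na(blocks[[score]]), ]
    occ_per_subj <- dplyr::count(
      dplyr::distinct(bd, .data$subject_id, .data$occasion_index),
      .data$subject_id)
    if (nrow(occ_per_subj) == 0 || max(occ_per_subj$n) < 2) {
      warning("day ", d, " skipped: fewer than 2 occasions per subject")
      return(NULL)
    }
    vc <- tryCatch(estimate_components(bd, score, method = method),
                   error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    tibble::tibble(day = d, rc = rc(vc),
                   sigma2_person = vc$sigma2_person,
                   sigma2_person_time = vc$sigma2_person_time,
                   sigma2_error = vc$sigma2_error,
                   n_subjects = vc$n_subjects, n_occasions = vc$n_occasions)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rc_daily", class(out))
  out
}
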