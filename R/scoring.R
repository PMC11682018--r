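#' Flag invalid trials
#'
#' Marks anticipatory responses (reaction time below `min_rt` ms) as
#' invalid and drops practice trials. Trials without a registered response
#' (`rt_ms` missing) are kept as valid: on no-go trials a withheld response
#' is the correct behavior, and non-responses elsewhere still enter the
#' error-rate denominators.
#'
#' @param trials Tibble of task trials with columns `task` (`"stroop"` or
#'   `"gng"`), `condition` (`congruent`/`incongruent`/`go`/`nogo`), `rt_ms`,
#'   `correct`; a `practice` column, if present, drops rows with
#'   `practice == 1`.
#' @param min_rt Validity threshold in ms; strictly smaller RTs are invalid.
#' @return The input with a logical `valid` column appended.
#' @examples
#' tr <- tibble::tibble(task = "stroop", condition = "incongruent",
#'                      rt_ms = c(149, 150, NA), correct = c(TRUE, TRUE, FALSE))
#' filter_trials(tr)$valid
#' @export
filter_trials <- function(trials, min_rt = 150) {
  check_columns(trials, c("task", "condition", "rt_ms", "correct"), "trials")
  bad_task <- setdiff(unique(trials$task), c("stroop", "gng"))
  if (length(bad_task)) {
    stop("unknown task value(s): ", paste(bad_task, collapse = ", "),
         call. = FALSE)
  }
  ok <- (trials$task == "stroop" &
           trials$condition %in% c("congruent", "incongruent")) |
    (trials$task == "gng" & trials$condition %in% c("go", "nogo"))
  if (any(!ok)) {
    stop("condition inconsistent with task in ", sum(!ok), " trial(s), e.g. ",
         trials$task[!ok][1], "/", trials$condition[!ok][1], call. = FALSE)
  }
  if ("practice" %in% names(trials)) {
    trials <- dplyr::filter(trials, .data$practice != 1)
  }
  dplyr::mutate(trials, valid = is.na(.data$rt_ms) | .data$rt_ms >= min_rt)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("`", what, "` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# Safe ratio / mean helpers for empty denominators.
ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Score task blocks
#'
#' Aggregates filtered trials into per-block scores: the Stroop error rate
#' on incongruent trials, the Stroop interference score (mean correct
#' incongruent RT minus mean correct congruent RT), the go/no-go commission
#' rate on no-go trials, and the mean correct go RT. A block's scores for a
#' task are reported only when every relevant condition has at least
#' `min_trials` valid trials; otherwise the task's validity flag is `FALSE`
#' and its scores are missing. RT aggregates use correct, valid trials only.
#'
#' @param trials Trial tibble with `subject_id`, `occasion_index`, `block`
#'   plus the columns of [filter_trials()]. The `valid` flag is computed
#'   with `min_rt` when absent.
#' @param min_trials Minimum valid trials per block and condition.
#' @param min_rt Passed to [filter_trials()] when `valid` is absent.
#' @param n_per_condition Optional trial-subset size: scores are computed on
#'   the first `n_per_condition` valid-or-not trials of each condition in
#'   presentation order (requires a `trial` order column), used for
#'   test-length reliability curves. The `min_trials` rule is then waived.
#' @param stroop_nonresponse How to treat Stroop non-responses (missing RT):
#'   `"error"` counts them as errors, `"missing"` drops them from the
#'   error-rate denominator.
#' @return A tibble with one row per subject x occasion x block and the
#'   score, validity-flag, and valid-trial-count columns present for the
#'   tasks found in `trials` (plus `day`/`beep` when present).
#' @examples
#' sim <- simulate_trials(ema_config(n_subjects = 2, n_days = 1, seed = 1))
#' score_blocks(sim$trials)
#' @export
score_blocks <- function(trials, min_trials = 10, min_rt = 150,
                         n_per_condition = NULL,
                         stroop_nonresponse = c("error", "missing")) {
  stroop_nonresponse <- match.arg(stroop_nonresponse)
  check_columns(trials, c("subject_id", "occasion_index", "block"), "trials")
  if (nrow(trials) == 0) stop("`trials` is empty", call. = FALSE)
  if (!"valid" %in% names(trials)) trials <- filter_trials(trials, min_rt)
  if (!is.null(n_per_condition)) {
    if (n_per_condition <= 0) {
      stop("`n_per_condition` must be positive", call. = FALSE)
    }
    check_columns(trials, "trial", "trials")
    trials <- trials |>
      dplyr::arrange(.data$trial) |>
      dplyr::group_by(.data$subject_id, .data$occasion_index, .data$task,
                      .data$block, .data$condition) |>
      dplyr::slice_head(n = n_per_condition) |>
      dplyr::ungroup()
    min_trials <- 1
  }
  extra <- intersect(c("day", "beep"), names(trials))
  keys <- c("subject_id", "occasion_index", extra, "block")
  resp <- !is.na(trials$rt_ms)
  v <- trials$valid
  # incongruent-trial denominator: non-responses optionally dropped
  inc_keep <- v & trials$condition == "incongruent" &
    (stroop_nonresponse == "error" | resp)
  scored <- trials |>
    dplyr::mutate(
      .v_con = v & .data$condition == "congruent",
      .v_inc = inc_keep,
      .v_go = v & .data$condition == "go",
      .v_nogo = v & .data$condition == "nogo",
      .err = !(.data$correct %in% TRUE),
      .rt_ok = v & resp & (.data$correct %in% TRUE),
      .rt = ifelse(resp, .data$rt_ms, 0)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "task")))) |>
    dplyr::summarise(
      n_con = sum(.data$.v_con), n_inc = sum(.data$.v_inc),
      n_err_inc = sum(.data$.v_inc & .data$.err),
      rt_con_sum = sum(.data$.rt[.data$.v_con & .data$.rt_ok]),
      rt_con_n = sum(.data$.v_con & .data$.rt_ok),
      rt_inc_sum = sum(.data$.rt[.data$.v_inc & .data$.rt_ok]),
      rt_inc_n = sum(.data$.v_inc & .data$.rt_ok),
      n_go = sum(.data$.v_go), n_nogo = sum(.data$.v_nogo),
      n_comm = sum(.data$.v_nogo & .data$.err),
      rt_go_sum = sum(.data$.rt[.data$.v_go & .data$.rt_ok]),
      rt_go_n = sum(.data$.v_go & .data$.rt_ok),
      .groups = "drop"
    )
  pieces <- list()
  if (any(scored$task == "stroop")) {
    pieces$stroop <- scored |>
      dplyr::filter(.data$task == "stroop") |>
      dplyr::mutate(
        valid_stroop = .data$n_con >= min_trials & .data$n_inc >= min_trials,
        stroop_er = ifelse(.data$valid_stroop,
                           ratio_or_na(.data$n_err_inc, .data$n_inc), NA_real_),
        stroop_rtdiff = ifelse(
          .data$valid_stroop,
          ratio_or_na(.data$rt_inc_sum, .data$rt_inc_n) -
            ratio_or_na(.data$rt_con_sum, .data$rt_con_n), NA_real_)
      ) |>
      dplyr::select(dplyr::all_of(keys), "stroop_er", "stroop_rtdiff",
                    "valid_stroop", n_valid_congruent = "n_con",
                    n_valid_incongruent = "n_inc")
  }
  if (any(scored$task == "gng")) {
    pieces$gng <- scored |>
      dplyr::filter(.data$task == "gng") |>
      dplyr::mutate(
        valid_gng = .data$n_go >= min_trials & .data$n_nogo >= min_trials,
        gng_er = ifelse(.data$valid_gng,
                        ratio_or_na(.data$n_comm, .data$n_nogo), NA_real_),
        gng_rt = ifelse(.data$valid_gng,
                        ratio_or_na(.data$rt_go_sum, .data$rt_go_n), NA_real_)
      ) |>
      dplyr::select(dplyr::all_of(keys), "gng_er", "gng_rt", "valid_gng",
                    n_valid_go = "n_go", n_valid_nogo = "n_nogo")
  }
  out <- purrr::reduce(pieces, dplyr::full_join, by = keys)
  dplyr::arrange(out, .data$subject_id, .data$occasion_index, .data$block)
}
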