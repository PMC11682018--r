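#' Flag prompts answered carelessly fast
#'
#' A prompt is flagged when the mean per-item questionnaire completion time
#' is strictly below `threshold` seconds; all of that occasion's task data
#' are then removed downstream.
#'
#' @param questionnaire Tibble with `subject_id`, `occasion_index`,
#'   `item_time_s` (one row per item).
#' @param threshold Seconds per item.
#' @return Tibble of flagged `(subject_id, occasion_index)` pairs with the
#'   offending `mean_item_time_s`.
#' @export
flag_fast_prompts <- function(questionnaire, threshold = 1) {
  check_columns(questionnaire, c("subject_id", "occasion_index", "item_time_s"),
                "questionnaire")
  if (nrow(questionnaire) == 0) {
    warning("empty questionnaire; no prompts flagged")
    return(tibble::tibble(subject_id = integer(), occasion_index = integer(),
                          mean_item_time_s = numeric()))
  }
  questionnaire |>
    dplyr::group_by(.data$subject_id, .data$occasion_index) |>
    dplyr::summarise(mean_item_time_s = mean(.data$item_time_s),
                     .groups = "drop") |>
    dplyr::filter(.data$mean_item_time_s < threshold)
}

#' Longest run of identical responses
#'
#' The careless-responding "longstring" index: the length of the longest
#' sequence of consecutive identical values.
#'
#' @param x A vector of response codes in presentation order; `NA`s break
#'   runs.
#' @return Integer run length (0 for an empty input, with a warning).
#' @examples
#' longstring(c("a", "a", "b", "a", "a", "a"))
#' @export
longstring <- function(x) {
  if (length(x) == 0) {
    warning("empty response sequence; longstring is 0")
    return(0L)
  }
  r <- rle(as.character(x))
  max(r$lengths[!is.na(r$values)], 0L)
}

#' Apply the careless-responding exclusion rules
#'
#' Applies, in order: (1) prompts with mean questionnaire item time below
#' `item_time_threshold` seconds are dropped entirely; (2) prompts whose
#' Stroop-block longstring exceeds `mean + sd_cut * SD` (moments pooled over
#' all remaining blocks) are dropped entirely; (3) occasions whose
#' occasion-level task error rate exceeds `mean + sd_cut * SD` (per task,
#' pooled over remaining occasions) lose that task's scores; (4) subjects
#' with fewer than `min_assessments` complete assessments (both tasks valid
#' on both blocks) are flagged for exclusion from model fitting. Thresholds
#' are computed once, after rule (1), and recorded in the report.
#'
#' @param blocks Scored blocks from [score_blocks()].
#' @param questionnaire Optional questionnaire tibble for rule (1).
#' @param trials Optional trial tibble with `response_code` for rule (2).
#' @param item_time_threshold Seconds per item for rule (1).
#' @param sd_cut Number of SDs above the mean for rules (2) and (3).
#' @param min_assessments Minimum complete assessments for rule (4).
#' @return A list with `blocks` (filtered; subjects failing rule 4 keep
#'   their rows but are listed in the report) and `report`, a
#'   `screening_report` recording per-rule counts, the computed thresholds,
#'   and the flagged units.
#' @export
apply_exclusions <- function(blocks, questionnaire = NULL, trials = NULL,
                             item_time_threshold = 1, sd_cut = 3,
                             min_assessments = 5) {
  check_columns(blocks, c("subject_id", "occasion_index", "block"), "blocks")
  has_stroop <- "stroop_er" %in% names(blocks)
  has_gng <- "gng_er" %in% names(blocks)
  key <- function(d) paste(d$subject_id, d$occasion_index)

  # (1) fast prompts
  fast <- if (!is.null(questionnaire)) {
    flag_fast_prompts(questionnaire, item_time_threshold)
  } else {
    tibble::tibble(subject_id = integer(), occasion_index = integer())
  }
  blocks1 <- dplyr::anti_join(blocks, fast,
                              by = c("subject_id", "occasion_index"))

  # (2) Stroop longstring
  ls_flagged <- tibble::tibble(subject_id = integer(),
                               occasion_index = integer(), block = integer(),
                               longstring = integer())
  ls_threshold <- NA_real_
  if (!is.null(trials) && "response_code" %in% names(trials) &&
      any(trials$task == "stroop")) {
    ls_tab <- trials |>
      dplyr::filter(.data$task == "stroop") |>
      dplyr::semi_join(blocks1, by = c("subject_id", "occasion_index")) |>
      dplyr::arrange(.data$trial) |>
      dplyr::group_by(.data$subject_id, .data$occasion_index, .data$block) |>
      dplyr::summarise(longstring = longstring(.data$response_code),
                       .groups = "drop")
    ls_sd <- sd(ls_tab$longstring)
    if (is.na(ls_sd) || ls_sd == 0) {
      warning("degenerate longstring SD; no blocks flagged by rule 2")
    } else {
      ls_threshold <- mean(ls_tab$longstring) + sd_cut * ls_sd
      ls_flagged <- dplyr::filter(ls_tab, .data$longstring > ls_threshold)
    }
  }
  blocks2 <- dplyr::anti_join(blocks1, ls_flagged,
                              by = c("subject_id", "occasion_index"))

  # (3) extreme occasion-level error rates, per task
  er_rule <- function(d, er_col) {
    occ <- d |>
      dplyr::group_by(.data$subject_id, .data$occasion_index) |>
      dplyr::summarise(er = mean(.data[[er_col]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::filter(is.finite(.data$er))
    er_sd <- sd(occ$er)
    if (is.na(er_sd) || er_sd == 0) {
      warning("degenerate ", er_col, " SD; no occasions flagged by rule 3")
      return(list(flagged = occ[0, ], threshold = NA_real_))
    }
    thr <- mean(occ$er) + sd_cut * er_sd
    list(flagged = dplyr::filter(occ, .data$er > thr), threshold = thr)
  }
  blank_scores <- function(d, flagged, cols, flag_col) {
    hit <- key(d) %in% key(flagged)
    for (cl in intersect(cols, names(d))) d[[cl]][hit] <- NA_real_
    if (flag_col %in% names(d)) d[[flag_col]][hit] <- FALSE
    d
  }
  stroop_er_rule <- list(flagged = blocks2[0, c("subject_id", "occasion_index")],
                         threshold = NA_real_)
  gng_er_rule <- stroop_er_rule
  blocks3 <- blocks2
  if (has_stroop) {
    stroop_er_rule <- er_rule(blocks2, "stroop_er")
    blocks3 <- blank_scores(blocks3, stroop_er_rule$flagged,
                            c("stroop_er", "stroop_rtdiff"), "valid_stroop")
  }
  if (has_gng) {
    gng_er_rule <- er_rule(blocks2, "gng_er")
    blocks3 <- blank_scores(blocks3, gng_er_rule$flagged,
                            c("gng_er", "gng_rt"), "valid_gng")
  }

  # (4) minimum complete assessments
  task_valid <- function(d, flag, have) {
    if (!have) return(TRUE)
    if (flag %in% names(d)) !anyNA(d[[flag]]) && all(d[[flag]]) else TRUE
  }
  complete <- blocks3 |>
    dplyr::group_by(.data$subject_id, .data$occasion_index) |>
    dplyr::summarise(complete = dplyr::n() >= 2 &&
                       task_valid(dplyr::pick(dplyr::everything()), "valid_stroop", has_stroop) &&
                       task_valid(dplyr::pick(dplyr::everything()), "valid_gng", has_gng),
                     .groups = "drop")
  per_subject <- complete |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_complete = sum(.data$complete), .groups = "drop")
  excluded_subjects <- per_subject$subject_id[
    per_subject$n_complete < min_assessments]

  report <- structure(list(
    n_prompts_flagged_itemtime = nrow(fast),
    n_prompts_flagged_longstring = length(unique(key(ls_flagged))),
    n_occasions_excluded = c(
      stroop = if (has_stroop) nrow(stroop_er_rule$flagged) +
        length(unique(key(ls_flagged))) + nrow(fast) else NA_integer_,
      gng = if (has_gng) nrow(gng_er_rule$flagged) +
        length(unique(key(ls_flagged))) + nrow(fast) else NA_integer_),
    n_subjects_retained = nrow(per_subject) - length(excluded_subjects),
    excluded_subjects = excluded_subjects,
    thresholds = list(item_time_s = item_time_threshold,
                      longstring = ls_threshold,
                      stroop_er = stroop_er_rule$threshold,
                      gng_er = gng_er_rule$threshold,
                      sd_cut = sd_cut, min_assessments = min_assessments),
    complete_definition = "both tasks valid on both blocks at an occasion",
    flagged = list(fast_prompts = fast, longstring_blocks = ls_flagged,
                   stroop_er_occasions = stroop_er_rule$flagged,
                   gng_er_occasions = gng_er_rule$flagged)
  ), class = "screening_report")

  list(blocks = blocks3, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat("  prompts flagged (item time < ", x$thresholds$item_time_s, " s): ",
      x$n_prompts_flagged_itemtime, "\n", sep = "")
  cat("  prompts flagged (longstring > ",
      round(x$thresholds$longstring, 2), "): ",
      x$n_prompts_flagged_longstring, "\n", sep = "")
  cat("  occasions excluded: ",
      paste(names(x$n_occasions_excluded), x$n_occasions_excluded,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  subjects retained (>= ", x$thresholds$min_assessments,
      " complete): ", x$n_subjects_retained, "\n", sep = "")
  invisible(x)
}
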