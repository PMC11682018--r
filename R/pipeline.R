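#' Run the full analysis pipeline
#'
#' Chains the stages on trial-level inputs: trial filtering and block
#' scoring, careless-responding screening, the AR(1) state-trait model per
#' score with variance-decomposition indices, reliability-of-change curves
#' (by trial count and by day), within/between convergent-validity
#' correlations, and multilevel context models. Inputs are either an
#' [ema_config()] (data are simulated) or the tables themselves.
#'
#' @param config Optional [ema_config()]; when supplied, `trials`,
#'   `questionnaire`, and `context` are generated with [simulate_trials()].
#' @param trials,questionnaire,context Input tibbles (ignored when `config`
#'   is given).
#' @param scores Scores to model.
#' @param min_trials,min_rt Scoring thresholds.
#' @param item_time_threshold,sd_cut,min_assessments Screening thresholds.
#' @param rc_step Grid step for the test-length curve; `NULL` skips it.
#' @param output_dir Optional directory; when given, every artifact is
#'   written (`blocks.csv`, `blocks_clean.csv`, `screening.json`,
#'   `fits.json`, `rc_curve.csv`, `rc_daily.csv`, `correlations.csv`,
#'   `context_models.json`, `manifest.json`).
#' @return A list bundle with elements `blocks`, `screening`, `fits`,
#'   `indices`, `rc_curve`, `rc_daily`, `correlations`, `context_models`,
#'   and `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(ema_config(n_subjects = 8, n_days = 3, seed = 1),
#'                     rc_step = NULL)
#' res$indices
#' }
#' @export
run_pipeline <- function(config = NULL, trials = NULL, questionnaire = NULL,
                         context = NULL,
                         scores = c("stroop_er", "stroop_rtdiff", "gng_er",
                                    "gng_rt"),
                         min_trials = 10, min_rt = 150,
                         item_time_threshold = 1, sd_cut = 3,
                         min_assessments = 5, rc_step = 2,
                         output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config)) {
    sim <- stage("simulate", simulate_trials(config))
    trials <- sim$trials
    questionnaire <- sim$questionnaire
    context <- sim$context
  }
  if (is.null(trials)) stop("either `config` or `trials` must be supplied")

  blocks <- stage("score",
                  score_blocks(trials, min_trials = min_trials,
                               min_rt = min_rt))
  scr <- stage("screen",
               apply_exclusions(blocks, questionnaire, trials,
                                item_time_threshold = item_time_threshold,
                                sd_cut = sd_cut,
                                min_assessments = min_assessments))
  clean <- scr$blocks[!scr$blocks$subject_id %in%
                        scr$report$excluded_subjects, ]

  scores <- intersect(scores, names(clean))
  fits <- stage("fit", purrr::map(
    setNames(scores, scores),
    ~ fit_dsem(clean, .x, min_occasions = min_assessments)))
  indices <- purrr::imap(fits, ~ dplyr::bind_cols(
    tibble::tibble(score = .y), glance(.x))) |> dplyr::bind_rows()

  rc_curve <- if (!is.null(rc_step)) {
    stage("curves", rc_by_trialcount(trials, scores = scores, step = rc_step))
  } else NULL
  rc_daily <- stage("curves", purrr::map(
    setNames(scores, scores),
    ~ suppressWarnings(rc_by_day(clean, .x))) |>
      dplyr::bind_rows(.id = "score"))

  occ_scores <- clean |>
    dplyr::group_by(.data$subject_id, .data$occasion_index) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(scores),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  validity_vars <- scores
  if (!is.null(questionnaire)) {
    selfreport <- questionnaire |>
      dplyr::group_by(.data$subject_id, .data$occasion_index) |>
      dplyr::summarise(
        webexec = sum(.data$value[grepl("^webexec", .data$item)]),
        selfcontrol = sum(.data$value[.data$item %in%
                                        c("selfdiscipline", "willpower")]),
        .groups = "drop")
    occ_scores <- dplyr::left_join(occ_scores, selfreport,
                                   by = c("subject_id", "occasion_index"))
    validity_vars <- c(validity_vars,
                       intersect(c("webexec", "selfcontrol"),
                                 names(occ_scores)))
  }
  correlations <- stage("validity",
                        corr_matrix(occ_scores, validity_vars))

  context_models <- NULL
  if (!is.null(context)) {
    ctx_data <- dplyr::inner_join(occ_scores, context,
                                  by = c("subject_id", "occasion_index"))
    context_models <- stage("context", purrr::map(
      setNames(scores, scores),
      ~ fit_context_model(ctx_data, .x)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lstema")),
    seed = if (!is.null(config)) config$seed else NA,
    thresholds = list(min_trials = min_trials, min_rt = min_rt,
                      item_time_threshold = item_time_threshold,
                      sd_cut = sd_cut, min_assessments = min_assessments),
    scores = scores,
    n_subjects = length(unique(blocks$subject_id)),
    stages = c("score", "screen", "fit", "curves", "validity",
               if (!is.null(context_models)) "context")
  )
  bundle <- list(blocks = blocks, screening = scr$report,
                 blocks_clean = clean, fits = fits, indices = indices,
                 rc_curve = rc_curve, rc_daily = rc_daily,
                 correlations = correlations,
                 context_models = context_models, manifest = manifest)
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(output_dir, f),
                                       row.names = FALSE)
  w(bundle$blocks, "blocks.csv")
  w(bundle$blocks_clean, "blocks_clean.csv")
  if (!is.null(bundle$rc_curve)) w(bundle$rc_curve, "rc_curve.csv")
  w(bundle$rc_daily, "rc_daily.csv")
  w(bundle$correlations, "correlations.csv")
  rep <- bundle$screening
  rep$flagged <- lapply(rep$flagged, as.data.frame)
  jsonlite::write_json(unclass(rep), file.path(output_dir, "screening.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  fits_json <- lapply(bundle$fits, function(f) {
    list(params = unclass(f$params), se = as.list(f$se), loglik = f$loglik,
         convergence = f$convergence, n_subjects = f$n_subjects,
         n_occasions = f$n_occasions,
         indices = as.list(as.data.frame(f$indices)))
  })
  jsonlite::write_json(fits_json, file.path(output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$context_models)) {
    cm <- lapply(bundle$context_models, function(m) {
      list(coefficients = as.data.frame(m$coefficients),
           r2_within = m$r2_within,
           var_random_intercept = m$var_random_intercept,
           var_residual = m$var_residual, transform = m$transform)
    })
    jsonlite::write_json(cm, file.path(output_dir, "context_models.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
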