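test_that("fast prompts are flagged by mean item time with a strict cut", {
  q <- tibble::tibble(subject_id = 1, occasion_index = rep(1:3, each = 6),
                      item_time_s = c(rep(0.9, 6), rep(1.0, 6), rep(2, 6)))
  flagged <- flag_fast_prompts(q)
  expect_equal(flagged$occasion_index, 1)
  # 6 items totalling 5.4 s -> mean 0.9 s
  expect_equal(flagged$mean_item_time_s, 5.4 / 6)
  expect_error(flag_fast_prompts(dplyr::select(q, -item_time_s)),
               "item_time_s")
  expect_warning(out <- flag_fast_prompts(q[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("longstring returns the longest run of identical responses", {
  expect_equal(longstring(c("A", "A", "B", "A", "A", "A")), 3)
  expect_equal(longstring(rep("x", 24)), 24)
  expect_equal(longstring(rep(c("a", "b"), 12)), 1)
  expect_warning(expect_equal(longstring(character(0)), 0), "empty")
})

test_that("clean synthetic data yield zero exclusions", {
  sim <- simulate_trials(tiny_trial_config(seed = 31, careless_fraction = 0))
  bl <- score_blocks(sim$trials)
  res <- apply_exclusions(bl, sim$questionnaire, min_assessments = 1)
  expect_equal(res$report$n_prompts_flagged_itemtime, 0)
  expect_equal(res$report$n_prompts_flagged_longstring, 0)
  expect_equal(unname(res$report$n_occasions_excluded), c(0, 0))
  expect_equal(nrow(res$blocks), nrow(bl))
  expect_equal(length(res$report$excluded_subjects), 0)
  # with the longstring rule active, a 3 SD cut on a finite clean sample may
  # flag chance outliers, but only ones recorded above the frozen threshold
  res2 <- apply_exclusions(bl, sim$questionnaire, sim$trials,
                           min_assessments = 1)
  ls <- res2$report$flagged$longstring_blocks
  expect_equal(nrow(res2$blocks) +
                 2 * nrow(dplyr::distinct(ls, subject_id, occasion_index)),
               nrow(bl))
  if (nrow(ls) > 0) {
    expect_true(all(ls$longstring > res2$report$thresholds$longstring))
  }
})

test_that("a planted extreme error rate drops exactly that occasion's task", {
  set.seed(42)
  n_subj <- 10; n_occ <- 8
  bl <- tidyr::expand_grid(subject_id = 1:n_subj, occasion_index = 1:n_occ,
                           block = 1:2) |>
    dplyr::mutate(
      stroop_er = pmin(pmax(rnorm(dplyr::n(), 0.19, 0.05), 0), 1),
      stroop_rtdiff = rnorm(dplyr::n(), 55, 20),
      gng_er = pmin(pmax(rnorm(dplyr::n(), 0.3, 0.05), 0), 1),
      gng_rt = rnorm(dplyr::n(), 290, 20),
      valid_stroop = TRUE, valid_gng = TRUE)
  bl$stroop_er[bl$subject_id == 3 & bl$occasion_index == 4] <- 1.0
  res <- apply_exclusions(bl, min_assessments = 1)
  dropped <- res$blocks[res$blocks$subject_id == 3 &
                          res$blocks$occasion_index == 4, ]
  expect_true(all(is.na(dropped$stroop_er)))
  expect_true(all(is.na(dropped$stroop_rtdiff)))
  expect_true(all(!dropped$valid_stroop))
  # the same occasion keeps its go/no-go scores
  expect_true(all(!is.na(dropped$gng_er)))
  expect_equal(nrow(res$report$flagged$stroop_er_occasions), 1)
  expect_equal(nrow(res$report$flagged$gng_er_occasions), 0)
  kept <- res$blocks[!(res$blocks$subject_id == 3 &
                         res$blocks$occasion_index == 4), ]
  expect_true(all(!is.na(kept$stroop_er)))
})

test_that("planted fast prompts are excluded exactly and only where planted", {
  sim <- simulate_trials(ema_config(n_subjects = 5, n_days = 3,
                                    prompts_per_day = 2, seed = 17,
                                    compliance_rate = 1))
  bl <- score_blocks(sim$trials)
  q <- sim$questionnaire
  planted <- dplyr::distinct(q, subject_id, occasion_index)[c(2, 5, 9, 12, 20), ]
  hit <- paste(q$subject_id, q$occasion_index) %in%
    paste(planted$subject_id, planted$occasion_index)
  q$item_time_s[hit] <- 0.5
  res <- apply_exclusions(bl, q, sim$trials, min_assessments = 1)
  expect_equal(res$report$n_prompts_flagged_itemtime, 5)
  expect_equal(
    dplyr::arrange(res$report$flagged$fast_prompts[, 1:2], subject_id,
                   occasion_index),
    dplyr::arrange(planted, subject_id, occasion_index),
    ignore_attr = TRUE)
  removed <- dplyr::anti_join(bl, res$blocks,
                              by = c("subject_id", "occasion_index", "block"))
  expect_equal(sort(unique(paste(removed$subject_id, removed$occasion_index))),
               sort(paste(planted$subject_id, planted$occasion_index)))
})

test_that("planted careless prompts trip the longstring rule", {
  sim <- simulate_trials(ema_config(n_subjects = 8, n_days = 4,
                                    prompts_per_day = 2, seed = 23,
                                    compliance_rate = 1,
                                    careless_fraction = 0.06))
  planted <- sim$latents |>
    dplyr::filter(score == "stroop_er", careless) |>
    dplyr::distinct(subject_id, occasion_index)
  expect_gt(nrow(planted), 0)
  bl <- score_blocks(sim$trials)
  res <- apply_exclusions(bl, NULL, sim$trials, min_assessments = 1)
  flagged <- dplyr::distinct(res$report$flagged$longstring_blocks,
                             subject_id, occasion_index)
  expect_true(all(paste(flagged$subject_id, flagged$occasion_index) %in%
                    paste(planted$subject_id, planted$occasion_index)))
  expect_gt(nrow(flagged), 0)
})

test_that("degenerate spread disables outlier rules with a warning", {
  bl <- tidyr::expand_grid(subject_id = 1:4, occasion_index = 1:3,
                           block = 1:2) |>
    dplyr::mutate(gng_er = 0.2, gng_rt = 300, valid_gng = TRUE)
  expect_warning(res <- apply_exclusions(bl, min_assessments = 1), "degenerate")
  expect_equal(nrow(res$blocks), nrow(bl))
})

test_that("subjects below the minimum complete assessments are flagged", {
  sim <- simulate_scores(ema_config(
    n_subjects = 6, n_days = 3, prompts_per_day = 2, seed = 3,
    compliance_rate = 1,
    scores = default_score_params()))
  bl <- sim$blocks
  # subject 6: only 2 observed occasions
  drop <- bl$subject_id == 6 & bl$occasion_index > 2
  bl$stroop_er[drop] <- NA; bl$stroop_rtdiff[drop] <- NA
  bl$gng_er[drop] <- NA; bl$gng_rt[drop] <- NA
  bl$valid_stroop[drop] <- FALSE; bl$valid_gng[drop] <- FALSE
  res <- apply_exclusions(bl, min_assessments = 5)
  expect_true(6 %in% res$report$excluded_subjects)
  expect_equal(res$report$n_subjects_retained, 5)
})

test_that("the report freezes thresholds so re-screening is idempotent", {
  sim <- simulate_trials(ema_config(n_subjects = 6, n_days = 3,
                                    prompts_per_day = 2, seed = 29,
                                    compliance_rate = 1,
                                    careless_fraction = 0.1))
  bl <- score_blocks(sim$trials)
  res1 <- apply_exclusions(bl, sim$questionnaire, sim$trials,
                           min_assessments = 1)
  expect_type(res1$report$thresholds$longstring, "double")
  expect_type(res1$report$thresholds$stroop_er, "double")
  # every removal is reconstructible from the report's flag tables
  removed <- dplyr::anti_join(
    dplyr::distinct(bl, subject_id, occasion_index),
    dplyr::distinct(res1$blocks, subject_id, occasion_index),
    by = c("subject_id", "occasion_index"))
  from_report <- dplyr::bind_rows(
    res1$report$flagged$fast_prompts[, c("subject_id", "occasion_index")],
    res1$report$flagged$longstring_blocks[, c("subject_id", "occasion_index")]
  ) |> dplyr::distinct()
  expect_setequal(paste(removed$subject_id, removed$occasion_index),
                  paste(from_report$subject_id, from_report$occasion_index))
})
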