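#' Within-subject centering and grand-mean standardization
#'
#' Subtracts each subject's mean and divides by the pooled standard
#' deviation of the centered values, so the result has mean zero within
#' every subject and pooled SD one — the transformation applied to
#' continuous variables before the multilevel context models.
#'
#' @param values Numeric vector.
#' @param subject Subject labels, same length.
#' @return Transformed numeric vector (`NA`s preserved).
#' @examples
#' within_center_standardize(c(10, 12, 0, 4), c(1, 1, 2, 2))
#' @export
within_center_standardize <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  centered <- values - stats::ave(values, subject,
                                  FUN = function(x) mean(x, na.rm = TRUE))
  s <- sd(centered, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("pooled SD of within-centered values is 0; cannot standardize",
         call. = FALSE)
  }
  centered / s
}

#' Within/between decomposition of a Pearson correlation
#'
#' Splits the association between two repeatedly measured variables into a
#' between-subject part (the Pearson correlation of per-subject means,
#' unweighted) and a within-subject part (the Pearson correlation of
#' person-mean-centered observations pooled over all observations).
#' Two-sided p-values use the t distribution with `n_subjects - 2` degrees
#' of freedom for the between part and
#' `n_observations - n_subjects - 1` for the within part.
#'
#' @param data Tibble containing the variables and subject labels.
#' @param x,y Names of the two numeric columns.
#' @param subject Name of the subject column.
#' @return A one-row tibble of class `corr_pair`: `r_between`, `r_within`,
#'   `p_between`, `p_within`, `n_subjects`, `n_observations`.
#' @examples
#' sim <- simulate_scores(ema_config(n_subjects = 10, n_days = 3, seed = 3))
#' within_between_corr(sim$blocks, "stroop_er", "gng_er")
#' @export
within_between_corr <- function(data, x, y, subject = "subject_id") {
  check_columns(data, c(x, y, subject), "data")
  d <- data[stats::complete.cases(data[[x]], data[[y]]),
            c(subject, x, y)]
  names(d) <- c("subject", "x", "y")
  n_obs <- nrow(d)
  means <- d |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mx = mean(.data$x), my = mean(.data$y), n = dplyr::n(),
                     .groups = "drop")
  n_subj <- nrow(means)

  r_p <- function(r, df) {
    if (is.na(r) || df < 1 || abs(r) >= 1) return(NA_real_)
    2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  }
  if (n_subj < 3) {
    r_b <- p_b <- NA_real_
  } else {
    r_b <- cor(means$mx, means$my)
    p_b <- r_p(r_b, n_subj - 2)
  }
  cx <- d$x - means$mx[match(d$subject, means$subject)]
  cy <- d$y - means$my[match(d$subject, means$subject)]
  multi <- d$subject %in% means$subject[means$n >= 2]
  if (!any(multi) || sd(cx[multi]) == 0 || sd(cy[multi]) == 0) {
    r_w <- p_w <- NA_real_
  } else {
    r_w <- cor(cx[multi], cy[multi])
    p_w <- r_p(r_w, n_obs - n_subj - 1)
  }
  out <- tibble::tibble(r_between = r_b, r_within = r_w, p_between = p_b,
                        p_within = p_w, n_subjects = n_subj,
                        n_observations = n_obs)
  class(out) <- c("corr_pair", class(out))
  out
}

#' Within/between correlation matrix for several variables
#'
#' Convenience wrapper applying [within_between_corr()] to every variable
#' pair.
#'
#' @param data Tibble of observations.
#' @param vars Character vector of numeric column names.
#' @param subject Name of the subject column.
#' @return A tibble with one row per unordered pair.
#' @export
corr_matrix <- function(data, vars, subject = "subject_id") {
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    dplyr::bind_cols(tibble::tibble(var1 = p[1], var2 = p[2]),
                     within_between_corr(data, p[1], p[2], subject))
  }) |> dplyr::bind_rows()
}

#' Multilevel context model with within-subject variance explained
#'
#' Fits, by restricted maximum likelihood, a linear mixed model with a
#' random intercept per subject, regressing a within-centered and
#' grand-mean-standardized task score on contextual predictors: beep number
#' (categorical, first beep as reference), being alone, being outdoors, and
#' tiredness (within-centered and standardized). The within-subject
#' variance explained by the fixed effects is
#' `r2_within = var(fixed-effect linear predictor) / (that variance +
#' residual variance)`, the marginal-R2 construction applied to the
#' within-centered outcome.
#'
#' @param data Tibble with the outcome, `subject_id`, and the predictor
#'   columns `beep`, `alone`, `outdoors`, `tiredness`.
#' @param outcome Name of the outcome column (raw scale; transformed
#'   internally).
#' @param predictors Character vector among `"beep"`, `"alone"`,
#'   `"outdoors"`, `"tiredness"`.
#' @return A `context_model` list: `coefficients` (tibble of standardized
#'   estimates with p-values), `r2_within`, `var_random_intercept`,
#'   `var_residual`, `n_subjects`, `n_observations`, `outcome`, and
#'   `transform` metadata.
#' @export
fit_context_model <- function(data, outcome,
                              predictors = c("beep", "alone", "outdoors",
                                             "tiredness")) {
  check_columns(data, c(outcome, "subject_id", predictors), "data")
  d <- data[stats::complete.cases(data[, c(outcome, predictors,
                                           "subject_id")]), ]
  d$.y <- within_center_standardize(d[[outcome]], d$subject_id)
  if ("beep" %in% predictors) d$beep <- factor(d$beep)
  if ("tiredness" %in% predictors) {
    d$tiredness <- within_center_standardize(d$tiredness, d$subject_id)
  }
  form <- stats::reformulate(c(predictors, "(1 | subject_id)"),
                             response = ".y")
  X <- stats::model.matrix(stats::reformulate(predictors), d)
  aliased <- qr(X)$rank < ncol(X)
  if (aliased) {
    stop("rank-deficient context design; check predictors: ",
         paste(predictors, collapse = ", "), call. = FALSE)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(d) - length(fe) - length(unique(d$subject_id))
  coefs <- tibble::tibble(term = names(fe), estimate = unname(fe),
                          std.error = se,
                          statistic = unname(fe) / se,
                          p.value = 2 * pt(-abs(unname(fe) / se),
                                           df = max(df, 1)))
  eta <- as.numeric(X %*% fe)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_resid <- stats::sigma(fit)^2
  r2w <- var(eta) / (var(eta) + var_resid)
  structure(list(coefficients = coefs, r2_within = r2w,
                 var_random_intercept = vc$vcov[vc$grp == "subject_id"],
                 var_residual = var_resid,
                 n_subjects = length(unique(d$subject_id)),
                 n_observations = nrow(d), outcome = outcome,
                 transform = paste("outcome and tiredness within-subject",
                                   "centered, then grand-mean standardized;",
                                   "beep categorical vs beep 1"),
                 fit = fit),
            class = "context_model")
}

#' @export
print.context_model <- function(x, digits = 3, ...) {
  cat("Multilevel context model --", x$outcome, "\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_observations, "\n")
  cat("  within-subject variance explained (fixed effects):",
      round(x$r2_within, digits), "\n")
  print(dplyr::mutate(x$coefficients,
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, digits))))
  invisible(x)
}

#' @rdname fit_context_model
#' @param x A `context_model`.
#' @param ... Unused.
#' @method tidy context_model
#' @export
tidy.context_model <- function(x, ...) x$coefficients

#' @rdname fit_context_model
#' @method glance context_model
#' @export
glance.context_model <- function(x, ...) {
  tibble::tibble(r2_within = x$r2_within,
                 var_random_intercept = x$var_random_intercept,
                 var_residual = x$var_residual,
                 n_subjects = x$n_subjects,
                 n_observations = x$n_observations)
}
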