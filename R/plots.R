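#' Plot a reliability-versus-trial-count curve
#'
#' @param object An `rc_curve` from [rc_by_trialcount()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rc_curve
#' @export
autoplot.rc_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_per_condition, y = .data$rc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~score) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trials per block and condition",
                  y = expression(R[c]),
                  title = "Within-subject reliability by test length")
}

#' Plot per-day within-subject reliability
#'
#' @param object An `rc_daily` from [rc_by_day()]; a `score` column, if
#'   present, is used for faceting.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rc_daily
#' @export
autoplot.rc_daily <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$rc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "study day", y = expression(R[c]),
                  title = "Within-subject reliability per day")
  if ("score" %in% names(object)) p <- p + ggplot2::facet_wrap(~score)
  p
}

#' Plot the variance decomposition of a fitted state-trait model
#'
#' Stacked shares of total variance: common consistency (trait), occasion
#' specificity and the autoregressive carry-over, and measurement error.
#'
#' @param object A `dsem_fit` from [fit_dsem()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dsem_fit
#' @export
autoplot.dsem_fit <- function(object, ...) {
  ix <- object$indices
  shares <- tibble::tibble(
    component = factor(c("trait (consistency)", "state residual (specificity)",
                         "autoregressive carry-over", "measurement error"),
                       levels = c("measurement error",
                                  "autoregressive carry-over",
                                  "state residual (specificity)",
                                  "trait (consistency)")),
    share = c(ix$con, ix$spe, ix$rel - ix$con - ix$spe, 1 - ix$rel)
  )
  ggplot2::ggplot(shares, ggplot2::aes(x = "", y = .data$share,
                                       fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of total variance",
                  title = paste("Variance decomposition:", object$score))
}
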