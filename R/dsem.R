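#' Joint mean and covariance implied by the state-trait AR(1) model
#'
#' Builds the exact mean vector and covariance matrix of the `2T` block
#' indicators of one subject under the model
#' `Y[i,t] = xi + OCC[t] + beta * time[t] + eps[i,t]` with
#' `OCC[1] = zeta[1]`, `OCC[t] = phi * OCC[t-1] + zeta[t]`, shared trait
#' `xi`, and independent errors of equal variance. Entries are ordered
#' indicator-within-occasion: `(t1 b1, t1 b2, t2 b1, ...)`. This closed form
#' is the brute-force oracle for the sequential likelihood.
#'
#' @param params A [dsem_params()].
#' @param T Number of scheduled occasions.
#' @param stationary Start the occasion process from its stationary
#'   distribution instead of `OCC[1] = zeta[1]`.
#' @return List with `mean` (length `2T`) and `cov` (`2T x 2T`).
#' @examples
#' dsem_covariance(dsem_params(var_trait = 1, phi = 0.5), T = 3)
#' @export
dsem_covariance <- function(params, T, stationary = FALSE) {
  validate_dsem_params(params)
  stopifnot(T >= 1)
  p <- params
  # Var(OCC_t): running geometric sum, exact for any abs(phi) < 1 incl. 0
  v_occ <- if (stationary) {
    rep(p$var_state / (1 - p$phi^2), T)
  } else {
    p$var_state * cumsum(p$phi^(2 * (0:(T - 1))))
  }
  tt <- matrix(rep(seq_len(T), T), T, T)
  occ_cov <- p$phi^abs(tt - t(tt)) * v_occ[pmin(tt, t(tt))]
  idx <- rep(seq_len(T), each = 2)
  cov <- p$var_trait + occ_cov[idx, idx]
  diag(cov) <- diag(cov) + p$var_error
  mean <- rep(p$mu_trait + p$beta * (seq_len(T) - 1), each = 2)
  list(mean = mean, cov = cov)
}

# Reshape long block data into two N x T indicator matrices on the
# scheduled occasion grid.
dsem_matrices <- function(data, score, T = NULL) {
  check_columns(data, c("subject_id", "occasion_index", "block", score), "data")
  if (is.null(T)) T <- max(data$occasion_index)
  subjects <- sort(unique(data$subject_id))
  Y1 <- Y2 <- matrix(NA_real_, length(subjects), T)
  i <- match(data$subject_id, subjects)
  j <- data$occasion_index
  b1 <- data$block == sort(unique(data$block))[1]
  Y1[cbind(i[b1], j[b1])] <- data[[score]][b1]
  Y2[cbind(i[!b1], j[!b1])] <- data[[score]][!b1]
  list(Y1 = Y1, Y2 = Y2, subjects = subjects, T = T)
}

# Vectorized-over-subjects Kalman filter for the 2-dimensional state
# (trait, occasion factor). Processes the two indicators sequentially;
# exact for the Gaussian model, missing entries marginalized by skipping.
kalman_loglik <- function(mu, s2t, beta, phi, s2z, s2e, Y1, Y2,
                          stationary = FALSE) {
  N <- nrow(Y1)
  T <- ncol(Y1)
  m1 <- rep(mu, N)
  m2 <- numeric(N)
  P11 <- rep(s2t, N)
  P12 <- numeric(N)
  P22 <- numeric(N)
  ll <- numeric(N)
  for (t in seq_len(T)) {
    if (t == 1) {
      P22 <- rep(if (stationary) s2z / (1 - phi^2) else s2z, N)
    } else {
      m2 <- phi * m2
      P12 <- phi * P12
      P22 <- phi^2 * P22 + s2z
    }
    trend <- beta * (t - 1)
    for (i in 1:2) {
      y <- if (i == 1) Y1[, t] else Y2[, t]
      obs <- which(!is.na(y))
      if (!length(obs)) next
      S <- P11[obs] + 2 * P12[obs] + P22[obs] + s2e
      if (any(S <= 0)) return(rep(-Inf, N))
      v <- y[obs] - (m1[obs] + m2[obs] + trend)
      hP1 <- P11[obs] + P12[obs]
      hP2 <- P12[obs] + P22[obs]
      K1 <- hP1 / S
      K2 <- hP2 / S
      ll[obs] <- ll[obs] - 0.5 * (log(2 * pi * S) + v^2 / S)
      m1[obs] <- m1[obs] + K1 * v
      m2[obs] <- m2[obs] + K2 * v
      P11[obs] <- P11[obs] - K1 * hP1
      P12[obs] <- P12[obs] - K1 * hP2
      P22[obs] <- P22[obs] - K2 * hP2
    }
  }
  ll
}

#' Marginal log-likelihood of block-score data under the state-trait model
#'
#' Sums, over subjects, the Gaussian log-density of the observed block
#' indicators under the joint distribution of [dsem_covariance()]. Missing
#' entries on the scheduled grid are marginalized, not imputed. The
#' implementation is a sequential state-space filter over occasions;
#' it agrees with the direct joint-Gaussian density to numerical precision.
#'
#' @param params A [dsem_params()].
#' @param data Long block tibble (`subject_id`, `occasion_index`, `block`,
#'   and the score column).
#' @param score Name of the score column.
#' @param T Number of scheduled occasions (defaults to the largest occasion
#'   index present).
#' @param stationary Passed to the occasion-process initialization.
#' @return The scalar log-likelihood.
#' @export
dsem_loglik <- function(params, data, score, T = NULL, stationary = FALSE) {
  validate_dsem_params(params)
  m <- dsem_matrices(data, score, T)
  empty <- rowSums(!is.na(m$Y1)) + rowSums(!is.na(m$Y2)) == 0
  if (any(empty)) {
    warning(sum(empty), " subject(s) with no observed entries contribute 0")
  }
  sum(kalman_loglik(params$mu_trait, params$var_trait, params$beta,
                    params$phi, params$var_state, params$var_error,
                    m$Y1, m$Y2, stationary))
}

#' Fit the AR(1) latent state-trait model
#'
#' Maximum marginal likelihood estimation of the six model parameters from
#' two parallel block indicators per occasion, with variances kept
#' non-negative through a log parameterization and `abs(phi) < 1` through a
#' tanh parameterization. Optimization is deterministic: moment-based
#' starting values plus a fixed grid of autoregression starts. Standard
#' errors come from the observed information (numerical Hessian) via the
#' delta method.
#'
#' @param data Long block tibble as in [dsem_loglik()]. Only subjects with
#'   at least `min_occasions` occasions on which both blocks are observed
#'   are used.
#' @param score Name of the score column.
#' @param min_occasions Minimum complete occasions per subject.
#' @param T Number of scheduled occasions (defaults to the largest occasion
#'   index present).
#' @param stationary Occasion-process initialization, as in
#'   [dsem_covariance()].
#' @param phi_starts Fixed grid of starting values for `phi`.
#' @param se Compute standard errors (skipping them speeds up simulation
#'   studies).
#' @return A `dsem_fit` with elements `params` ([dsem_params()]), `se`,
#'   `loglik`, `convergence`, `n_subjects`, `n_occasions`, `indices`
#'   ([compute_indices()]), and `score`.
#' @examples
#' sim <- simulate_scores(ema_config(n_subjects = 20, n_days = 4, seed = 1))
#' fit <- fit_dsem(sim$blocks, "gng_rt")
#' tidy(fit)
#' @export
fit_dsem <- function(data, score, min_occasions = 5, T = NULL,
                     stationary = FALSE, phi_starts = c(0, 0.3, 0.6),
                     se = TRUE) {
  m <- dsem_matrices(data[!is.na(data[[score]]), ], score, T)
  n_complete <- rowSums(!is.na(m$Y1) & !is.na(m$Y2))
  keep <- n_complete >= min_occasions
  if (!any(keep)) stop("no subjects with >= ", min_occasions,
                       " complete occasions", call. = FALSE)
  Y1 <- m$Y1[keep, , drop = FALSE]
  Y2 <- m$Y2[keep, , drop = FALSE]

  # moment starts: person means -> trait; block disagreement -> error
  pm <- rowMeans(cbind(Y1, Y2), na.rm = TRUE)
  s2t0 <- max(var(pm), 1e-6)
  s2e0 <- max(var(as.numeric(Y1 - Y2), na.rm = TRUE) / 2, 1e-6, na.rm = TRUE)
  within <- (Y1 + Y2) / 2 - pm
  s2w <- var(as.numeric(within), na.rm = TRUE)
  s2z0 <- max(s2w - s2e0 / 2, s2e0 / 10, 1e-6)

  nll <- function(theta) {
    -sum(kalman_loglik(theta[1], exp(theta[2]), theta[3], tanh(theta[4]),
                       exp(theta[5]), exp(theta[6]), Y1, Y2, stationary))
  }
  fits <- lapply(phi_starts, function(phi0) {
    start <- c(mean(pm), log(s2t0), 0, atanh(min(max(phi0, -0.99), 0.99)),
               log(s2z0), log(s2e0))
    tryCatch(
      optim(start, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) list(value = Inf, convergence = 1L, par = start)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  th <- best$par
  params <- dsem_params(mu_trait = th[1], var_trait = exp(th[2]),
                        beta = th[3], phi = tanh(th[4]),
                        var_state = exp(th[5]), var_error = exp(th[6]))

  se_nat <- rep(NA_real_, 6)
  if (se) {
    H <- tryCatch(optimHess(th, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        jac <- c(1, exp(th[2]), 1, 1 - tanh(th[4])^2, exp(th[5]), exp(th[6]))
        se_nat <- sqrt(pmax(diag(V), 0)) * abs(jac)
      }
    }
  }
  names(se_nat) <- c("mu_trait", "var_trait", "beta", "phi", "var_state",
                     "var_error")

  structure(list(params = params, se = se_nat, loglik = -best$value,
                 convergence = best$convergence == 0,
                 n_subjects = sum(keep), n_occasions = m$T,
                 indices = compute_indices(params), score = score,
                 stationary = stationary),
            class = "dsem_fit")
}

#' Variance-decomposition indices from model parameters
#'
#' The occasion-factor variance is approximated by truncating the
#' autoregressive accumulation at four lags,
#' `var_occ = var_state * (1 + phi^2 + phi^4 + phi^6 + phi^8)`
#' (equivalently `var_state * (1 - phi^10) / (1 - phi^2)`); the exact
#' stationary value `var_state / (1 - phi^2)` is also reported for
#' sensitivity. Total variance is `var_trait + var_occ + var_error`. The
#' indices are: overall reliability `rel = (var_trait + var_occ) /
#' var_total`, common consistency `con = var_trait / var_total`, occasion
#' specificity `spe = var_state / var_total`, and within-subject
#' reliability `rel_within = var_occ / (var_occ + var_error)`. Note that
#' `con + spe < rel` whenever `phi != 0`, since the occasion factor carries
#' more variance than a single innovation.
#'
#' @param params A [dsem_params()].
#' @param lags Truncation order of the occasion-variance approximation.
#' @return A one-row tibble of class `variance_indices` with `var_occ`,
#'   `var_occ_stationary`, `var_total`, `rel`, `con`, `spe`, `rel_within`.
#' @examples
#' compute_indices(dsem_params(var_trait = 1, phi = 0, var_state = 1,
#'                             var_error = 2))
#' @export
compute_indices <- function(params, lags = 4) {
  validate_dsem_params(params)
  p <- params
  var_occ <- p$var_state * sum(p$phi^(2 * (0:lags)))
  var_total <- p$var_trait + var_occ + p$var_error
  if (var_total == 0) {
    warning("total variance is 0; indices undefined")
    rel <- con <- spe <- rel_within <- NA_real_
  } else {
    rel <- (p$var_trait + var_occ) / var_total
    con <- p$var_trait / var_total
    spe <- p$var_state / var_total
    rel_within <- if (var_occ + p$var_error == 0) NA_real_ else
      var_occ / (var_occ + p$var_error)
  }
  out <- tibble::tibble(
    var_occ = var_occ,
    var_occ_stationary = p$var_state / (1 - p$phi^2),
    var_total = var_total, rel = rel, con = con, spe = spe,
    rel_within = rel_within
  )
  class(out) <- c("variance_indices", class(out))
  out
}

#' @export
print.dsem_fit <- function(x, digits = 4, ...) {
  cat("AR(1) latent state-trait model fit --", x$score, "\n")
  cat("  subjects:", x$n_subjects, " occasions:", x$n_occasions,
      " logLik:", format(x$loglik, digits = 8),
      if (!x$convergence) " (NOT converged)" else "", "\n")
  est <- unlist(x$params)
  print(round(rbind(estimate = est, se = x$se[names(est)]), digits))
  cat("indices:\n")
  print(round(as.data.frame(x$indices), digits))
  invisible(x)
}

#' @rdname fit_dsem
#' @param x A `dsem_fit`.
#' @param ... Unused.
#' @method tidy dsem_fit
#' @export
tidy.dsem_fit <- function(x, ...) {
  est <- unlist(x$params)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(x$se[names(est)]))
}

#' @rdname fit_dsem
#' @method glance dsem_fit
#' @export
glance.dsem_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$convergence,
                 n_subjects = x$n_subjects, n_occasions = x$n_occasions,
                 rel = x$indices$rel, con = x$indices$con,
                 spe = x$indices$spe, rel_within = x$indices$rel_within)
}

#' @importFrom stats optimHess
NULL
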