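test_that("model covariance has the right closed-form limits", {
  # phi = 0: indicators share only trait + current innovation
  p <- dsem_params(var_trait = 1, phi = 0, var_state = 0.5, var_error = 0.25)
  mc <- dsem_covariance(p, 3)
  expect_equal(mc$cov[1, 2], 1.5)     # two blocks, same occasion
  expect_equal(mc$cov[1, 3], 1)       # across occasions: trait only
  expect_equal(mc$cov[1, 1], 1.75)
  # pure noise
  p0 <- dsem_params(var_trait = 0, phi = 0.4, var_state = 0, var_error = 2)
  expect_equal(dsem_covariance(p0, 4)$cov, diag(2, 8))
  # started process variance converges to the stationary geometric sum
  p5 <- dsem_params(var_trait = 0, phi = 0.5, var_state = 1, var_error = 0)
  mc5 <- dsem_covariance(p5, 60)
  expect_equal(mc5$cov[120, 120], 1 / (1 - 0.25), tolerance = 1e-12)
  # stationary initialization is flat from the first occasion
  mc5s <- dsem_covariance(p5, 5, stationary = TRUE)
  expect_equal(diag(mc5s$cov), rep(4 / 3, 10))
  # trend enters the mean, not the covariance
  pb <- dsem_params(mu_trait = 2, beta = 0.5, var_trait = 1)
  expect_equal(dsem_covariance(pb, 3)$mean, rep(c(2, 2.5, 3), each = 2))
})

test_that("covariance entries match direct enumeration of the innovations", {
  set.seed(7)
  for (k in 1:20) {
    p <- dsem_params(var_trait = runif(1, 0, 2), phi = runif(1, -0.9, 0.9),
                     var_state = runif(1, 0, 2), var_error = runif(1, 0, 2))
    T <- sample(2:6, 1)
    mc <- dsem_covariance(p, T)
    t1 <- sample(T, 1); t2 <- sample(T, 1); b1 <- sample(2, 1); b2 <- sample(2, 1)
    i <- 2 * (t1 - 1) + b1; j <- 2 * (t2 - 1) + b2
    expect_equal(mc$cov[i, j],
                 oracle_cov_entry(p, t1, t2, i == j), tolerance = 1e-12)
  }
})

test_that("sequential likelihood equals the joint-Gaussian oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(11)
  for (k in 1:5) {
    p <- dsem_params(mu_trait = rnorm(1), var_trait = runif(1, 0.1, 2),
                     beta = rnorm(1, 0, 0.1), phi = runif(1, -0.9, 0.9),
                     var_state = runif(1, 0.1, 2),
                     var_error = runif(1, 0.1, 2))
    T <- 4; N <- 3
    mc <- dsem_covariance(p, T)
    dat <- purrr::map_dfr(1:N, function(s) {
      y <- as.numeric(mvtnorm::rmvnorm(1, mc$mean, mc$cov))
      y[runif(2 * T) < 0.25] <- NA
      tibble::tibble(subject_id = s, occasion_index = rep(1:T, each = 2),
                     block = rep(1:2, T), y = y)
    })
    expect_equal(suppressWarnings(dsem_loglik(p, dat, "y", T = T)),
                 oracle_loglik(p, dat, "y", T), tolerance = 1e-10)
  }
})

test_that("inflating the error variance far from the optimum lowers loglik", {
  sim <- simulate_scores(single_score_config(n_subjects = 10, n_days = 2,
                                             seed = 2))
  p <- sim_params <- dsem_params(var_trait = 1, phi = 0.3, var_state = 0.5,
                                 var_error = 100)
  p2 <- dsem_params(var_trait = 1, phi = 0.3, var_state = 0.5,
                    var_error = 200)
  expect_gt(dsem_loglik(p, sim$blocks, "y"),
            dsem_loglik(p2, sim$blocks, "y"))
})

test_that("average loglik per observation matches the Gaussian theory value", {
  p <- dsem_params(var_trait = 1, phi = 0.3, var_state = 0.5,
                   var_error = 0.5)
  T <- 8
  cfg <- ema_config(n_subjects = 3000, n_days = 2, prompts_per_day = 4,
                    compliance_rate = 1, seed = 14, scores = list(y = p))
  sim <- simulate_scores(cfg)
  ll <- dsem_loglik(p, sim$blocks, "y", T = T)
  mc <- dsem_covariance(p, T)
  n <- 2 * T
  expected <- -0.5 * (n * log(2 * pi) +
                        determinant(mc$cov)$modulus[1] + n) / n
  expect_equal(ll / (3000 * n), expected, tolerance = 0.01)
})

test_that("subjects with no observed entries contribute zero with a warning", {
  dat <- tibble::tibble(subject_id = rep(1:2, each = 4),
                        occasion_index = rep(rep(1:2, each = 2), 2),
                        block = rep(1:2, 4),
                        y = c(rnorm(4), rep(NA, 4)))
  p <- dsem_params()
  expect_warning(ll <- dsem_loglik(p, dat, "y"), "no observed entries")
  expect_equal(ll, suppressWarnings(dsem_loglik(p, dat[1:4, ], "y", T = 2)))
})

test_that("variance indices follow the printed formulas", {
  # phi = 0 closed form
  ix <- compute_indices(dsem_params(var_trait = 1, phi = 0, var_state = 1,
                                    var_error = 2))
  expect_equal(ix$var_occ, 1)
  expect_equal(ix$var_total, 4)
  expect_equal(ix$rel, 0.5)
  expect_equal(ix$con, 0.25)
  expect_equal(ix$spe, 0.25)
  expect_equal(ix$rel_within, 1 / 3)
  expect_equal(ix$rel, ix$con + ix$spe)
  # truncated geometric sum at phi = 0.5
  ix5 <- compute_indices(dsem_params(var_trait = 1, phi = 0.5, var_state = 1,
                                     var_error = 1))
  expect_equal(ix5$var_occ, 1.33203125)
  expect_equal(ix5$var_occ, (1 - 0.5^10) / (1 - 0.25))
  expect_equal(ix5$var_occ_stationary, 4 / 3)
  # error-free limit
  ix0 <- compute_indices(dsem_params(var_trait = 1, phi = 0.3, var_state = 1,
                                     var_error = 0))
  expect_equal(ix0$rel, 1)
  expect_equal(ix0$rel_within, 1)
  expect_warning(ixz <- compute_indices(dsem_params(var_trait = 0, phi = 0,
                                                    var_state = 0,
                                                    var_error = 0)),
                 "undefined")
  expect_true(is.na(ixz$rel))
})

test_that("consistency plus specificity never exceeds reliability", {
  set.seed(5)
  for (k in 1:50) {
    p <- dsem_params(var_trait = runif(1, 0, 2), phi = runif(1, -0.95, 0.95),
                     var_state = runif(1, 0.01, 2),
                     var_error = runif(1, 0.01, 2))
    ix <- compute_indices(p)
    expect_lte(ix$con + ix$spe, ix$rel + 1e-12)
    if (abs(p$phi) > 1e-8) expect_lt(ix$con + ix$spe, ix$rel)
    expect_gte(ix$rel_within, 0)
    expect_lte(ix$rel, 1)
  }
})

test_that("indices are invariant to rescaling the measurement unit", {
  p <- dsem_params(mu_trait = 3, var_trait = 1.2, beta = 0.01, phi = 0.4,
                   var_state = 0.7, var_error = 0.9)
  a <- 37.2
  p_scaled <- dsem_params(mu_trait = 3 * a, var_trait = 1.2 * a^2,
                          beta = 0.01 * a, phi = 0.4,
                          var_state = 0.7 * a^2, var_error = 0.9 * a^2)
  ix1 <- compute_indices(p)
  ix2 <- compute_indices(p_scaled)
  for (f in c("rel", "con", "spe", "rel_within")) {
    expect_equal(ix1[[f]], ix2[[f]], tolerance = 1e-12)
  }
})

test_that("the estimator recovers a degenerate state variance as near zero", {
  cfg <- single_score_config(n_subjects = 50, n_days = 5, phi = 0,
                             var_state = 0, var_error = 0.5, seed = 9)
  sim <- simulate_scores(cfg)
  fit <- fit_dsem(sim$blocks, "y", se = FALSE)
  expect_lt(fit$indices$spe, 0.03)
  expect_equal(fit$indices$rel, fit$indices$con, tolerance = 0.03)
})

test_that("fitting is deterministic and produces finite SEs on convergence", {
  sim <- simulate_scores(single_score_config(n_subjects = 25, n_days = 4,
                                             seed = 10,
                                             compliance_rate = 0.7))
  f1 <- fit_dsem(sim$blocks, "y")
  f2 <- fit_dsem(sim$blocks, "y")
  expect_identical(tidy(f1), tidy(f2))
  expect_true(f1$convergence)
  expect_true(is.finite(f1$loglik))
  expect_true(all(is.finite(tidy(f1)$std.error)))
  expect_true(all(tidy(f1)$std.error > 0))
  g <- glance(f1)
  expect_equal(g$n_subjects, 25)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("subjects with too few complete assessments are excluded from fits", {
  sim <- simulate_scores(single_score_config(n_subjects = 12, n_days = 4,
                                             seed = 15))
  bl <- sim$blocks
  bl$y[bl$subject_id == 1 & bl$occasion_index > 3] <- NA
  fit <- fit_dsem(bl, "y", min_occasions = 5, se = FALSE)
  expect_equal(fit$n_subjects, 11)
  expect_error(fit_dsem(bl[bl$subject_id == 1, ], "y", min_occasions = 5),
               "complete occasions")
})
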