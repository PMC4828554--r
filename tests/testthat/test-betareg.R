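# Beta regression: link pair, density, likelihood, ML oracle, MCMC vs grid
# and vs ML, and a small coverage study.

test_that("logit / inv_logit are a stable inverse pair", {
  expect_equal(logit(0.5), 0)
  expect_equal(inv_logit(0), 0.5)
  expect_lt(abs(logit(inv_logit(-20)) + 20), 1e-9)
  # positive eta is limited by the double-precision gap below 1: the
  # round-trip error grows like eps * exp(eta), so 1e-12 accuracy is only
  # representable up to about eta = 8
  for (eta in c(-30, -20, -5, 0, 5, 8)) {
    expect_lt(abs(logit(inv_logit(eta)) - eta), 1e-12 * max(1, abs(eta)))
  }
  expect_lt(abs(logit(inv_logit(30)) - 30), 30 * .Machine$double.eps * exp(30))
  expect_true(is.finite(inv_logit(700)) && inv_logit(700) <= 1)
  expect_error(logit(0), class = "invalid_argument")
  expect_error(logit(1), class = "invalid_argument")
})

test_that("beta log-density: closed forms and quadrature normalization", {
  expect_equal(beta_logpdf(0.3, 0.5, 2), 0)                 # Beta(1,1) is uniform
  expect_equal(beta_logpdf(0.25, 0.5, 4), log(6 * 0.25 * 0.75))  # Beta(2,2)
  for (mu in c(0.2, 0.5, 0.8)) for (phi in c(0.5, 5, 50)) {
    expect_lt(abs(beta_norm_quad(mu, phi) - 1), 1e-6)
  }
  expect_error(beta_logpdf(0, 0.5, 2), class = "invalid_argument")
  expect_error(beta_logpdf(1, 0.5, 2), class = "invalid_argument")
  expect_error(beta_logpdf(0.5, 0.5, 0), class = "invalid_argument")
})

test_that("log-likelihood is additive and agrees with an independent coding", {
  X <- make_normal_design(10, 2, seed = 51)
  set.seed(52)
  y <- runif(10, 0.05, 0.95)
  bd <- betareg_data(rownames(X), y, X)
  beta <- c(0.1, -0.2, 0.3); phi <- 7

  one <- betareg_data("a", y[1], X[1, , drop = FALSE])
  expect_equal(betareg_loglik(one, beta, phi),
               beta_logpdf(y[1], inv_logit(drop(X[1, ] %*% beta)), phi))

  dup <- betareg_data(c(rownames(X), "extra"), c(y, y[1]), rbind(X, X[1, ]))
  expect_equal(betareg_loglik(dup, beta, phi),
               betareg_loglik(bd, beta, phi) +
                 beta_logpdf(y[1], inv_logit(drop(X[1, ] %*% beta)), phi))

  # independent coding through dbeta shape parameters
  mu <- plogis(drop(X %*% beta))
  direct <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  expect_lt(abs(betareg_loglik(bd, beta, phi) - direct), 1e-10)

  expect_error(betareg_loglik(bd, c(1, 2), phi), class = "invalid_argument")
})

test_that("ML fit: symmetry, recovery, and optimality", {
  # responses paired with their reflections: intercept-only MLE is exactly 0
  set.seed(53)
  y_half <- runif(15, 0.55, 0.95)
  y <- c(y_half, 1 - y_half)
  bd <- betareg_data(sprintf("s%02d", 1:30), y, matrix(1, 30, 1))
  fit <- betareg_fit_ml(bd)
  expect_lt(abs(fit$beta[[1]]), 1e-6)
  expect_lt(fit$score_norm, 1e-6)
  expect_true(all(fit$se > 0))

  X <- make_normal_design(2000, 1, seed = 54)
  truth <- c(-0.1, 0.15); phi_true <- 40
  bd2 <- simulate_beta_outcomes(X, betareg_params(beta = truth, phi = phi_true, seed = 55))
  fit2 <- betareg_fit_ml(bd2)
  expect_lt(abs(fit2$beta[[1]] - truth[1]), 3 * fit2$se[[1]])
  expect_lt(abs(fit2$beta[[2]] - truth[2]), 3 * fit2$se[[2]])
  expect_lt(abs(fit2$phi - phi_true), 3 * fit2$se[["phi"]])
  # fitted likelihood dominates the generating parameters on the same data
  expect_gte(fit2$loglik, betareg_loglik(bd2, truth, phi_true))

  expect_error(betareg_fit_ml(betareg_data(c("a", "b"), c(0.4, 0.6), matrix(1, 2, 1))),
               class = "invalid_argument")   # too few observations
})

test_that("MCMC retains the documented number of draws and is reproducible", {
  s <- mcmc_settings(48000, 9500)           # reference stage-2 run length
  expect_identical((s$n_iter - s$n_burn) %/% s$thin, 38500L)

  X <- make_normal_design(40, 1, seed = 56)
  bd <- simulate_beta_outcomes(X, betareg_params(beta = c(0, 0.3), phi = 20, seed = 57))
  st <- mcmc_settings(600, 200, seed = 58)
  m1 <- run_beta_mcmc(bd, betareg_priors(), st)
  m2 <- run_beta_mcmc(bd, betareg_priors(), st)
  expect_identical(m1$beta_draws, m2$beta_draws)
  expect_identical(m1$phi_draws, m2$phi_draws)
  expect_identical(nrow(m1$beta_draws), 400L)
  expect_true(all(m1$phi_draws > 0))
})

test_that("posterior matches a 2-D grid on an intercept-only instance", {
  y <- c(0.3, 0.6)
  pri <- betareg_priors(beta_prior_sd = 2, phi_shape = 2, phi_rate = 0.5)
  bd <- betareg_data(c("a", "b"), y, matrix(1, 2, 1))
  gm <- beta_grid_means(y, pri)
  mc <- run_beta_mcmc(bd, pri, mcmc_settings(40000, 8000, seed = 59))
  expect_lt(abs(mean(mc$beta_draws[, 1]) - gm[["beta"]]),
            3 * mc_error(mc$beta_draws[, 1]))
  expect_lt(abs(mean(mc$phi_draws) - gm[["phi"]]),
            3 * mc_error(mc$phi_draws))
})

test_that("diffuse-prior posterior means agree with the ML oracle", {
  X <- make_normal_design(400, 1, seed = 60)
  bd <- simulate_beta_outcomes(X, betareg_params(beta = c(0.2, 0.1), phi = 30, seed = 61))
  fit <- betareg_fit_ml(bd)
  mc <- run_beta_mcmc(bd, betareg_priors(beta_prior_sd = 1e4),
                      mcmc_settings(6000, 1500, seed = 62))
  psd <- apply(mc$beta_draws, 2, sd)
  expect_true(all(abs(colMeans(mc$beta_draws) - fit$beta) < 3 * psd))
  expect_lt(abs(mean(mc$phi_draws) - fit$phi), 3 * sd(mc$phi_draws))
  # adapted scales land in the targeted acceptance band
  expect_true(all(mc$accept > 0.15 & mc$accept < 0.6))
})

test_that("credible intervals cover generating parameters at ~95%", {
  # 100 seeded replications at reduced scale (n = 80, short chains); the
  # stated tolerance is +/- 7 percentage points around 95%
  reps <- 100
  hits <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    X <- make_normal_design(80, 1, seed = 700 + r)
    truth <- c(0.3, 0.4); phi_true <- 20
    bd <- simulate_beta_outcomes(X, betareg_params(beta = truth, phi = phi_true,
                                                   seed = 800 + r))
    mc <- run_beta_mcmc(bd, betareg_priors(), mcmc_settings(2500, 800, seed = 900 + r))
    for (j in 1:2) {
      ci <- quantile(mc$beta_draws[, j], c(0.025, 0.975), type = 7)
      hits <- hits + (ci[1] <= truth[j] && truth[j] <= ci[2])
      total <- total + 1L
    }
  }
  coverage <- hits / total
  expect_gte(coverage, 0.88)
  expect_lte(coverage, 1.0)
})
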