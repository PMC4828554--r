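# Stochastic frontier Gibbs sampler: conjugate full conditionals against
# brute-force oracles, sampler invariants, recovery, and efficiency scoring.

test_that("beta full conditional: flat-prior limit and conjugate algebra", {
  sim <- simulate_frontier_panel(8, 5, frontier_params(seed = 31))
  ols <- qr.coef(qr(sim$panel$X), sim$panel$y)
  fc <- full_conditional_beta(sim$panel, rep(0, 40), 0.3,
                              frontier_priors(beta_prior_sd = 1e8))
  expect_lt(max(abs(fc$mean - ols)), 1e-4)
  expect_true(isSymmetric(fc$cov))
  expect_true(all(eigen(fc$cov, only.values = TRUE)$values > 0))

  # one observation, one coefficient, y = 0, x = 1, u = 0: N(0, 1/2)
  tiny <- panel_dataset("a", 1L, 0, matrix(1, 1, 1))
  fc1 <- full_conditional_beta(tiny, 0, 1, frontier_priors(beta_prior_sd = 1))
  expect_equal(fc1$mean, 0)
  expect_equal(drop(fc1$cov), 0.5)
})

test_that("beta full conditional matches a normalized grid of likelihood x prior", {
  set.seed(32)
  x <- rnorm(5); u <- runif(5, 0, 0.2); sigma2 <- 0.3
  y <- 1.4 * x + rnorm(5, 0, sqrt(sigma2)) - u
  pan <- panel_dataset(letters[1:5], rep(1L, 5), y, matrix(1, 5, 1))
  pan$X <- matrix(x, 5, 1, dimnames = list(NULL, "x"))  # single non-intercept column
  pri <- frontier_priors(beta_prior_sd = 1)
  fc <- full_conditional_beta(pan, u, sigma2, pri)
  s <- sqrt(drop(fc$cov))
  bg <- seq(fc$mean - 8 * s, fc$mean + 8 * s, length.out = 20001)
  dx <- bg[2] - bg[1]
  ytilde <- y + u
  loglik <- sapply(bg, function(b) sum(dnorm(ytilde - x * b, 0, sqrt(sigma2), log = TRUE)))
  dens <- exp(loglik + dnorm(bg, 0, 1, log = TRUE))
  dens <- dens / (sum(dens) * dx)
  expect_lt(max(abs(dens - dnorm(bg, fc$mean, s))), 1e-6)
})

test_that("u full conditional: limits, symmetry, and quadrature oracle", {
  # vanishing prior precision: conditional tends to N(r, sigma2)
  fc <- full_conditional_u(c(0.3, -0.2), 0.5, 1e12)
  expect_lt(abs(fc$var - 0.5), 1e-6)
  expect_lt(max(abs(fc$mean - c(0.3, -0.2))), 1e-6)

  fc0 <- full_conditional_u(0, 1, 1)
  expect_equal(fc0$mean, 0)
  expect_equal(fc0$var, 0.5)

  # quadrature oracle at sigma2 = 0.04, lambda = 0.16, r = 0.1
  fcq <- full_conditional_u(0.1, 0.04, 0.16)
  kern <- function(u) exp(-(u - 0.1)^2 / (2 * 0.04)) * exp(-u^2 / (2 * 0.16))
  z0 <- integrate(kern, 0, Inf, rel.tol = 1e-12)$value
  m1 <- integrate(function(u) u * kern(u), 0, Inf, rel.tol = 1e-12)$value / z0
  m2 <- integrate(function(u) u^2 * kern(u), 0, Inf, rel.tol = 1e-12)$value / z0
  w <- sqrt(fcq$var)
  a <- -fcq$mean / w
  lam_tn <- dnorm(a) / pnorm(a, lower.tail = FALSE)
  mean_tn <- fcq$mean + w * lam_tn
  var_tn <- fcq$var * (1 + a * lam_tn - lam_tn^2)
  expect_lt(abs(mean_tn - m1), 1e-4)
  expect_lt(abs(var_tn - (m2 - m1^2)), 1e-4)

  expect_error(full_conditional_u(0.1, 0, 1), class = "invalid_argument")
  expect_error(full_conditional_u(0.1, 1, -1), class = "invalid_argument")
})

test_that("noise-precision full conditional: arithmetic and grid shape", {
  pri <- frontier_priors(noise_shape = 0.001, noise_rate = 0.001)
  # zero residuals (u = X beta - y >= 0): rate stays at b0
  pan0 <- panel_dataset(c("a", "b"), c(1L, 1L), c(-0.5, -0.2), matrix(1, 2, 1))
  fc0 <- full_conditional_noise_precision(pan0, 0, c(0.5, 0.2), pri)
  expect_equal(fc0$rate, 0.001)
  expect_equal(fc0$shape, 0.001 + 1)

  # residuals (-1, -1) with a0 = b0 = 0.001 -> Gamma(1.001, 1.001)
  pan <- panel_dataset(c("a", "b"), c(1L, 1L), c(-1, -1), matrix(1, 2, 1))
  fc <- full_conditional_noise_precision(pan, 0, c(0, 0), pri)
  expect_equal(fc$shape, 1.001)
  expect_equal(fc$rate, 1.001)

  # implied sigma2 density matches a normalized grid of likelihood x prior
  resid <- c(0.6, -0.3, 0.2)
  pan3 <- panel_dataset(letters[1:3], rep(1L, 3), resid, matrix(1, 3, 1))
  pri3 <- frontier_priors(noise_shape = 2, noise_rate = 0.1)
  fc3 <- full_conditional_noise_precision(pan3, 0, c(0, 0, 0), pri3)
  s2g <- seq(1e-4, 20, length.out = 200000)   # covers essentially all the mass
  ds2 <- s2g[2] - s2g[1]
  lik <- -(length(resid) / 2) * log(2 * pi * s2g) - sum(resid^2) / (2 * s2g)
  prior <- -(pri3$noise_shape + 1) * log(s2g) - pri3$noise_rate / s2g
  grid_dens <- exp(lik + prior)
  grid_dens <- grid_dens / (sum(grid_dens) * ds2)
  implied <- dgamma(1 / s2g, fc3$shape, fc3$rate) / s2g^2
  expect_lt(max(abs(grid_dens - implied)), 1e-6)
})

test_that("inefficiency-precision full conditional: arithmetic and recovery", {
  pri <- frontier_priors(ineff_shape = 0.01, ineff_rate = 0.01)
  fc0 <- full_conditional_ineff_precision(rep(0, 6), pri)
  expect_equal(fc0$shape, 0.01 + 3)
  expect_equal(fc0$rate, 0.01)

  fc <- full_conditional_ineff_precision(c(1, 1), pri)
  expect_equal(fc$shape, 1.01)
  expect_equal(fc$rate, 1.01)

  set.seed(34)
  lam_true <- 0.2
  u <- rhalfnorm(10000, lam_true)
  fcr <- full_conditional_ineff_precision(u, pri)
  lam_post <- 1 / rgamma(50000, fcr$shape, fcr$rate)
  expect_lt(abs(mean(lam_post) - lam_true), 3 * sd(lam_post))

  expect_error(full_conditional_ineff_precision(c(-0.1, 1), pri),
               class = "invalid_argument")
})

test_that("run_gibbs retains the documented number of draws", {
  s <- mcmc_settings(37500, 12000)          # reference run length
  expect_identical((s$n_iter - s$n_burn) %/% s$thin, 25500L)
  expect_error(mcmc_settings(100, 100), class = "invalid_argument")
  expect_error(mcmc_settings(100, 10, thin = 0), class = "invalid_argument")

  sim <- simulate_frontier_panel(4, 3, frontier_params(seed = 35))
  dr <- run_gibbs(sim$panel, frontier_priors(), mcmc_settings(130, 40, thin = 3, seed = 1))
  expect_identical(nrow(dr$beta_draws), 30L)
  expect_identical(nrow(dr$u_draws), 30L)
})

test_that("run_gibbs invariants and seed determinism hold", {
  sim <- simulate_frontier_panel(6, 4, frontier_params(seed = 36))
  st <- mcmc_settings(400, 100, seed = 9)
  d1 <- run_gibbs(sim$panel, frontier_priors(), st)
  d2 <- run_gibbs(sim$panel, frontier_priors(), st)
  d3 <- run_gibbs(sim$panel, frontier_priors(), mcmc_settings(400, 100, seed = 10))
  expect_identical(d1, d2)
  expect_false(identical(d1$beta_draws, d3$beta_draws))
  expect_true(all(d1$u_draws >= 0))
  expect_true(all(d1$sigma2_draws > 0))
  expect_true(all(d1$lambda_draws > 0))
})

test_that("run_gibbs recovers a degenerate no-inefficiency truth", {
  truth <- c(4.3, 0.05, 0.02, 0.01)
  sim <- simulate_frontier_panel(20, 8, frontier_params(
    beta = truth, sigma_v = 0.05, lambda_u = 1e-8, seed = 37))
  dr <- run_gibbs(sim$panel, frontier_priors(), mcmc_settings(3000, 800, seed = 38))
  pm <- colMeans(dr$beta_draws)
  psd <- apply(dr$beta_draws, 2, sd)
  # slope coefficients recover directly
  expect_true(all(abs(pm[-1] - truth[-1]) < 3 * psd[-1]))
  expect_lt(mean(dr$lambda_draws), 0.01)
  # the intercept is only identified jointly with the mean inefficiency
  # E[u] = sqrt(2 lambda / pi) (the Gamma prior floors lambda above zero, so
  # the raw intercept sits E[u] above truth); the frontier level
  # beta0 - E[u] is the identified quantity
  level <- dr$beta_draws[, 1] - sqrt(2 * dr$lambda_draws / pi)
  expect_lt(abs(mean(level) - truth[1]), 3 * sd(level))
})

test_that("run_gibbs recovers frontier parameters at reduced scale", {
  # reduced-scale version of the stated 29x13 recovery (full scale runs in
  # the acceptance suite): 4000 iterations instead of 20000
  truth <- frontier_params()              # beta (4.3, 0.05, 0.02, 0.01), sv 0.05, lam 0.1
  sim <- simulate_frontier_panel(29, 13, truth)
  dr <- run_gibbs(sim$panel, frontier_priors(), mcmc_settings(4000, 1000, seed = 39))
  pm <- colMeans(dr$beta_draws)
  psd <- apply(dr$beta_draws, 2, sd)
  expect_true(all(abs(pm - truth$beta) < 3 * psd))
  expect_lt(abs(mean(dr$sigma2_draws) - truth$sigma_v^2), 3 * sd(dr$sigma2_draws))
  expect_lt(abs(mean(dr$lambda_draws) - truth$lambda_u), 3 * sd(dr$lambda_draws))
  expect_gt(cor(colMeans(dr$u_draws), sim$u), 0.7)
})

test_that("technical efficiency scores behave under exp(-u)", {
  u1 <- matrix(0, 50, 6)
  units <- rep(c("a", "b", "c"), each = 2)
  eff1 <- technical_efficiency(fake_frontier_draws(u1, units))
  expect_true(all(eff1$score == 1))

  set.seed(40)
  u2 <- matrix(rexp(300, 5), 50, 6)
  effa <- technical_efficiency(fake_frontier_draws(u2, units))
  effb <- technical_efficiency(fake_frontier_draws(2 * u2, units))
  sa <- effa$score[order(effa$unit)]
  sb <- effb$score[order(effb$unit)]
  expect_true(all(sb < sa))               # doubling u strictly decreases scores
  expect_true(all(effa$score > 0 & effa$score <= 1))

  # closed form E[exp(-u)] = 2 exp(lam/2) pnorm(-sqrt(lam)) for half-normal u
  set.seed(41)
  lam <- 0.25
  u <- rhalfnorm(1e5, lam)
  target <- 2 * exp(lam / 2) * pnorm(-sqrt(lam))
  e <- exp(-u)
  expect_lt(abs(mean(e) - target), 3 * sd(e) / sqrt(length(e)))
})

test_that("ranking is dense, deterministic, and breaks ties alphabetically", {
  ref <- reference_efficiency_scores()
  ranked <- rank_efficiency(setNames(ref$score, ref$country))
  expect_identical(ranked$rank, 1:29)
  expect_identical(ranked$unit[ranked$rank], ref$country[ref$rank])

  tie <- rank_efficiency(c(Mexico = 0.955, Iceland = 0.955, Zebra = 0.2))
  expect_identical(tie$unit, c("Iceland", "Mexico", "Zebra"))
  expect_identical(tie$rank, 1:3)

  single <- rank_efficiency(c(only = 0.5))
  expect_identical(single$rank, 1L)

  expect_error(rank_efficiency(data.frame(unit = c("a", "a"), score = c(0.5, 0.6))),
               class = "invalid_argument")
  expect_error(rank_efficiency(c(a = 0, b = 0.5)), class = "invalid_argument")
  expect_error(rank_efficiency(c(a = 1.2, b = 0.5)), class = "invalid_argument")
})
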