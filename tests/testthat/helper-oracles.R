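# Independent oracles shared across test files. These deliberately avoid the
# package's own code paths: quantiles by sort-and-index, posteriors by grid
# integration with the latent inefficiencies integrated out in closed form.

# type-7 quantile by direct order-statistic interpolation
quantile_type7_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  })
}

# log-density of the composed error eps = v - u, v ~ N(0, s2), u ~ |N(0, lam)|
eps_logdens <- function(eps, s2, lam) {
  stot <- sqrt(s2 + lam)
  log(2) + dnorm(eps / stot, log = TRUE) - log(stot) +
    pnorm(-eps * sqrt(lam) / (sqrt(s2) * stot), log.p = TRUE)
}

# Posterior means of (beta, sigma2, lambda) for an intercept-only frontier
# with N observations, by 3-D grid integration over (beta, log s2, log lam).
sfa_grid_means <- function(y, priors, bg, ls2_range = log(c(1e-5, 3)),
                           llam_range = log(c(1e-6, 3)), ns = 201, nl = 201) {
  s2g <- exp(seq(ls2_range[1], ls2_range[2], length.out = ns))
  lamg <- exp(seq(llam_range[1], llam_range[2], length.out = nl))
  # precision ~ Ga(a,b) => p(s2) propto s2^(-a-1) e^(-b/s2); extra log(s2) is
  # the Jacobian of the log-spaced grid
  lp_s2 <- dgamma(1 / s2g, priors$noise_shape, priors$noise_rate, log = TRUE) -
    2 * log(s2g) + log(s2g)
  lp_lam <- dgamma(1 / lamg, priors$ineff_shape, priors$ineff_rate, log = TRUE) -
    2 * log(lamg) + log(lamg)
  lp_b <- dnorm(bg, 0, priors$beta_prior_sd, log = TRUE)
  post <- array(NA_real_, c(length(bg), ns, nl))
  for (is in seq_len(ns)) for (il in seq_len(nl)) {
    ll <- 0
    for (yi in y) ll <- ll + eps_logdens(yi - bg, s2g[is], lamg[il])
    post[, is, il] <- ll + lp_b + lp_s2[is] + lp_lam[il]
  }
  w <- exp(post - max(post))
  tot <- sum(w)
  c(beta = sum(apply(w, 1, sum) * bg) / tot,
    sigma2 = sum(apply(w, 2, sum) * s2g) / tot,
    lambda = sum(apply(w, 3, sum) * lamg) / tot)
}

# Posterior means of (beta0, phi) for intercept-only beta regression by 2-D
# grid integration over (beta0, log phi).
beta_grid_means <- function(y, priors, bg = seq(-8, 8, length.out = 601),
                            pg = exp(seq(log(1e-3), log(200), length.out = 601))) {
  lp <- outer(bg, pg, function(b, p) {
    mu <- plogis(b)
    ll <- 0
    for (yi in y) ll <- ll + dbeta(yi, mu * p, (1 - mu) * p, log = TRUE)
    ll + dnorm(b, 0, priors$beta_prior_sd, log = TRUE) +
      dgamma(p, priors$phi_shape, priors$phi_rate, log = TRUE) + log(p)
  })
  w <- exp(lp - max(lp))
  c(beta = sum(rowSums(w) * bg) / sum(w), phi = sum(colSums(w) * pg) / sum(w))
}

# Quadrature of the implemented beta density over (0,1). Endpoint
# singularities (shape < 1) are removed by the substitutions y = u^(1/a) and
# 1 - y = w^(1/b) on the two halves.
beta_norm_quad <- function(mu, phi) {
  a <- mu * phi
  b <- (1 - mu) * phi
  f <- function(y) exp(beta_logpdf(y, mu, phi))
  left <- if (a >= 1) {
    integrate(f, 0, 0.5, rel.tol = 1e-9, subdivisions = 2000L)$value
  } else {
    integrate(function(u) f(u^(1 / a)) * (1 / a) * u^(1 / a - 1),
              0, 0.5^a, rel.tol = 1e-9, subdivisions = 2000L)$value
  }
  right <- if (b >= 1) {
    integrate(f, 0.5, 1, rel.tol = 1e-9, subdivisions = 2000L)$value
  } else {
    # keep 1 - y representable: integrate down to 1 - y = t_min only (t_min large enough that 1 - t_min is accurately representable), and add
    # the analytic sliver of the power-law tail K (1-y)^(b-1) beyond it
    t_min <- 1e-8
    main <- integrate(function(w) f(1 - w^(1 / b)) * (1 / b) * w^(1 / b - 1),
                      t_min^b, 0.5^b, rel.tol = 1e-9, subdivisions = 2000L)$value
    main + f(1 - t_min) * t_min / b
  }
  left + right
}

# standard-normal-covariate design with intercept and unit rownames
make_normal_design <- function(n, p = 1L, seed = 1L) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("X", seq_len(p)))))
  colnames(X)[1] <- "(Intercept)"
  rownames(X) <- sprintf("u%04d", seq_len(n))
  X
}

# hand-built frontier_draws object for efficiency-scoring tests
fake_frontier_draws <- function(u_draws, unit, period = rep(1L, ncol(u_draws))) {
  structure(list(
    beta_draws = matrix(0, nrow(u_draws), 1, dimnames = list(NULL, "(Intercept)")),
    sigma2_draws = rep(1, nrow(u_draws)),
    lambda_draws = rep(1, nrow(u_draws)),
    u_draws = u_draws,
    settings = mcmc_settings(nrow(u_draws) + 1L, 1L, 1L, 1L),
    unit = unit, period = period), class = "frontier_draws")
}
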