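# Bayesian stochastic frontier estimation by Gibbs sampling with data
# augmentation. Model, per observation it:
#
#   y_it = x_it' beta + v_it - u_it,   v_it ~ N(0, sigma^2),
#   u_it ~ half-normal: |N(0, lambda)|   (lambda = variance of the folded normal)
#
# Priors: beta_j ~ N(0, sigma_beta^2); sigma^-2 ~ Gamma(a0, b0);
# lambda^-1 ~ Gamma(c, d). All four full conditionals are conjugate once the
# latent u are treated as parameters, which is exactly what the augmentation
# buys.

#' Priors for the Bayesian stochastic frontier model
#'
#' @param beta_prior_sd prior standard deviation of every frontier
#'   coefficient, `beta_j ~ N(0, beta_prior_sd^2)`. Default 100 (weakly
#'   informative on a log-outcome scale).
#' @param noise_shape,noise_rate Gamma prior on the noise precision
#'   `sigma^-2`; defaults 0.001, 0.001 (proper but diffuse).
#' @param ineff_shape,ineff_rate Gamma prior on the inefficiency precision
#'   `lambda^-1`; defaults 0.01, 0.01.
#' @return an object of class `frontier_priors`.
#' @export
frontier_priors <- function(beta_prior_sd = 100,
                            noise_shape = 0.001, noise_rate = 0.001,
                            ineff_shape = 0.01, ineff_rate = 0.01) {
  check_scalar_pos(beta_prior_sd, "beta_prior_sd")
  check_scalar_pos(noise_shape, "noise_shape")
  check_scalar_pos(noise_rate, "noise_rate")
  check_scalar_pos(ineff_shape, "ineff_shape")
  check_scalar_pos(ineff_rate, "ineff_rate")
  structure(list(beta_prior_sd = beta_prior_sd,
                 noise_shape = noise_shape, noise_rate = noise_rate,
                 ineff_shape = ineff_shape, ineff_rate = ineff_rate),
            class = "frontier_priors")
}

#' MCMC run-length settings
#'
#' Defaults for the frontier stage follow the reference analysis: 37500
#' iterations with the first 12000 discarded and no thinning.
#'
#' @param n_iter total iterations.
#' @param n_burn burn-in iterations discarded (`0 <= n_burn < n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (`>= 1`).
#' @param seed integer RNG seed.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 37500L, n_burn = 12000L, thin = 1L, seed = 1L) {
  n_iter <- check_count(n_iter, "n_iter")
  n_burn <- check_count(n_burn, "n_burn", min = 0L)
  thin <- check_count(thin, "thin")
  seed <- check_count(seed, "seed", min = 0L)
  if (n_burn >= n_iter) stop_invalid("'n_burn' must be < 'n_iter'")
  structure(list(n_iter = n_iter, n_burn = n_burn, thin = thin, seed = seed),
            class = "mcmc_settings")
}

n_retained <- function(settings) {
  (settings$n_iter - settings$n_burn) %/% settings$thin
}

#' Full conditional of the frontier coefficients
#'
#' Given the latent inefficiencies the model is a linear regression on the
#' augmented outcome `ytilde = y + u`, so `beta | . ~ N(m, V)` with
#' `V = (X'X / sigma2 + I / sigma_beta^2)^-1` and
#' `m = V X' ytilde / sigma2`.
#'
#' @param data a [panel_dataset()].
#' @param u nonnegative latent inefficiency vector (one per observation).
#' @param sigma2 current noise variance (> 0).
#' @param priors a [frontier_priors()].
#' @return list with `mean` (vector) and `cov` (symmetric p.d. matrix).
#' @export
full_conditional_beta <- function(data, u, sigma2, priors = frontier_priors()) {
  stopifnot(inherits(data, "panel_dataset"))
  if (length(u) != length(data$y)) stop_invalid("'u' must have one element per observation")
  if (any(u < 0)) stop_invalid("'u' must be nonnegative")
  check_scalar_pos(sigma2, "sigma2")
  X <- data$X
  ytilde <- data$y + u
  A <- crossprod(X) / sigma2 + diag(1 / priors$beta_prior_sd^2, ncol(X))
  R <- tryCatch(chol(A), error = function(e) {
    stop_numerical(paste0("singular full-conditional precision for beta: ", conditionMessage(e)))
  })
  V <- chol2inv(R)
  m <- drop(V %*% (crossprod(X, ytilde) / sigma2))
  list(mean = m, cov = (V + t(V)) / 2)
}

#' Full conditional of one latent inefficiency
#'
#' With residual base `r_i = x_i' beta - y_i`, the conditional of `u_i` is
#' `N(mu_star_i, omega2)` truncated to `[0, Inf)`, where
#' `omega2 = (1/sigma2 + 1/lambda)^-1` and `mu_star_i = omega2 r_i / sigma2`.
#'
#' @param residual_base vector `x'beta - y` per observation.
#' @param sigma2 noise variance (> 0).
#' @param lambda half-normal scale (variance of the underlying normal, > 0).
#' @return list with `mean` (vector `mu_star`) and `var` (scalar `omega2`).
#' @export
full_conditional_u <- function(residual_base, sigma2, lambda) {
  check_finite_vector(residual_base, "residual_base")
  check_scalar_pos(sigma2, "sigma2")
  check_scalar_pos(lambda, "lambda")
  omega2 <- 1 / (1 / sigma2 + 1 / lambda)
  list(mean = omega2 * residual_base / sigma2, var = omega2)
}

#' Full conditional of the noise precision
#'
#' `sigma^-2 | . ~ Gamma(a0 + N/2, b0 + 0.5 * sum((y - X beta + u)^2))`.
#'
#' @inheritParams full_conditional_beta
#' @param beta current coefficient vector.
#' @return list with `shape` and `rate` of the Gamma full conditional.
#' @export
full_conditional_noise_precision <- function(data, beta, u, priors = frontier_priors()) {
  stopifnot(inherits(data, "panel_dataset"))
  resid <- data$y - drop(data$X %*% beta) + u
  list(shape = priors$noise_shape + length(resid) / 2,
       rate = priors$noise_rate + 0.5 * sum(resid^2))
}

#' Full conditional of the inefficiency precision
#'
#' `lambda^-1 | . ~ Gamma(c + N/2, d + 0.5 * sum(u^2))`.
#'
#' @param u nonnegative latent inefficiency vector.
#' @param priors a [frontier_priors()].
#' @return list with `shape` and `rate`.
#' @export
full_conditional_ineff_precision <- function(u, priors = frontier_priors()) {
  if (any(u < 0)) stop_invalid("'u' must be nonnegative")
  list(shape = priors$ineff_shape + length(u) / 2,
       rate = priors$ineff_rate + 0.5 * sum(u^2))
}

frontier_log_posterior <- function(data, beta, sigma2, lambda, u, priors) {
  resid <- data$y - drop(data$X %*% beta) + u
  sum(stats::dnorm(resid, 0, sqrt(sigma2), log = TRUE)) +
    sum(log(2) + stats::dnorm(u, 0, sqrt(lambda), log = TRUE)) +
    sum(stats::dnorm(beta, 0, priors$beta_prior_sd, log = TRUE)) +
    stats::dgamma(1 / sigma2, priors$noise_shape, priors$noise_rate, log = TRUE) +
    stats::dgamma(1 / lambda, priors$ineff_shape, priors$ineff_rate, log = TRUE)
}

#' Gibbs sampler for the Bayesian stochastic frontier model
#'
#' Cycles the four conjugate full conditionals in the fixed order
#' (u, beta, noise precision, inefficiency precision), starting from
#' deterministic initial values: beta at OLS, u at 0.01, sigma2 at the OLS
#' residual variance, lambda at 0.1. The RNG is seeded once from
#' `settings$seed`, so identical settings give bit-identical draws.
#'
#' @param data a [panel_dataset()].
#' @param priors a [frontier_priors()].
#' @param settings an [mcmc_settings()].
#' @param verbose emit a progress line (iteration, current log posterior)
#'   every 1000 iterations.
#' @return an object of class `frontier_draws`: list with `beta_draws`
#'   (retained draws x coefficients), `sigma2_draws`, `lambda_draws`,
#'   `u_draws` (retained draws x observations), plus the `settings` and the
#'   panel's `unit`/`period` vectors for downstream scoring.
#' @export
run_gibbs <- function(data, priors = frontier_priors(), settings = mcmc_settings(),
                      verbose = FALSE) {
  stopifnot(inherits(data, "panel_dataset"))
  if (!inherits(priors, "frontier_priors")) stop_invalid("'priors' must be frontier_priors()")
  if (!inherits(settings, "mcmc_settings")) stop_invalid("'settings' must be mcmc_settings()")
  X <- data$X
  y <- data$y
  n <- length(y)
  k <- ncol(X)
  XtX <- crossprod(X)

  ols <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, k))
  ols[is.na(ols)] <- 0
  beta <- as.numeric(ols)
  sigma2 <- max(mean((y - drop(X %*% beta))^2), 1e-8)
  u <- rep(0.01, n)
  lambda <- 0.1

  keep <- n_retained(settings)
  beta_draws <- matrix(NA_real_, keep, k, dimnames = list(NULL, colnames(X)))
  sigma2_draws <- numeric(keep)
  lambda_draws <- numeric(keep)
  u_draws <- matrix(NA_real_, keep, n)
  prior_prec <- diag(1 / priors$beta_prior_sd^2, k)

  set.seed(settings$seed)
  slot <- 0L
  for (iter in seq_len(settings$n_iter)) {
    res <- tryCatch({
      # u | rest: independent truncated normals
      r <- drop(X %*% beta) - y
      fc_u <- full_conditional_u(r, sigma2, lambda)
      u <- rtnorm_nonneg(n, fc_u$mean, fc_u$var)

      # beta | rest: conjugate normal on the augmented outcome
      A <- XtX / sigma2 + prior_prec
      R <- chol(A)
      m <- backsolve(R, forwardsolve(t(R), crossprod(X, y + u) / sigma2))
      beta <- drop(m + backsolve(R, stats::rnorm(k)))

      # sigma^-2 | rest
      resid <- y - drop(X %*% beta) + u
      sigma2 <- 1 / stats::rgamma(1, priors$noise_shape + n / 2,
                                  priors$noise_rate + 0.5 * sum(resid^2))

      # lambda^-1 | rest
      lambda <- 1 / stats::rgamma(1, priors$ineff_shape + n / 2,
                                  priors$ineff_rate + 0.5 * sum(u^2))
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      stop_numerical(sprintf("Gibbs update failed at iteration %d: %s",
                             iter, conditionMessage(res)))
    }
    if (verbose && iter %% 1000L == 0L) {
      message(sprintf("gibbs iter %d/%d log-posterior %.3f", iter, settings$n_iter,
                      frontier_log_posterior(data, beta, sigma2, lambda, u, priors)))
    }
    if (iter > settings$n_burn && (iter - settings$n_burn) %% settings$thin == 0L) {
      slot <- slot + 1L
      beta_draws[slot, ] <- beta
      sigma2_draws[slot] <- sigma2
      lambda_draws[slot] <- lambda
      u_draws[slot, ] <- u
    }
  }
  structure(list(beta_draws = beta_draws, sigma2_draws = sigma2_draws,
                 lambda_draws = lambda_draws, u_draws = u_draws,
                 settings = settings, unit = data$unit, period = data$period),
            class = "frontier_draws")
}

#' @export
print.frontier_draws <- function(x, ...) {
  cat(sprintf("frontier_draws: %d retained draws, %d coefficients, %d observations\n",
              nrow(x$beta_draws), ncol(x$beta_draws), ncol(x$u_draws)))
  invisible(x)
}

#' Technical-efficiency scores from posterior draws
#'
#' Per observation, efficiency is the posterior mean of `exp(-u_it)` over the
#' retained draws; per unit, the score is the arithmetic mean of its
#' per-observation efficiencies across periods. Scores lie in (0, 1].
#'
#' @param draws a `frontier_draws` object from [run_gibbs()].
#' @param data the [panel_dataset()] the draws were fitted to (optional when
#'   the draws carry unit labels, which [run_gibbs()] output always does).
#' @return an `efficiency_table`: data.frame with columns `unit`, `score`,
#'   `rank` (dense ranks, ties broken alphabetically), sorted by rank.
#' @export
technical_efficiency <- function(draws, data = NULL) {
  stopifnot(inherits(draws, "frontier_draws"))
  if (nrow(draws$u_draws) < 1L) stop_invalid("no retained draws")
  unit <- if (!is.null(data)) data$unit else draws$unit
  if (length(unit) != ncol(draws$u_draws)) {
    stop_invalid("unit labels do not match the number of observations in the draws")
  }
  eff_obs <- colMeans(exp(-draws$u_draws))
  scores <- tapply(eff_obs, unit, mean)
  rank_efficiency(stats::setNames(as.numeric(scores), names(scores)))
}

#' Dense efficiency ranking
#'
#' Ranks units 1..N by decreasing score; exact ties are ordered
#' alphabetically (C locale) by unit label, so the ranking is a permutation
#' and fully deterministic.
#'
#' @param scores named numeric vector of scores in (0, 1], or a data.frame
#'   with columns `unit` and `score`.
#' @return an `efficiency_table` data.frame (`unit`, `score`, `rank`) sorted
#'   by rank.
#' @export
rank_efficiency <- function(scores) {
  if (is.data.frame(scores)) {
    unit <- as.character(scores$unit)
    score <- as.numeric(scores$score)
  } else {
    unit <- names(scores)
    score <- as.numeric(scores)
  }
  if (is.null(unit) || any(!nzchar(unit))) stop_invalid("scores must carry unit labels")
  if (anyDuplicated(unit)) stop_invalid("duplicate unit labels in scores")
  if (any(!is.finite(score)) || any(score <= 0 | score > 1)) {
    stop_invalid("all scores must lie in (0, 1]")
  }
  ord <- order_c_locale(-score, unit)
  out <- data.frame(unit = unit[ord], score = score[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Write / read an efficiency table as CSV
#'
#' Schema: `country,score,rank`.
#'
#' @param table an `efficiency_table`.
#' @param path CSV path.
#' @return `write_efficiency_csv` returns `path` invisibly;
#'   `read_efficiency_csv` an `efficiency_table`.
#' @export
write_efficiency_csv <- function(table, path) {
  stopifnot(inherits(table, "efficiency_table"))
  df <- data.frame(country = table$unit, score = table$score, rank = table$rank)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_efficiency_csv
#' @export
read_efficiency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(unit = df$country, score = df$score, rank = df$rank,
                    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_table", "data.frame")
  out
}
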