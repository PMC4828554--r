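# Beta regression with a logit link: density, log-likelihood, maximum
# likelihood (the frequentist oracle), and an adaptive Metropolis-within-
# Gibbs sampler for the Bayesian fit. The mean/precision parameterization is
# E(y) = mu, Var(y) = mu (1 - mu) / (1 + phi), with shapes (mu phi,
# (1 - mu) phi).

#' Logit link and its inverse
#'
#' `inv_logit` is computed via [stats::plogis()] and is stable for
#' `|eta| <= 700`; `logit` rejects arguments outside the open unit interval.
#'
#' @param mu value(s) in (0,1).
#' @param eta real value(s).
#' @return numeric vector.
#' @export
logit <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0 | mu >= 1)) {
    stop_invalid("'mu' must lie strictly in (0,1)")
  }
  stats::qlogis(mu)
}

#' @rdname logit
#' @export
inv_logit <- function(eta) {
  if (any(!is.finite(eta))) stop_invalid("'eta' must be finite")
  stats::plogis(eta)
}

#' Log-density of the beta distribution in mean/precision form
#'
#' `lgamma(phi) - lgamma(mu phi) - lgamma((1-mu) phi) + (mu phi - 1) log y +
#' ((1-mu) phi - 1) log(1-y)`. All three arguments are vectorized and
#' recycled.
#'
#' @param y observation(s) strictly in (0,1).
#' @param mu mean(s) strictly in (0,1).
#' @param phi precision(s), > 0.
#' @return numeric vector of log-densities.
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1)) {
    stop_invalid("'y' must lie strictly in (0,1) (density undefined on the boundary)")
  }
  if (any(!is.finite(mu)) || any(mu <= 0 | mu >= 1)) {
    stop_invalid("'mu' must lie strictly in (0,1)")
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) stop_invalid("'phi' must be > 0")
  lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
    (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y)
}

#' Beta-regression log-likelihood
#'
#' Sum of [beta_logpdf()] terms with `mu_t = inv_logit(x_t' beta)`.
#'
#' @param data a [betareg_data()].
#' @param beta coefficient vector (intercept + indicators), length `ncol(X)`.
#' @param phi precision, > 0.
#' @return scalar log-likelihood.
#' @export
betareg_loglik <- function(data, beta, phi) {
  stopifnot(inherits(data, "betareg_data"))
  if (length(beta) != ncol(data$X)) {
    stop_invalid(sprintf("beta has length %d but the design has %d columns",
                         length(beta), ncol(data$X)))
  }
  check_scalar_pos(phi, "phi")
  mu <- inv_logit(drop(data$X %*% beta))
  mu <- pmin(pmax(mu, .Machine$double.xmin), 1 - .Machine$double.eps)
  sum(beta_logpdf(data$y, mu, phi))
}

#' Priors for Bayesian beta regression
#'
#' @param beta_prior_sd prior SD of each coefficient, `beta ~ N(0,
#'   beta_prior_sd^2)`; default 100.
#' @param phi_shape,phi_rate Gamma prior on the precision `phi`; defaults
#'   0.01, 0.01 (positive and diffuse).
#' @return an object of class `betareg_priors`.
#' @export
betareg_priors <- function(beta_prior_sd = 100, phi_shape = 0.01, phi_rate = 0.01) {
  check_scalar_pos(beta_prior_sd, "beta_prior_sd")
  check_scalar_pos(phi_shape, "phi_shape")
  check_scalar_pos(phi_rate, "phi_rate")
  structure(list(beta_prior_sd = beta_prior_sd, phi_shape = phi_shape,
                 phi_rate = phi_rate),
            class = "betareg_priors")
}

# analytic score of the log-likelihood in (beta, phi)
betareg_score <- function(data, beta, phi) {
  X <- data$X
  y <- data$y
  mu <- inv_logit(drop(X %*% beta))
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  g_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                 (1 - mu) * digamma((1 - mu) * phi) +
                 mu * log(y) + (1 - mu) * log1p(-y))
  c(g_beta, g_phi)
}

# central-difference Jacobian of a vector-valued map (used on gradients, so
# the symmetrized result is a numerical Hessian)
num_jacobian <- function(f, x, eps = 1e-5) {
  k <- length(x)
  H <- matrix(NA_real_, length(f(x)), k)
  for (j in seq_len(k)) {
    h <- eps * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

ml_start_values <- function(data) {
  eta0 <- logit(data$y)
  beta0 <- qr.coef(qr(data$X), eta0)
  beta0[is.na(beta0)] <- 0
  mu0 <- inv_logit(drop(data$X %*% beta0))
  n <- length(data$y)
  k <- ncol(data$X)
  s2 <- sum((data$y - mu0)^2) / max(n - k, 1)
  phi0 <- mean(mu0 * (1 - mu0)) / max(s2, 1e-10) - 1
  list(beta = as.numeric(beta0), phi = max(phi0, 0.1))
}

#' Maximum-likelihood beta regression (Newton-type)
#'
#' Quasi-Newton maximization (BFGS with the analytic score) in `(beta, log
#' phi)`, started from a least-squares fit on the logit scale and polished by
#' Newton steps until the score norm drops below `tol`. Standard errors come
#' from the observed information (numerical Hessian of the negative
#' log-likelihood at the optimum) in the `(beta, phi)` parameterization.
#'
#' @param data a [betareg_data()].
#' @param tol convergence tolerance on the score norm (default 1e-6).
#' @param max_newton maximum number of polishing Newton steps.
#' @return list with `beta` (named estimates), `phi`, `se` (named, for beta
#'   then phi), `loglik`, `score_norm`, `vcov`.
#' @export
betareg_fit_ml <- function(data, tol = 1e-6, max_newton = 50L) {
  stopifnot(inherits(data, "betareg_data"))
  n <- length(data$y)
  k <- ncol(data$X)
  if (n <= k + 2L) stop_invalid("need more observations than coefficients + 2")
  start <- ml_start_values(data)

  negll <- function(th) -betareg_loglik(data, th[seq_len(k)], exp(th[k + 1L]))
  neggr <- function(th) {
    g <- betareg_score(data, th[seq_len(k)], exp(th[k + 1L]))
    g[k + 1L] <- g[k + 1L] * exp(th[k + 1L])   # chain rule for log phi
    -g
  }
  th <- c(start$beta, log(start$phi))
  opt <- stats::optim(th, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  th <- opt$par
  # Newton polish on the log-phi scale, with step halving
  for (i in seq_len(max_newton)) {
    gn <- neggr(th)                       # gradient of the negative log-likelihood
    if (sqrt(sum(gn^2)) < tol / 100) break
    H <- num_jacobian(neggr, th)          # Hessian of the negative log-likelihood
    step <- tryCatch(solve(H, gn), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    f0 <- negll(th)
    moved <- FALSE
    for (halving in 0:10) {
      cand <- th - step / 2^halving
      fc <- negll(cand)
      if (is.finite(fc) && fc <= f0 + 1e-10) { th <- cand; moved <- TRUE; break }
    }
    if (!moved) break
  }
  beta_hat <- th[seq_len(k)]
  phi_hat <- exp(th[k + 1L])
  score <- betareg_score(data, beta_hat, phi_hat)
  score_norm <- sqrt(sum(score^2))
  if (!is.finite(score_norm) || score_norm > tol) {
    stop_numerical(sprintf(
      "beta-regression ML did not converge: score norm %.3g (tol %.3g) after BFGS + Newton",
      score_norm, tol))
  }
  # observed information = negative Jacobian of the analytic score
  Hobs <- -num_jacobian(function(p) betareg_score(data, p[seq_len(k)], p[k + 1L]),
                        c(beta_hat, phi_hat))
  vcov <- tryCatch(solve(Hobs), error = function(e) {
    stop_numerical("observed information is singular at the ML estimate")
  })
  se <- sqrt(pmax(diag(vcov), 0))
  if (any(se == 0)) stop_numerical("non-positive observed-information standard error")
  names(beta_hat) <- colnames(data$X)
  names(se) <- c(colnames(data$X), "phi")
  list(beta = beta_hat, phi = phi_hat, se = se,
       loglik = betareg_loglik(data, beta_hat, phi_hat),
       score_norm = score_norm, vcov = vcov)
}

#' Metropolis-within-Gibbs sampler for Bayesian beta regression
#'
#' Componentwise Gaussian random-walk proposals on each coefficient and on
#' `log(phi)` (with the Jacobian term), targeting likelihood x `N(0,
#' sigma_beta^2)` coefficient priors x Gamma prior on `phi`. Proposal scales
#' adapt toward an acceptance rate of about 0.35 in batches of 50 iterations
#' during burn-in only, then stay frozen so the retained chain is Markovian.
#' Proposals whose likelihood overflows or lands outside the support are
#' rejected and counted. Seeded once, so runs are reproducible.
#'
#' @param data a [betareg_data()].
#' @param priors a [betareg_priors()].
#' @param settings an [mcmc_settings()]; the reference stage-2 run length is
#'   `mcmc_settings(48000, 9500)`.
#' @param verbose progress line every 1000 iterations.
#' @return an object of class `betareg_draws`: list with `beta_draws`
#'   (retained draws x coefficients), `phi_draws`, `accept` (post-burn-in
#'   acceptance rate per block), `n_overflow` (rejected non-finite
#'   proposals), and `settings`.
#' @export
run_beta_mcmc <- function(data, priors = betareg_priors(),
                          settings = mcmc_settings(48000L, 9500L), verbose = FALSE) {
  stopifnot(inherits(data, "betareg_data"))
  if (!inherits(priors, "betareg_priors")) stop_invalid("'priors' must be betareg_priors()")
  if (!inherits(settings, "mcmc_settings")) stop_invalid("'settings' must be mcmc_settings()")
  X <- data$X
  y <- data$y
  n <- length(y)
  k <- ncol(X)
  logy <- log(y)
  log1y <- log1p(-y)
  loglik_eta <- function(eta, phi) {
    mu <- stats::plogis(eta)
    if (any(mu <= 0) || any(mu >= 1)) return(-Inf)
    sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
          (mu * phi - 1) * logy + ((1 - mu) * phi - 1) * log1y)
  }

  start <- ml_start_values(data)
  beta <- start$beta
  phi <- start$phi
  eta <- drop(X %*% beta)
  ll <- loglik_eta(eta, phi)
  if (!is.finite(ll)) { beta <- rep(0, k); eta <- rep(0, n); ll <- loglik_eta(eta, phi) }

  nblk <- k + 1L
  scales <- rep(0.1, nblk)
  acc_batch <- integer(nblk)
  acc_keep <- integer(nblk)
  n_overflow <- 0L
  keep <- n_retained(settings)
  beta_draws <- matrix(NA_real_, keep, k, dimnames = list(NULL, colnames(X)))
  phi_draws <- numeric(keep)
  slot <- 0L
  batch_len <- 50L
  sd_b <- priors$beta_prior_sd

  set.seed(settings$seed)
  for (iter in seq_len(settings$n_iter)) {
    for (j in seq_len(k)) {
      prop <- beta[j] + scales[j] * stats::rnorm(1)
      eta_prop <- eta + X[, j] * (prop - beta[j])
      ll_prop <- loglik_eta(eta_prop, phi)
      if (!is.finite(ll_prop)) {
        n_overflow <- n_overflow + 1L
        lr <- -Inf
      } else {
        lr <- ll_prop - ll +
          stats::dnorm(prop, 0, sd_b, log = TRUE) - stats::dnorm(beta[j], 0, sd_b, log = TRUE)
      }
      if (log(stats::runif(1)) < lr) {
        beta[j] <- prop; eta <- eta_prop; ll <- ll_prop
        acc_batch[j] <- acc_batch[j] + 1L
        if (iter > settings$n_burn) acc_keep[j] <- acc_keep[j] + 1L
      }
    }
    lphi_prop <- log(phi) + scales[nblk] * stats::rnorm(1)
    phi_prop <- exp(lphi_prop)
    ll_prop <- loglik_eta(eta, phi_prop)
    if (!is.finite(ll_prop) || !is.finite(phi_prop) || phi_prop <= 0) {
      n_overflow <- n_overflow + 1L
      lr <- -Inf
    } else {
      lr <- ll_prop - ll +
        stats::dgamma(phi_prop, priors$phi_shape, priors$phi_rate, log = TRUE) -
        stats::dgamma(phi, priors$phi_shape, priors$phi_rate, log = TRUE) +
        lphi_prop - log(phi)   # Jacobian of the log transform
    }
    if (log(stats::runif(1)) < lr) {
      phi <- phi_prop; ll <- ll_prop
      acc_batch[nblk] <- acc_batch[nblk] + 1L
      if (iter > settings$n_burn) acc_keep[nblk] <- acc_keep[nblk] + 1L
    }

    if (iter <= settings$n_burn && iter %% batch_len == 0L) {
      rate <- acc_batch / batch_len
      delta <- min(0.25, 3 / sqrt(iter / batch_len))
      scales <- scales * exp(delta * (rate - 0.35))
      acc_batch[] <- 0L
    }
    if (verbose && iter %% 1000L == 0L) {
      message(sprintf("betareg iter %d/%d log-likelihood %.3f", iter, settings$n_iter, ll))
    }
    if (iter > settings$n_burn && (iter - settings$n_burn) %% settings$thin == 0L) {
      slot <- slot + 1L
      beta_draws[slot, ] <- beta
      phi_draws[slot] <- phi
    }
  }
  post_iters <- settings$n_iter - settings$n_burn
  accept <- acc_keep / post_iters
  names(accept) <- c(colnames(X), "log_phi")
  structure(list(beta_draws = beta_draws, phi_draws = phi_draws,
                 accept = accept, n_overflow = n_overflow, settings = settings),
            class = "betareg_draws")
}

#' @export
print.betareg_draws <- function(x, ...) {
  cat(sprintf("betareg_draws: %d retained draws, %d coefficients + phi; mean acceptance %.2f\n",
              nrow(x$beta_draws), ncol(x$beta_draws), mean(x$accept)))
  invisible(x)
}
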