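# Synthetic-data generators with known ground truth. Both stages of the
# pipeline are tested against datasets produced here: a frontier panel with
# normal noise and half-normal inefficiency, and beta-distributed responses
# with a logit-linear mean.

#' Ground-truth parameters for the synthetic frontier panel
#'
#' @param beta coefficient vector: intercept, then `length(beta) - 2`
#'   standard-normal covariates, then the time-trend coefficient. Defaults to
#'   the stated recovery scenario `c(4.3, 0.05, 0.02, 0.01)` (intercept near
#'   log life expectancy, small covariate and trend effects).
#' @param sigma_v noise standard deviation (> 0, outcome units).
#' @param lambda_u variance of the underlying normal of the half-normal
#'   inefficiency distribution (>= 0, outcome units squared): `u = |N(0,
#'   lambda_u)|`, so `E[u^2] = lambda_u` and `E[u] = sqrt(2 lambda_u / pi)`.
#' @param seed integer random seed.
#' @return an object of class `frontier_params`.
#' @export
frontier_params <- function(beta = c(4.3, 0.05, 0.02, 0.01),
                            sigma_v = 0.05, lambda_u = 0.1, seed = 1L) {
  check_finite_vector(beta, "beta")
  if (length(beta) < 2L) stop_invalid("'beta' needs at least intercept + trend coefficients")
  check_scalar_pos(sigma_v, "sigma_v")
  check_scalar_pos(lambda_u, "lambda_u", allow_zero = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(beta = as.numeric(beta), sigma_v = sigma_v,
                 lambda_u = lambda_u, seed = seed),
            class = "frontier_params")
}

#' Ground-truth parameters for synthetic beta-regression outcomes
#'
#' @param beta logit-scale coefficient vector (intercept + p indicators).
#'   Defaults to one active indicator with coefficient 0.3 among 20.
#' @param phi beta-distribution precision (> 0); response variance is
#'   `mu (1 - mu) / (1 + phi)`.
#' @param seed integer random seed.
#' @return an object of class `betareg_params`.
#' @export
betareg_params <- function(beta = c(0, 0.3, rep(0, 19)), phi = 30, seed = 1L) {
  check_finite_vector(beta, "beta")
  if (length(beta) < 2L) stop_invalid("'beta' needs intercept plus at least one indicator")
  check_scalar_pos(phi, "phi")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(beta = as.numeric(beta), phi = phi, seed = seed),
            class = "betareg_params")
}

#' Draw half-normal inefficiencies
#'
#' `u = |Z|`, `Z ~ N(0, lambda)`; `lambda` is the variance of the underlying
#' normal, so `E[u] = sqrt(2 lambda / pi)` and `E[u^2] = lambda`.
#'
#' @param n number of draws.
#' @param lambda variance of the underlying normal (>= 0).
#' @return nonnegative numeric vector of length `n`.
#' @export
rhalfnorm <- function(n, lambda) {
  n <- check_count(n, "n", min = 0L)
  check_scalar_pos(lambda, "lambda", allow_zero = TRUE)
  abs(stats::rnorm(n, 0, sqrt(lambda)))
}

#' Simulate a balanced frontier panel with known inefficiencies
#'
#' Builds a `n_units x n_periods` panel. The design has an intercept,
#' `length(beta) - 2` i.i.d. standard-normal covariates, and a deterministic
#' time trend `1..n_periods` as the last column. The outcome is
#' `y = X beta + v - u` with `v ~ N(0, sigma_v^2)` and half-normal `u`.
#' Random sub-streams are consumed in a fixed order (covariates, then noise,
#' then inefficiency) so a given seed always yields the identical dataset.
#'
#' @param n_units,n_periods panel dimensions (>= 1).
#' @param params a [frontier_params()] object.
#' @return list with elements `panel` (a [panel_dataset()]) and `u` (the true
#'   per-observation inefficiencies actually used, `>= 0`).
#' @examples
#' sim <- simulate_frontier_panel(5, 3, frontier_params(seed = 42))
#' sim$panel
#' @export
simulate_frontier_panel <- function(n_units, n_periods, params = frontier_params()) {
  n_units <- check_count(n_units, "n_units")
  n_periods <- check_count(n_periods, "n_periods")
  if (!inherits(params, "frontier_params")) params <- do.call(frontier_params, params)
  k_rand <- length(params$beta) - 2L
  n <- n_units * n_periods
  unit <- rep(sprintf("unit%02d", seq_len(n_units)), each = n_periods)
  period <- rep(seq_len(n_periods), times = n_units)

  set.seed(params$seed)
  Z <- if (k_rand > 0L) {
    matrix(stats::rnorm(n * k_rand), nrow = n,
           dimnames = list(NULL, paste0("x", seq_len(k_rand))))
  } else {
    matrix(numeric(0), nrow = n, ncol = 0L)
  }
  X <- cbind(`(Intercept)` = 1, Z, trend = as.numeric(period))
  v <- stats::rnorm(n, 0, params$sigma_v)
  u <- rhalfnorm(n, params$lambda_u)
  y <- drop(X %*% params$beta) + v - u
  list(panel = panel_dataset(unit, period, y, X), u = u)
}

#' Simulate an indicator design matrix
#'
#' Policy-indicator scores are integers 0-6; columns are drawn i.i.d.
#' uniformly on that grid. The returned matrix has a leading intercept
#' column.
#'
#' @param n_units number of units.
#' @param p number of indicator columns.
#' @param seed integer seed.
#' @return numeric matrix `n_units x (1 + p)` with unit labels as rownames.
#' @export
simulate_indicator_design <- function(n_units, p = 20L, seed = 1L) {
  n_units <- check_count(n_units, "n_units")
  p <- check_count(p, "p")
  set.seed(check_count(seed, "seed", min = 0L))
  ind <- matrix(sample(0:6, n_units * p, replace = TRUE), nrow = n_units,
                dimnames = list(NULL, paste0("X", seq_len(p))))
  X <- cbind(`(Intercept)` = 1, ind)
  rownames(X) <- sprintf("unit%03d", seq_len(n_units))
  X
}

#' Simulate beta-distributed responses on a given design
#'
#' For each row, `mu = inv_logit(x' beta)` and the response is drawn from
#' `Beta(mu * phi, (1 - mu) * phi)`. Draws that land exactly on 0 or 1 by
#' floating-point underflow are redrawn (the beta density lives on the open
#' interval), so the returned responses are always strictly inside (0,1).
#'
#' @param design numeric matrix with a leading intercept column (as from
#'   [simulate_indicator_design()]); rownames, when present, become unit
#'   labels.
#' @param params a [betareg_params()] object whose `beta` length matches
#'   `ncol(design)`.
#' @return a [betareg_data()] object.
#' @export
simulate_beta_outcomes <- function(design, params = betareg_params()) {
  if (!inherits(params, "betareg_params")) params <- do.call(betareg_params, params)
  design <- as.matrix(design)
  if (any(!is.finite(design))) stop_invalid("design contains non-finite values")
  if (ncol(design) != length(params$beta)) {
    stop_invalid(sprintf("design has %d columns but beta has length %d",
                         ncol(design), length(params$beta)))
  }
  n <- nrow(design)
  mu <- inv_logit(drop(design %*% params$beta))
  set.seed(params$seed)
  y <- stats::rbeta(n, mu * params$phi, (1 - mu) * params$phi)
  for (tries in 1:100) {
    bad <- which(y <= 0 | y >= 1)
    if (!length(bad)) break
    y[bad] <- stats::rbeta(length(bad), mu[bad] * params$phi, (1 - mu[bad]) * params$phi)
  }
  if (any(y <= 0 | y >= 1)) stop_numerical("could not draw responses inside (0,1)")
  unit <- rownames(design)
  if (is.null(unit)) unit <- sprintf("unit%03d", seq_len(n))
  betareg_data(unit, y, design)
}

#' Write ground-truth sidecar CSVs for synthetic datasets
#'
#' Stores the generating parameters (and per-observation inefficiencies for
#' the frontier stage) next to a synthetic dataset so recovery tests can read
#' truth back without re-simulating.
#'
#' @param sim result of [simulate_frontier_panel()].
#' @param params the generating [frontier_params()] / [betareg_params()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frontier_truth_csv <- function(sim, params, path) {
  df <- data.frame(
    name = c(paste0("beta", seq_along(params$beta) - 1L), "sigma_v", "lambda_u",
             paste0("u_", seq_along(sim$u))),
    value = c(params$beta, params$sigma_v, params$lambda_u, sim$u)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frontier_truth_csv
#' @export
write_betareg_truth_csv <- function(params, path) {
  df <- data.frame(
    name = c(paste0("beta", seq_along(params$beta) - 1L), "phi"),
    value = c(params$beta, params$phi)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
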