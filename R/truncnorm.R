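#' Sample from a normal distribution truncated to the nonnegative half-line
#'
#' Inverse-CDF sampling of `N(mu, var)` conditioned on being `>= 0`, done on
#' the log-probability scale so it stays accurate deep in the tail (means as
#' low as `-10 * sqrt(var)` and beyond). Used as the data-augmentation
#' primitive for the latent inefficiencies.
#'
#' @param n number of draws.
#' @param mu mean(s) of the untruncated normal (recycled to length `n`).
#' @param var variance(s) of the untruncated normal (> 0, recycled).
#' @return numeric vector of `n` nonnegative draws.
#' @export
rtnorm_nonneg <- function(n, mu, var) {
  n <- check_count(n, "n", min = 0L)
  if (any(!is.finite(mu))) stop_invalid("'mu' must be finite")
  if (any(!is.finite(var)) || any(var <= 0)) stop_invalid("'var' must be > 0")
  sd <- sqrt(var)
  alpha <- -mu / sd                      # lower truncation point in standard units
  # P(Z > z) = u * P(Z > alpha), solved on the log scale for tail safety
  log_sa <- stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(log(stats::runif(n)) + log_sa, lower.tail = FALSE, log.p = TRUE)
  pmax(mu + sd * z, 0)
}
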