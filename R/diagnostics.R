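# Posterior summarization and the two decision rules used downstream: the
# 5%-of-SD Monte Carlo error convergence rule and the credible-interval
# "related factor" flag.

#' Batch-means Monte Carlo standard error of a posterior mean
#'
#' The chain is split into `B = floor(sqrt(n))` consecutive batches of
#' `floor(n / B)` draws (any remainder at the end is dropped); the estimate
#' is the standard deviation of the batch means divided by `sqrt(B)`. For
#' autocorrelated chains this correctly inflates the naive `sd/sqrt(n)`.
#'
#' @param chain numeric vector of at least 20 draws.
#' @return nonnegative scalar.
#' @export
mc_error <- function(chain) {
  check_finite_vector(chain, "chain")
  n <- length(chain)
  if (n < 20L) stop_invalid("chain must hold at least 20 draws")
  B <- floor(sqrt(n))
  m <- n %/% B
  means <- colMeans(matrix(chain[seq_len(B * m)], nrow = m))
  stats::sd(means) / sqrt(B)
}

#' Posterior summary of one scalar chain
#'
#' Mean, SD (denominator n-1), batch-means MC error, and the 2.5%, 50%,
#' 97.5% empirical quantiles with linear interpolation (type 7).
#'
#' @param chain numeric vector of at least 20 draws.
#' @param label node label.
#' @param start index of the first retained iteration (reported, not used).
#' @return a one-row `posterior_summary` data.frame with columns `node`,
#'   `mean`, `sd`, `mc_error`, `q2.5`, `median`, `q97.5`, `start`, `sample`.
#' @export
summarize_chain <- function(chain, label = "node", start = 1L) {
  check_finite_vector(chain, "chain")
  if (length(chain) < 20L) stop_invalid("chain must hold at least 20 draws")
  q <- unname(stats::quantile(chain, c(0.025, 0.5, 0.975), type = 7))
  out <- data.frame(node = label, mean = mean(chain), sd = stats::sd(chain),
                    mc_error = mc_error(chain), q2.5 = q[1L], median = q[2L],
                    q97.5 = q[3L], start = as.integer(start),
                    sample = length(chain), stringsAsFactors = FALSE)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' The 5% Monte Carlo error convergence rule
#'
#' A node passes when its MC error is below 5% of its posterior SD (the
#' WinBUGS-era rule of thumb). A degenerate chain with `sd = 0` passes only
#' when the MC error is exactly 0. Vectorized over the rows of a summary
#' table.
#'
#' @param summary a `posterior_summary` (or any data.frame with `sd` and
#'   `mc_error` columns).
#' @return logical vector, one element per row.
#' @export
convergence_ok <- function(summary) {
  if (!all(c("sd", "mc_error") %in% names(summary))) {
    stop_invalid("summary must have 'sd' and 'mc_error' columns")
  }
  if (any(summary$sd < 0) || any(summary$mc_error < 0)) {
    stop_invalid("'sd' and 'mc_error' must be nonnegative")
  }
  ifelse(summary$sd == 0, summary$mc_error == 0, summary$mc_error < 0.05 * summary$sd)
}

#' Credible-interval significance ("related factor") flag
#'
#' An indicator is flagged as related when its central 95% credible interval
#' `[q2.5, q97.5]` excludes zero. Zero lying exactly on an endpoint counts as
#' included (conservative closed-interval convention). Vectorized over rows.
#'
#' @param summary a `posterior_summary` (or any data.frame with `q2.5` and
#'   `q97.5` columns).
#' @return logical vector, one element per row.
#' @export
related_factor <- function(summary) {
  if (!all(c("q2.5", "q97.5") %in% names(summary))) {
    stop_invalid("summary must have 'q2.5' and 'q97.5' columns")
  }
  summary$q2.5 > 0 | summary$q97.5 < 0
}

#' Summarize frontier posterior draws node by node
#'
#' One row per frontier coefficient plus the noise variance `sigma2` and the
#' inefficiency scale `lambda` (latent inefficiencies are not tabulated).
#'
#' @param draws a `frontier_draws` object from [run_gibbs()].
#' @return a `posterior_summary` data.frame, one row per node.
#' @export
summarize_frontier_draws <- function(draws) {
  stopifnot(inherits(draws, "frontier_draws"))
  start <- draws$settings$n_burn + 1L
  rows <- lapply(colnames(draws$beta_draws), function(nm) {
    summarize_chain(draws$beta_draws[, nm], nm, start)
  })
  rows <- c(rows, list(summarize_chain(draws$sigma2_draws, "sigma2", start),
                       summarize_chain(draws$lambda_draws, "lambda", start)))
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Summarize beta-regression posterior draws
#'
#' One row per coefficient plus a final row for the precision `phi`, with a
#' `related` column from [related_factor()] (`NA` for `phi`, where the flag
#' is not meaningful).
#'
#' @param draws a `betareg_draws` object from [run_beta_mcmc()].
#' @return a `posterior_summary` data.frame with an extra `related` column.
#' @export
summarize_betareg_draws <- function(draws) {
  stopifnot(inherits(draws, "betareg_draws"))
  start <- draws$settings$n_burn + 1L
  rows <- lapply(colnames(draws$beta_draws), function(nm) {
    summarize_chain(draws$beta_draws[, nm], nm, start)
  })
  rows <- c(rows, list(summarize_chain(draws$phi_draws, "phi", start)))
  out <- do.call(rbind, rows)
  out$related <- related_factor(out)
  out$related[out$node == "phi"] <- NA
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Write posterior summaries as CSV
#'
#' Frontier summaries use columns `node,mean,sd,mc_error,q2.5,median,q97.5,
#' start,sample`; beta-regression summaries use
#' `variable,mean,sd,mc_error,q2.5,q97.5,related`.
#'
#' @param summary a `posterior_summary` data.frame.
#' @param path CSV path.
#' @param style `"frontier"` or `"betareg"` column layout.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, style = c("frontier", "betareg")) {
  style <- match.arg(style)
  if (style == "frontier") {
    df <- summary[, c("node", "mean", "sd", "mc_error", "q2.5", "median", "q97.5",
                      "start", "sample")]
  } else {
    df <- data.frame(variable = summary$node, mean = summary$mean, sd = summary$sd,
                     mc_error = summary$mc_error, q2.5 = summary$q2.5,
                     q97.5 = summary$q97.5, related = summary$related,
                     stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
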