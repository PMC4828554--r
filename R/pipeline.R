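# Two-stage orchestration: frontier Gibbs sampling -> efficiency scores ->
# beta regression of scores on policy indicators, with CSV artifacts and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Either point `panel_csv` / `indicators_csv` at existing datasets, or set
#' `synthetic = TRUE` to generate both from the ground-truth parameter
#' objects (written to `out_dir` together with truth sidecars).
#'
#' @param out_dir output directory (created if missing).
#' @param panel_csv stage-1 panel CSV path (schema `unit,period,y,x1..xK`),
#'   or `NULL` in synthetic mode.
#' @param indicators_csv stage-2 indicator CSV path (schema
#'   `unit,score,X1..Xp`), or `NULL` in synthetic mode.
#' @param synthetic logical; generate inputs from `frontier_truth` /
#'   `betareg_truth`.
#' @param n_units,n_periods synthetic panel dimensions (default 29 x 13).
#' @param frontier_truth a [frontier_params()] for synthetic mode.
#' @param betareg_truth a [betareg_params()] for synthetic mode.
#' @param frontier_priors a [frontier_priors()].
#' @param betareg_priors a [betareg_priors()].
#' @param stage1 an [mcmc_settings()] for the frontier stage (default
#'   37500 iterations, 12000 burn-in).
#' @param stage2 an [mcmc_settings()] for the beta-regression stage (default
#'   48000 iterations, 9500 burn-in).
#' @param strict_convergence fail the pipeline when any monitored node
#'   violates the 5% MC-error rule.
#' @param verbose progress logging from the samplers.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            panel_csv = NULL, indicators_csv = NULL,
                            synthetic = is.null(panel_csv),
                            n_units = 29L, n_periods = 13L,
                            frontier_truth = frontier_params(),
                            betareg_truth = betareg_params(),
                            frontier_priors = bsfareg::frontier_priors(),
                            betareg_priors = bsfareg::betareg_priors(),
                            stage1 = mcmc_settings(37500L, 12000L),
                            stage2 = mcmc_settings(48000L, 9500L),
                            strict_convergence = FALSE, verbose = FALSE) {
  if (!synthetic) {
    if (!is.null(panel_csv) && !file.exists(panel_csv)) {
      stop_invalid(sprintf("panel CSV '%s' does not exist", panel_csv))
    }
    if (!is.null(indicators_csv) && !file.exists(indicators_csv)) {
      stop_invalid(sprintf("indicators CSV '%s' does not exist", indicators_csv))
    }
  }
  structure(list(out_dir = out_dir, panel_csv = panel_csv,
                 indicators_csv = indicators_csv, synthetic = synthetic,
                 n_units = check_count(n_units, "n_units"),
                 n_periods = check_count(n_periods, "n_periods"),
                 frontier_truth = frontier_truth, betareg_truth = betareg_truth,
                 frontier_priors = frontier_priors, betareg_priors = betareg_priors,
                 stage1 = stage1, stage2 = stage2,
                 strict_convergence = isTRUE(strict_convergence),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a flat-key file
#'
#' Recognized keys (all optional unless noted): `out_dir`, `panel_csv`,
#' `indicators_csv`, `synthetic`, `n_units`, `n_periods`, `frontier_beta`
#' (comma-separated), `sigma_v`, `lambda_u`, `betareg_beta`, `phi`, `seed`,
#' `stage1_iterations`, `stage1_burnin`, `stage1_thin`, `stage2_iterations`,
#' `stage2_burnin`, `stage2_thin`, `beta_prior_sd`, `noise_shape`,
#' `noise_rate`, `ineff_shape`, `ineff_rate`, `phi_shape`, `phi_rate`,
#' `strict_convergence`, `verbose`.
#'
#' @param path flat-key config file (`key = value` lines).
#' @param overrides named list merged over the file's values (CLI flags).
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_file <- function(path, overrides = list()) {
  cfg <- read_flat_config(path)
  cfg[names(overrides)] <- overrides
  get1 <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  seed <- as.integer(get1("seed", 1))
  fp <- frontier_params(beta = get1("frontier_beta", c(4.3, 0.05, 0.02, 0.01)),
                        sigma_v = get1("sigma_v", 0.05),
                        lambda_u = get1("lambda_u", 0.1), seed = seed)
  bp <- betareg_params(beta = get1("betareg_beta", c(0, 0.3, rep(0, 19))),
                       phi = get1("phi", 30), seed = seed + 1L)
  pipeline_config(
    out_dir = get1("out_dir", "bsfareg-output"),
    panel_csv = get1("panel_csv", NULL),
    indicators_csv = get1("indicators_csv", NULL),
    synthetic = isTRUE(get1("synthetic", is.null(cfg$panel_csv))),
    n_units = get1("n_units", 29L), n_periods = get1("n_periods", 13L),
    frontier_truth = fp, betareg_truth = bp,
    frontier_priors = frontier_priors(
      beta_prior_sd = get1("beta_prior_sd", 100),
      noise_shape = get1("noise_shape", 0.001), noise_rate = get1("noise_rate", 0.001),
      ineff_shape = get1("ineff_shape", 0.01), ineff_rate = get1("ineff_rate", 0.01)),
    betareg_priors = betareg_priors(
      beta_prior_sd = get1("beta_prior_sd", 100),
      phi_shape = get1("phi_shape", 0.01), phi_rate = get1("phi_rate", 0.01)),
    stage1 = mcmc_settings(get1("stage1_iterations", 37500L),
                           get1("stage1_burnin", 12000L),
                           get1("stage1_thin", 1L), seed),
    stage2 = mcmc_settings(get1("stage2_iterations", 48000L),
                           get1("stage2_burnin", 9500L),
                           get1("stage2_thin", 1L), seed + 2L),
    strict_convergence = isTRUE(get1("strict_convergence", FALSE)),
    verbose = isTRUE(get1("verbose", FALSE))
  )
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  config$out_dir
}

pipeline_panel <- function(config) {
  if (config$synthetic) {
    sim <- simulate_frontier_panel(config$n_units, config$n_periods,
                                   config$frontier_truth)
    out <- ensure_out_dir(config)
    write_panel_csv(sim$panel, file.path(out, "synthetic_panel.csv"))
    write_frontier_truth_csv(sim, config$frontier_truth,
                             file.path(out, "synthetic_panel_truth.csv"))
    sim$panel
  } else {
    read_panel_csv(config$panel_csv)
  }
}

check_convergence_or_fail <- function(summary, stage, strict) {
  ok <- convergence_ok(summary)
  bad <- summary$node[!ok]
  if (length(bad)) {
    msg <- sprintf("%s: MC error >= 5%% of SD for node(s): %s",
                   stage, paste(bad, collapse = ", "))
    if (strict) {
      stop(errorCondition(msg, class = c("convergence_failure", "bsfareg_error")))
    }
    message(msg)
  }
  invisible(ok)
}

#' Run the frontier stage of the pipeline
#'
#' Fits the Bayesian stochastic frontier by [run_gibbs()], scores and ranks
#' units with [technical_efficiency()], writes `stage1_summary.csv`
#' (node-level posterior summaries), `stage1_draws.csv` (one row per
#' retained draw of the frontier parameters) and `efficiency_scores.csv`,
#' and logs the 5% convergence rule per node (failing under
#' `strict_convergence`).
#'
#' @param config a [pipeline_config()].
#' @param panel optionally a pre-loaded [panel_dataset()]; by default read or
#'   simulated per the configuration.
#' @return list with `draws`, `efficiency`, `summary`, `converged`.
#' @export
run_stage1 <- function(config, panel = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- ensure_out_dir(config)
  if (is.null(panel)) panel <- pipeline_panel(config)
  draws <- run_gibbs(panel, config$frontier_priors, config$stage1,
                     verbose = config$verbose)
  summary <- summarize_frontier_draws(draws)
  eff <- technical_efficiency(draws, panel)
  write_summary_csv(summary, file.path(out, "stage1_summary.csv"), "frontier")
  param_draws <- data.frame(draws$beta_draws, sigma2 = draws$sigma2_draws,
                            lambda = draws$lambda_draws, check.names = FALSE)
  utils::write.csv(param_draws, file.path(out, "stage1_draws.csv"), row.names = FALSE)
  write_efficiency_csv(eff, file.path(out, "efficiency_scores.csv"))
  converged <- check_convergence_or_fail(summary, "stage 1", config$strict_convergence)
  list(draws = draws, efficiency = eff, summary = summary, converged = converged)
}

# Boundary policy for the beta likelihood: efficiency scores may be exactly
# 1 (and in pathological cases 0); the beta density is undefined there. When
# any boundary value is present, the standard shrink (y (n-1) + 0.5) / n is
# applied to ALL scores, loudly.
shrink_boundary_scores <- function(scores) {
  n <- length(scores)
  if (any(scores >= 1 | scores <= 0)) {
    message(sprintf(
      "stage 2: %d boundary efficiency score(s); applying (y*(n-1)+0.5)/n to all %d scores",
      sum(scores >= 1 | scores <= 0), n))
    scores <- (scores * (n - 1) + 0.5) / n
  }
  scores
}

#' Run the beta-regression stage of the pipeline
#'
#' Joins efficiency scores to the indicator design by unit label
#' (case-sensitive, must match one-to-one), fits [run_beta_mcmc()], writes
#' `stage2_draws.csv` and `stage2_summary.csv` (with the `related` flag from
#' [related_factor()]), and applies the convergence rule.
#'
#' When `scores` is `NULL` the response is taken from the indicator CSV's own
#' `score` column, in which case boundary values are rejected outright.
#' Scores handed over from stage 1 may legitimately equal 1 and are then
#' shrunk by `(y (n-1) + 0.5) / n` (applied to all scores, with a message).
#'
#' @param config a [pipeline_config()].
#' @param scores an `efficiency_table` from stage 1, or `NULL`.
#' @param indicators optional pre-built design matrix with unit rownames
#'   (synthetic mode builds one; otherwise the configured CSV is read).
#' @return list with `draws`, `summary`, `related` (character vector of
#'   flagged indicator names), `converged`, and the fitted `data`.
#' @export
run_stage2 <- function(config, scores = NULL, indicators = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- ensure_out_dir(config)

  if (is.null(indicators)) {
    if (config$synthetic) {
      n_units <- if (is.null(scores)) config$n_units else nrow(scores)
      design <- simulate_indicator_design(
        n_units, p = length(config$betareg_truth$beta) - 1L,
        seed = config$betareg_truth$seed)
      if (!is.null(scores)) {
        rownames(design) <- sort(scores$unit)
      } else {
        # standalone synthetic stage 2: draw beta-distributed responses
        bdata <- simulate_beta_outcomes(design, config$betareg_truth)
        write_betareg_csv(bdata, file.path(out, "synthetic_indicators.csv"))
        attr(design, "score") <- bdata$y
        rownames(design) <- bdata$unit
      }
      write_betareg_truth_csv(config$betareg_truth,
                              file.path(out, "synthetic_indicators_truth.csv"))
    } else {
      csv <- read_betareg_csv(config$indicators_csv)
      design <- csv$X
      rownames(design) <- csv$unit
      attr(design, "score") <- csv$y
    }
  } else {
    design <- indicators
  }

  if (is.null(scores)) {
    y <- attr(design, "score")
    if (is.null(y)) stop_invalid("no efficiency scores supplied and the indicator data carry none")
    unit <- rownames(design)
  } else {
    stopifnot(inherits(scores, "efficiency_table"))
    unit <- rownames(design)
    missing_units <- setdiff(scores$unit, unit)
    extra_units <- setdiff(unit, scores$unit)
    if (length(missing_units) || length(extra_units)) {
      stop_invalid(sprintf(
        "unit labels do not match one-to-one; missing from indicators: %s; missing from scores: %s",
        paste(missing_units, collapse = ", "), paste(extra_units, collapse = ", ")))
    }
    if (any(scores$score <= 0 | scores$score > 1)) {
      stop_invalid("efficiency scores must lie in (0, 1]")
    }
    y <- shrink_boundary_scores(scores$score[match(unit, scores$unit)])
  }
  data <- betareg_data(unit, y, design)

  draws <- run_beta_mcmc(data, config$betareg_priors, config$stage2,
                         verbose = config$verbose)
  summary <- summarize_betareg_draws(draws)
  related <- summary$node[which(summary$related)]
  related <- setdiff(related, "(Intercept)")
  utils::write.csv(
    data.frame(draws$beta_draws, phi = draws$phi_draws, check.names = FALSE),
    file.path(out, "stage2_draws.csv"), row.names = FALSE)
  write_summary_csv(summary, file.path(out, "stage2_summary.csv"), "betareg")
  conv_rows <- summary[summary$node != "phi", ]
  converged <- check_convergence_or_fail(conv_rows, "stage 2", config$strict_convergence)
  list(draws = draws, summary = summary, related = related,
       converged = converged, data = data)
}

#' Run the full two-stage analysis
#'
#' [run_stage1()] followed by [run_stage2()] on the stage-1 scores, plus a
#' `manifest.json` recording the configuration, seeds and package version so
#' a run can be replayed exactly.
#'
#' @param config a [pipeline_config()].
#' @return list with `stage1`, `stage2`, `manifest` (path), `status` (0 on
#'   success).
#' @export
run_two_stage <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- ensure_out_dir(config)
  s1 <- run_stage1(config)
  s2 <- run_stage2(config, scores = s1$efficiency)
  manifest <- list(
    package = "bsfareg",
    version = as.character(utils::packageVersion("bsfareg")),
    r_version = R.version.string,
    synthetic = config$synthetic,
    n_units = config$n_units, n_periods = config$n_periods,
    frontier_truth = if (config$synthetic) unclass(config$frontier_truth),
    betareg_truth = if (config$synthetic) unclass(config$betareg_truth),
    frontier_priors = unclass(config$frontier_priors),
    betareg_priors = unclass(config$betareg_priors),
    stage1 = unclass(config$stage1), stage2 = unclass(config$stage2),
    strict_convergence = config$strict_convergence,
    related_factors = s2$related
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  list(stage1 = s1, stage2 = s2, manifest = manifest_path, status = 0L)
}
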