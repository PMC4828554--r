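# Published posterior-summary and ranking tables from the motivating OECD
# health-system efficiency analysis (29 countries, panel 1997-2009; 20
# policy indicators). Bundled verbatim, including their misprints, as
# worked-example inputs for the ranking, convergence-rule, and related-
# factor routines. The underlying micro data are proprietary and are NOT
# part of this package.

reference_path <- function(file) {
  p <- system.file("extdata", file, package = "bsfareg")
  if (!nzchar(p)) stop_invalid(sprintf("bundled reference file '%s' not found", file))
  p
}

#' Bundled OECD worked-example tables
#'
#' `reference_efficiency_scores()` returns the published per-country
#' technical-efficiency scores and ranks (columns `country`, `score`,
#' `rank`); `reference_stage1_summary()` the frontier-stage posterior
#' summaries (`node`, `mean`, `sd`, `mc_error`, `q2.5`, `median`, `q97.5`,
#' `start`, `sample`); `reference_stage2_summary()` the beta-regression
#' summaries for the intercept and the 20 policy indicators (`variable`,
#' `mean`, `sd`, `mc_error`, `q2.5`, `q97.5`).
#'
#' @return a data.frame (see above for columns).
#' @export
reference_efficiency_scores <- function() {
  utils::read.csv(reference_path("oecd_efficiency_scores.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_efficiency_scores
#' @export
reference_stage1_summary <- function() {
  utils::read.csv(reference_path("oecd_stage1_summary.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reference_efficiency_scores
#' @export
reference_stage2_summary <- function() {
  utils::read.csv(reference_path("oecd_stage2_summary.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
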