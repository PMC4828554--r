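#' Balanced panel dataset for frontier estimation
#'
#' Container for a balanced unit-by-period panel with one outcome (typically
#' log life expectancy) and a covariate matrix with a leading intercept
#' column. Every unit must be observed in exactly the same set of periods and
#' all values must be finite.
#'
#' @param unit character vector of unit (country) labels, one per observation.
#' @param period integer vector of period indices (the time trend), one per
#'   observation.
#' @param y numeric outcome vector.
#' @param X numeric covariate matrix, one row per observation. If the first
#'   column is not constant equal to 1, an intercept column is prepended.
#' @return an object of class `panel_dataset`: a list with elements `unit`,
#'   `period`, `y`, `X` (including the intercept column).
#' @export
panel_dataset <- function(unit, period, y, X) {
  unit <- as.character(unit)
  n <- length(unit)
  if (length(period) != n || length(y) != n) {
    stop_invalid("'unit', 'period' and 'y' must have equal length")
  }
  X <- as.matrix(X)
  if (nrow(X) != n) stop_invalid("nrow(X) must match the number of observations")
  check_finite_vector(y, "y")
  if (any(!is.finite(X))) stop_invalid("covariate matrix contains non-finite values")
  period <- as.integer(period)
  if (anyNA(period)) stop_invalid("'period' must be integer-valued")
  if (!all(X[, 1L] == 1)) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1L) paste0("x", seq_len(ncol(X) - 1L)))
  }
  periods <- sort(unique(period))
  tab <- table(unit, period)
  if (any(tab != 1L)) {
    stop_invalid("panel is not balanced: every unit must appear exactly once per period")
  }
  structure(
    list(unit = unit, period = period, y = as.numeric(y), X = X),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "panel_dataset: %d units x %d periods (%d observations), %d covariate columns (incl. intercept)\n",
    length(unique(x$unit)), length(unique(x$period)), length(x$y), ncol(x$X)
  ))
  invisible(x)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) {
  covs <- x$X[, -1L, drop = FALSE]
  colnames(covs) <- paste0("x", seq_len(ncol(covs)))
  data.frame(unit = x$unit, period = x$period, y = x$y, covs,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a panel dataset as CSV
#'
#' The CSV schema is `unit,period,y,x1..xK` where `x1..xK` are the
#' non-intercept covariate columns (the time trend, when present, is stored
#' like any other covariate). [read_panel_csv()] reconstructs the
#' `panel_dataset` including its intercept column, so write/read round-trips
#' exactly.
#'
#' @param panel a [panel_dataset()].
#' @param path CSV file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a [panel_dataset()].
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_dataset"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("panel CSV '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("unit", "period", "y")
  if (!all(need %in% names(df))) {
    stop_invalid("panel CSV must have columns unit,period,y,x1..xK")
  }
  xcols <- setdiff(names(df), need)
  panel_dataset(df$unit, df$period, df$y, as.matrix(df[, xcols, drop = FALSE]))
}

#' Cross-sectional dataset for beta regression
#'
#' Holds one response per unit, strictly inside (0,1) (an efficiency score),
#' and a design matrix with a leading intercept column plus `p >= 1`
#' indicator columns (policy indicators scored 0-6 in the motivating
#' application, though any finite values are accepted).
#'
#' @param unit character vector of unit labels (must be unique).
#' @param y numeric response vector, every value strictly in (0,1).
#' @param X numeric design matrix; an intercept column is prepended when the
#'   first column is not constant 1.
#' @return an object of class `betareg_data` with elements `unit`, `y`, `X`.
#' @export
betareg_data <- function(unit, y, X) {
  unit <- as.character(unit)
  n <- length(unit)
  if (anyDuplicated(unit)) stop_invalid("duplicate unit labels in beta-regression data")
  if (length(y) != n) stop_invalid("'unit' and 'y' must have equal length")
  check_finite_vector(y, "y")
  if (any(y <= 0 | y >= 1)) {
    bad <- unit[y <= 0 | y >= 1]
    stop_invalid(sprintf(
      "responses must lie strictly in (0,1); boundary/outside values for: %s",
      paste(bad, collapse = ", ")
    ))
  }
  X <- as.matrix(X)
  if (nrow(X) != n) stop_invalid("nrow(X) must match the number of units")
  if (any(!is.finite(X))) stop_invalid("design matrix contains non-finite values")
  if (!all(X[, 1L] == 1)) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(colnames(X)) || any(!nzchar(colnames(X)))) {
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1L) paste0("X", seq_len(ncol(X) - 1L)))
  }
  # intercept-only designs are allowed (used by degenerate-case oracles)
  structure(list(unit = unit, y = as.numeric(y), X = X), class = "betareg_data")
}

#' @export
print.betareg_data <- function(x, ...) {
  cat(sprintf("betareg_data: %d units, %d indicator columns\n",
              length(x$unit), ncol(x$X) - 1L))
  invisible(x)
}

#' Write / read beta-regression data as CSV
#'
#' Schema: `unit,score,X1..Xp` (indicator columns, intercept implicit).
#'
#' @param data a [betareg_data()].
#' @param path CSV file path.
#' @return `write_betareg_csv` returns `path` invisibly; `read_betareg_csv`
#'   returns a [betareg_data()].
#' @export
write_betareg_csv <- function(data, path) {
  stopifnot(inherits(data, "betareg_data"))
  ind <- data$X[, -1L, drop = FALSE]
  colnames(ind) <- paste0("X", seq_len(ncol(ind)))
  df <- data.frame(unit = data$unit, score = data$y, ind,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_betareg_csv
#' @export
read_betareg_csv <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("indicator CSV '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("unit", "score") %in% names(df))) {
    stop_invalid("indicator CSV must have columns unit,score,X1..Xp")
  }
  xcols <- setdiff(names(df), c("unit", "score"))
  betareg_data(df$unit, df$score, as.matrix(df[, xcols, drop = FALSE]))
}
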