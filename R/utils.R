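# Internal helpers: classed errors, argument checks, flat-key config parsing.

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("invalid_argument", "bsfareg_error")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("numerical_failure", "bsfareg_error")))
}

check_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (allow_zero) {
    if (x < 0) stop_invalid(sprintf("'%s' must be >= 0, got %g", name, x))
  } else if (x <= 0) {
    stop_invalid(sprintf("'%s' must be > 0, got %g", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stop_invalid(sprintf("'%s' must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_finite_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop_invalid(sprintf("'%s' must be a finite numeric vector", name))
  }
  invisible(x)
}

#' Read a flat-key configuration file
#'
#' Parses a plain-text configuration file with one `key = value` pair per
#' line. Blank lines and lines starting with `#` are ignored. Values holding
#' commas are split into vectors; numeric-looking values are converted to
#' numeric, `true`/`false` to logical, everything else kept as character.
#'
#' @param path path to the configuration file.
#' @return named list of parsed values.
#' @export
read_flat_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("config file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop_invalid(sprintf("config line is not 'key = value': '%s'", ln))
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      out[[key]] <- num
    } else if (length(parts) == 1L && tolower(parts) %in% c("true", "false")) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- parts
    }
  }
  out
}

# C-locale (radix) ordering so that ranking ties break identically on any
# platform regardless of collation settings.
order_c_locale <- function(...) order(..., method = "radix")
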