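`%||%` <- function(x, y) if (is.null(x)) y else x

as_date_scalar <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    abort(sprintf("`%s` must be a single valid date (got %s).", what,
                  paste(format(x), collapse = ", ")))
  }
  d
}

check_positive_scalar <- function(x, what, integer = FALSE, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0) &&
    (!integer || x == as.integer(x))
  if (!ok) {
    abort(sprintf("configuration error: `%s` must be a %s%s number.",
                  what,
                  if (allow_zero) "non-negative " else "positive ",
                  if (integer) "whole " else ""))
  }
  invisible(x)
}

check_probability <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("configuration error: `%s` must be a probability in [0, 1].", what))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# cumulative sum restarted at each new group; `g` must be sorted runs
cumsum_by <- function(x, g) {
  cs <- cumsum(x)
  first <- !duplicated(g)
  base <- cs[first] - x[first]
  cs - base[cumsum(first)]
}
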