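# internal helpers

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  assert_that(ok, sprintf(
    "`%s` must be a single finite number in %s%s, %s%s.",
    name, if (strict) "(" else "[", format(lower), format(upper),
    if (strict) ")" else "]"
  ))
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  assert_that(ok, sprintf("`%s` must be a single integer >= %d.", name, min))
}

# values of a uniform series out of a vector or data frame column
series_values <- function(x, column = "value") {
  if (is.data.frame(x)) {
    assert_that(column %in% names(x),
                sprintf("column `%s` not found in data frame.", column))
    x <- x[[column]]
  }
  assert_that(is.numeric(x), "series values must be numeric.")
  assert_that(all(is.finite(x)), "series values must all be finite.")
  as.double(x)
}

# sampling period of a data frame series, from a `t` column when present
series_dt <- function(x, dt = NULL) {
  if (!is.null(dt)) return(dt)
  if (is.data.frame(x) && "t" %in% names(x) && nrow(x) >= 2L) {
    return(diff(x$t[1:2]))
  }
  1
}

# trapezoid integral of y over an ordered grid x
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# cumulative trapezoid integral, same length as x, starting at 0
cum_trapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# derive a per-component seed from a root seed; stays below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + i * 104729) %% 2147483629)
}
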