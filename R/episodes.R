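#' Construct a density model on the Hurst range
#'
#' A `density_model` holds a probability density for the Hurst exponent on an
#' ordered grid inside \[0, 1\], normalized so its trapezoid integral is 1.
#' Use [estimate_density()] to build one from a sample; this constructor is
#' for analytic densities (e.g. a Gaussian evaluated on a grid).
#'
#' @param grid Ordered numeric grid in \[0, 1\].
#' @param pdf Nonnegative density values on the grid (renormalized on
#'   construction).
#' @param bandwidth Bandwidth used, if any (`NA` for analytic densities).
#' @param sample The underlying sample, if any.
#' @return An object of class `density_model`.
#' @examples
#' g <- seq(0, 1, length.out = 512)
#' dm <- density_model(g, dnorm(g, 0.5, 0.1))
#' @export
density_model <- function(grid, pdf, bandwidth = NA_real_, sample = NULL) {
  assert_that(is.numeric(grid) && is.numeric(pdf) &&
                length(grid) == length(pdf) && length(grid) >= 8L,
              "`grid` and `pdf` must be numeric of equal length >= 8.")
  assert_that(!is.unsorted(grid, strictly = TRUE),
              "`grid` must be strictly increasing.")
  assert_that(min(grid) >= 0 && max(grid) <= 1,
              "`grid` must lie inside [0, 1].")
  assert_that(all(is.finite(pdf)) && all(pdf >= 0),
              "`pdf` must be finite and nonnegative.")
  total <- trapz(grid, pdf)
  assert_that(total > 0, "`pdf` integrates to zero.")
  structure(
    list(grid = as.double(grid), pdf = as.double(pdf) / total,
         bandwidth = bandwidth, sample = sample),
    class = "density_model"
  )
}

#' Kernel density of a Hurst-exponent sample
#'
#' Gaussian-kernel density of the mesoscale Hurst sample on an equidistant
#' grid over \[0, 1\], renormalized to integrate to exactly 1 on the grid.
#' The default bandwidth is the Sheather-Jones plug-in (`stats::bw.SJ`),
#' which preserves the multimodal structure these samples exhibit;
#' Silverman's rule-of-thumb is available as `bandwidth = "nrd0"` or any
#' numeric bandwidth can be given.
#'
#' @param sample Numeric vector of Hurst exponents, length >= 8, all strictly
#'   in (0, 1). A data frame is accepted via `column`.
#' @param bandwidth `"SJ"` (default), `"nrd0"`, or a positive number.
#' @param n_grid Grid resolution (default 512).
#' @param column Column to use when `sample` is a data frame (default
#'   `h_mean`, the profile column).
#' @return A [density_model()].
#' @examples
#' h <- pmin(pmax(rnorm(100, 0.5, 0.05), 0.01), 0.99)
#' dm <- estimate_density(h)
#' @export
estimate_density <- function(sample, bandwidth = "SJ", n_grid = 512,
                             column = "h_mean") {
  v <- series_values(sample, column)
  v <- v[!is.na(v)]
  assert_that(length(v) >= 8L, "need at least 8 Hurst values.")
  assert_that(all(v > 0 & v < 1), "Hurst values must lie strictly in (0, 1).")
  assert_count(n_grid, "n_grid", min = 32L)
  bw <- if (is.numeric(bandwidth)) {
    assert_scalar_number(bandwidth, "bandwidth", 0, Inf, strict = TRUE)
    bandwidth
  } else if (identical(bandwidth, "SJ")) {
    tryCatch(stats::bw.SJ(v), error = function(e) stats::bw.nrd0(v))
  } else if (identical(bandwidth, "nrd0")) {
    stats::bw.nrd0(v)
  } else {
    abort("`bandwidth` must be \"SJ\", \"nrd0\" or a positive number.")
  }
  d <- density(v, bw = bw, kernel = "gaussian", from = 0, to = 1, n = n_grid)
  density_model(d$x, d$y, bandwidth = bw, sample = v)
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "<density_model> %d-point grid on [%.2f, %.2f]%s%s\n",
    length(x$grid), min(x$grid), max(x$grid),
    if (is.na(x$bandwidth)) "" else sprintf(", bandwidth %.4f", x$bandwidth),
    if (is.null(x$sample)) "" else sprintf(", n = %d", length(x$sample))
  ))
  invisible(x)
}

#' @method tidy density_model
#' @export
tidy.density_model <- function(x, ...) {
  tibble::tibble(h = x$grid, density = x$pdf)
}

# smoothed second derivative of the density on its grid
# (local quadratic Savitzky-Golay over 7 points)
density_second_derivative <- function(d) {
  dx <- d$grid[2] - d$grid[1]
  signal::sgolayfilt(d$pdf, p = 2, n = 7, m = 2) / dx^2
}

#' Locate inflection points of a density
#'
#' Zero crossings of the (lightly smoothed) second derivative of the density,
#' located by linear interpolation between grid points and returned sorted
#' ascending. The second derivative is computed by a 7-point local-quadratic
#' Savitzky-Golay filter; crossing pairs closer than `min_separation` grid
#' cells are numerical ripple and are discarded, as are crossings in the
#' filter's 3-point edge zones. A monotone or uniform density yields an empty
#' result.
#'
#' @param d A [density_model()].
#' @param min_separation Minimum spacing between consecutive crossings, in
#'   grid cells (default 2).
#' @return Sorted numeric vector of inflection locations (possibly empty).
#' @examples
#' g <- seq(0, 1, length.out = 512)
#' find_inflections(density_model(g, dnorm(g, 0.5, 0.1))) # ~ 0.4, 0.6
#' @export
find_inflections <- function(d, min_separation = 2L) {
  assert_that(inherits(d, "density_model"), "`d` must be a density_model.")
  n <- length(d$grid)
  dx <- d$grid[2] - d$grid[1]
  d2 <- density_second_derivative(d)
  # ignore the filter's edge zones
  usable <- 4:(n - 4)
  s <- d2[usable]
  g <- d$grid[usable]
  cross <- which(s[-length(s)] * s[-1] < 0)
  if (length(cross) == 0L) return(numeric(0))
  xi <- g[cross] + dx * s[cross] / (s[cross] - s[cross + 1])
  # drop ripple: pairs of crossings closer than min_separation cells
  if (length(xi) >= 2L) {
    repeat {
      gaps <- diff(xi)
      j <- which(gaps < min_separation * dx)
      if (length(j) == 0L) break
      xi <- xi[-c(j[1], j[1] + 1)]
      if (length(xi) < 2L) break
    }
  }
  sort(xi)
}

#' Mood-state probabilities between density inflection points
#'
#' Implements the operational mood-state decomposition: consecutive
#' inflection points \eqn{x_i < x_{i+1}} of the Hurst density delimit state
#' `i`, whose probability is the integral of the density over
#' \eqn{[x_i, x_{i+1}]}. The most probable ("likely observable") state is the
#' argmax (ties to the lowest index). Mass outside the outermost inflection
#' points is reported as `tail_mass`, never silently dropped — the state
#' probabilities sum to `1 - tail_mass`. Each state is labelled by
#' [classify_episode()] applied to its interval midpoint (mild mania
#' collapsing to mania), and tagged by the type of density extremum it
#' contains: a local maximum marks a meta-stable episode, a local minimum the
#' Wiener-like stable region.
#'
#' @param d A [density_model()].
#' @param inflections Optional sorted vector of inflection points; defaults
#'   to [find_inflections()]`(d)`. At least 2 are required.
#' @param min_separation Passed to [find_inflections()].
#' @return A `mood_states` tibble with columns `state`, `lower`, `upper`,
#'   `midpoint`, `probability`, `label`, `extremum`, and attributes
#'   `observable_state`, `tail_mass`, `inflection_points`. `glance()` gives a
#'   one-row summary.
#' @examples
#' g <- seq(0, 1, length.out = 512)
#' dm <- density_model(g, dnorm(g, 0.5, 0.1))
#' mood_state_probabilities(dm, inflections = c(0.4, 0.6))
#' @export
mood_state_probabilities <- function(d, inflections = NULL,
                                     min_separation = 2L) {
  assert_that(inherits(d, "density_model"), "`d` must be a density_model.")
  if (is.null(inflections)) {
    inflections <- find_inflections(d, min_separation = min_separation)
  }
  if (length(inflections) < 2L) {
    abort("no states identifiable: fewer than 2 inflection points.")
  }
  xi <- sort(inflections)
  cdf <- cum_trapz(d$grid, d$pdf)
  cdf_at <- function(x) approx(d$grid, cdf, xout = x, rule = 2)$y
  n_states <- length(xi) - 1L
  lower <- xi[-length(xi)]
  upper <- xi[-1]
  probability <- cdf_at(upper) - cdf_at(lower)
  midpoint <- (lower + upper) / 2

  # extremum type: does the interval contain a local max / min of the pdf?
  extremum <- vapply(seq_len(n_states), function(i) {
    inside <- d$grid > lower[i] & d$grid < upper[i]
    if (!any(inside)) return("transition")
    # < 0 / > 0 (rather than == -2 / == 2) so that two-point plateaus at an
    # extremum, e.g. a symmetric mode straddling two grid cells, still count
    y <- d$pdf
    locmax <- which(diff(sign(diff(y))) < 0) + 1L
    locmin <- which(diff(sign(diff(y))) > 0) + 1L
    has_max <- any(d$grid[locmax] > lower[i] & d$grid[locmax] < upper[i])
    has_min <- any(d$grid[locmin] > lower[i] & d$grid[locmin] < upper[i])
    if (has_max) "meta_stable" else if (has_min) "stable" else "transition"
  }, character(1))

  mid_clamped <- pmin(pmax(midpoint, 1e-9), 1 - 1e-9)
  label <- collapse_episode(classify_episode(mid_clamped))

  states <- tibble::tibble(
    state = seq_len(n_states),
    lower = lower, upper = upper, midpoint = midpoint,
    probability = probability, label = label, extremum = extremum
  )
  attr(states, "observable_state") <- which.max(probability)
  attr(states, "tail_mass") <- 1 - (cdf_at(max(xi)) - cdf_at(min(xi)))
  attr(states, "inflection_points") <- xi
  class(states) <- c("mood_states", class(states))
  states
}

#' @method glance mood_states
#' @export
glance.mood_states <- function(x, ...) {
  i <- attr(x, "observable_state")
  tibble::tibble(
    n_states = nrow(x),
    observable_state = i,
    observable_label = x$label[i],
    observable_probability = x$probability[i],
    tail_mass = attr(x, "tail_mass")
  )
}

#' @export
print.mood_states <- function(x, ...) {
  cat(sprintf("<mood_states> %d states, tail mass %.3f\n",
              nrow(x), attr(x, "tail_mass")))
  print(tibble::as_tibble(x))
  i <- attr(x, "observable_state")
  cat(sprintf("likely observable: state %d (%s), probability %.3f\n",
              i, x$label[i], x$probability[i]))
  invisible(x)
}

#' Plot a Hurst density with its mood states
#'
#' @param object A [density_model()].
#' @param states Optional `mood_states` to shade; computed when `NULL` and
#'   possible.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_model
#' @export
autoplot.density_model <- function(object, states = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Hurst exponent", y = "density",
                  title = "Mesoscale complexity density") +
    ggplot2::theme_minimal()
  if (is.null(states)) {
    states <- tryCatch(mood_state_probabilities(object),
                       error = function(e) NULL)
  }
  if (!is.null(states)) {
    shade <- tibble::as_tibble(states)
    p <- p +
      ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                     ymin = 0, ymax = Inf, fill = .data$label),
        alpha = 0.2
      ) +
      ggplot2::geom_vline(xintercept = attr(states, "inflection_points"),
                          linetype = "dotted")
  }
  p
}
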