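#' Build a fractional-Gaussian-noise scenario library
#'
#' The extrapolation engine's reference set: for each Hurst parameter on
#' `h_grid`, one fGn realization of `length` samples is simulated at the
#' calibrated variance, segmented into `window_len`-sample windows, projected
#' to its windowed-Hurst trajectory (same estimator configuration as the
#' profile stage), and summarized by a [density_model()] of that trajectory.
#' Scenario seeds are derived from the root `seed` per scenario id, so two
#' scenarios with the same Hurst parameter still get distinct realizations.
#'
#' @param n_scenarios Number of scenarios (>= 2); ignored when `h_grid` is
#'   given.
#' @param h_grid Hurst parameters of the scenarios; default `n_scenarios`
#'   equidistant values spanning (0.01, 0.99).
#' @param length Samples per scenario; default `40 * window_len`. Must allow
#'   at least 8 windows (and at least `4 * window_len` samples).
#' @param variance Per-sample variance of the scenario fGn, calibrated from
#'   the observed data (default 1; the windowed-Hurst densities are invariant
#'   to it because the estimator is scale-invariant).
#' @param window_len Samples per window (default 120).
#' @param seed Integer root seed.
#' @param k_min,bandwidth Estimator / density configuration (defaults match
#'   [profile_actigraphy()] and [estimate_density()]).
#'
#' @return An object of class `scenario_library`: a list with a `scenarios`
#'   tibble (`id`, `h`, `seed`, `n_windows`), parallel lists `hurst`
#'   (windowed-Hurst trajectories) and `densities` ([density_model()]s), and
#'   the generating parameters.
#' @examples
#' lib <- build_library(n_scenarios = 5, length = 8 * 120, seed = 1)
#' @export
build_library <- function(n_scenarios = 150, h_grid = NULL, length = NULL,
                          variance = 1, window_len = 120, seed = 1,
                          k_min = 3, bandwidth = "SJ") {
  if (is.null(h_grid)) {
    assert_count(n_scenarios, "n_scenarios", min = 2L)
    step <- 0.98 / (n_scenarios + 1)
    h_grid <- seq(0.01 + step, 0.99 - step, length.out = n_scenarios)
  }
  assert_that(is.numeric(h_grid) && length(h_grid) >= 2L &&
                all(h_grid > 0 & h_grid < 1),
              "`h_grid` values must lie strictly in (0, 1).")
  n_scenarios <- base::length(h_grid)
  assert_count(window_len, "window_len", min = 17L)
  if (is.null(length)) length <- 40L * window_len
  assert_count(length, "length", min = 4L * window_len)
  n_windows <- length %/% window_len
  assert_that(n_windows >= 8L,
              "`length` must allow at least 8 windows per scenario.")
  assert_scalar_number(variance, "variance", 0, Inf, strict = TRUE)

  k_max <- floor(log2(window_len - 1))
  scen_seed <- vapply(seq_len(n_scenarios), function(i) derive_seed(seed, i),
                      integer(1))
  hurst <- vector("list", n_scenarios)
  densities <- vector("list", n_scenarios)
  for (i in seq_len(n_scenarios)) {
    x <- simulate_fgn(length, h_grid[i], seed = scen_seed[i],
                      sigma = sqrt(variance))$value
    start <- (seq_len(n_windows) - 1L) * window_len + 1L
    traj <- vapply(start, function(s0) {
      window_hurst(x[s0:(s0 + window_len - 1L)], dt = 1,
                   k_min = k_min, k_max = k_max,
                   subsample = "exact", integrate = TRUE)
    }, numeric(1))
    hurst[[i]] <- traj
    densities[[i]] <- estimate_density(traj[!is.na(traj)],
                                       bandwidth = bandwidth)
  }

  structure(
    list(
      scenarios = tibble::tibble(id = seq_len(n_scenarios), h = h_grid,
                                 seed = scen_seed, n_windows = n_windows),
      hurst = hurst,
      densities = densities,
      window_len = as.integer(window_len),
      length = as.integer(length),
      variance = variance,
      k_min = k_min,
      bandwidth = bandwidth
    ),
    class = "scenario_library"
  )
}

#' @export
print.scenario_library <- function(x, ...) {
  cat(sprintf(
    "<scenario_library> %d fGn scenarios, h in [%.3f, %.3f]\n  %d samples each (%d windows of %d), variance %.3g\n",
    nrow(x$scenarios), min(x$scenarios$h), max(x$scenarios$h),
    x$length, x$scenarios$n_windows[1], x$window_len, x$variance
  ))
  invisible(x)
}

#' L^p distance between two densities
#'
#' \eqn{\left(\int_0^1 |P - Q|^p\, dx\right)^{1/p}} by the trapezoid rule on
#' the first density's grid (the second is linearly interpolated onto it).
#' For `p >= 1` this is a metric on gridded densities.
#'
#' @param p_density,q_density [density_model()] objects.
#' @param p Norm order, >= 1 (default 2).
#' @return Nonnegative distance.
#' @examples
#' g <- seq(0, 1, length.out = 256)
#' a <- density_model(g, dnorm(g, 0.3, 0.05))
#' b <- density_model(g, dnorm(g, 0.7, 0.05))
#' pdf_distance(a, b)
#' @export
pdf_distance <- function(p_density, q_density, p = 2) {
  assert_that(inherits(p_density, "density_model") &&
                inherits(q_density, "density_model"),
              "both arguments must be density_model objects.")
  assert_scalar_number(p, "p", 1, Inf)
  grid <- p_density$grid
  q <- approx(q_density$grid, q_density$pdf, xout = grid, rule = 2)$y
  trapz(grid, abs(p_density$pdf - q)^p)^(1 / p)
}

#' Extrapolate a partial Hurst trajectory via the scenario library
#'
#' Density matching: the observed mesoscale trajectory (length `k`) is
#' summarized by its Hurst density, the scenario whose windowed-Hurst density
#' is closest in L^p distance is selected (ties to the lowest scenario id),
#' and the trajectory is extended with that scenario's windowed-Hurst values
#' at indices `k+1, ..., k+horizon`. The observed prefix is preserved
#' exactly.
#'
#' @param y_observed Observed windowed Hurst values: a numeric vector
#'   (length >= 8, values in (0, 1)) or a data frame with an `h_mean` column
#'   (e.g. a [profile_actigraphy()] result).
#' @param library A [build_library()] result; its scenarios must have at
#'   least `k + horizon` windows.
#' @param horizon Number of windows to extrapolate (>= 1).
#' @param p Norm order of the density distance (default 2).
#' @param bandwidth Bandwidth rule for the observed density (default the
#'   library's).
#' @param column Column to use when `y_observed` is a data frame.
#'
#' @return An object of class `hurst_forecast`: a list with `extended` (the
#'   union trajectory, length `k + horizon`), `observed`, `selected_id`,
#'   `selected_h`, `distance`, `p`, `k`, `horizon`, and a `distances` tibble
#'   over all scenarios. `tidy()` returns the trajectory with a `source`
#'   column.
#' @examples
#' lib <- build_library(n_scenarios = 5, length = 20 * 120, seed = 1)
#' y <- lib$hurst[[3]][1:8]
#' fc <- extrapolate(y, lib, horizon = 4)
#' @export
extrapolate <- function(y_observed, library, horizon, p = 2,
                        bandwidth = NULL, column = "h_mean") {
  assert_that(inherits(library, "scenario_library"),
              "`library` must be a scenario_library.")
  assert_that(nrow(library$scenarios) >= 1L, "empty scenario library.")
  y <- series_values(y_observed, column)
  y <- y[!is.na(y)]
  k <- length(y)
  assert_that(k >= 8L, "need at least 8 observed Hurst values.")
  assert_that(all(y > 0 & y < 1),
              "observed Hurst values must lie strictly in (0, 1).")
  assert_count(horizon, "horizon", min = 1L)
  assert_scalar_number(p, "p", 1, Inf)
  n_windows <- library$scenarios$n_windows[1]
  assert_that(k + horizon <= n_windows,
              sprintf("library scenarios have %d windows; need k + horizon = %d.",
                      n_windows, k + horizon))

  obs_density <- estimate_density(y, bandwidth = bandwidth %||%
                                    library$bandwidth)
  dist <- vapply(library$densities, pdf_distance, numeric(1),
                 p_density = obs_density, p = p)
  i0 <- which.min(dist) # ties: lowest scenario id
  tail_values <- library$hurst[[i0]][(k + 1):(k + horizon)]

  structure(
    list(
      extended = c(y, tail_values),
      observed = y,
      selected_id = library$scenarios$id[i0],
      selected_h = library$scenarios$h[i0],
      distance = dist[i0],
      p = p,
      k = k,
      horizon = as.integer(horizon),
      distances = tibble::tibble(id = library$scenarios$id,
                                 h = library$scenarios$h,
                                 distance = dist)
    ),
    class = "hurst_forecast"
  )
}

#' @export
print.hurst_forecast <- function(x, ...) {
  cat(sprintf(
    "<hurst_forecast> %d observed + %d extrapolated windows\n  selected scenario %d (h = %.3f), L^%g distance %.4f\n",
    x$k, x$horizon, x$selected_id, x$selected_h, x$p, x$distance
  ))
  invisible(x)
}

#' @method tidy hurst_forecast
#' @export
tidy.hurst_forecast <- function(x, ...) {
  tibble::tibble(
    window_index = seq_along(x$extended),
    H = x$extended,
    source = rep(c("observed", "extrapolated"), c(x$k, x$horizon))
  )
}

#' @method autoplot hurst_forecast
#' @export
autoplot.hurst_forecast <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_index, y = .data$H,
                                   colour = .data$source)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window", y = "Hurst exponent",
                  title = sprintf("Trajectory extrapolation (scenario h = %.2f)",
                                  object$selected_h)) +
    ggplot2::theme_minimal()
}

#' Per-window extrapolation errors against a known continuation
#'
#' Absolute error of each extrapolated window in percent of the true value.
#'
#' @param forecast A [extrapolate()] result.
#' @param truth Numeric vector of true Hurst values for the extrapolated
#'   windows (length >= horizon; extra values are ignored).
#' @return A tibble with `window_index`, `predicted`, `actual`, `error_pct`.
#' @export
extrapolation_errors <- function(forecast, truth) {
  assert_that(inherits(forecast, "hurst_forecast"),
              "`forecast` must be a hurst_forecast.")
  truth <- series_values(truth)
  assert_that(length(truth) >= forecast$horizon,
              "`truth` shorter than the forecast horizon.")
  predicted <- forecast$extended[(forecast$k + 1):(forecast$k +
                                                     forecast$horizon)]
  actual <- truth[seq_len(forecast$horizon)]
  tibble::tibble(
    window_index = forecast$k + seq_len(forecast$horizon),
    predicted = predicted,
    actual = actual,
    error_pct = 100 * abs(predicted - actual) / abs(actual)
  )
}

#' Mood trend from the derivative of an interpolated Hurst trajectory
#'
#' Interpolates the mesoscale Hurst trajectory with a monotonicity-preserving
#' piecewise-cubic Hermite spline and evaluates its derivative on the segment
#' grid. A falling Hurst exponent (memory-pattern decay) signals expected
#' manic states, a rising one (memory elongation) expected depressive states,
#' and a flat one (|derivative| < `tol`) no mood change.
#'
#' @param trajectory Numeric vector of Hurst values (length >= 3), or a data
#'   frame with an `h_mean` column.
#' @param tol Zero-derivative tolerance per segment (default 0.01, in Hurst
#'   units per window).
#' @param column Column to use when `trajectory` is a data frame.
#' @return A `mood_trend` tibble: `segment`, `H`, `derivative`,
#'   `interpretation` (one of `manic_expected`, `no_change`,
#'   `depressive_expected`).
#' @examples
#' mood_trend(c(0.8, 0.7, 0.55, 0.4, 0.3))
#' @export
mood_trend <- function(trajectory, tol = 0.01, column = "h_mean") {
  y <- series_values(trajectory, column)
  y <- y[!is.na(y)]
  assert_that(length(y) >= 3L, "need at least 3 trajectory points.")
  assert_scalar_number(tol, "tol", 0, Inf)
  t <- seq_along(y)
  f <- splinefun(t, y, method = "monoH.FC")
  deriv <- f(t, deriv = 1)
  interpretation <- dplyr::case_when(
    abs(deriv) < tol ~ "no_change",
    deriv < 0 ~ "manic_expected",
    TRUE ~ "depressive_expected"
  )
  out <- tibble::tibble(segment = t, H = y, derivative = deriv,
                        interpretation = interpretation)
  class(out) <- c("mood_trend", class(out))
  out
}

#' @method autoplot mood_trend
#' @export
autoplot.mood_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$segment, y = .data$H)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$interpretation)) +
    ggplot2::labs(x = "segment", y = "Hurst exponent",
                  title = "Mood trend from trajectory derivative") +
    ggplot2::theme_minimal()
}
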