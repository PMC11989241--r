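#' Evaluate a truncated Weierstrass cosine series
#'
#' Generates the classical almost-nowhere-differentiable cosine ladder
#' \deqn{f(t) = \sum_{n=0}^{N-1} 2^{-n h} \cos(2^n t)}
#' on an equidistant grid. Its graph is self-affine with Hurst exponent
#' `h` (fractal dimension `2 - h`), which makes it a standard deterministic
#' benchmark for Hurst estimators.
#'
#' @param h Roughness exponent, strictly between 0 and 1. Smaller values give
#'   rougher graphs.
#' @param n_points Number of equidistant sample points (at least 3).
#' @param n_terms Number of cosine terms (default 31, i.e. frequencies
#'   \eqn{2^0 \dots 2^{30}}).
#' @param domain Length-2 numeric, the closed sampling interval. The default
#'   `c(0, 2*pi)` sweeps every frequency through full periods.
#'
#' @return A tibble with columns `t` (sample times) and `value`. Deterministic:
#'   identical arguments give bit-identical output.
#' @examples
#' w <- weierstrass(0.5, n_points = 1024)
#' head(w)
#' @export
weierstrass <- function(h, n_points, n_terms = 31, domain = c(0, 2 * pi)) {
  assert_scalar_number(h, "h", 0, 1, strict = TRUE)
  assert_count(n_points, "n_points", min = 3L)
  assert_count(n_terms, "n_terms", min = 1L)
  assert_that(is.numeric(domain) && length(domain) == 2L &&
                all(is.finite(domain)) && domain[1] < domain[2],
              "`domain` must be c(t_min, t_max) with t_min < t_max.")
  t <- seq(domain[1], domain[2], length.out = n_points)
  value <- numeric(n_points)
  for (n in seq_len(n_terms) - 1L) {
    value <- value + 2^(-n * h) * cos(2^n * t)
  }
  tibble::tibble(t = t, value = value)
}

# Unit-variance fractional Gaussian noise by circulant embedding
# (Davies-Harte). Exact covariance; falls back to a dense Cholesky
# factorization of the Toeplitz covariance if the embedding is not
# nonnegative-definite (does not occur for fGn with 0 < h < 1, but the
# guard is kept for robustness at extreme arguments).
fgn_unit <- function(n, h) {
  if (n == 1L) return(rnorm(1))
  gam <- fgn_autocovariance(n, h)
  first_row <- c(gam[1:(n + 1)], rev(gam[2:n]))
  m <- 2 * n
  ev <- Re(fft(first_row))
  if (min(ev) < -1e-6 * max(ev)) {
    return(fgn_dense(n, h, gam))
  }
  ev[ev < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  # Re and Im of fft(sqrt(ev / m) z) are independent draws with the
  # circulant covariance; keep the real part
  Re(fft(sqrt(ev / m) * z))[1:n]
}

# gamma(k) = (|k+1|^{2h} - 2|k|^{2h} + |k-1|^{2h}) / 2 for unit-variance fGn,
# evaluated as k^{2h} (expm1(2h log1p(1/k)) + expm1(2h log1p(-1/k))) / 2 for
# k >= 1 to avoid the catastrophic cancellation of the direct form at large
# lags (which otherwise corrupts the embedding eigenvalues).
fgn_autocovariance <- function(n, h) {
  k <- 1:n
  c(1, k^(2 * h) * (expm1(2 * h * log1p(1 / k)) +
                      expm1(2 * h * log1p(-1 / k))) / 2)
}

fgn_dense <- function(n, h, gam) {
  sigma <- stats::toeplitz(gam[1:n])
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("fractional Gaussian noise covariance is not positive definite.")
  })
  as.vector(crossprod(ch, rnorm(n)))
}

#' Simulate fractional Gaussian noise
#'
#' Draws one realization of stationary fractional Gaussian noise (fGn), the
#' increment process of fractional Brownian motion, by exact circulant
#' embedding of the fGn autocovariance
#' \eqn{\gamma(j) = \sigma^2 dt^{2h} (|j+1|^{2h} - 2|j|^{2h} + |j-1|^{2h})/2}.
#' The process has mean zero and per-sample variance \eqn{\sigma^2 dt^{2h}};
#' for `h = 0.9` the lag-1 autocorrelation is \eqn{2^{2h-1}-1 \approx 0.741}.
#'
#' @param n Number of samples (at least 2).
#' @param h Hurst exponent in (0, 1).
#' @param seed Integer seed; every stochastic function in the package takes an
#'   explicit seed and leaves the global RNG state untouched.
#' @param sigma Scale parameter (> 0) of the parent fractional Brownian motion,
#'   whose variance at time t is \eqn{\sigma^2 t^{2h}}.
#' @param dt Sampling period (> 0).
#'
#' @return A tibble with columns `t` and `value`.
#' @seealso [simulate_fbm()], whose values are the cumulative sum of the fGn
#'   drawn with the same seed.
#' @examples
#' x <- simulate_fgn(512, h = 0.7, seed = 1)
#' mean(x$value)
#' @export
simulate_fgn <- function(n, h, seed, sigma = 1, dt = 1) {
  assert_count(n, "n", min = 2L)
  assert_scalar_number(h, "h", 0, 1, strict = TRUE)
  assert_count(seed, "seed", min = -.Machine$integer.max)
  assert_scalar_number(sigma, "sigma", 0, Inf, strict = TRUE)
  assert_scalar_number(dt, "dt", 0, Inf, strict = TRUE)
  values <- withr::with_seed(as.integer(seed), fgn_unit(n, h))
  values <- sigma * dt^h * values
  tibble::tibble(t = dt * (seq_len(n) - 1), value = values)
}

#' Simulate fractional Brownian motion
#'
#' Draws one realization of fractional Brownian motion (fBm) with Hurst
#' exponent `h` as the cumulative sum of exact-covariance fractional Gaussian
#' noise, so that \eqn{Var[fBm(t)] = \sigma^2 t^{2h}}. `h = 0.5` gives a
#' Wiener process; `h > 0.5` persistent, `h < 0.5` anti-persistent paths.
#'
#' @inheritParams simulate_fgn
#' @return A tibble with columns `t` and `value`; `value` equals
#'   `cumsum(simulate_fgn(n, h, seed, sigma, dt)$value)`.
#' @examples
#' b <- simulate_fbm(1024, h = 0.9, seed = 7)
#' @export
simulate_fbm <- function(n, h, seed, sigma = 1, dt = 1) {
  g <- simulate_fgn(n, h, seed, sigma, dt)
  tibble::tibble(t = g$t + g$t[2] - g$t[1], value = cumsum(g$value))
}

#' Default regime mix for synthetic actigraphy
#'
#' The regime composition used as the package-wide study condition: 16
#' depression windows (H = 0.9), 7 mania windows (H = 0.2) and 8 stable
#' windows (H = 0.55) of 120 one-minute epochs each, i.e. the tri-modal
#' mesoscale structure of a bipolar-disorder recording dominated by
#' depressive episodes.
#'
#' @return A tibble with columns `label`, `hurst`, `n_windows`.
#' @export
episode_mix_regimes <- function() {
  tibble::tibble(
    label = c("depression", "mania", "stable"),
    hurst = c(0.9, 0.2, 0.55),
    n_windows = c(16L, 7L, 8L)
  )
}

regime_ranges <- list(
  mania = c(0, 1 / 3),
  stable = c(1 / 2, 2 / 3),
  depression = c(2 / 3, 1)
)

validate_regimes <- function(regimes) {
  assert_that(is.data.frame(regimes) && nrow(regimes) >= 1L,
              "`regimes` must be a data frame with at least one row.")
  assert_that(all(c("label", "hurst", "n_windows") %in% names(regimes)),
              "`regimes` needs columns label, hurst, n_windows.")
  assert_that(all(regimes$label %in% names(regime_ranges)),
              "regime labels must be one of mania, stable, depression.")
  assert_that(all(regimes$n_windows >= 1 &
                    regimes$n_windows == as.integer(regimes$n_windows)),
              "each regime needs a positive integer number of windows.")
  for (i in seq_len(nrow(regimes))) {
    rng <- regime_ranges[[regimes$label[i]]]
    assert_that(regimes$hurst[i] > rng[1] && regimes$hurst[i] < rng[2] ||
                  (regimes$label[i] != "mania" && regimes$hurst[i] == rng[1]),
                sprintf("regime %d: hurst %.3f outside the %s range (%.3f, %.3f).",
                        i, regimes$hurst[i], regimes$label[i], rng[1], rng[2]))
  }
  invisible(regimes)
}

#' Generate a regime-switching synthetic actigraphy stream
#'
#' Emulates a tri-axial 1-minute-epoch actigraphy recording whose consecutive
#' windows are independent fractional-Gaussian-noise realizations, one Hurst
#' regime per mood episode. Each axis of each window receives a small
#' independent jitter on the regime Hurst exponent (mimicking the small
#' between-axis differences seen in real recordings), so the windowed
#' complexity profile of the stream has the tri-modal density structure of a
#' bipolar-disorder recording. Ground-truth window labels are returned
#' alongside the data.
#'
#' @param regimes Data frame with columns `label` (one of `"mania"`,
#'   `"stable"`, `"depression"`), `hurst` (inside that label's episode range)
#'   and `n_windows`. Default [episode_mix_regimes()].
#' @param window_len Samples per window (default 120, i.e. 120 minutes at
#'   1-minute epochs).
#' @param seed Integer root seed; all window/axis draws derive from it.
#' @param dt Epoch length in minutes (default 1).
#' @param jitter Half-width of the uniform per-axis jitter on the regime Hurst
#'   exponent (default 0.03; the jittered value is clamped to (0.02, 0.98)).
#' @param baseline Nonnegative shift added to all values to mimic acceleration
#'   magnitudes (default 0).
#' @param start Start timestamp (POSIXct, default 2024-01-01 00:00 UTC).
#'
#' @return An object of class `synth_actigraphy`: a list with
#'   \describe{
#'     \item{data}{tibble `timestamp, x, y, z` of the concatenated windows}
#'     \item{labels}{tibble of per-window ground truth: `window_index`,
#'       `start_time`, `label`, `hurst`}
#'     \item{window_len, dt}{the generating parameters}
#'   }
#' @examples
#' s <- synth_actigraphy(seed = 1)
#' s$labels
#' @export
synth_actigraphy <- function(regimes = episode_mix_regimes(), window_len = 120,
                             seed = 1, dt = 1, jitter = 0.03, baseline = 0,
                             start = as.POSIXct("2024-01-01 00:00:00",
                                                tz = "UTC")) {
  validate_regimes(regimes)
  assert_count(window_len, "window_len", min = 17L)
  assert_scalar_number(jitter, "jitter", 0, 0.03)
  assert_scalar_number(baseline, "baseline", 0, Inf)
  assert_scalar_number(dt, "dt", 0, Inf, strict = TRUE)

  window_h <- rep(regimes$hurst, regimes$n_windows)
  window_label <- rep(regimes$label, regimes$n_windows)
  n_windows <- length(window_h)

  axes <- withr::with_seed(as.integer(seed), {
    lapply(1:3, function(axis) {
      unlist(lapply(seq_len(n_windows), function(w) {
        hj <- window_h[w] + runif(1, -jitter, jitter)
        hj <- min(max(hj, 0.02), 0.98)
        fgn_unit(window_len, hj)
      }))
    })
  })

  n <- n_windows * window_len
  timestamp <- start + 60 * dt * (seq_len(n) - 1)
  out <- list(
    data = tibble::tibble(
      timestamp = timestamp,
      x = axes[[1]] + baseline,
      y = axes[[2]] + baseline,
      z = axes[[3]] + baseline
    ),
    labels = tibble::tibble(
      window_index = seq_len(n_windows),
      start_time = timestamp[(seq_len(n_windows) - 1) * window_len + 1],
      label = window_label,
      hurst = window_h
    ),
    window_len = as.integer(window_len),
    dt = dt
  )
  class(out) <- "synth_actigraphy"
  out
}

#' @export
print.synth_actigraphy <- function(x, ...) {
  cat(sprintf(
    "<synth_actigraphy> %d windows x %d samples (dt = %g min), 3 axes\n",
    nrow(x$labels), x$window_len, x$dt
  ))
  counts <- table(x$labels$label)
  cat("  regimes:", paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", "), "\n")
  invisible(x)
}
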