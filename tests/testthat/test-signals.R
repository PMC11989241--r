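test_that("weierstrass matches the geometric closed form at t = 0 and is deterministic", {
  w <- weierstrass(0.5, n_points = 101, domain = c(0, 2 * pi))
  # f(0) = sum_{n=0}^{30} 2^(-n/2), a finite geometric series
  r <- 2^(-0.5)
  closed_form <- (1 - r^31) / (1 - r)
  expect_equal(w$value[1], closed_form, tolerance = 1e-12)
  expect_equal(w$value[1], sum(2^(-0.5 * (0:30))), tolerance = 1e-14)

  expect_identical(weierstrass(0.7, 4097), weierstrass(0.7, 4097))
})

test_that("weierstrass validates its specification", {
  expect_error(weierstrass(0, 100), "h")
  expect_error(weierstrass(1.2, 100), "h")
  expect_error(weierstrass(0.5, 2), "n_points")
  expect_error(weierstrass(0.5, 100, domain = c(1, 1)), "domain")
})

test_that("fGn and fBm are linked by cumulative summation under the same seed", {
  g <- simulate_fgn(512, h = 0.8, seed = 9, sigma = 1.5, dt = 2)
  b <- simulate_fbm(512, h = 0.8, seed = 9, sigma = 1.5, dt = 2)
  expect_identical(b$value, cumsum(g$value))
  expect_identical(simulate_fgn(512, 0.8, seed = 9)$value,
                   simulate_fgn(512, 0.8, seed = 9)$value)
})

test_that("fGn has the closed-form lag-1 autocorrelation and zero mean", {
  # gamma(1)/gamma(0) = 2^(2h-1) - 1
  h <- 0.9
  target <- 2^(2 * h - 1) - 1
  # non-centred estimator: the process mean is known to be zero, and
  # mean-centring is badly biased under long-range dependence
  rho <- vapply(1:30, function(s) {
    v <- simulate_fgn(2^14, h, seed = s)$value
    n <- length(v)
    sum(v[-n] * v[-1]) / sum(v^2)
  }, numeric(1))
  se <- stats::sd(rho) / sqrt(length(rho))
  expect_lt(abs(mean(rho) - target), 3 * se + 1e-3)

  # white noise: lag-1 autocorrelation vanishes as 1/sqrt(n)
  v <- simulate_fgn(2^16, 0.5, seed = 3)$value
  n <- length(v)
  rho1 <- sum(v[-n] * v[-1]) / sum(v^2)
  expect_lt(abs(rho1), 3 / sqrt(n))

  means <- vapply(1:30, function(s) mean(simulate_fgn(2^12, 0.7, s)$value),
                  numeric(1))
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(30))
})

test_that("fGn per-sample variance matches sigma^2 dt^(2h)", {
  h <- 0.7; sigma <- 1.3; dt <- 0.5
  target <- sigma^2 * dt^(2 * h)
  # mean square rather than var(): the process mean is exactly zero, and the
  # centred sample variance is biased under long-range dependence
  vars <- vapply(1:100, function(s) {
    mean(simulate_fgn(2^12, h, seed = s, sigma = sigma, dt = dt)$value^2)
  }, numeric(1))
  se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - target), 3 * se)
})

test_that("fBm variance scales as t^(2h)", {
  h <- 0.7
  idx <- 2^(4:13)
  paths <- vapply(1:120, function(s) simulate_fbm(2^13, h, seed = s)$value[idx],
                  numeric(length(idx)))
  v <- apply(paths, 1, stats::var)
  slope <- stats::coef(stats::lm(log(v) ~ log(idx)))[2]
  expect_lt(abs(slope - 2 * h), 0.05)
})

test_that("synth_actigraphy emits exactly k labels and k * window_len samples per axis", {
  s <- study_stream()
  expect_equal(nrow(s$labels), 31L)
  expect_equal(nrow(s$data), 31L * 120L)
  expect_named(s$data, c("timestamp", "x", "y", "z"))
  expect_equal(as.vector(table(s$labels$label)[c("depression", "mania", "stable")]),
               c(16L, 7L, 8L))

  small <- synth_actigraphy(
    regimes = data.frame(label = "stable", hurst = 0.55, n_windows = 2),
    window_len = 32, seed = 5
  )
  expect_equal(nrow(small$data), 64L)
  expect_equal(nrow(small$labels), 2L)
})

test_that("synth_actigraphy rejects empty or invalid regimes", {
  expect_error(synth_actigraphy(regimes = data.frame()), "regimes")
  expect_error(synth_actigraphy(
    regimes = data.frame(label = "mania", hurst = 0.2, n_windows = 0)
  ), "integer")
  expect_error(synth_actigraphy(
    regimes = data.frame(label = "mania", hurst = 0.8, n_windows = 2)
  ), "range")
  expect_error(synth_actigraphy(
    regimes = data.frame(label = "elated", hurst = 0.5, n_windows = 2)
  ), "label")
})

test_that("single-regime streams recover their Hurst exponent at window scale", {
  s <- synth_actigraphy(
    regimes = data.frame(label = "stable", hurst = 0.5, n_windows = 12),
    seed = 7
  )
  prof <- profile_actigraphy(s$data)
  err <- abs(prof$h_mean - 0.5)
  expect_lt(stats::median(err), 0.15)
  expect_gte(mean(err <= 0.15), 0.8)
})
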