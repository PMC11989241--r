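test_that("midpoint variation evaluates hand-checked cases and vanishes on affine input", {
  expect_identical(midpoint_variation(c(0, 1, 0)), 1)
  expect_identical(midpoint_variation(c(0, 1, 0, 1, 0)), 3)
  expect_identical(midpoint_variation(2 + 3 * (1:50)), 0)
  expect_identical(midpoint_variation(rep(4, 20)), 0)
  expect_error(midpoint_variation(c(1, 2)), "3 points")
})

test_that("dyadic deltas: affine input, identity stride, and white-noise growth", {
  expect_true(all(dyadic_deltas(5 - 2 * (1:1025), k_min = 2)$delta == 0))

  x <- small_fbm()$value[1:(2^10 + 1)]
  dd <- dyadic_deltas(x, k_min = 4, k_max = 10)
  expect_equal(dd$delta[dd$level == 10], midpoint_variation(x))
  expect_equal(dd$n_points, 2^(4:10) + 1L)

  # i.i.d. data: E[Delta_k] is proportional to the interior point count,
  # so the level-(k+1) to level-k ratio is (2^(k+1)-1)/(2^k-1)
  k <- 6
  target <- (2^(k + 1) - 1) / (2^k - 1)
  ratios <- vapply(1:100, function(s) {
    v <- simulate_fgn(2^10 + 1, 0.5, seed = 100 + s)$value
    dd <- dyadic_deltas(v, k_min = k, k_max = k + 1)
    dd$delta[2] / dd$delta[1]
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - target), 3 * se)
})

test_that("dyadic deltas validate the level range", {
  expect_error(dyadic_deltas(rnorm(20), k_min = 1), "k_min")
  expect_error(dyadic_deltas(rnorm(20), k_min = 4, k_max = 6), "too short")
})

test_that("scaling cost is zero at a perfect fit and nonnegative elsewhere", {
  lv <- 4:9
  a_star <- 2.7; h_star <- 1.4; tt <- 512
  d <- a_star * (tt / (2^lv + 1))^(1 - h_star)
  expect_equal(scaling_cost(a_star, h_star, lv, d, total_time = tt), 0,
               tolerance = 1e-20)
  for (a in c(0.5, 3, 10)) {
    expect_gte(scaling_cost(a, 1.2, lv, d, total_time = tt), 0)
  }
  # realized-grid form agrees with the nominal one on exactly dyadic grids
  spacing <- tt / (2^lv + 1)
  g_nom <- (tt / (2^lv + 1))^(1 - 1.3)
  g_real <- (2^lv - 1) * spacing^(2 - 1.3)
  expect_equal(g_real / g_nom, (2^lv - 1) * spacing, tolerance = 1e-12)
})

test_that("cost cross-sections in the amplitude are convex", {
  v <- simulate_fgn(2^12, 0.5, seed = 21)$value
  dd <- dyadic_deltas(v, k_min = 4)
  a_grid <- seq(1, 20, by = 0.1)
  for (h in c(0.5, 1.5)) {
    cs <- vapply(a_grid, scaling_cost, numeric(1), h = h, levels = dd$level,
                 deltas = dd$delta, total_time = 2^12)
    expect_true(all(diff(cs, differences = 2) >= -1e-6 * max(cs)))
  }
})

test_that("the estimator recovers Hurst exponents and is monotone in the truth", {
  for (h in c(0.3, 0.7)) {
    fits <- vapply(1:5, function(s) {
      estimate_hurst(simulate_fbm(2^14, h, seed = s)$value)$H
    }, numeric(1))
    expect_lt(abs(mean(fits) - h), 0.1)
  }
  mean_h <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(h) {
    mean(vapply(1:3, function(s) {
      estimate_hurst(simulate_fbm(2^14, h, seed = 40 + s)$value)$H
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h) > 0))
})

test_that("the estimate is invariant to amplitude and time rescaling", {
  x <- small_fbm()$value
  ref <- estimate_hurst(x)
  for (c0 in c(0.1, 10)) {
    expect_lt(abs(estimate_hurst(c0 * x)$H - ref$H), 1e-9)
  }
  expect_lt(abs(estimate_hurst(x, dt = 7)$H - ref$H), 1e-9)
})

test_that("grid search plus refinement matches an exhaustive brute force", {
  x <- small_fbm()$value
  fit <- estimate_hurst(x)
  dd <- fit$levels
  hs <- seq(1.01, 1.99, length.out = 300)
  las <- seq(log(1e-4), log(1e4), length.out = 300)
  best <- c(Inf, NA)
  for (h in hs) {
    g <- dd$n_interior * dd$spacing^(2 - h)
    costs <- vapply(exp(las), function(a) sum((dd$delta - a * g)^2), numeric(1))
    if (min(costs) < best[1]) best <- c(min(costs), h)
  }
  coarse_cell <- 0.98 / 63
  expect_lt(abs(fit$exponent - best[2]), coarse_cell)
  expect_lte(fit$cost, best[1] + 1e-9 * best[1])
})

test_that("degenerate series raise, and the Hurst/fd identity holds exactly", {
  expect_error(estimate_hurst(0.5 + 1.25 * (1:200)), "degenerate")
  expect_error(estimate_hurst(rep(3.3, 200)), "degenerate")

  fit <- estimate_hurst(small_fbm()$value)
  expect_identical(fit$fd, fit$ambient_dim - fit$H)
  expect_true(fit$H > 0 && fit$H < 1)
  expect_gt(fit$a, 0)
  expect_gte(fit$cost, 0)

  expect_equal(hurst_to_fd(0.9), 1.1)
  expect_equal(hurst_to_fd(0.5), 1.5)
  expect_equal(hurst_to_fd(0.3, d = 3), 2.7)
  expect_error(hurst_to_fd(1.2), "0, 1")
})

test_that("stationary noise is handled through integration", {
  fits <- vapply(1:5, function(s) {
    estimate_hurst(simulate_fgn(2^14, 0.5, seed = 60 + s)$value,
                   integrate = TRUE)$H
  }, numeric(1))
  expect_lt(abs(mean(fits) - 0.5), 0.1)
})

test_that("tidy and glance expose the fit in rectangular form", {
  fit <- estimate_hurst(small_fbm()$value)
  td <- tidy(fit)
  expect_true(all(c("level", "delta", "fitted", "spacing") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$H, fit$H)
})
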