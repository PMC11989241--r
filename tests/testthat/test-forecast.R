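lib_small <- function() {
  memo("lib_small",
       build_library(h_grid = seq(0.15, 0.85, length.out = 8),
                     length = 20 * 120, seed = 31))
}

test_that("pdf_distance is a metric and matches the Gaussian closed form", {
  g <- seq(0, 1, length.out = 512)
  a <- density_model(g, dnorm(g, 0.3, 0.05))
  b <- density_model(g, dnorm(g, 0.7, 0.05))
  expect_equal(pdf_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(pdf_distance(a, b), pdf_distance(b, a))

  # || N(0.3, s) - N(0.7, s) ||_2 with s = 0.05: the cross term is
  # exp(-dmu^2 / (4 s^2)) ~ 0, so the squared distance is 1 / (sqrt(pi) s)
  sigma <- 0.05
  dmu <- 0.4
  closed <- sqrt((1 - exp(-dmu^2 / (4 * sigma^2))) / (sqrt(pi) * sigma))
  expect_equal(pdf_distance(a, b), closed, tolerance = 1e-3)

  # triangle inequality on random kernel densities
  withr::with_seed(77, {
    for (r in 1:5) {
      dens <- lapply(1:3, function(i) {
        estimate_density(pmin(pmax(rnorm(40, runif(1, 0.2, 0.8), 0.1),
                                   0.02), 0.98))
      })
      d12 <- pdf_distance(dens[[1]], dens[[2]])
      d13 <- pdf_distance(dens[[1]], dens[[3]])
      d23 <- pdf_distance(dens[[2]], dens[[3]])
      expect_lte(d12, d13 + d23 + 1e-12)
    }
  })
  expect_error(pdf_distance(a, b, p = 0.5), "p")
})

test_that("library construction honours the grid, seeds and variance calibration", {
  lib <- lib_small()
  expect_equal(nrow(lib$scenarios), 8L)
  expect_equal(lib$scenarios$n_windows[1], 20L)
  expect_length(lib$hurst[[1]], 20L)
  for (dm in lib$densities) {
    expect_equal(sum(diff(dm$grid) * (dm$pdf[-1] + dm$pdf[-512]) / 2), 1,
                 tolerance = 1e-6)
  }
  # default grid is equidistant with the requested size
  lib_def <- build_library(n_scenarios = 4, length = 8 * 120, seed = 2)
  expect_equal(nrow(lib_def$scenarios), 4L)
  steps <- diff(lib_def$scenarios$h)
  expect_lt(max(abs(steps - mean(steps))), 1e-12)

  # duplicate Hurst parameters still give distinct realizations
  lib_dup <- build_library(h_grid = c(0.5, 0.5), length = 8 * 120, seed = 3)
  expect_false(identical(lib_dup$hurst[[1]], lib_dup$hurst[[2]]))

  # scenario variance is calibrated to the requested target
  target <- 2.5
  lib_var <- build_library(h_grid = c(0.5, 0.5, 0.5, 0.5), length = 40 * 120,
                           variance = target, seed = 4)
  vars <- vapply(seq_len(4), function(i) {
    mean(simulate_fgn(lib_var$length, 0.5,
                      seed = lib_var$scenarios$seed[i],
                      sigma = sqrt(target))$value^2)
  }, numeric(1))
  se <- target * sqrt(2 / lib_var$length)
  expect_lt(abs(mean(vars) - target), 3 * se / sqrt(4))
})

test_that("extrapolation preserves the observed prefix bitwise", {
  lib <- lib_small()
  y <- lib$hurst[[5]][1:9]
  fc <- extrapolate(y, lib, horizon = 6)
  expect_identical(fc$extended[1:9], y)
  expect_length(fc$extended, 15L)
  expect_equal(fc$k, 9L)
  expect_error(extrapolate(y, lib, horizon = 0), "horizon")
  expect_error(extrapolate(y[1:5], lib, horizon = 2), "at least 8")
  expect_error(extrapolate(y, lib, horizon = 100), "windows")
})

test_that("a 31-of-41-window protocol yields a 41-point extended trajectory", {
  lib <- build_library(h_grid = seq(0.2, 0.8, length.out = 6),
                       length = 45 * 120, seed = 55)
  y <- lib$hurst[[3]][1:31]
  fc <- extrapolate(y, lib, horizon = 10)
  expect_length(fc$extended, 41L)
  expect_identical(fc$extended[1:31], y)
})

test_that("appending strictly worse scenarios never changes the selection", {
  lib <- lib_small()
  y <- lib$hurst[[2]][1:10]
  fc1 <- extrapolate(y, lib, horizon = 4)
  # append a scenario whose density is far from any Hurst sample near y
  g <- seq(0, 1, length.out = 512)
  far <- density_model(g, dnorm(g, if (mean(y) < 0.5) 0.95 else 0.05, 0.01))
  lib2 <- lib
  lib2$scenarios <- dplyr::bind_rows(
    lib2$scenarios,
    tibble::tibble(id = 9L, h = 0.99, seed = 1L, n_windows = 20L)
  )
  lib2$hurst <- c(lib2$hurst, list(rep(0.95, 20)))
  lib2$densities <- c(lib2$densities, list(far))
  fc2 <- extrapolate(y, lib2, horizon = 4)
  expect_identical(fc2$selected_id, fc1$selected_id)
  expect_identical(fc2$extended, fc1$extended)
})

test_that("mood trend interprets derivative signs per the phenomenological table", {
  down <- mood_trend(c(0.9, 0.8, 0.65, 0.5, 0.35), tol = 0.01)
  expect_true(all(down$interpretation == "manic_expected"))
  flat <- mood_trend(rep(0.55, 6))
  expect_true(all(flat$interpretation == "no_change"))
  up <- mood_trend(c(0.2, 0.35, 0.5, 0.7, 0.85))
  expect_true(all(up$interpretation == "depressive_expected"))
  expect_error(mood_trend(c(0.4, 0.5)), "3")
})

test_that("the trend flips exactly at a trajectory minimum", {
  y <- c(0.8, 0.6, 0.4, 0.3, 0.4, 0.6, 0.8)
  tr <- mood_trend(y, tol = 1e-6)
  expect_true(all(tr$interpretation[1:3] == "manic_expected"))
  expect_true(all(tr$interpretation[5:7] == "depressive_expected"))
  # the monotone interpolant has zero slope at the interior extremum
  expect_equal(tr$interpretation[4], "no_change")
})

test_that("extrapolation errors are absolute percentages of the truth", {
  lib <- lib_small()
  y <- lib$hurst[[4]][1:10]
  fc <- extrapolate(y, lib, horizon = 3)
  truth <- c(0.5, 0.4, 0.8)
  err <- extrapolation_errors(fc, truth)
  expect_equal(err$error_pct,
               100 * abs(err$predicted - truth) / truth)
  expect_equal(err$window_index, 11:13)
})
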