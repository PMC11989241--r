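#' Split a series into non-overlapping windows
#'
#' Consecutive windows of `window_len` samples; a trailing partial window is
#' dropped, so exactly `floor(n / window_len)` windows are returned.
#'
#' @param x Numeric vector or data frame with a `value` column.
#' @param window_len Window length in samples (>= 17, so that at least two
#'   dyadic levels fit in each window).
#' @param column Column to use when `x` is a data frame.
#' @return A tibble with one row per window: `window_index`, `start`, `end`
#'   (sample indices) and a list-column `values`.
#' @examples
#' segment_series(rnorm(360), 120) # 3 windows
#' @export
segment_series <- function(x, window_len, column = "value") {
  v <- series_values(x, column)
  assert_count(window_len, "window_len", min = 17L)
  assert_that(window_len <= length(v),
              "`window_len` exceeds the series length.")
  n_windows <- length(v) %/% window_len
  start <- (seq_len(n_windows) - 1L) * window_len + 1L
  tibble::tibble(
    window_index = seq_len(n_windows),
    start = start,
    end = start + as.integer(window_len) - 1L,
    values = lapply(seq_len(n_windows),
                    function(w) v[start[w]:(start[w] + window_len - 1L)])
  )
}

EPISODE_LEVELS <- c("mania", "mild_mania", "stable", "depression")

#' Classify a Hurst exponent into a mood-episode label
#'
#' Complexity-based episode indexing: anti-persistent windows (low H, erratic
#' movement) index manic episodes, persistent windows (high H, long-memory
#' movement) depressive episodes, and near-Wiener windows stability. Bins are
#' half-open, boundary values going to the higher-H bin:
#' `mania` for H < 1/3, `mild_mania` for 1/3 <= H < 1/2, `stable` for
#' 1/2 <= H < 2/3, `depression` for H >= 2/3.
#'
#' @param H Numeric vector of Hurst exponents, all strictly in (0, 1).
#' @return A factor with levels mania, mild_mania, stable, depression.
#' @examples
#' classify_episode(c(0.21, 0.55, 0.9))
#' @export
classify_episode <- function(H) {
  assert_that(is.numeric(H) && all(is.finite(H)) && all(H > 0 & H < 1),
              "`H` must lie strictly in (0, 1).")
  cut(H, breaks = c(0, 1 / 3, 1 / 2, 2 / 3, 1),
      labels = EPISODE_LEVELS, right = FALSE)
}

# collapse the four-level episode scale onto mania / stable / depression
collapse_episode <- function(label) {
  out <- as.character(label)
  out[out == "mild_mania"] <- "mania"
  out
}

# window-level estimate; NA for degenerate windows
window_hurst <- function(values, dt, k_min, k_max, subsample, integrate) {
  tryCatch(
    estimate_hurst(values, dt = dt, k_min = k_min, k_max = k_max,
                   subsample = subsample, integrate = integrate)$H,
    error = function(e) NA_real_
  )
}

#' Windowed complexity profile of a tri-axial actigraphy stream
#'
#' Projects a long actigraphy recording onto the mesoscale: per window (120
#' one-minute epochs by default) and per acceleration axis, the Hurst exponent
#' is estimated by the variational scaling principle, and each window receives
#' episode labels from [classify_episode()]. The per-window `h_mean` is the
#' arithmetic mean of the axis estimates. Since raw acceleration fluctuations
#' are stationary noise-like series, windows are cumulated to their path
#' before estimation (`integrate = TRUE`), and exact-stride subsampling is
#' used, both window-aware defaults of the estimator.
#'
#' Windows on which an axis is degenerate (constant/affine) get `NA` for that
#' axis; `h_mean` averages the remaining axes.
#'
#' @param data A data frame with numeric axis columns (default `x`, `y`, `z`)
#'   and optionally a `timestamp` column.
#' @param window_len Samples per window (default 120).
#' @param axes Names of the axis columns.
#' @param dt Sampling period in minutes (default 1; taken from `timestamp`
#'   when present).
#' @param k_min Smallest dyadic level for the windowed estimator (default 3;
#'   short windows support levels 3 to `floor(log2(window_len - 1))`).
#' @param subsample,integrate Estimator configuration, see [estimate_hurst()].
#'
#' @return A `complexity_profile` tibble with one row per window:
#'   `window_index`, `start_time`, `h_<axis>` and `label_<axis>` per axis,
#'   `h_mean`, `label_mean`. Attributes `window_len` and `dt` are set.
#' @examples
#' s <- synth_actigraphy(seed = 1)
#' prof <- profile_actigraphy(s$data)
#' @export
profile_actigraphy <- function(data, window_len = 120, axes = c("x", "y", "z"),
                               dt = NULL, k_min = 3,
                               subsample = "exact", integrate = TRUE) {
  assert_that(is.data.frame(data), "`data` must be a data frame.")
  assert_that(all(axes %in% names(data)),
              sprintf("axis columns missing: %s.",
                      paste(setdiff(axes, names(data)), collapse = ", ")))
  assert_count(window_len, "window_len", min = 17L)
  assert_that(window_len <= nrow(data),
              "`window_len` exceeds the number of samples.")
  if (is.null(dt)) {
    dt <- if ("timestamp" %in% names(data) && nrow(data) >= 2L) {
      as.double(difftime(data$timestamp[2], data$timestamp[1], units = "mins"))
    } else {
      1
    }
  }
  k_max <- floor(log2(window_len - 1))

  n_windows <- nrow(data) %/% window_len
  start <- (seq_len(n_windows) - 1L) * window_len + 1L
  start_time <- if ("timestamp" %in% names(data)) {
    data$timestamp[start]
  } else {
    (start - 1) * dt
  }

  h_axis <- lapply(axes, function(ax) {
    v <- series_values(data[[ax]])
    vapply(seq_len(n_windows), function(w) {
      window_hurst(v[start[w]:(start[w] + window_len - 1L)], dt,
                   k_min, k_max, subsample, integrate)
    }, numeric(1))
  })
  names(h_axis) <- axes

  h_mat <- do.call(cbind, h_axis)
  h_mean <- rowMeans(h_mat, na.rm = TRUE)
  h_mean[is.nan(h_mean)] <- NA_real_

  label_of <- function(h) {
    out <- rep(NA_character_, length(h))
    ok <- !is.na(h)
    out[ok] <- as.character(classify_episode(h[ok]))
    out
  }

  prof <- tibble::tibble(window_index = seq_len(n_windows),
                         start_time = start_time)
  for (ax in axes) prof[[paste0("h_", ax)]] <- h_axis[[ax]]
  prof$h_mean <- h_mean
  for (ax in axes) prof[[paste0("label_", ax)]] <- label_of(h_axis[[ax]])
  prof$label_mean <- label_of(h_mean)

  attr(prof, "window_len") <- as.integer(window_len)
  attr(prof, "dt") <- dt
  attr(prof, "axes") <- axes
  class(prof) <- c("complexity_profile", class(prof))
  prof
}

#' @method autoplot complexity_profile
#' @export
autoplot.complexity_profile <- function(object, ...) {
  axes <- attr(object, "axes") %||% c("x", "y", "z")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("window_index", paste0("h_", axes))],
    cols = -"window_index", names_to = "axis", names_prefix = "h_",
    values_to = "H"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$window_index, y = .data$H,
                               fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(1 / 3, 1 / 2, 2 / 3),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "120-min window", y = "Hurst exponent",
                  title = "Windowed complexity profile") +
    ggplot2::theme_minimal()
}

#' Write / read a complexity profile as TSV
#'
#' Column layout: `window_index start_time h_x h_y h_z h_mean label_x label_y
#' label_z label_mean`.
#'
#' @param profile A `complexity_profile` (or compatible data frame).
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a tibble.
#' @export
write_profile <- function(profile, path) {
  ord <- intersect(
    c("window_index", "start_time", "h_x", "h_y", "h_z", "h_mean",
      "label_x", "label_y", "label_z", "label_mean"),
    names(profile)
  )
  readr::write_tsv(tibble::as_tibble(profile)[ord], path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
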