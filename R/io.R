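#' Read an actigraphy CSV
#'
#' The package-wide actigraphy dialect: a CSV with header
#' `timestamp,x,y,z`, ISO-8601 timestamps on a regular grid (1-minute epochs
#' by default). Timestamps must be strictly increasing and equidistant within
#' 1% of the median step; violations raise an error naming the offending
#' rows.
#'
#' @param path CSV file path.
#' @return A tibble `timestamp, x, y, z` with attribute `dt` (epoch length in
#'   minutes).
#' @export
read_actigraphy <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  data <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    x = readr::col_double(),
    y = readr::col_double(),
    z = readr::col_double()
  ))
  assert_that(all(c("timestamp", "x", "y", "z") %in% names(data)),
              "actigraphy CSV needs columns timestamp, x, y, z.")
  assert_that(!any(is.na(data$timestamp)), "unparseable timestamps present.")
  for (ax in c("x", "y", "z")) {
    bad <- which(!is.finite(data[[ax]]))
    assert_that(length(bad) == 0L,
                sprintf("non-numeric or missing `%s` values at rows: %s.",
                        ax, paste(head(bad, 5), collapse = ", ")))
  }
  steps <- as.double(diff(data$timestamp), units = "mins")
  dup <- which(steps <= 0)
  assert_that(length(dup) == 0L,
              sprintf("non-monotone or duplicated timestamps after rows: %s.",
                      paste(head(dup, 5), collapse = ", ")))
  med <- stats::median(steps)
  irregular <- which(abs(steps - med) > 0.01 * med)
  assert_that(length(irregular) == 0L,
              sprintf("irregular sampling (gaps) after rows: %s.",
                      paste(head(irregular, 5), collapse = ", ")))
  attr(data, "dt") <- med
  data
}

#' Write an actigraphy stream as CSV
#'
#' Writes the package actigraphy dialect (`timestamp,x,y,z`, ISO-8601). For a
#' [synth_actigraphy()] object the ground-truth window labels can be written
#' to a JSON sidecar.
#'
#' @param x A [synth_actigraphy()] object or a data frame with columns
#'   `timestamp, x, y, z`.
#' @param path Output CSV path.
#' @param labels_path Optional path for the ground-truth sidecar JSON (only
#'   for `synth_actigraphy` input).
#' @return `path`, invisibly.
#' @export
write_actigraphy <- function(x, path, labels_path = NULL) {
  labels <- NULL
  if (inherits(x, "synth_actigraphy")) {
    labels <- x$labels
    x <- x$data
  }
  assert_that(is.data.frame(x) &&
                all(c("timestamp", "x", "y", "z") %in% names(x)),
              "`x` must have columns timestamp, x, y, z.")
  out <- x
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out[c("timestamp", "x", "y", "z")], path)
  if (!is.null(labels_path)) {
    assert_that(!is.null(labels),
                "ground-truth labels are only available for synth_actigraphy input.")
    sidecar <- labels
    sidecar$start_time <- format(sidecar$start_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")
    jsonlite::write_json(sidecar, labels_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Run the full complexity pipeline
#'
#' Chains the three analysis stages on one actigraphy stream: windowed
#' complexity profile, mood-state decomposition of the Hurst density, and
#' scenario-library extrapolation of the `h_mean` trajectory with a trend
#' assessment. Writes `profile.tsv`, `states.json`, `forecast.json` and
#' `run_log.json` (input hash, configuration, seed, versions) to
#' `output_dir`. All randomness derives from `seed`; the same input,
#' configuration and seed reproduce identical outputs.
#'
#' @param input Actigraphy CSV path or a data frame `timestamp, x, y, z`.
#' @param output_dir Directory for the outputs (created if needed).
#' @param window_len Samples per window (default 120).
#' @param seed Integer root seed (default 1).
#' @param observe Number of leading windows treated as observed for the
#'   forecast; default 3/4 of the windows (rounded down).
#' @param horizon Windows to extrapolate (default 10).
#' @param library_size Number of library scenarios (default 50).
#' @param p Density-distance norm order (default 2).
#' @param bandwidth Bandwidth rule for densities (default `"SJ"`).
#'
#' @return Invisibly, a list with the `profile`, `states`, `forecast`,
#'   `trend` objects and the output paths.
#' @export
run_pipeline <- function(input, output_dir, window_len = 120, seed = 1,
                         observe = NULL, horizon = 10, library_size = 50,
                         p = 2, bandwidth = "SJ") {
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    data <- read_actigraphy(input)
  } else {
    data <- input
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  profile <- profile_actigraphy(data, window_len = window_len)
  profile_path <- file.path(output_dir, "profile.tsv")
  write_profile(profile, profile_path)

  h <- profile$h_mean[!is.na(profile$h_mean)]
  n_windows <- length(h)
  assert_that(n_windows >= 12L,
              "pipeline needs at least 12 profiled windows.")

  dens <- estimate_density(h, bandwidth = bandwidth)
  states <- mood_state_probabilities(dens)
  states_path <- file.path(output_dir, "states.json")
  jsonlite::write_json(
    list(
      inflection_points = attr(states, "inflection_points"),
      states = lapply(seq_len(nrow(states)), function(i) list(
        interval = c(states$lower[i], states$upper[i]),
        probability = states$probability[i],
        label = states$label[i],
        extremum = states$extremum[i]
      )),
      observable_state = attr(states, "observable_state"),
      tail_mass = attr(states, "tail_mass")
    ),
    states_path, auto_unbox = TRUE, digits = NA
  )

  if (is.null(observe)) observe <- max(8L, (3L * n_windows) %/% 4L)
  assert_that(observe >= 8L && observe < n_windows,
              "`observe` must be in [8, number of windows).")
  observed <- h[seq_len(observe)]
  lib <- build_library(
    n_scenarios = library_size,
    length = max(4L, observe + horizon + 2L) * window_len,
    variance = var(observed),
    window_len = window_len,
    seed = derive_seed(seed, 1L),
    bandwidth = bandwidth
  )
  fc <- extrapolate(observed, lib, horizon = horizon, p = p)
  trend <- mood_trend(fc$extended)
  forecast_path <- file.path(output_dir, "forecast.json")
  jsonlite::write_json(
    list(
      selected_h = fc$selected_h,
      selected_id = fc$selected_id,
      distance = fc$distance,
      p = fc$p,
      observed = fc$observed,
      extended_trajectory = fc$extended,
      trend = lapply(seq_len(nrow(trend)), function(i) list(
        segment = trend$segment[i],
        derivative = trend$derivative[i],
        interpretation = trend$interpretation[i]
      ))
    ),
    forecast_path, auto_unbox = TRUE, digits = NA
  )

  log_path <- file.path(output_dir, "run_log.json")
  jsonlite::write_json(
    list(
      input = if (is.null(input_path)) "in-memory data frame" else input_path,
      input_md5 = if (is.null(input_path)) NA else
        unname(tools::md5sum(input_path)),
      n_samples = nrow(data),
      config = list(window_len = window_len, observe = observe,
                    horizon = horizon, library_size = library_size, p = p,
                    bandwidth = bandwidth),
      seed = seed,
      package_version = as.character(utils::packageVersion("actihurst")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ),
    log_path, auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    profile = profile, states = states, forecast = fc, trend = trend,
    paths = list(profile = profile_path, states = states_path,
                 forecast = forecast_path, log = log_path)
  ))
}
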