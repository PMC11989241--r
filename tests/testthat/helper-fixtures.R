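# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# the study-condition stream: 16 depression / 7 mania / 8 stable windows
study_stream <- function() memo("stream", synth_actigraphy(seed = 42))

study_profile <- function() {
  memo("profile", profile_actigraphy(study_stream()$data))
}

# a quick fBm for structural tests
small_fbm <- function() memo("fbm", simulate_fbm(2^12, h = 0.7, seed = 11))

# independent per-trial seeds for selection-recovery trials
derive_seed_for_test <- function(h, r) {
  as.integer(7000L + round(h * 100) * 53L + r)
}
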