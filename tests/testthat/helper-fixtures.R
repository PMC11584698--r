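# Shared fixtures: a small synthetic session built once per test run, and a
# compact configuration used by several files. 128 Hz keeps every band edge
# (40 Hz) well below Nyquist while keeping the suite fast.

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 128, n_trials_left = 10,
                   n_trials_right = 10, seed = 101L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

.fixture_env <- new.env()

get_small_session <- function() {
  if (is.null(.fixture_env$ses))
    .fixture_env$ses <- simulate_session(small_cfg())
  .fixture_env$ses
}

get_small_events <- function() {
  if (is.null(.fixture_env$ev)) {
    ses <- get_small_session()
    fs <- ses$recording$fs
    ecg_f <- preprocess_ecg(ses$recording$data[, "ECG"], fs)
    .fixture_env$ev <- cardiac_events(ecg_f, fs)
    .fixture_env$ecg_f <- ecg_f
  }
  .fixture_env$ev
}

get_small_ecg_filtered <- function() {
  get_small_events()
  .fixture_env$ecg_f
}
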