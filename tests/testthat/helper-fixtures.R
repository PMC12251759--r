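# Shared fixtures, built in code. Heavier objects are memoised so several
# test files can reuse them within one run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

# tiny three-position benchmark: 1 subject, 6 trials/position, 6 s, 4 channels
tiny_bench <- function() memo("tiny_bench", {
  cfg <- synth_config(n_channels = 4, trial_duration = 6,
                      n_trials_per_position = 6, seed = 42)
  shifts <- list(shift_model("left", 0.3, 0.1, seed = 1),
                 shift_model("center", 0, 0, seed = 2),
                 shift_model("right", 0.3, 0.1, seed = 3))
  generate_benchmark(cfg, shifts, n_subjects = 1)
})

# frames for the tiny benchmark, no normalization, 200 ms feature window
tiny_frames <- function() memo("tiny_frames", {
  bench <- tiny_bench()
  pp <- preproc_config(feature_window = 200)
  fr <- lapply(bench$trials, function(tr)
    preprocess_trial(tr$recording, tr$labels, pp, NULL))
  names(fr) <- names(bench$trials)
  fr
})

tiny_preproc <- function() preproc_config(feature_window = 200)

# small model configuration matching the tiny benchmark frames
tiny_model_cfg <- function(ada = FALSE) {
  pp <- tiny_preproc()
  model_config(n_input_channels = 4 * pp$n_segments, t_seg = pp$seg_samples,
               ada = ada)
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
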