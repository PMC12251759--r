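test_that("generation is deterministic and labels are balanced", {
  cfg <- synth_config(n_channels = 3, trial_duration = 6, seed = 7)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_equal(ncol(a$recording$signal), 6 * 2000)
  expect_length(a$labels$labels, 6 * 20)
  # every class occupies at least 10% of the label frames
  for (s in 1:5) {
    lab <- generate_trial(cfg, seed = s)$labels$labels
    expect_true(all(tabulate(lab + 1L, 3L) >= 0.10 * length(lab)))
  }
})

test_that("with zero activation the signal is pure measurement noise", {
  cfg <- synth_config(n_channels = 2, trial_duration = 20,
                      activation_matrix = matrix(0, 2, 3),
                      baseline_activation = 0, measurement_noise_sd = 1,
                      seed = 11)
  tr <- generate_trial(cfg)
  v <- apply(tr$recording$signal, 1, var)
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("class activation scales channel RMS as the envelope model states", {
  # fixed schedules: an all-flexion trial vs an all-rest trial; envelope is
  # baseline + activation, so the RMS ratio is (0.5 + 4) / 0.5 = 9
  am <- matrix(0, 2, 3); am[1, 2] <- 4
  cfg <- synth_config(n_channels = 2, trial_duration = 10,
                      activation_matrix = am, baseline_activation = 0.5,
                      measurement_noise_sd = 0, seed = 3)
  flex <- generate_trial(cfg, schedule = list(edges = 0, classes = 1L))
  rest <- generate_trial(cfg, schedule = list(edges = 0, classes = 0L))
  rms <- function(x) sqrt(mean(x^2))
  ratio <- rms(flex$recording$signal[1, ]) / rms(rest$recording$signal[1, ])
  expect_equal(ratio, 9, tolerance = 0.10)
  # channel 2 has no flexion activation: ratio ~ 1
  ratio2 <- rms(flex$recording$signal[2, ]) / rms(rest$recording$signal[2, ])
  expect_equal(ratio2, 1, tolerance = 0.10)
})

test_that("electrode shift reduces to identity and scales linearly", {
  bench <- tiny_bench()
  rec <- bench$trials[[1]]$recording
  id_shift <- shift_model("left", gain_log_sd = 0, crosstalk_alpha = 0,
                          seed = 9)
  out <- apply_electrode_shift(rec, id_shift)
  expect_equal(out$signal, rec$signal, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(out$position_tag, "left")
  # forced scalar gain 2 doubles every channel RMS exactly
  out2 <- apply_electrode_shift(rec, id_shift, gains = rep(2, 4))
  expect_equal(out2$signal, 2 * rec$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  # applying gains g then h equals one application with g * h (no crosstalk)
  g <- c(0.5, 1, 1.5, 2); h <- c(2, 1.3, 0.8, 1.1)
  twice <- apply_electrode_shift(apply_electrode_shift(rec, id_shift, g),
                                 id_shift, h)
  once <- apply_electrode_shift(rec, id_shift, g * h)
  expect_equal(twice$signal, once$signal, tolerance = 1e-12)
})

test_that("crosstalk mixing follows the stated neighbour rule", {
  x <- matrix(c(rnorm(50), rep(0, 50)), nrow = 2, byrow = TRUE)
  rec <- emg_recording(x, fs = 2000)
  sh <- shift_model("right", gain_log_sd = 0, crosstalk_alpha = 0.2, seed = 1)
  out <- apply_electrode_shift(rec, sh)
  # hand-computed 2x2 mixing: edge channels take alpha from their single
  # neighbour: out1 = 0.8 x1 + 0.2 x2 ; out2 = 0.2 x1 + 0.8 x2
  expect_equal(out$signal[1, ], 0.8 * x[1, ], tolerance = 1e-12)
  expect_equal(out$signal[2, ], 0.2 * x[1, ], tolerance = 1e-12)
  # mixing weights sum to 1 for every output channel
  M <- emgswn:::crosstalk_matrix(7, 0.3)
  expect_equal(rowSums(M), rep(1, 7))
  expect_error(shift_model("left", crosstalk_alpha = 0.7), "0, 0.5")
})

test_that("benchmark manifest covers subjects x positions x trials and the
           center path is the identity", {
  bench <- tiny_bench()
  expect_equal(nrow(bench$manifest), 1 * 3 * 6)
  cfg <- synth_config(n_channels = 4, trial_duration = 6,
                      n_trials_per_position = 4, seed = 42)
  shifts <- list(shift_model("left", 0.3, 0.1, seed = 1),
                 shift_model("center", 0, 0, seed = 2),
                 shift_model("right", 0.3, 0.1, seed = 3))
  b2 <- generate_benchmark(cfg, shifts, 2)
  expect_equal(nrow(b2$manifest), 2 * 3 * 4)
  # center trials equal generate_trial output exactly
  row <- bench$manifest[bench$manifest$position == "center", ][1, ]
  direct <- generate_trial(cfg, row$trial_id, row$subject_id, seed = row$seed)
  expect_identical(bench$trials[[row$key]]$recording$signal,
                   direct$recording$signal)
  expect_error(generate_benchmark(cfg, shifts[c(1, 1, 2)], 1), "distinct")
})

test_that("shifted trials differ from center by a per-channel linear map", {
  cfg <- synth_config(n_channels = 4, trial_duration = 4,
                      n_trials_per_position = 4, seed = 13)
  shifts <- list(shift_model("left", 0.4, 0, seed = 1),   # crosstalk off
                 shift_model("center", 0, 0, seed = 2),
                 shift_model("right", 0.4, 0, seed = 3))
  bench <- generate_benchmark(cfg, shifts, 1)
  man <- bench$manifest
  k_center <- man$key[man$position == "center"]
  k_left <- man$key[man$position == "left"]
  # recover the gains by per-channel least squares on the first trial
  g_hat <- vapply(1:4, function(c) {
    xc <- bench$trials[[k_center[1]]]$recording$signal[c, ]
    xl <- bench$trials[[k_left[1]]]$recording$signal[c, ]
    sum(xc * xl) / sum(xc * xc)
  }, 0)
  expect_true(all(g_hat > 0))
  # same linear map on every trial of the session
  for (k in 2:3) {
    xc <- bench$trials[[k_center[k]]]$recording$signal
    xl <- bench$trials[[k_left[k]]]$recording$signal
    expect_equal(xl, g_hat * xc, tolerance = 1e-9)
  }
})
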