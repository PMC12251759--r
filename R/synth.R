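#' Synthetic surface-EMG generator configuration
#'
#' The generator emulates the statistical structure a myoelectric
#' classification pipeline assumes: per-channel amplitude envelopes that depend
#' on the active motion class (rest / elbow flexion / elbow extension),
#' band-limited stochastic carriers (surface EMG is well modelled as amplitude-
#' modulated coloured noise), additive measurement noise, and ground-truth
#' motion labels on a 20 Hz grid. Electrode shift is modelled separately by
#' [shift_model()] as a per-channel gain perturbation with optional
#' neighbour-channel crosstalk.
#'
#' @param n_channels Number of EMG channels (default 12, a typical multi-site
#'   upper-arm montage).
#' @param fs_raw Raw sampling rate in Hz (default 2000). Must exceed twice the
#'   400 Hz upper design margin of the carrier band.
#' @param trial_duration Trial length in seconds (default 60).
#' @param n_trials_per_position Trials generated per electrode position
#'   (default 20).
#' @param class_dwell_range Lower/upper bounds (seconds) of the uniform dwell
#'   time each motion class holds before the schedule moves on (default
#'   `c(0.5, 3)`).
#' @param activation_matrix `n_channels x 3` nonnegative gain matrix (columns:
#'   rest, flexion, extension). The default places two overlapping Gaussian
#'   spatial profiles over the channel array: flexion loads the first half of
#'   the channels (flexor-side sites), extension the second half.
#' @param baseline_activation Nonnegative resting envelope level common to all
#'   channels (default 0.1).
#' @param envelope_smoothing Moving-average length in seconds applied to the
#'   class-dependent envelope so activation rises and falls over a
#'   physiological timescale (default 0.1 s).
#' @param measurement_noise_sd Standard deviation of additive white measurement
#'   noise, in the same amplitude units as the signal (default 0.05).
#' @param seed Base integer seed; all generator output is a pure function of
#'   the configuration and this seed.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_channels = 12, fs_raw = 2000, trial_duration = 60,
                         n_trials_per_position = 20,
                         class_dwell_range = c(0.5, 3),
                         activation_matrix = NULL,
                         baseline_activation = 0.1,
                         envelope_smoothing = 0.1,
                         measurement_noise_sd = 0.05,
                         seed = 1L) {
  check_scalar_num(n_channels, "n_channels", min = 1)
  check_scalar_num(fs_raw, "fs_raw", min = 800 + 1e-9)
  if (fs_raw <= 2 * 400)
    stop("`fs_raw` must exceed twice the 400 Hz design margin", call. = FALSE)
  check_scalar_num(trial_duration, "trial_duration", min = 1e-9)
  check_scalar_num(n_trials_per_position, "n_trials_per_position", min = 1)
  if (!is.numeric(class_dwell_range) || length(class_dwell_range) != 2L ||
      any(class_dwell_range <= 0) || class_dwell_range[1L] > class_dwell_range[2L])
    stop("`class_dwell_range` bounds must be positive and ordered", call. = FALSE)
  if (is.null(activation_matrix)) {
    ch <- seq_len(n_channels)
    flex <- 3 * exp(-((ch - 0.3 * n_channels) / (0.22 * n_channels))^2)
    ext <- 3 * exp(-((ch - 0.8 * n_channels) / (0.22 * n_channels))^2)
    activation_matrix <- cbind(rest = rep(0, n_channels), flexion = flex,
                               extension = ext)
  }
  activation_matrix <- as.matrix(activation_matrix)
  if (nrow(activation_matrix) != n_channels || ncol(activation_matrix) != 3L ||
      any(activation_matrix < 0))
    stop("`activation_matrix` must be n_channels x 3 and nonnegative", call. = FALSE)
  check_scalar_num(baseline_activation, "baseline_activation", min = 0)
  check_scalar_num(envelope_smoothing, "envelope_smoothing", min = 0)
  check_scalar_num(measurement_noise_sd, "measurement_noise_sd", min = 0)
  structure(list(n_channels = as.integer(n_channels), fs_raw = fs_raw,
                 trial_duration = trial_duration,
                 n_trials_per_position = as.integer(n_trials_per_position),
                 class_dwell_range = class_dwell_range,
                 activation_matrix = activation_matrix,
                 baseline_activation = baseline_activation,
                 envelope_smoothing = envelope_smoothing,
                 measurement_noise_sd = measurement_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Electrode-shift model
#'
#' A shift of the electrode array by a few centimetres acts primarily as an
#' amplitude change of the recorded EMG, so the shift is modelled as a static
#' per-channel gain drawn log-normally (median gain 1) plus optional
#' neighbour-channel crosstalk: each output channel mixes its own (gain-scaled)
#' signal with its index neighbours. Mixing weights per output channel sum
#' to 1. No spectral change is modelled.
#'
#' @param position_tag One of `"left"`, `"center"`, `"right"`.
#' @param gain_log_sd Standard deviation of the log-gain (dimensionless);
#'   0 means unit gains.
#' @param crosstalk_alpha Neighbour-leakage fraction in `[0, 0.5]`. An interior
#'   channel receives `1 - alpha` of itself and `alpha / 2` from each
#'   neighbour; an edge channel receives `alpha` from its single neighbour.
#' @param seed Integer seed; gains are drawn per (position_tag, channel) so a
#'   given position has a fixed perturbation across trials, like a static
#'   electrode placement.
#' @return A list of class `"shift_model"`.
#' @export
shift_model <- function(position_tag, gain_log_sd = 0.3, crosstalk_alpha = 0,
                        seed = 1L) {
  position_tag <- match.arg(position_tag, c("left", "center", "right"))
  check_scalar_num(gain_log_sd, "gain_log_sd", min = 0)
  if (!is.numeric(crosstalk_alpha) || length(crosstalk_alpha) != 1L ||
      crosstalk_alpha < 0 || crosstalk_alpha > 0.5)
    stop("`crosstalk_alpha` must lie in [0, 0.5]", call. = FALSE)
  structure(list(position_tag = position_tag, gain_log_sd = gain_log_sd,
                 crosstalk_alpha = crosstalk_alpha, seed = as.integer(seed)),
            class = "shift_model")
}

#' Construct an EMG recording object
#'
#' @param signal Numeric matrix, channels x samples, finite.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param position_tag Electrode-position tag.
#' @param trial_id,subject_id Identifiers.
#' @return A list of class `"emg_recording"`.
#' @export
emg_recording <- function(signal, fs, channel_names = NULL,
                          position_tag = "center", trial_id = "trial1",
                          subject_id = "subject1") {
  signal <- as.matrix(signal)
  if (any(!is.finite(signal))) stop("`signal` must be finite", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signal)))
  stopifnot(length(channel_names) == nrow(signal))
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 position_tag = position_tag, trial_id = trial_id,
                 subject_id = subject_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s / %s [%s]: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$position_tag, nrow(x$signal),
              ncol(x$signal), x$fs))
  invisible(x)
}

#' Construct a motion-label object
#'
#' @param labels Integer vector with values 0 (rest), 1 (flexion),
#'   2 (extension).
#' @param fs_labels Label frame rate in Hz (default 20).
#' @return A list of class `"motion_labels"`.
#' @export
motion_labels <- function(labels, fs_labels = 20) {
  labels <- as.integer(labels)
  if (any(!labels %in% 0:2)) stop("labels must be in {0, 1, 2}", call. = FALSE)
  structure(list(labels = labels, fs_labels = fs_labels), class = "motion_labels")
}

# Piecewise-constant class schedule. Classes cycle in a freshly shuffled order
# each cycle; dwell times are uniform in `dwell_range`. Resampled until every
# class occupies at least `min_share` of the 20 Hz label frames.
make_class_schedule <- function(duration, dwell_range, min_share = 0.10,
                                fs_labels = 20, max_tries = 200) {
  n_lab <- round(duration * fs_labels)
  for (try in seq_len(max_tries)) {
    t_edges <- numeric(0)
    cls <- integer(0)
    t_cur <- 0
    while (t_cur < duration) {
      for (k in sample(0:2)) {
        d <- stats::runif(1, dwell_range[1L], dwell_range[2L])
        t_edges <- c(t_edges, t_cur)
        cls <- c(cls, k)
        t_cur <- t_cur + d
        if (t_cur >= duration) break
      }
    }
    class_at <- function(tt) cls[findInterval(tt, t_edges)]
    lab <- class_at((seq_len(n_lab)) / fs_labels - 0.5 / fs_labels)
    if (all(tabulate(lab + 1L, 3L) >= min_share * n_lab))
      return(list(edges = t_edges, classes = cls))
  }
  stop("could not draw a class schedule with all classes >= ",
       min_share * 100, "% of frames; widen `class_dwell_range` or lengthen the trial",
       call. = FALSE)
}

# zero-mean, unit-variance noise band-limited to `band` Hz
bandlimited_carrier <- function(n, fs, band = c(40, 200)) {
  x <- stats::rnorm(n + 1000)            # head room for the filter transient
  y <- sosfilt(butter_sos(3, band, fs, "pass"), x)
  y <- y[-seq_len(1000)]
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

#' Generate one synthetic EMG trial at the center electrode position
#'
#' Each channel is an amplitude-modulated band-limited (40--200 Hz) unit-
#' variance carrier plus white measurement noise:
#' `signal_c(t) = e_c(t) * carrier_c(t) + noise`, where the envelope
#' `e_c(t) = baseline + activation_matrix[c, class(t)]` is smoothed with a
#' moving average of `envelope_smoothing` seconds. The class schedule is
#' piecewise constant with uniform dwell times, cycling through the three
#' classes in random order; every class is guaranteed at least 10% of the
#' label frames. Output is bit-identical for identical configuration and seed.
#'
#' @param config A [synth_config()].
#' @param trial_id,subject_id Identifiers stored in the recording.
#' @param seed Seed for this trial (defaults to `config$seed`).
#' @param schedule Optional fixed schedule, a list with `edges` (start times in
#'   seconds) and `classes` (values 0/1/2), bypassing the random schedule.
#' @return `list(recording = emg_recording at the center position,
#'   labels = motion_labels at 20 Hz)`.
#' @export
generate_trial <- function(config, trial_id = "trial1", subject_id = "subject1",
                           seed = config$seed, schedule = NULL) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_raw
  n <- round(config$trial_duration * fs)
  n_lab <- round(config$trial_duration * 20)
  C <- config$n_channels
  with_rng_seed(seed, {
    if (is.null(schedule))
      schedule <- make_class_schedule(config$trial_duration,
                                      config$class_dwell_range)
    t_samp <- (seq_len(n) - 0.5) / fs
    cls_samp <- schedule$classes[findInterval(t_samp, schedule$edges)]
    sig <- matrix(0, C, n)
    k_sm <- max(1L, round(config$envelope_smoothing * fs))
    for (c in seq_len(C)) {
      env <- config$baseline_activation +
        config$activation_matrix[c, cls_samp + 1L]
      if (k_sm > 1L) {
        env_pad <- c(rep(env[1L], k_sm - 1L), env)
        env <- as.numeric(stats::filter(env_pad, rep(1 / k_sm, k_sm),
                                        sides = 1))[k_sm:(n + k_sm - 1L)]
      }
      carrier <- bandlimited_carrier(n, fs)
      noise <- if (config$measurement_noise_sd > 0)
        stats::rnorm(n, 0, config$measurement_noise_sd) else 0
      sig[c, ] <- env * carrier + noise
    }
    t_lab <- (seq_len(n_lab)) / 20 - 0.5 / 20
    lab <- schedule$classes[findInterval(t_lab, schedule$edges)]
    list(recording = emg_recording(sig, fs, position_tag = "center",
                                   trial_id = trial_id, subject_id = subject_id),
         labels = motion_labels(lab))
  })
}

# Crosstalk mixing matrix: rows are output channels; weights sum to 1.
crosstalk_matrix <- function(n_channels, alpha) {
  M <- diag(1 - alpha, n_channels)
  if (n_channels == 1L) return(diag(1, 1L))
  for (c in seq_len(n_channels)) {
    nb <- c(c - 1L, c + 1L)
    nb <- nb[nb >= 1L & nb <= n_channels]
    M[c, nb] <- alpha / length(nb)
  }
  M
}

# gains drawn per (position_tag, channel); fixed across trials of a session
shift_gains <- function(shift, n_channels) {
  tag_off <- match(shift$position_tag, c("left", "center", "right"))
  with_rng_seed(derive_seed(shift$seed, "shift", tag_off),
                exp(stats::rnorm(n_channels, 0, shift$gain_log_sd)))
}

#' Apply an electrode-shift perturbation to a recording
#'
#' Computes `signal' = M %*% diag(g) %*% signal`, with `g` the per-channel
#' log-normal gains of the shift model and `M` its crosstalk mixing matrix
#' (see [shift_model()]). The operation is linear in the signal and
#' deterministic per seed; the recording's position tag is updated.
#'
#' @param rec An [emg_recording()].
#' @param shift A [shift_model()].
#' @param gains Optional explicit per-channel gain vector overriding the drawn
#'   log-normal gains (useful for controlled perturbation studies).
#' @return The perturbed [emg_recording()].
#' @export
apply_electrode_shift <- function(rec, shift, gains = NULL) {
  stopifnot(inherits(rec, "emg_recording"), inherits(shift, "shift_model"))
  C <- nrow(rec$signal)
  if (is.null(gains)) gains <- shift_gains(shift, C)
  stopifnot(length(gains) == C, all(gains > 0))
  M <- crosstalk_matrix(C, shift$crosstalk_alpha)
  rec$signal <- M %*% (gains * rec$signal)
  rec$position_tag <- shift$position_tag
  rec
}

#' Generate a three-position electrode-shift benchmark
#'
#' For each synthetic subject, generates `n_trials_per_position` center-position
#' trials and derives the left/right-position versions of the *same* trials via
#' [apply_electrode_shift()] (identity for the center tag), isolating the shift
#' effect from trial-to-trial variability. Shift gains vary across subjects
#' (each subject has their own electrode placement) but are fixed across a
#' subject's trials at a given position.
#'
#' @param config A [synth_config()].
#' @param shifts List of three [shift_model()]s whose position tags are
#'   exactly `left`, `center`, `right` (any order). The center model follows
#'   the identity path.
#' @param n_subjects Number of synthetic subjects.
#' @return `list(trials, manifest)`: `trials` is a named list of
#'   `list(recording, labels)` keyed by trial key; `manifest` is a tibble with
#'   one row per trial (subject_id, trial_id, position, seed, fs, duration,
#'   key).
#' @export
generate_benchmark <- function(config, shifts, n_subjects = 1) {
  stopifnot(inherits(config, "synth_config"))
  tags <- vapply(shifts, function(s) s$position_tag, character(1))
  if (anyDuplicated(tags) || !setequal(tags, c("left", "center", "right")))
    stop("`shifts` must carry the three distinct position tags left/center/right",
         call. = FALSE)
  names(shifts) <- tags
  trials <- list()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subject_id <- sprintf("sub%02d", s)
    for (k in seq_len(config$n_trials_per_position)) {
      trial_id <- sprintf("trial%02d", k)
      tr_seed <- derive_seed(config$seed, subject_id, trial_id)
      center <- generate_trial(config, trial_id, subject_id, seed = tr_seed)
      for (pos in c("center", "left", "right")) {
        rec <- if (pos == "center") center$recording else {
          sh <- shifts[[pos]]
          sh$seed <- derive_seed(sh$seed, subject_id)
          apply_electrode_shift(center$recording, sh)
        }
        key <- paste(subject_id, pos, trial_id, sep = "_")
        trials[[key]] <- list(recording = rec, labels = center$labels)
        rows[[key]] <- tibble::tibble(subject_id = subject_id,
                                      trial_id = trial_id, position = pos,
                                      seed = tr_seed, fs = config$fs_raw,
                                      duration = config$trial_duration,
                                      key = key)
      }
    }
  }
  list(trials = trials, manifest = dplyr::bind_rows(rows))
}
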