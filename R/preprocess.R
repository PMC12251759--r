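#' Preprocessing configuration
#'
#' Parameters of the causal processing chain from raw EMG to classifier input
#' frames: band-pass filtering, decimation, (optional) sliding-window
#' normalization, rectification and windowed frame assembly.
#'
#' @param band Pass band in Hz (default `c(40, 200)`), the informative surface-
#'   EMG band.
#' @param filter_order Order of the band-pass Butterworth transfer function
#'   (default 6; must be even — the band-pass is designed from an order
#'   `filter_order/2` low-pass prototype).
#' @param fs_raw Raw sampling rate in Hz (default 2000).
#' @param fs_proc Processing rate after decimation in Hz (default 500);
#'   `fs_raw` must be an integer multiple.
#' @param segment_len Sub-window segment length in ms (default 100).
#' @param segment_overlap Segment overlap in ms (default 50).
#' @param frame_rate Prediction frame rate in Hz (default 20, one frame per
#'   50 ms hop).
#' @param feature_window Feature-extraction window in ms (200--1000 typical);
#'   it is cut into `S = (feature_window - segment_len) /
#'   (segment_len - segment_overlap) + 1` segments which are stacked along the
#'   channel axis, so the classifier input keeps a constant temporal length
#'   while its channel count grows with the window.
#' @return A list of class `"preproc_config"` with derived sample counts.
#' @export
preproc_config <- function(band = c(40, 200), filter_order = 6, fs_raw = 2000,
                           fs_proc = 500, segment_len = 100,
                           segment_overlap = 50, frame_rate = 20,
                           feature_window = 1000) {
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L] ||
      band[2L] >= fs_proc / 2)
    stop("`band` must be an increasing Hz pair below the decimated Nyquist rate",
         call. = FALSE)
  if (filter_order %% 2 != 0 || filter_order < 2)
    stop("`filter_order` must be a positive even integer", call. = FALSE)
  if (fs_raw %% fs_proc != 0)
    stop("`fs_raw` must be an integer multiple of `fs_proc`", call. = FALSE)
  if (segment_overlap >= segment_len)
    stop("`segment_overlap` must be smaller than `segment_len`", call. = FALSE)
  if (feature_window < segment_len)
    stop("`feature_window` must be at least `segment_len`", call. = FALSE)
  if (fs_proc %% frame_rate != 0)
    stop("`fs_proc` must be divisible by `frame_rate`", call. = FALSE)
  hop_ms <- segment_len - segment_overlap
  if ((feature_window - segment_len) %% hop_ms != 0)
    stop("`feature_window - segment_len` must be a multiple of the segment hop",
         call. = FALSE)
  structure(list(
    band = band, filter_order = filter_order, fs_raw = fs_raw,
    fs_proc = fs_proc, segment_len = segment_len,
    segment_overlap = segment_overlap, frame_rate = frame_rate,
    feature_window = feature_window,
    seg_samples = as.integer(segment_len * fs_proc / 1000),
    seg_hop_samples = as.integer(hop_ms * fs_proc / 1000),
    frame_hop_samples = as.integer(fs_proc / frame_rate),
    window_samples = as.integer(feature_window * fs_proc / 1000),
    n_segments = as.integer((feature_window - segment_len) / hop_ms + 1)
  ), class = "preproc_config")
}

#' Number of stacked segments for a feature window
#'
#' `S = (feature_window - segment_len) / (segment_len - segment_overlap) + 1`;
#' with the 100 ms / 50 ms defaults a 1000 ms window yields 19 segments, so a
#' 12-channel recording produces `12 * 19 = 228` concatenated input channels.
#'
#' @param feature_window Feature window in ms.
#' @param segment_len Segment length in ms.
#' @param segment_overlap Segment overlap in ms.
#' @return Integer segment count.
#' @export
n_segments <- function(feature_window, segment_len = 100, segment_overlap = 50) {
  hop <- segment_len - segment_overlap
  if ((feature_window - segment_len) %% hop != 0)
    stop("`feature_window - segment_len` must be a multiple of the segment hop",
         call. = FALSE)
  as.integer((feature_window - segment_len) / hop + 1)
}

## ---- Butterworth design in second-order sections -------------------------

# Digital Butterworth in cascaded biquads. The transfer-function coefficients
# come from signal::butter; poles are recovered with polyroot and grouped into
# conjugate pairs, zeros are known analytically (band-pass: half at z = +1,
# half at z = -1; low-pass: all at z = -1). For type "pass", `n` is the
# low-pass prototype order and the transfer function has order 2n; for type
# "low", `n` is the transfer-function order and must be even so the cascade
# splits into biquads. Returns list(b = k x 3, a = k x 3).
butter_sos <- function(n, W_hz, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  if (type == "low" && n %% 2 != 0)
    stop("low-pass SOS design requires an even order", call. = FALSE)
  Wn <- W_hz / (fs / 2)
  flt <- signal::butter(n, Wn, type = type)
  b <- flt$b
  a <- flt$a
  gain <- b[1L]
  poles <- polyroot(rev(a))
  # sort by imaginary part magnitude then real part so conjugates are adjacent
  poles <- poles[order(round(Re(poles), 10), round(abs(Im(poles)), 10))]
  n_sec <- (length(a) - 1L) %/% 2L
  if (length(a) - 1L != 2L * n_sec)
    stop("internal: odd filter order in SOS conversion")
  sos_a <- matrix(0, n_sec, 3L)
  used <- rep(FALSE, length(poles))
  s <- 1L
  for (i in seq_along(poles)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) > 1e-8) {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6)[1L]
      if (is.na(j)) stop("internal: unpaired complex pole in SOS conversion")
      used[c(i, j)] <- TRUE
      sos_a[s, ] <- c(1, -2 * Re(p), Mod(p)^2)
    } else {
      j <- which(!used & abs(Im(poles)) <= 1e-8)
      j <- setdiff(j, i)[1L]
      if (is.na(j)) stop("internal: unpaired real pole in SOS conversion")
      used[c(i, j)] <- TRUE
      sos_a[s, ] <- c(1, -Re(p) - Re(poles[j]), Re(p) * Re(poles[j]))
    }
    s <- s + 1L
  }
  sos_b <- matrix(rep(if (type == "pass") c(1, 0, -1) else c(1, 2, 1),
                      each = n_sec), n_sec, 3L)
  sos_b[1L, ] <- sos_b[1L, ] * gain
  list(b = sos_b, a = sos_a)
}

# Causal (forward-only, zero initial conditions) filtering through cascaded
# second-order sections.
sosfilt <- function(sos, x) {
  for (s in seq_len(nrow(sos$b)))
    x <- as.numeric(signal::filter(sos$b[s, ], sos$a[s, ], x))
  x
}

#' Band-pass filter and decimate a recording
#'
#' Applies a causal `filter_order`-th order Butterworth band-pass per channel
#' in second-order sections, then an explicit causal anti-alias low-pass
#' (6th-order Butterworth with cutoff midway between the band edge and the new
#' Nyquist frequency) and downsamples by `fs_raw / fs_proc`. The whole chain is
#' linear and forward-only, preserving the real-time character of the pipeline.
#'
#' @param rec An [emg_recording()] at `config$fs_raw`.
#' @param config A [preproc_config()].
#' @return An [emg_recording()] at `config$fs_proc` with
#'   `ceiling(n_samples / q)` samples.
#' @export
bandpass_decimate <- function(rec, config) {
  stopifnot(inherits(rec, "emg_recording"), inherits(config, "preproc_config"))
  if (rec$fs != config$fs_raw)
    stop("recording sampling rate (", rec$fs, " Hz) does not match `fs_raw` (",
         config$fs_raw, " Hz)", call. = FALSE)
  q <- config$fs_raw %/% config$fs_proc
  bp <- butter_sos(config$filter_order %/% 2L, config$band, config$fs_raw,
                   "pass")
  aa_cut <- (config$band[2L] + config$fs_proc / 2) / 2
  aa <- butter_sos(6L, aa_cut, config$fs_raw, "low")
  keep <- seq(1L, ncol(rec$signal), by = q)
  out <- matrix(0, nrow(rec$signal), length(keep))
  for (c in seq_len(nrow(rec$signal))) {
    y <- sosfilt(bp, rec$signal[c, ])
    y <- sosfilt(aa, y)
    out[c, ] <- y[keep]
  }
  rec$signal <- out
  rec$fs <- config$fs_proc
  rec
}

#' Full-wave rectification
#'
#' Elementwise absolute value; `NA` warm-up samples (from the `"skip"`
#' normalization policy) pass through unchanged.
#'
#' @param x Numeric vector, matrix, or [emg_recording()].
#' @return Object of the same type with rectified signal.
#' @export
rectify <- function(x) {
  if (inherits(x, "emg_recording")) {
    x$signal <- abs(x$signal)
    return(x)
  }
  abs(x)
}

#' Assemble classifier input frames from a processed signal
#'
#' For each prediction time on the `frame_rate` grid (hop 50 ms at the
#' defaults), takes the trailing `feature_window` ms, cuts it into segments of
#' `segment_len` ms with `segment_len - segment_overlap` ms hop, and stacks
#' the segments along the channel axis — segment-major, oldest segment first;
#' within a segment the original channel order. Every frame therefore has a
#' constant temporal length of `segment_len * fs_proc / 1000` samples (50 at
#' the defaults) and `n_channels * S` stacked channels. The first frame is
#' emitted once a full feature window of valid (non-`NA`) signal is available;
#' each frame is labelled by the motion label at its end time, so prediction
#' stays causal.
#'
#' @param signal Numeric matrix channels x samples at `fs_proc` (already
#'   normalized or not, and rectified). Leading `NA` columns (normalization
#'   warm-up) delay the first frame.
#' @param labels A [motion_labels()] object aligned to the same trial.
#' @param config A [preproc_config()].
#' @return A list of class `"dnn_input_sequence"`: `frames` (array
#'   `(n_channels * S) x T_seg x F`), `frame_times` (seconds, end times on the
#'   20 Hz grid), `labels` (integer vector length `F`), plus bookkeeping
#'   fields. If the valid signal is shorter than the feature window, an empty
#'   sequence is returned with a warning.
#' @export
assemble_frames <- function(signal, labels, config) {
  stopifnot(inherits(config, "preproc_config"), inherits(labels, "motion_labels"))
  signal <- as.matrix(signal)
  C <- nrow(signal)
  N <- ncol(signal)
  W <- config$window_samples
  hop <- config$frame_hop_samples
  seg <- config$seg_samples
  seg_hop <- config$seg_hop_samples
  S <- config$n_segments
  na_cols <- colSums(is.na(signal)) > 0L
  if (any(na_cols) && !identical(which(na_cols), seq_len(sum(na_cols))))
    stop("`NA` samples are only allowed as a leading warm-up block", call. = FALSE)
  valid_from <- sum(na_cols) + 1L
  first_end <- as.integer(ceiling((W + valid_from - 1L) / hop) * hop)
  ends <- if (first_end > N) integer(0) else seq.int(first_end, N, by = hop)
  empty <- function() {
    warning("signal shorter than the feature window; empty frame sequence",
            call. = FALSE)
    structure(list(frames = array(0, c(C * S, seg, 0L)),
                   frame_times = numeric(0), labels = integer(0),
                   n_channels = C, n_segments = S,
                   feature_window = config$feature_window,
                   fs_proc = config$fs_proc, frame_rate = config$frame_rate),
              class = "dnn_input_sequence")
  }
  if (length(ends) == 0L) return(empty())
  lab_rate_ratio <- as.integer(config$fs_proc / labels$fs_labels)
  lab_idx <- ends %/% lab_rate_ratio
  if (max(lab_idx) > length(labels$labels))
    stop("labels shorter than the signal implies", call. = FALSE)
  F_n <- length(ends)
  frames <- array(0, c(C * S, seg, F_n))
  starts <- ends - W + 1L
  for (s in seq_len(S)) {
    seg_start <- starts + (s - 1L) * seg_hop
    idx <- as.vector(outer(0:(seg - 1L), seg_start, "+"))   # seg x F
    block <- array(signal[, idx], c(C, seg, F_n))
    frames[((s - 1L) * C + 1L):(s * C), , ] <- block
  }
  structure(list(frames = frames, frame_times = ends / config$fs_proc,
                 labels = as.integer(labels$labels[lab_idx]),
                 n_channels = C, n_segments = S,
                 feature_window = config$feature_window,
                 fs_proc = config$fs_proc, frame_rate = config$frame_rate),
            class = "dnn_input_sequence")
}

#' Run the full causal preprocessing chain on one trial
#'
#' Band-pass filter and decimate, optionally apply sliding-window
#' normalization, rectify, and assemble frames. This is the Fig.-2-style chain
#' the classifier consumes; normalization sits between decimation and
#' rectification.
#'
#' @param rec Raw [emg_recording()].
#' @param labels [motion_labels()] for the trial.
#' @param config [preproc_config()].
#' @param swn `NULL` for no normalization, or an [swn_config()] (its `fs` must
#'   equal `config$fs_proc`).
#' @return A `"dnn_input_sequence"`; see [assemble_frames()].
#' @export
preprocess_trial <- function(rec, labels, config, swn = NULL) {
  dec <- bandpass_decimate(rec, config)
  x <- dec$signal
  if (!is.null(swn)) {
    stopifnot(inherits(swn, "swn_config"))
    if (swn$fs != config$fs_proc)
      stop("`swn$fs` must equal `config$fs_proc`", call. = FALSE)
    x <- normalize_stream(x, swn)
    attr(x, "swn_state") <- NULL
  }
  assemble_frames(rectify(x), labels, config)
}
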