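#' Sliding-window normalization (SWN) configuration
#'
#' SWN is a causal z-score normalization: at each sample time `t` the trailing
#' window of `window_ms` milliseconds is standardized by its own mean and
#' population standard deviation. Because a z-score is invariant to per-channel
#' gain and offset, SWN aligns EMG amplitudes across channels and recording
#' sessions in real time, which is the mechanism by which it confers robustness
#' to electrode shift (a shift of a few centimetres acts mostly as a
#' per-channel amplitude change).
#'
#' @param window_ms Window length in milliseconds. The study sweeps
#'   200--1000 ms in 200 ms steps; any positive length is accepted.
#' @param fs Sampling rate in Hz of the signal being normalized (after
#'   decimation this is typically 500 Hz).
#' @param eps Variance floor in amplitude units. If the window standard
#'   deviation is at or below `eps` the output for that sample is 0, so flat
#'   segments produce bounded output.
#' @param warmup_policy `"skip"` (default): no output until a full window is
#'   available; the first `L_norm - 1` outputs are `NA` and downstream frame
#'   assembly starts after warm-up. `"grow"`: statistics are computed over the
#'   partial trailing window as soon as 2 samples are available.
#' @return A list of class `"swn_config"` with the fields above plus `l_norm`,
#'   the window length in samples.
#' @examples
#' cfg <- swn_config(window_ms = 600, fs = 500)
#' cfg$l_norm  # 300 samples
#' @export
swn_config <- function(window_ms = 600, fs = 500, eps = 1e-8,
                       warmup_policy = c("skip", "grow")) {
  warmup_policy <- match.arg(warmup_policy)
  if (!is.numeric(window_ms) || length(window_ms) != 1L || window_ms <= 0)
    stop("`window_ms` must be a single positive number", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  l_norm <- window_ms * fs / 1000
  if (abs(l_norm - round(l_norm)) > 1e-9 || round(l_norm) < 2)
    stop("`window_ms * fs / 1000` must be an integer number of samples >= 2 (got ",
         l_norm, ")", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  structure(list(window_ms = window_ms, fs = fs, eps = eps,
                 warmup_policy = warmup_policy, l_norm = as.integer(round(l_norm))),
            class = "swn_config")
}

#' Z-score normalize a single full window
#'
#' Standardizes one window of samples by its mean and population (divide-by-N)
#' standard deviation. If the standard deviation is at or below `eps`, the
#' output is all zeros (degenerate-variance rule).
#'
#' @param x Numeric vector, one full window of samples.
#' @param eps Variance floor; see [swn_config()].
#' @return Numeric vector of the same length: `(x - mean(x)) / max(sd_pop, eps)`.
#' @examples
#' normalize_window(c(1, 2, 3))  # -1.2247, 0, 1.2247
#' @export
normalize_window <- function(x, eps = 1e-8) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite value in window at index ", which(!is.finite(x))[1L], call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s <= eps) return(rep(0, length(x)))
  (x - m) / s
}

## rolling trailing-window mean / population sd via cumulative sums.
## x is centered by its global mean first so the cumulative sums stay small and
## the sum-of-squares cancellation error is far below the 1e-9 contract.
rolling_zscore <- function(x, l_norm, eps, warmup_policy) {
  n <- length(x)
  out <- rep(NA_real_, n)
  mu <- mean(x)
  xc <- x - mu
  cs <- cumsum(xc)
  css <- cumsum(xc * xc)
  if (n >= l_norm) {
    t_idx <- l_norm:n
    s1 <- cs[t_idx] - c(0, cs)[t_idx - l_norm + 1L]
    s2 <- css[t_idx] - c(0, css)[t_idx - l_norm + 1L]
    m <- s1 / l_norm
    v <- pmax(s2 / l_norm - m * m, 0)
    # variances at the cancellation noise floor of the cumulative sums are
    # numerically indistinguishable from zero (flat windows must map to 0)
    v[v < 1e-14 * css[t_idx] / l_norm] <- 0
    s <- sqrt(v)
    y <- (xc[t_idx] - m) / pmax(s, eps)
    y[s <= eps] <- 0
    out[t_idx] <- y
  }
  if (warmup_policy == "grow" && n >= 2L) {
    t_idx <- 2:min(l_norm - 1L, n)
    if (length(t_idx) > 0L && t_idx[1L] <= t_idx[length(t_idx)]) {
      m <- cs[t_idx] / t_idx
      v <- pmax(css[t_idx] / t_idx - m * m, 0)
      v[v < 1e-14 * css[t_idx] / t_idx] <- 0  # cancellation noise floor
      s <- sqrt(v)
      y <- (xc[t_idx] - m) / pmax(s, eps)
      y[s <= eps] <- 0
      out[t_idx] <- y
    }
  }
  out
}

#' Apply sliding-window normalization to a multichannel signal
#'
#' Causal batch form of SWN. For every sample time `t` with a full trailing
#' window (or a partial one of at least 2 samples under the `"grow"` policy),
#' the newest sample is replaced by its z-score within the trailing window:
#' `y_t = (x_t - m_t) / max(s_t, eps)`, with `m_t` and `s_t` the mean and
#' population standard deviation over the window. Each channel is normalized
#' independently. Output at `t` depends only on samples at or before `t`.
#'
#' Warm-up samples (before the policy allows output) are returned as `NA` so
#' that downstream frame assembly can skip them while sample indices stay
#' aligned with the input.
#'
#' @param signal Numeric matrix, channels x samples (a single channel may be
#'   given as a vector).
#' @param config An [swn_config()].
#' @return A matrix of the same shape with attribute `"swn_state"`, an
#'   [swn_state_new()] object holding the trailing window so streaming can be
#'   resumed with [swn_state_update()].
#' @seealso [swn_state_update()] for the sample-by-sample streaming form.
#' @export
normalize_stream <- function(signal, config) {
  stopifnot(inherits(config, "swn_config"))
  vec_in <- is.null(dim(signal))
  if (vec_in) signal <- matrix(signal, nrow = 1L)
  if (!is.numeric(signal)) stop("`signal` must be numeric", call. = FALSE)
  bad <- which(!is.finite(signal), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite sample in channel ", bad[1L, 1L], " at index ", bad[1L, 2L],
         call. = FALSE)
  n <- ncol(signal)
  if (n < 1L) stop("`signal` must contain at least one sample", call. = FALSE)
  out <- matrix(NA_real_, nrow(signal), n)
  for (c in seq_len(nrow(signal)))
    out[c, ] <- rolling_zscore(signal[c, ], config$l_norm, config$eps,
                               config$warmup_policy)
  state <- swn_state_new(nrow(signal), config)
  tail_idx <- max(1L, n - config$l_norm + 1L):n
  state$buffer[seq_along(tail_idx), ] <- t(signal[, tail_idx, drop = FALSE])
  state$filled <- length(tail_idx)
  state$head <- length(tail_idx) %% config$l_norm
  state$samples_seen <- n
  state$sum <- rowSums(signal[, tail_idx, drop = FALSE])
  state$sumsq <- rowSums(signal[, tail_idx, drop = FALSE]^2)
  if (vec_in) {
    res <- out[1L, ]
    attr(res, "swn_state") <- state
    res
  } else {
    attr(out, "swn_state") <- state
    out
  }
}

#' Create a streaming SWN state
#'
#' Holds, per channel, a ring buffer of the last `L_norm` samples together with
#' running sums and sums of squares. The running statistics are refreshed from
#' the buffer once per buffer turn so floating-point drift cannot accumulate.
#'
#' @param n_channels Number of channels the stream will carry.
#' @param config An [swn_config()].
#' @return A list of class `"swn_state"`.
#' @export
swn_state_new <- function(n_channels, config) {
  stopifnot(inherits(config, "swn_config"), n_channels >= 1L)
  structure(list(
    config = config,
    buffer = matrix(NA_real_, config$l_norm, n_channels),  # rows: slots, cols: channels
    head = 0L,          # next write slot (0-based)
    filled = 0L,
    samples_seen = 0L,
    sum = rep(0, n_channels),
    sumsq = rep(0, n_channels)
  ), class = "swn_state")
}

#' Advance a streaming SWN state by one sample
#'
#' Sample-by-sample counterpart of [normalize_stream()]: pushes one multichannel
#' sample and returns its normalized value (or `NA` during warm-up under the
#' `"skip"` policy). Equality with the batch form is part of the test suite.
#'
#' @param state An [swn_state_new()] object.
#' @param x_new Numeric vector, one sample per channel.
#' @return `list(state = updated state, y = normalized sample)`.
#' @export
swn_state_update <- function(state, x_new) {
  stopifnot(inherits(state, "swn_state"))
  cfg <- state$config
  nc <- ncol(state$buffer)
  if (length(x_new) != nc)
    stop("`x_new` must have one value per channel (", nc, ")", call. = FALSE)
  if (any(!is.finite(x_new)))
    stop("non-finite sample in channel ", which(!is.finite(x_new))[1L],
         " at index ", state$samples_seen + 1L, call. = FALSE)
  L <- cfg$l_norm
  slot <- state$head + 1L
  if (state$filled == L) {
    old <- state$buffer[slot, ]
    state$sum <- state$sum - old + x_new
    state$sumsq <- state$sumsq - old^2 + x_new^2
  } else {
    state$sum <- state$sum + x_new
    state$sumsq <- state$sumsq + x_new^2
    state$filled <- state$filled + 1L
  }
  state$buffer[slot, ] <- x_new
  state$head <- slot %% L
  state$samples_seen <- state$samples_seen + 1L
  # periodic exact refresh guards against sum-of-squares cancellation drift
  if (state$head == 0L && state$filled == L) {
    state$sum <- colSums(state$buffer)
    state$sumsq <- colSums(state$buffer^2)
  }
  n_win <- state$filled
  y <- rep(NA_real_, nc)
  emit <- (n_win == L) || (cfg$warmup_policy == "grow" && n_win >= 2L)
  if (emit) {
    m <- state$sum / n_win
    v <- pmax(state$sumsq / n_win - m^2, 0)
    v[v < 1e-14 * state$sumsq / n_win] <- 0   # cancellation noise floor
    s <- sqrt(v)
    y <- (x_new - m) / pmax(s, cfg$eps)
    y[s <= cfg$eps] <- 0
  }
  list(state = state, y = y)
}
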