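#' Joint kinematics container
#'
#' Elbow-joint angle trace at the label frame rate, with angular velocity and
#' acceleration derived by central differences (one-sided at the edges).
#'
#' @param elbow_angle Numeric vector of joint angles in degrees.
#' @param fs Sampling rate in Hz (default 20).
#' @return A list of class `"joint_kinematics"` with `angle`, `velocity`
#'   (deg/s), `acceleration` (deg/s^2), `fs`.
#' @export
joint_kinematics <- function(elbow_angle, fs = 20) {
  if (!is.numeric(elbow_angle) || any(!is.finite(elbow_angle)) ||
      length(elbow_angle) < 3L)
    stop("`elbow_angle` must be a finite numeric vector of length >= 3",
         call. = FALSE)
  n <- length(elbow_angle)
  cd <- function(x) {
    d <- numeric(n)
    d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
    d[1L] <- (x[2L] - x[1L]) * fs
    d[n] <- (x[n] - x[n - 1L]) * fs
    d
  }
  vel <- cd(elbow_angle)
  acc <- cd(vel)
  structure(list(angle = elbow_angle, velocity = vel, acceleration = acc,
                 fs = fs), class = "joint_kinematics")
}

#' Derive motion labels from joint kinematics (threshold-rule stand-in)
#'
#' A documented stand-in labelling rule for users importing real kinematic
#' data: flexion when angular velocity exceeds `+vel_threshold`, extension
#' below `-vel_threshold`, rest otherwise, with a hysteresis band — once a
#' movement class is active it is retained until the speed falls below
#' `vel_threshold - hysteresis`, which prevents label chatter around the
#' threshold. The original labelling procedure of the motion-capture protocol
#' this emulates is not public; synthetic data bypasses this module entirely
#' because the generator carries ground-truth labels. Negating the angle
#' trace swaps flexion and extension labels exactly.
#'
#' @param kin A [joint_kinematics()] object.
#' @param vel_threshold Velocity threshold in deg/s (> `hysteresis`).
#' @param hysteresis Hysteresis band width in deg/s (>= 0).
#' @return A [motion_labels()] object at `kin$fs`.
#' @export
derive_labels <- function(kin, vel_threshold = 10, hysteresis = 2) {
  stopifnot(inherits(kin, "joint_kinematics"))
  if (!(vel_threshold > hysteresis) || hysteresis < 0)
    stop("need `vel_threshold` > `hysteresis` >= 0", call. = FALSE)
  v <- kin$velocity
  lab <- integer(length(v))
  state <- 0L
  for (i in seq_along(v)) {
    if (v[i] > vel_threshold) state <- 1L
    else if (v[i] < -vel_threshold) state <- 2L
    else if (state == 1L && v[i] < vel_threshold - hysteresis) state <- 0L
    else if (state == 2L && v[i] > -(vel_threshold - hysteresis)) state <- 0L
    lab[i] <- state
  }
  motion_labels(lab, fs_labels = kin$fs)
}
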