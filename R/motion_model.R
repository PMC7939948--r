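# Pose/trajectory containers and the synthetic squat-motion generator that
# stands in for an AR-headset tracker. Coordinates are metric and y-up: the
# floor is the plane y = 0 and head height is the y coordinate.

#' Construct a head-pose trajectory
#'
#' A trajectory is an ordered stream of time-stamped 6-DOF head poses:
#' position in meters (y is the vertical axis, floor at 0) and orientation as
#' a unit quaternion `(qw, qx, qy, qz)`.
#'
#' @param samples data.frame with columns `t, x, y, z, qw, qx, qy, qz`; `t` in
#'   seconds from session start, strictly increasing and non-negative.
#' @param sample_rate_hz nominal sampling rate, positive. Inter-sample spacing
#'   must stay within 10% of `1 / sample_rate_hz`.
#' @param meta free-form provenance list (seed, generator settings, ...).
#' @param check_spacing enforce the uniform-spacing invariant; readers set
#'   this to `FALSE` for streams with rejected (dropped) rows.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(samples, sample_rate_hz, meta = list(), check_spacing = TRUE) {
  cols <- c("t", "x", "y", "z", "qw", "qx", "qy", "qz")
  assert_that(is.data.frame(samples) && all(cols %in% names(samples)),
              "samples must be a data.frame with columns t,x,y,z,qw,qx,qy,qz")
  samples <- samples[, cols]
  assert_that(is.numeric(sample_rate_hz) && length(sample_rate_hz) == 1 && sample_rate_hz > 0,
              "sample_rate_hz must be a positive number")
  assert_that(nrow(samples) >= 1 && all(samples$t >= 0),
              "trajectory needs >= 1 sample with non-negative times")
  if (nrow(samples) >= 2) {
    dt <- diff(samples$t)
    assert_that(all(dt > 0), "sample times must be strictly increasing")
    if (check_spacing) {
      nominal <- 1 / sample_rate_hz
      assert_that(all(abs(dt - nominal) <= 0.1 * nominal),
                  "inter-sample spacing deviates more than 10% from 1/sample_rate_hz")
    }
  }
  qn <- sqrt(samples$qw^2 + samples$qx^2 + samples$qy^2 + samples$qz^2)
  assert_that(all(abs(qn - 1) <= 1e-6), "orientation quaternions must have unit norm")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<trajectory> %d samples @ %g Hz, %.2f s, head height %.3f-%.3f m\n",
              n, x$sample_rate_hz, if (n > 1) diff(range(x$samples$t)) else 0,
              min(x$samples$y), max(x$samples$y)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) nrow(x$samples)

#' Restrict a trajectory to a time window
#'
#' @param traj a [trajectory()].
#' @param t_min,t_max inclusive window bounds in seconds.
#' @return A `trajectory` containing the samples with `t_min <= t <= t_max`.
#' @export
subset_trajectory <- function(traj, t_min = -Inf, t_max = Inf) {
  keep <- traj$samples$t >= t_min & traj$samples$t <= t_max
  trajectory(traj$samples[keep, , drop = FALSE], traj$sample_rate_hz, traj$meta)
}

# yaw -> unit quaternion for a rotation about the vertical (y) axis
yaw_quaternion <- function(yaw) {
  c(qw = cos(yaw / 2), qx = 0, qy = sin(yaw / 2), qz = 0)
}

# rotate a 3-vector by a unit quaternion (w,x,y,z)
quat_rotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  uv <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  uuv <- c(u[2] * uv[3] - u[3] * uv[2], u[3] * uv[1] - u[1] * uv[3], u[1] * uv[2] - u[2] * uv[1])
  v + 2 * (w * uv + uuv)
}

# facing (front) and right unit vectors in the horizontal plane for a yaw.
# yaw 0 faces +z; right = up x front.
facing_frame <- function(yaw) {
  front <- c(sin(yaw), cos(yaw))   # (x, z)
  right <- c(cos(yaw), -sin(yaw))  # (x, z)
  list(front = front, right = right)
}

#' Simulation profile for the synthetic squat generator
#'
#' @param standing_height head height when standing, meters.
#' @param target_depth_fraction fraction of standing height descended at the
#'   squat bottom (bottom height = `standing_height * (1 - target_depth_fraction)`),
#'   in (0, 1).
#' @param rep_duration nominal duration of one repetition, seconds.
#' @param sway_amplitude amplitude of natural lateral sway, meters.
#' @param noise_sd standard deviation of i.i.d. Gaussian position noise per
#'   axis, meters.
#' @param seed integer seed controlling all randomness of the generator.
#' @param yaw facing direction, radians (0 faces +z).
#' @param anchor horizontal position `(x, z)` of the virtual footprints, meters.
#' @param sample_rate_hz tracking rate, Hz.
#' @return A `sim_profile` list.
#' @export
sim_profile <- function(standing_height = 1.70, target_depth_fraction = 0.30,
                        rep_duration = 3, sway_amplitude = 0.02, noise_sd = 0,
                        seed = 1L, yaw = 0, anchor = c(0, 0), sample_rate_hz = 30) {
  assert_that(standing_height > 0, "standing_height must be positive")
  assert_that(target_depth_fraction > 0 && target_depth_fraction < 1,
              "target_depth_fraction must be in (0, 1)")
  assert_that(rep_duration > 0, "rep_duration must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(sample_rate_hz > 0, "sample_rate_hz must be positive")
  structure(list(standing_height = standing_height,
                 target_depth_fraction = target_depth_fraction,
                 rep_duration = rep_duration, sway_amplitude = sway_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed), yaw = yaw,
                 anchor = anchor, sample_rate_hz = sample_rate_hz),
            class = "sim_profile")
}

#' The closed set of execution-error tags
#' @export
error_kinds <- function() {
  c("depth", "tempo_fast", "tempo_slow", "dev_left", "dev_right", "dev_front", "dev_back")
}

#' Per-repetition plan of injected execution errors
#'
#' @param tags character vector, one tag per planned repetition, each from
#'   `c(error_kinds(), "none")`.
#' @return An `error_plan` object.
#' @export
error_plan <- function(tags) {
  allowed <- c(error_kinds(), "none")
  assert_that(length(tags) >= 1 && all(tags %in% allowed),
              sprintf("error plan tags must be in {%s}", paste(allowed, collapse = ", ")))
  structure(list(tags = as.character(tags)), class = "error_plan")
}

#' Simulate a monitored squat session
#'
#' Generates the head-pose stream an AR headset would record for one exercise
#' session, together with ground-truth repetition boundaries and injected
#' error tags. The vertical coordinate follows a raised-cosine dip per
#' repetition; repetitions are contiguous within the session, preceded by a
#' still calibration stand. Injected tags are realized geometrically so the
#' monitor can (and must) recover them:
#' \describe{
#'   \item{depth}{bottom shallower than `ref_bottom + depth_tolerance` by a
#'     safety margin,}
#'   \item{tempo_fast / tempo_slow}{rep duration outside
#'     `rep_duration * (1 +/- tempo_tolerance)`,}
#'   \item{dev_*}{horizontal excursion beyond `deviation_radius` in the tagged
#'     direction of the calibrated facing frame.}
#' }
#'
#' @param profile a [sim_profile()].
#' @param prescription an [exercise_prescription()]; `sets_per_session *
#'   reps_per_set` must equal the plan length.
#' @param plan an [error_plan()]; default all `"none"`.
#' @param thresholds the [thresholds()] the downstream monitor will use;
#'   injection margins are derived from them.
#' @param calib_lead_s seconds of still standing at the head of the trajectory
#'   (used for calibration), default 2.
#' @param set_rest_s standing rest between sets, seconds (default 0; any rest
#'   accrues half to each neighboring rep's measured duration).
#' @param margin safety margin by which injected errors exceed their detection
#'   threshold (fraction for depth, relative for tempo, meters for deviation).
#' @return A list with elements `trajectory` (a [trajectory()]) and `labels`
#'   (class `rep_labels`: data.frame `start`, `end` sample indices and `tag`).
#' @examples
#' prof <- sim_profile(noise_sd = 0)
#' rx <- exercise_prescription(sets_per_session = 1, reps_per_set = 3)
#' sim <- simulate_squat_session(prof, rx)
#' min(sim$trajectory$samples$y)  # ~ 1.70 * (1 - 0.30)
#' @export
simulate_squat_session <- function(profile, prescription, plan = NULL,
                                   thresholds = default_thresholds(),
                                   calib_lead_s = 2, set_rest_s = 0,
                                   margin = 0.05) {
  n_reps <- prescription$sets_per_session * prescription$reps_per_set
  if (is.null(plan)) plan <- error_plan(rep("none", n_reps))
  assert_that(inherits(plan, "error_plan") && length(plan$tags) == n_reps,
              "plan length must equal sets_per_session * reps_per_set")

  H <- profile$standing_height
  d0 <- profile$target_depth_fraction
  # shallow depth for injected depth errors: bottom fraction sits `margin`
  # above the detection bound but must still cross the rep-entry threshold
  shallow_bottom <- (1 - d0) + thresholds$depth_tolerance + margin
  if (any(plan$tags == "depth")) {
    assert_that(shallow_bottom < 1 - thresholds$enter_fraction - 0.02,
                "depth_tolerance + margin too large: injected shallow squats would not register as reps")
  }
  durations <- vapply(plan$tags, function(tag) {
    switch(tag,
           tempo_fast = profile$rep_duration * (1 - thresholds$tempo_tolerance) * (1 - 6 * margin),
           tempo_slow = profile$rep_duration * (1 + thresholds$tempo_tolerance) * (1 + 6 * margin),
           profile$rep_duration)
  }, numeric(1))
  depths <- vapply(plan$tags, function(tag) {
    if (tag == "depth") 1 - shallow_bottom else d0
  }, numeric(1))
  dev_amp <- thresholds$deviation_radius + margin

  frame <- facing_frame(profile$yaw)
  # (x, z) unit direction of each injected deviation, in world coordinates
  dev_dir <- lapply(plan$tags, function(tag) {
    switch(tag,
           dev_left  = -frame$right,
           dev_right =  frame$right,
           dev_front =  frame$front,
           dev_back  = -frame$front,
           c(0, 0))
  })

  # timeline: calibration stand, then reps (contiguous within a set), rest
  # between sets
  rep_set <- rep(seq_len(prescription$sets_per_session), each = prescription$reps_per_set)
  starts <- numeric(n_reps)
  t_cursor <- calib_lead_s
  for (i in seq_len(n_reps)) {
    if (i > 1 && rep_set[i] != rep_set[i - 1]) t_cursor <- t_cursor + set_rest_s
    starts[i] <- t_cursor
    t_cursor <- t_cursor + durations[i]
  }
  total_t <- t_cursor + calib_lead_s
  dt <- 1 / profile$sample_rate_hz
  t <- seq(0, total_t, by = dt)

  y <- rep(H, length(t))
  xh <- rep(profile$anchor[1], length(t))
  zh <- rep(profile$anchor[2], length(t))
  for (i in seq_len(n_reps)) {
    in_rep <- t >= starts[i] & t < starts[i] + durations[i]
    u <- (t[in_rep] - starts[i]) / durations[i]
    y[in_rep] <- H - depths[i] * H * 0.5 * (1 - cos(2 * pi * u))
    bump <- dev_amp * sin(pi * u)^2
    xh[in_rep] <- xh[in_rep] + dev_dir[[i]][1] * bump
    zh[in_rep] <- zh[in_rep] + dev_dir[[i]][2] * bump
  }
  # natural lateral sway, well inside the deviation radius
  sway <- profile$sway_amplitude * sin(2 * pi * t / 5)
  xh <- xh + frame$right[1] * sway
  zh <- zh + frame$right[2] * sway

  # rnorm(sd = 0) is exactly zero, so the seed is consumed either way and
  # noise_sd = 0 stays bit-identical across calls
  noise <- withr::with_seed(profile$seed,
    matrix(stats::rnorm(3 * length(t), sd = profile$noise_sd), ncol = 3))
  xh <- xh + noise[, 1]
  y <- y + noise[, 2]
  zh <- zh + noise[, 3]

  q <- unname(yaw_quaternion(profile$yaw))
  samples <- data.frame(t = t, x = xh, y = y, z = zh,
                        qw = q[1], qx = q[2], qy = q[3], qz = q[4])
  traj <- trajectory(samples, profile$sample_rate_hz,
                     meta = list(generator = "simulate_squat_session", seed = profile$seed))

  idx_start <- vapply(starts, function(s) which.min(abs(t - s)), integer(1))
  idx_end <- vapply(starts + durations, function(s) which.min(abs(t - s)), integer(1))
  labels <- structure(
    data.frame(start = idx_start, end = idx_end, tag = plan$tags,
               stringsAsFactors = FALSE),
    class = c("rep_labels", "data.frame"))
  assert_that(all(labels$start < labels$end) && all(diff(labels$start) > 0),
              "internal: inconsistent ground-truth boundaries")
  list(trajectory = traj, labels = labels)
}

#' Extract a reference execution profile from a recorded trajectory
#'
#' Summarizes how a reference performer (typically the physiotherapist)
#' executes the exercise: the bottom-height fraction (minimum head height over
#' standing height) and the repetition duration, averaged over all detected
#' repetitions. Patient executions are compared against this profile.
#'
#' @param traj a [trajectory()] containing at least one detectable repetition.
#' @param calib the [calibrate()] profile for the performer.
#' @param thr segmentation [thresholds()].
#' @return A [reference_profile()].
#' @export
reference_profile_from_trajectory <- function(traj, calib, thr = default_thresholds()) {
  segs <- segment_reps(traj, calib, thr)
  if (nrow(segs) == 0) {
    stop_squatcoach("unusable_reference", "no detectable repetition in reference trajectory")
  }
  reference_profile(
    ref_bottom_fraction = mean(segs$bottom_height) / calib$standing_height,
    ref_rep_duration = mean(segs$duration)
  )
}
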