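# The monitoring engine: calibration from a still stand, hysteresis-based
# repetition segmentation of the vertical head coordinate, and per-repetition
# classification of execution errors against a reference profile.

#' Detection thresholds for the session monitor
#'
#' All cutoffs of the error-detection geometry in one configurable place.
#'
#' @param enter_fraction descent fraction of standing height that opens a
#'   repetition (the head must drop below
#'   `(1 - enter_fraction) * standing_height`).
#' @param exit_fraction recovery fraction that closes a repetition; must be
#'   smaller than `enter_fraction` (hysteresis prevents double counting).
#' @param depth_tolerance additive slack on the reference bottom fraction
#'   before an insufficient-depth error fires.
#' @param tempo_tolerance relative band around the reference rep duration
#'   within which tempo is compliant, in (0, 1).
#' @param deviation_radius horizontal radius (meters) around the footprint
#'   anchor within which posture is compliant.
#' @return A `thresholds` list.
#' @export
thresholds <- function(enter_fraction = 0.10, exit_fraction = 0.05,
                       depth_tolerance = 0.05, tempo_tolerance = 0.30,
                       deviation_radius = 0.15) {
  assert_that(exit_fraction > 0 && exit_fraction < enter_fraction && enter_fraction < 1,
              "need 0 < exit_fraction < enter_fraction < 1")
  assert_that(tempo_tolerance > 0 && tempo_tolerance < 1, "tempo_tolerance must be in (0, 1)")
  assert_that(deviation_radius > 0, "deviation_radius must be positive")
  assert_that(depth_tolerance >= 0, "depth_tolerance must be non-negative")
  structure(list(enter_fraction = enter_fraction, exit_fraction = exit_fraction,
                 depth_tolerance = depth_tolerance, tempo_tolerance = tempo_tolerance,
                 deviation_radius = deviation_radius),
            class = "thresholds")
}

#' @rdname thresholds
#' @export
default_thresholds <- function() thresholds()

#' Reference execution profile
#'
#' @param ref_bottom_fraction minimum head height at the squat bottom divided
#'   by standing height, in (0, 1).
#' @param ref_rep_duration reference repetition duration, seconds.
#' @return A `reference_profile` list.
#' @export
reference_profile <- function(ref_bottom_fraction, ref_rep_duration) {
  assert_that(ref_bottom_fraction > 0 && ref_bottom_fraction < 1,
              "ref_bottom_fraction must be in (0, 1)")
  assert_that(ref_rep_duration > 0, "ref_rep_duration must be positive")
  structure(list(ref_bottom_fraction = ref_bottom_fraction,
                 ref_rep_duration = ref_rep_duration),
            class = "reference_profile")
}

#' Calibrate the monitor from a still standing phase
#'
#' The participant stands still on the virtual footprints; standing height is
#' stored as the difference between the initial head position and the floor
#' along the vertical axis, the horizontal mean position anchors the footprint
#' and the mean orientation fixes the facing frame used to resolve deviation
#' directions.
#'
#' @param standing_samples a [trajectory()] covering at least 0.5 s of
#'   standing still (vertical spread below `max_spread`).
#' @param max_spread maximum tolerated vertical range during the stand, meters.
#' @return A `calibration_profile` with `initial_position`, `initial_yaw`,
#'   `standing_height` and `footprint_anchor`.
#' @export
calibrate <- function(standing_samples, max_spread = 0.05) {
  s <- standing_samples$samples
  if (nrow(s) < 2 || diff(range(s$t)) < 0.5) {
    stop_squatcoach("calibration_failure", "need at least 0.5 s of standing samples")
  }
  if (diff(range(s$y)) >= max_spread) {
    stop_squatcoach("calibration_failure",
                    sprintf("vertical spread %.3f m exceeds %.3f m: subject not standing still",
                            diff(range(s$y)), max_spread))
  }
  qm <- c(mean(s$qw), mean(s$qx), mean(s$qy), mean(s$qz))
  qm <- qm / sqrt(sum(qm^2))
  front <- quat_rotate(qm, c(0, 0, 1))
  yaw <- atan2(front[1], front[3])
  structure(list(initial_position = c(mean(s$x), mean(s$y), mean(s$z)),
                 initial_yaw = yaw,
                 standing_height = mean(s$y),
                 footprint_anchor = c(mean(s$x), mean(s$z))),
            class = "calibration_profile")
}

# centered moving average used only to stabilize threshold crossings under
# sensor noise; detection geometry is computed on raw samples
smooth_y <- function(y, rate) {
  k <- max(1L, 2L * floor(0.075 * rate) + 1L)
  if (k == 1L || length(y) < k) return(y)
  pad <- (k - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + length(y))]
}

# linear interpolation of the time at which y crosses `level` between
# samples i and i+1
cross_time <- function(t, y, i, level) {
  if (i < 1 || y[i + 1] == y[i]) return(t[max(i, 1) + 1])
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

#' Segment squat repetitions from a trajectory
#'
#' A hysteresis state machine on the vertical head coordinate: a repetition
#' opens when the (lightly smoothed) height drops below
#' `(1 - enter_fraction) * standing_height` and closes when it recovers above
#' `(1 - exit_fraction) * standing_height`. Segment boundaries are then placed
#' at the midpoint between one dip's recovery crossing and the next dip's
#' entry crossing of the outer (exit) level — exact for symmetric dips
#' performed back to back — with symmetry about the bottom supplying the
#' outermost boundaries, so that measured durations estimate the full
#' stand-to-stand repetition time.
#'
#' @param traj a [trajectory()].
#' @param calib a [calibrate()] profile.
#' @param thr segmentation [thresholds()].
#' @return A data.frame of class `rep_segments`: one row per repetition with
#'   `start`, `end` (sample indices), `bottom_height` (m), `duration` (s) and
#'   the signed horizontal extrema in the facing frame `lat_min`, `lat_max`
#'   (rightward positive), `sag_min`, `sag_max` (forward positive), meters
#'   from the footprint anchor.
#' @export
segment_reps <- function(traj, calib, thr = default_thresholds()) {
  s <- traj$samples
  empty <- data.frame(start = integer(), end = integer(), bottom_height = numeric(),
                      duration = numeric(), lat_min = numeric(), lat_max = numeric(),
                      sag_min = numeric(), sag_max = numeric())
  class(empty) <- c("rep_segments", "data.frame")
  if (nrow(s) < 2) return(empty)

  H <- calib$standing_height
  enter_level <- (1 - thr$enter_fraction) * H
  exit_level <- (1 - thr$exit_fraction) * H
  ys <- smooth_y(s$y, traj$sample_rate_hz)
  t <- s$t
  n <- length(ys)

  # state machine: collect [open, close] index pairs with hysteresis
  open_idx <- integer(0); close_idx <- integer(0)
  in_rep <- FALSE
  for (i in seq_len(n)) {
    if (!in_rep && ys[i] < enter_level) {
      open_idx <- c(open_idx, i); in_rep <- TRUE
    } else if (in_rep && ys[i] > exit_level) {
      close_idx <- c(close_idx, i); in_rep <- FALSE
    }
  }
  if (in_rep) close_idx <- c(close_idx, n)  # dip truncated by end of stream
  k <- length(open_idx)
  if (k == 0) return(empty)

  # outer-level crossing times flanking each dip
  t_down <- vapply(seq_len(k), function(j) {
    i <- open_idx[j] - 1L
    while (i >= 1 && ys[i] < exit_level) i <- i - 1L
    if (i < 1) t[1] else cross_time(t, ys, i, exit_level)
  }, numeric(1))
  t_up <- vapply(seq_len(k), function(j) {
    i <- close_idx[j]
    if (i >= n || ys[i] > exit_level) {
      if (i <= 1) t[n] else cross_time(t, ys, i - 1L, exit_level)
    } else t[n]
  }, numeric(1))
  t_bottom <- vapply(seq_len(k), function(j) {
    rng <- open_idx[j]:close_idx[j]
    t[rng[which.min(ys[rng])]]
  }, numeric(1))

  t_start <- numeric(k); t_end <- numeric(k)
  for (j in seq_len(k)) {
    if (j < k) t_end[j] <- (t_up[j] + t_down[j + 1]) / 2
    if (j > 1) t_start[j] <- t_end[j - 1]
  }
  if (k > 1) {
    t_start[1] <- max(t[1], 2 * t_bottom[1] - t_end[1])
    t_end[k] <- min(t[n], 2 * t_bottom[k] - t_start[k])
  } else {
    # isolated dip: no neighbor to exploit symmetry against; fall back to the
    # outer-threshold crossings (duration is then an underestimate)
    t_start[1] <- t_down[1]
    t_end[1] <- t_up[1]
  }

  idx_of <- function(tt) which.min(abs(t - tt))
  start <- vapply(t_start, idx_of, integer(1))
  end <- vapply(t_end, idx_of, integer(1))

  frame <- facing_frame(calib$initial_yaw)
  dx <- s$x - calib$footprint_anchor[1]
  dz <- s$z - calib$footprint_anchor[2]
  lat <- dx * frame$right[1] + dz * frame$right[2]
  sag <- dx * frame$front[1] + dz * frame$front[2]

  out <- data.frame(
    start = start, end = end,
    bottom_height = vapply(seq_len(k), function(j) min(s$y[start[j]:end[j]]), numeric(1)),
    duration = t[end] - t[start],
    lat_min = vapply(seq_len(k), function(j) min(lat[start[j]:end[j]]), numeric(1)),
    lat_max = vapply(seq_len(k), function(j) max(lat[start[j]:end[j]]), numeric(1)),
    sag_min = vapply(seq_len(k), function(j) min(sag[start[j]:end[j]]), numeric(1)),
    sag_max = vapply(seq_len(k), function(j) max(sag[start[j]:end[j]]), numeric(1))
  )
  class(out) <- c("rep_segments", "data.frame")
  out
}

#' Detect execution errors in one repetition
#'
#' Applies the error taxonomy — insufficient depth, too fast or too slow
#' execution, and excessive deviation to the left, right, front or back of the
#' participant's vertical center axis — to one segmented repetition:
#' \itemize{
#'   \item depth error iff `bottom_height / standing_height >
#'     ref_bottom_fraction + depth_tolerance`; magnitude is the fractional
#'     exceedance times standing height, meters;
#'   \item tempo_fast iff `duration < ref_rep_duration * (1 - tempo_tolerance)`,
#'     tempo_slow iff `duration > ref_rep_duration * (1 + tempo_tolerance)`;
#'     magnitude is the exceedance beyond the bound, seconds;
#'   \item at most one deviation error per repetition, fired iff any horizontal
#'     excursion from the footprint anchor exceeds `deviation_radius` and
#'     labeled by the direction of the largest exceedance in the calibrated
#'     facing frame; magnitude is the exceedance, meters.
#' }
#'
#' @param seg one row of [segment_reps()] output (or a list with the same
#'   fields).
#' @param calib the session's [calibrate()] profile.
#' @param ref the [reference_profile()] to compare against.
#' @param thr detection [thresholds()].
#' @param rep_index repetition index recorded on the emitted events.
#' @return A data.frame of class `error_events` with columns `rep_index`,
#'   `kind`, `magnitude`; zero rows for a compliant repetition.
#' @export
detect_rep_errors <- function(seg, calib, ref, thr = default_thresholds(), rep_index = 1L) {
  H <- calib$standing_height
  kinds <- character(0); mags <- numeric(0)

  bottom_fraction <- seg$bottom_height / H
  depth_bound <- ref$ref_bottom_fraction + thr$depth_tolerance
  if (bottom_fraction > depth_bound) {
    kinds <- c(kinds, "depth")
    mags <- c(mags, (bottom_fraction - depth_bound) * H)
  }

  fast_bound <- ref$ref_rep_duration * (1 - thr$tempo_tolerance)
  slow_bound <- ref$ref_rep_duration * (1 + thr$tempo_tolerance)
  if (seg$duration < fast_bound) {
    kinds <- c(kinds, "tempo_fast"); mags <- c(mags, fast_bound - seg$duration)
  } else if (seg$duration > slow_bound) {
    kinds <- c(kinds, "tempo_slow"); mags <- c(mags, seg$duration - slow_bound)
  }

  # dominant-direction deviation, one event per rep
  exc <- c(dev_right = seg$lat_max, dev_left = -seg$lat_min,
           dev_front = seg$sag_max, dev_back = -seg$sag_min) - thr$deviation_radius
  if (any(exc > 0)) {
    which_dev <- names(exc)[which.max(exc)]
    kinds <- c(kinds, which_dev); mags <- c(mags, max(exc))
  }

  out <- data.frame(rep_index = rep(as.integer(rep_index), length(kinds)),
                    kind = kinds, magnitude = mags, stringsAsFactors = FALSE)
  class(out) <- c("error_events", "data.frame")
  out
}

empty_error_events <- function() {
  out <- data.frame(rep_index = integer(), kind = character(), magnitude = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("error_events", "data.frame")
  out
}

#' Monitor a full exercise session
#'
#' Runs segmentation and per-repetition error detection over a session
#' trajectory, assigns repetitions to sets in prescription order, and emits
#' the coaching cues (repetition countdown, set completion, corrective
#' feedback) the in-session coach would speak.
#'
#' @param traj the session [trajectory()] (may include the calibration stand).
#' @param prescription an [exercise_prescription()].
#' @param calib the [calibrate()] profile for this participant.
#' @param ref the [reference_profile()].
#' @param thr detection [thresholds()].
#' @param session_id identifier stored on the record.
#' @param week 1-based week index of the session within the trial.
#' @param catalog message catalog used for cues, see [load_catalog()].
#' @return A `session_record`: list with `session_id`, `week`, `sets`
#'   (per-set completed rep counts), `errors` (an `error_events` data.frame
#'   with global 1-based `rep_index`), `duration_s`, `cues` (data.frame of
#'   emitted messages with in-session timestamps) and `surplus` flag set when
#'   more repetitions were detected than prescribed (surplus reps are logged
#'   to the final set).
#' @export
monitor_session <- function(traj, prescription, calib, ref,
                            thr = default_thresholds(), session_id = "session-1",
                            week = 1L, catalog = default_catalog()) {
  segs <- segment_reps(traj, calib, thr)
  n_sets <- prescription$sets_per_session
  rps <- prescription$reps_per_set
  n_rx <- n_sets * rps

  sets <- integer(n_sets)
  n_det <- nrow(segs)
  surplus <- n_det > n_rx
  for (i in seq_len(min(n_det, n_rx))) {
    set_i <- ceiling(i / rps)
    sets[set_i] <- sets[set_i] + 1L
  }
  if (surplus) {
    sets[n_sets] <- sets[n_sets] + (n_det - n_rx)
    warning(sprintf("%d repetitions detected beyond the %d prescribed; logged to the final set",
                    n_det - n_rx, n_rx))
  }

  errors <- empty_error_events()
  cues <- data.frame(t = numeric(), intent = character(), text = character(),
                     channel = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n_det)) {
    t_end <- traj$samples$t[segs$end[i]]
    ev <- detect_rep_errors(segs[i, ], calib, ref, thr, rep_index = i)
    if (nrow(ev) > 0) {
      errors <- rbind(errors, ev)
      for (j in seq_len(nrow(ev))) {
        cue <- realtime_cue(ev[j, ], catalog = catalog)
        cues <- rbind(cues, data.frame(t = t_end, intent = paste0("cue_", ev$kind[j]),
                                       text = cue$text, channel = cue$channel,
                                       stringsAsFactors = FALSE))
      }
    }
    if (i <= n_rx) {
      set_i <- ceiling(i / rps)
      rep_in_set <- i - (set_i - 1L) * rps
      msg <- countdown_and_progress(set_i, rep_in_set, prescription, catalog = catalog)
      if (!is.null(msg)) {
        cues <- rbind(cues, data.frame(t = t_end, intent = msg$trigger, text = msg$text,
                                       channel = msg$channel, stringsAsFactors = FALSE))
      }
    }
  }
  class(errors) <- c("error_events", "data.frame")

  duration <- if (nrow(traj$samples) >= 2) diff(range(traj$samples$t)) else 0
  structure(list(session_id = session_id, week = as.integer(week), sets = sets,
                 errors = errors, duration_s = duration, cues = cues,
                 surplus = surplus),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (week %d): sets [%s], %d error(s), %.0f s%s\n",
              x$session_id, x$week, paste(x$sets, collapse = ","),
              nrow(x$errors), x$duration_s,
              if (isTRUE(x$surplus)) ", surplus reps" else ""))
  invisible(x)
}
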