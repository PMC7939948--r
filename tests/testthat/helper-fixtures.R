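# Shared fixtures and independent oracles. Oracles deliberately use different
# code paths from the package (run-length regions instead of the state
# machine, full 2^n enumeration instead of the convolution).

default_profile <- function(...) sim_profile(noise_sd = 0, ...)

rx_1x3 <- function() exercise_prescription(sets_per_session = 1, reps_per_set = 3)

# simulate one session and calibrate it on the leading stand
sim_and_calibrate <- function(profile, prescription, plan = NULL, ...) {
  sim <- simulate_squat_session(profile, prescription, plan, ...)
  calib <- calibrate(subset_trajectory(sim$trajectory, 0, 1.9))
  list(sim = sim, calib = calib)
}

# a still standing trajectory at the given height (for calibration tests)
standing_trajectory <- function(y, duration = 1, rate = 30, x = 0, z = 0, yaw = 0) {
  t <- seq(0, duration, by = 1 / rate)
  yv <- rep_len(y, length(t))
  q <- c(cos(yaw / 2), 0, sin(yaw / 2), 0)
  trajectory(data.frame(t = t, x = x, y = yv, z = z,
                        qw = q[1], qx = q[2], qy = q[3], qz = q[4]), rate)
}

# hand-built session record (for adherence tests that do not need trajectories)
make_session_record <- function(week, sets = c(10L, 10L, 10L), errors = NULL,
                                duration = 191, id = paste0("s", week)) {
  if (is.null(errors)) {
    errors <- data.frame(rep_index = integer(), kind = character(),
                         magnitude = numeric(), stringsAsFactors = FALSE)
  }
  class(errors) <- c("error_events", "data.frame")
  structure(list(session_id = id, week = as.integer(week), sets = as.integer(sets),
                 errors = errors, duration_s = duration,
                 cues = data.frame(t = numeric(), intent = character(),
                                   text = character(), channel = character()),
                 surplus = FALSE),
            class = "session_record")
}

error_rows <- function(rep_index, kind, magnitude = 0.05) {
  out <- data.frame(rep_index = as.integer(rep_index), kind = kind,
                    magnitude = rep_len(magnitude, length(kind)),
                    stringsAsFactors = FALSE)
  class(out) <- c("error_events", "data.frame")
  out
}

# --- segmentation oracle -----------------------------------------------------
# Count connected regions of the raw vertical signal below the enter level,
# merging regions whose interleaving gap never recovers above the exit level.
oracle_rep_count <- function(y, standing_height, enter_fraction = 0.10,
                             exit_fraction = 0.05) {
  enter_level <- (1 - enter_fraction) * standing_height
  exit_level <- (1 - exit_fraction) * standing_height
  below <- y < enter_level
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg_start <- starts[r$values]
  reg_end <- ends[r$values]
  if (length(reg_start) == 0) return(0L)
  count <- 1L
  for (i in seq_along(reg_start)[-1]) {
    gap <- y[(reg_end[i - 1] + 1L):(reg_start[i] - 1L)]
    if (length(gap) > 0 && max(gap) > exit_level) count <- count + 1L
  }
  count
}

# --- Wilcoxon oracle ---------------------------------------------------------
# Full enumeration of all 2^n sign assignments of the ranked absolute
# differences; feasible for n <= 12.
oracle_wilcoxon_p <- function(values, mu) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 15)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}
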