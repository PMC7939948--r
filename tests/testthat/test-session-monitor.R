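# Calibration, segmentation (vs the run-length oracle), per-rep error
# geometry, and the session monitor's set bookkeeping.

test_that("calibration stores height as head height above the floor", {
  traj <- standing_trajectory(1.70)
  calib <- calibrate(traj)
  expect_equal(calib$standing_height, 1.70)
  expect_equal(calib$footprint_anchor, c(0, 0))
  expect_equal(calib$initial_yaw, 0)

  wobble <- standing_trajectory(c(1.69, 1.70, 1.71))
  expect_equal(calibrate(wobble)$standing_height, 1.70, tolerance = 1e-3)

  yawed <- standing_trajectory(1.60, yaw = 0.8, x = 0.3, z = -0.2)
  c2 <- calibrate(yawed)
  expect_equal(c2$initial_yaw, 0.8, tolerance = 1e-9)
  expect_equal(c2$footprint_anchor, c(0.3, -0.2))
})

test_that("calibration fails on movement or too little data", {
  moving <- standing_trajectory(seq(1.5, 1.8, length.out = 31))
  expect_error(calibrate(moving), class = "squatcoach_calibration_failure")
  short <- standing_trajectory(1.70, duration = 0.3)
  expect_error(calibrate(short), class = "squatcoach_calibration_failure")
})

test_that("segmentation counts dips like the threshold-region oracle", {
  rx10 <- exercise_prescription(sets_per_session = 1, reps_per_set = 10)
  fix <- sim_and_calibrate(default_profile(), rx10)
  segs <- segment_reps(fix$sim$trajectory, fix$calib)
  expect_equal(nrow(segs), 10)
  expect_equal(nrow(segs),
               oracle_rep_count(fix$sim$trajectory$samples$y, fix$calib$standing_height))
  # ordered and non-overlapping
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start < segs$end))
  expect_true(all(segs$start[-1] >= head(segs$end, -1)))

  flat <- standing_trajectory(1.70, duration = 5)
  expect_equal(nrow(segment_reps(flat, fix$calib)), 0)

  # dips to fraction 0.92 never cross the 0.90 enter threshold
  shallow <- sim_and_calibrate(default_profile(target_depth_fraction = 0.08), rx10)
  expect_equal(nrow(segment_reps(shallow$sim$trajectory, shallow$calib)), 0)
  expect_equal(oracle_rep_count(shallow$sim$trajectory$samples$y,
                                shallow$calib$standing_height), 0L)
})

test_that("segmentation matches the oracle across randomized noise-free sessions", {
  set.seed(101)
  for (i in 1:20) {
    n_reps <- sample(2:8, 1)
    prof <- sim_profile(
      standing_height = runif(1, 1.5, 1.95),
      target_depth_fraction = runif(1, 0.2, 0.45),
      rep_duration = runif(1, 2, 5),
      noise_sd = 0, seed = i)
    rx <- exercise_prescription(sets_per_session = 1, reps_per_set = n_reps)
    fix <- sim_and_calibrate(prof, rx)
    segs <- segment_reps(fix$sim$trajectory, fix$calib)
    expect_equal(nrow(segs),
                 oracle_rep_count(fix$sim$trajectory$samples$y, fix$calib$standing_height),
                 info = sprintf("instance %d", i))
    expect_equal(nrow(segs), n_reps, info = sprintf("instance %d", i))
  }
})

test_that("raising enter_fraction never increases the rep count", {
  rx <- exercise_prescription(sets_per_session = 1, reps_per_set = 5)
  fix <- sim_and_calibrate(default_profile(target_depth_fraction = 0.25), rx)
  fractions <- c(0.08, 0.12, 0.2, 0.24, 0.3)
  counts <- vapply(fractions, function(f) {
    nrow(segment_reps(fix$sim$trajectory, fix$calib,
                      thresholds(enter_fraction = f, exit_fraction = f / 2)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-rep error geometry matches the stated inequalities", {
  H <- 1.70
  calib <- calibrate(standing_trajectory(H))
  ref <- reference_profile(0.70, 3.0)
  thr <- thresholds()  # depth tol 0.05, tempo tol 0.30, radius 0.15
  base <- data.frame(bottom_height = 0.70 * H, duration = 3.0,
                     lat_min = -0.05, lat_max = 0.05, sag_min = -0.05, sag_max = 0.05)

  # compliant rep
  expect_equal(nrow(detect_rep_errors(base, calib, ref, thr)), 0)

  # bottom fraction 0.80 vs bound 0.75: fractional exceedance 0.05 scaled to meters
  shallow <- transform(base, bottom_height = 0.80 * H)
  ev <- detect_rep_errors(shallow, calib, ref, thr)
  expect_equal(ev$kind, "depth")
  expect_equal(ev$magnitude, 0.05 * H, tolerance = 1e-9)

  # duration 1.8 s vs fast bound 3.0 * 0.7 = 2.1 s
  fast <- transform(base, duration = 1.8)
  ev <- detect_rep_errors(fast, calib, ref, thr)
  expect_equal(ev$kind, "tempo_fast")
  expect_equal(ev$magnitude, 0.3, tolerance = 1e-9)

  slow <- transform(base, duration = 4.2)
  ev <- detect_rep_errors(slow, calib, ref, thr)
  expect_equal(ev$kind, "tempo_slow")
  expect_equal(ev$magnitude, 4.2 - 3.9, tolerance = 1e-9)

  # +0.20 m rightward excursion vs radius 0.15
  right <- transform(base, lat_max = 0.20)
  ev <- detect_rep_errors(right, calib, ref, thr)
  expect_equal(ev$kind, "dev_right")
  expect_equal(ev$magnitude, 0.05, tolerance = 1e-9)
})

test_that("at most one deviation error per rep, labeled by the dominant direction", {
  H <- 1.70
  calib <- calibrate(standing_trajectory(H))
  ref <- reference_profile(0.70, 3.0)
  both <- data.frame(bottom_height = 0.70 * H, duration = 3.0,
                     lat_min = -0.30, lat_max = 0.18, sag_min = -0.02, sag_max = 0.25)
  ev <- detect_rep_errors(both, calib, ref, thresholds())
  dev_ev <- ev[grepl("^dev_", ev$kind), ]
  expect_equal(nrow(dev_ev), 1)
  expect_equal(dev_ev$kind, "dev_left")  # 0.30 is the largest excursion
  expect_equal(anyDuplicated(ev$kind), 0)
})

test_that("detected errors are invariant to rotating the whole setup about the vertical axis", {
  rx <- exercise_prescription(sets_per_session = 1, reps_per_set = 4)
  plan <- error_plan(c("dev_left", "none", "dev_front", "depth"))
  base <- sim_and_calibrate(default_profile(), rx, plan)
  ref <- reference_profile(0.70, 3.0)
  errs0 <- monitor_session(base$sim$trajectory, rx, base$calib, ref)$errors

  for (ang in c(0.9, pi / 2, 2.5)) {
    prof <- default_profile(yaw = ang, anchor = c(0.4, -0.7))
    rot <- sim_and_calibrate(prof, rx, plan)
    errs <- monitor_session(rot$sim$trajectory, rx, rot$calib, ref)$errors
    expect_equal(errs$kind, errs0$kind, info = sprintf("yaw %.2f", ang))
    expect_equal(errs$magnitude, errs0$magnitude, tolerance = 1e-6)
  }
})

test_that("monitor assigns reps to sets and logs surplus reps to the final set", {
  rx <- exercise_prescription(sets_per_session = 3, reps_per_set = 10)
  fix <- sim_and_calibrate(default_profile(), rx)
  ref <- reference_profile(0.70, 3.0)
  rec <- monitor_session(fix$sim$trajectory, rx, fix$calib, ref)
  expect_equal(rec$sets, c(10L, 10L, 10L))
  expect_equal(nrow(rec$errors), 0)
  expect_false(rec$surplus)
  expect_gt(rec$duration_s, 0)

  # one depth tag in set 2 -> exactly one depth event with rep_index 11..20
  plan <- error_plan(c(rep("none", 14), "depth", rep("none", 15)))
  fix2 <- sim_and_calibrate(default_profile(), rx, plan)
  rec2 <- monitor_session(fix2$sim$trajectory, rx, fix2$calib, ref)
  expect_equal(nrow(rec2$errors), 1)
  expect_equal(rec2$errors$kind, "depth")
  expect_true(rec2$errors$rep_index %in% 11:20)

  # over-performed session: 4 reps against a 1x3 prescription
  rx_s <- rx_1x3()
  over <- sim_and_calibrate(default_profile(),
                            exercise_prescription(sets_per_session = 1, reps_per_set = 4))
  expect_warning(rec3 <- monitor_session(over$sim$trajectory, rx_s, over$calib, ref),
                 "beyond")
  expect_true(rec3$surplus)
  expect_equal(rec3$sets, 4L)

  # no motion after calibration
  still <- standing_trajectory(1.70, duration = 4)
  calib <- calibrate(still)
  rec4 <- monitor_session(subset_trajectory(still, 0, 0.01), rx, calib, ref)
  expect_equal(rec4$sets, c(0L, 0L, 0L))
  expect_equal(rec4$duration_s, 0)
})

test_that("monitor emits countdown and corrective cues at the right reps", {
  rx <- exercise_prescription(sets_per_session = 2, reps_per_set = 4)
  plan <- error_plan(c("depth", rep("none", 7)))
  fix <- sim_and_calibrate(default_profile(), rx, plan)
  ref <- reference_profile(0.70, 3.0)
  rec <- monitor_session(fix$sim$trajectory, rx, fix$calib, ref)
  expect_true("A little bit lower." %in% rec$cues$text)
  expect_equal(sum(rec$cues$intent == "set 1 completed"), 1)
  expect_equal(sum(rec$cues$intent == "session completed"), 1)
  expect_true(any(grepl("Only three more", rec$cues$text)))
})
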