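# Treatment-adherence dimensions (TAD1-5) and therapist-facing reports.
#
# TAD1 session completion rate, TAD2 set completion rate, TAD3 exercise
# repetition rate, TAD4 temporal exercise accuracy (reps without tempo
# errors), TAD5 spatial exercise accuracy (reps without depth or deviation
# errors). Rates are kept exact internally and rounded to whole percent for
# display; over-performance is capped at 100%.

#' Exercise prescription
#'
#' @param sessions_per_week prescribed sessions per week.
#' @param weeks trial length in weeks.
#' @param sets_per_session prescribed sets per session.
#' @param reps_per_set prescribed repetitions per set.
#' @param ref optional [reference_profile()] defining the prescribed tempo and
#'   depth.
#' @return An `exercise_prescription` list.
#' @export
exercise_prescription <- function(sessions_per_week = 3, weeks = 4,
                                  sets_per_session = 3, reps_per_set = 10,
                                  ref = NULL) {
  counts <- c(sessions_per_week, weeks, sets_per_session, reps_per_set)
  assert_that(all(counts >= 1) && all(counts == as.integer(counts)),
              "all prescription counts must be integers >= 1")
  structure(list(sessions_per_week = as.integer(sessions_per_week),
                 weeks = as.integer(weeks),
                 sets_per_session = as.integer(sets_per_session),
                 reps_per_set = as.integer(reps_per_set),
                 ref = ref),
            class = "exercise_prescription")
}

# completed sets / reps in one session under a prescription: a set counts as
# completed when it reached the prescribed rep count; per-set rep credit is
# capped at the prescription (surplus is logged but earns no credit)
session_counts <- function(session, prescription) {
  sets <- session$sets
  list(sets_done = sum(sets >= prescription$reps_per_set),
       reps_done = sum(pmin(sets, prescription$reps_per_set)))
}

#' Compute the five treatment-adherence dimensions
#'
#' @param sessions list of `session_record`s (see [monitor_session()]), each
#'   carrying a `week` index within `1..prescription$weeks`.
#' @param prescription the [exercise_prescription()].
#' @return An `adherence_report` with exact percentages `tad1..tad5`, the
#'   underlying counts, `mean_session_duration` (seconds, `NA` when no
#'   sessions), and `weekly_error_counts` (length `weeks`). The print method
#'   rounds percentages to the nearest integer.
#' @export
completion_rates <- function(sessions, prescription) {
  weeks <- prescription$weeks
  rx_sessions <- prescription$sessions_per_week * weeks
  rx_sets <- rx_sessions * prescription$sets_per_session
  rx_reps <- rx_sets * prescription$reps_per_set

  if (length(sessions) > 0) {
    wk <- vapply(sessions, function(s) s$week, integer(1))
    assert_that(all(wk >= 1 & wk <= weeks), "session week index outside 1..weeks")
  }

  counts <- lapply(sessions, session_counts, prescription = prescription)
  sets_done <- sum(vapply(counts, `[[`, numeric(1), "sets_done"))
  reps_done <- sum(vapply(counts, `[[`, numeric(1), "reps_done"))
  sessions_done <- sum(vapply(counts, function(cc) cc$sets_done >= 1, logical(1)))

  pct <- function(done, rx) if (rx == 0) 0 else min(100, 100 * done / rx)
  tad1 <- pct(sessions_done, rx_sessions)
  tad2 <- pct(sets_done, rx_sets)
  tad3 <- pct(reps_done, rx_reps)

  # accuracy dimensions over completed reps: a rep is temporally accurate if
  # it carries no tempo error, spatially accurate if neither depth nor
  # deviation errors
  tempo_err_reps <- 0L; spatial_err_reps <- 0L
  for (s in sessions) {
    if (nrow(s$errors) > 0) {
      tempo_err_reps <- tempo_err_reps +
        length(unique(s$errors$rep_index[s$errors$kind %in% c("tempo_fast", "tempo_slow")]))
      spatial_err_reps <- spatial_err_reps +
        length(unique(s$errors$rep_index[s$errors$kind %in%
          c("depth", "dev_left", "dev_right", "dev_front", "dev_back")]))
    }
  }
  total_reps <- sum(vapply(sessions, function(s) sum(s$sets), numeric(1)))
  tad4 <- if (total_reps == 0) 0 else 100 * (total_reps - tempo_err_reps) / total_reps
  tad5 <- if (total_reps == 0) 0 else 100 * (total_reps - spatial_err_reps) / total_reps

  durations <- vapply(sessions, function(s) s$duration_s, numeric(1))
  structure(list(
    tad1_session_completion = tad1, tad2_set_completion = tad2,
    tad3_repetition_rate = tad3, tad4_temporal_accuracy = tad4,
    tad5_spatial_accuracy = tad5,
    counts = list(sessions_done = sessions_done, sessions_rx = rx_sessions,
                  sets_done = sets_done, sets_rx = rx_sets,
                  reps_done = reps_done, reps_rx = rx_reps),
    mean_session_duration = if (length(sessions) == 0) NA_real_ else mean(durations),
    total_duration = sum(durations),
    weekly_error_counts = weekly_error_aggregate(sessions, weeks)),
    class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("Treatment adherence report\n")
  cat(sprintf("  TAD1 session completion: %d%% (%d/%d)\n",
              round(x$tad1_session_completion), x$counts$sessions_done, x$counts$sessions_rx))
  cat(sprintf("  TAD2 set completion:     %d%% (%d/%d)\n",
              round(x$tad2_set_completion), x$counts$sets_done, x$counts$sets_rx))
  cat(sprintf("  TAD3 repetition rate:    %d%% (%d/%d)\n",
              round(x$tad3_repetition_rate), x$counts$reps_done, x$counts$reps_rx))
  cat(sprintf("  TAD4 temporal accuracy:  %d%%\n", round(x$tad4_temporal_accuracy)))
  cat(sprintf("  TAD5 spatial accuracy:   %d%%\n", round(x$tad5_spatial_accuracy)))
  if (!is.na(x$mean_session_duration)) {
    cat(sprintf("  Duration: mean %d s per session (%d s total)\n",
                round(x$mean_session_duration), round(x$total_duration)))
  }
  cat(sprintf("  Errors per week: [%s]\n", paste(x$weekly_error_counts, collapse = ", ")))
  invisible(x)
}

#' Aggregate execution errors by week
#'
#' @param sessions list of `session_record`s.
#' @param weeks number of weeks; weeks without sessions report 0.
#' @return Integer vector of length `weeks`: error events per week.
#' @export
weekly_error_aggregate <- function(sessions, weeks) {
  counts <- integer(weeks)
  for (s in sessions) {
    assert_that(s$week >= 1 && s$week <= weeks, "session week index outside 1..weeks")
    counts[s$week] <- counts[s$week] + nrow(s$errors)
  }
  counts
}

#' Mean session duration
#'
#' @param sessions non-empty list of `session_record`s.
#' @param display round to the nearest second (the dashboard convention)?
#' @return Mean duration in seconds.
#' @export
mean_session_duration <- function(sessions, display = FALSE) {
  if (length(sessions) == 0) stop_squatcoach("no_data", "no sessions recorded")
  m <- mean(vapply(sessions, function(s) s$duration_s, numeric(1)))
  if (display) round(m) else m
}

#' Per-session error report for the physiotherapist
#'
#' @param session a `session_record`.
#' @param prescription the [exercise_prescription()] (for accuracy
#'   percentages).
#' @return An `error_report`: human-readable summary plus a one-row
#'   data.frame (`$row`) for machine consumption.
#' @export
error_report <- function(session, prescription) {
  cc <- session_counts(session, prescription)
  total_reps <- sum(session$sets)
  n_err <- nrow(session$errors)
  tempo_reps <- length(unique(session$errors$rep_index[
    session$errors$kind %in% c("tempo_fast", "tempo_slow")]))
  spatial_reps <- length(unique(session$errors$rep_index[
    session$errors$kind %in% c("depth", "dev_left", "dev_right", "dev_front", "dev_back")]))
  row <- data.frame(
    session_id = session$session_id, week = session$week,
    sets_done = cc$sets_done, reps_done = cc$reps_done,
    errors = n_err,
    temporal_accuracy = if (total_reps == 0) NA_real_ else 100 * (total_reps - tempo_reps) / total_reps,
    spatial_accuracy = if (total_reps == 0) NA_real_ else 100 * (total_reps - spatial_reps) / total_reps,
    duration_s = session$duration_s,
    surplus = isTRUE(session$surplus),
    stringsAsFactors = FALSE)
  structure(list(session = session, prescription = prescription, row = row),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  s <- x$session
  cat(sprintf("Error report for %s (week %d)\n", s$session_id, s$week))
  cat(sprintf("  Sets (completed reps): %s\n", paste(s$sets, collapse = ", ")))
  if (isTRUE(s$surplus)) cat("  NOTE: surplus repetitions beyond the prescription were logged\n")
  if (nrow(s$errors) == 0) {
    cat("  All sets compliant: no execution errors detected\n")
  } else {
    for (i in seq_len(nrow(s$errors))) {
      e <- s$errors[i, ]
      unit <- if (e$kind %in% c("tempo_fast", "tempo_slow")) "s" else "m"
      cat(sprintf("  Rep %d: %s (magnitude %.3f %s)\n", e$rep_index, e$kind, e$magnitude, unit))
    }
  }
  cat(sprintf("  Temporal accuracy %.0f%%, spatial accuracy %.0f%%, duration %.0f s\n",
              x$row$temporal_accuracy, x$row$spatial_accuracy, x$row$duration_s))
  invisible(x)
}
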