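# The coaching message engine: real-time corrective cues, repetition
# countdowns and set-completion talk, weekly reminder scheduling with seeded
# jitter, variant randomization with a no-immediate-repeat rule, and
# usage-based progression. Messages carry behavior-change-technique (BCT)
# tags; texts live in an editable JSON catalog, not in code.

#' Load a message catalog
#'
#' A catalog maps message intents (greeting, reminder, psychoeducation,
#' progress, per-error cues, countdown, set/session completion) to lists of
#' text variants, each with an `id`, a `text` (possibly an sprintf template)
#' and `bct_tags`.
#'
#' @param path JSON catalog file; defaults to the catalog shipped with the
#'   package.
#' @return A named list of intents, class `message_catalog`.
#' @export
load_catalog <- function(path = system.file("extdata", "message_catalog.json",
                                            package = "squatcoach")) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  assert_that(length(raw) > 0 && all(vapply(raw, length, integer(1)) >= 1),
              "each catalog intent needs at least one variant")
  for (intent in names(raw)) {
    for (v in raw[[intent]]) {
      assert_that(is.character(v$text) && nzchar(v$text),
                  sprintf("catalog intent '%s' has a variant without text", intent))
    }
  }
  structure(raw, class = "message_catalog")
}

catalog_cache <- new.env(parent = emptyenv())

#' @rdname load_catalog
#' @export
default_catalog <- function() {
  if (is.null(catalog_cache$default)) catalog_cache$default <- load_catalog()
  catalog_cache$default
}

new_message <- function(text, channel, bct_tags, trigger, variant_id = NA_character_) {
  assert_that(nzchar(text), "message text must be nonempty")
  structure(list(text = text, channel = channel,
                 bct_tags = as.integer(unlist(bct_tags)), trigger = trigger,
                 variant_id = variant_id),
            class = "coach_message")
}

#' @export
print.coach_message <- function(x, ...) {
  cat(sprintf("[%s | BCT %s] %s\n", x$channel, paste(x$bct_tags, collapse = ","), x$text))
  invisible(x)
}

#' Real-time corrective cue for a detected execution error
#'
#' Deterministic mapping from error kind to the corrective utterance the
#' in-session coach speaks: an insufficient-depth error yields
#' "A little bit lower."; tempo and deviation errors yield the matching
#' corrective cue tagged BCT 19/21.
#'
#' @param error one `error_events` row (needs `kind`; `magnitude` and
#'   `rep_index` enrich the trigger description).
#' @param catalog a [load_catalog()] catalog.
#' @return A `coach_message` on the AR channel.
#' @export
realtime_cue <- function(error, catalog = default_catalog()) {
  kind <- as.character(error$kind)
  assert_that(length(kind) == 1 && kind %in% error_kinds(),
              sprintf("unknown error kind '%s'", paste(kind, collapse = ",")))
  intent <- paste0("cue_", kind)
  assert_that(intent %in% names(catalog), sprintf("catalog has no intent '%s'", intent))
  v <- catalog[[intent]][[1]]
  trigger <- if (!is.null(error$magnitude)) {
    sprintf("%s error, magnitude %.3f", kind, error$magnitude)
  } else sprintf("%s error", kind)
  new_message(v$text, "ar", v$bct_tags, trigger, v$id)
}

number_word <- function(n) {
  words <- c("one", "two", "three", "four", "five", "six", "seven", "eight", "nine", "ten")
  if (n >= 1 && n <= 10) words[n] else as.character(n)
}

#' Countdown and set-progress talk
#'
#' Emits the coach's counting script: when three or fewer repetitions remain
#' in a set (counting the one just performed) a countdown message fires
#' ("Only three more!", "Only two more!"); completing a set yields a
#' completion-and-break message referencing the next set, and completing the
#' final set closes the session. Silent otherwise.
#'
#' @param set_index current set (1-based).
#' @param rep_index repetition just completed within the set (1-based).
#' @param prescription the [exercise_prescription()].
#' @param catalog a [load_catalog()] catalog.
#' @return A `coach_message`, or `NULL` when no utterance is due.
#' @export
countdown_and_progress <- function(set_index, rep_index, prescription,
                                   catalog = default_catalog()) {
  rps <- prescription$reps_per_set
  assert_that(set_index >= 1 && set_index <= prescription$sets_per_session &&
                rep_index >= 1 && rep_index <= rps,
              "set/rep indices outside the prescription")
  remaining <- rps - rep_index + 1L  # counting the current rep
  if (remaining > 3L) return(NULL)
  if (rep_index == rps) {
    if (set_index < prescription$sets_per_session) {
      v <- catalog[["set_complete"]][[1]]
      msg <- sprintf(v$text, set_index, set_index + 1L)
      new_message(msg, "ar", v$bct_tags, sprintf("set %d completed", set_index), v$id)
    } else {
      v <- catalog[["session_complete"]][[1]]
      new_message(v$text, "ar", v$bct_tags, "session completed", v$id)
    }
  } else {
    v <- catalog[["countdown"]][[1]]
    new_message(sprintf(v$text, number_word(remaining)), "ar", v$bct_tags,
                sprintf("%d reps remaining in set %d", remaining, set_index), v$id)
  }
}

#' Coaching plan for the smartphone channel
#'
#' @param weeks trial horizon in weeks.
#' @param reminders_per_week average number of weekly text messages (may be
#'   fractional; e.g. 4.25/week over 4 weeks yields 17 messages).
#' @param catalog a [load_catalog()] catalog.
#' @param seed integer seed driving day jitter and variant randomization.
#' @return A `coaching_plan` list.
#' @export
coaching_plan <- function(weeks = 4, reminders_per_week = 4.25,
                          catalog = default_catalog(), seed = 1L) {
  assert_that(weeks >= 0 && weeks == as.integer(weeks), "weeks must be a non-negative integer")
  assert_that(reminders_per_week >= 0, "reminders_per_week must be non-negative")
  structure(list(weeks = as.integer(weeks), reminders_per_week = reminders_per_week,
                 catalog = catalog, seed = as.integer(seed)),
            class = "coaching_plan")
}

#' Schedule the weekly coaching text messages
#'
#' The total `round(reminders_per_week * weeks)` messages are distributed as
#' evenly as possible across weeks (any remainder goes to the earliest weeks:
#' 17 over 4 weeks gives 5, 4, 4, 4), message days are drawn with seeded
#' jitter within each week, intents rotate through reminder, psychoeducation
#' and progress, and text variants are randomized under the
#' no-immediate-repeat rule. Identical plan and seed give identical schedules.
#'
#' @param plan a [coaching_plan()].
#' @return A data.frame of class `coaching_schedule`: `week`, `day` (1-7),
#'   `intent`, `variant_id`, `text`, `channel`; attribute `mean_per_week`.
#' @export
schedule_reminders <- function(plan) {
  weeks <- plan$weeks
  total <- round(plan$reminders_per_week * weeks)
  empty <- data.frame(week = integer(), day = integer(), intent = character(),
                      variant_id = character(), text = character(),
                      channel = character(), stringsAsFactors = FALSE)
  if (weeks == 0 || total == 0) {
    attr(empty, "mean_per_week") <- if (weeks > 0) 0 else NA_real_
    class(empty) <- c("coaching_schedule", "data.frame")
    return(empty)
  }
  base <- total %/% weeks
  extra <- total %% weeks
  per_week <- rep(base, weeks) + c(rep(1L, extra), rep(0L, weeks - extra))

  intents <- c("reminder", "psychoeducation", "progress")
  rows <- withr::with_seed(plan$seed, {
    prev <- list()
    out <- empty
    i_msg <- 0L
    for (w in seq_len(weeks)) {
      k <- per_week[w]
      if (k == 0) next
      days <- if (k <= 7) sort(sample.int(7, k)) else sort(sample.int(7, k, replace = TRUE))
      for (d in days) {
        i_msg <- i_msg + 1L
        intent <- intents[(i_msg - 1L) %% length(intents) + 1L]
        v <- select_variant(intent, plan$catalog, prev_id = prev[[intent]])
        prev[[intent]] <- v$id
        text <- if (grepl("%d", v$text, fixed = TRUE)) sprintf(v$text, i_msg) else v$text
        out <- rbind(out, data.frame(week = w, day = d, intent = intent,
                                     variant_id = v$id, text = text,
                                     channel = "smartphone", stringsAsFactors = FALSE))
      }
    }
    out
  })
  attr(rows, "mean_per_week") <- total / weeks
  class(rows) <- c("coaching_schedule", "data.frame")
  rows
}

#' Pick a message variant with the no-immediate-repeat rule
#'
#' Uniform seeded choice among an intent's variants, never repeating the
#' immediately preceding variant when two or more exist. Uses the current RNG
#' state unless `seed` is given.
#'
#' @param intent catalog intent name.
#' @param catalog a [load_catalog()] catalog.
#' @param prev_id variant id chosen last time for this intent, or `NULL`.
#' @param seed optional integer seed for a standalone deterministic draw.
#' @return The chosen variant (list with `id`, `text`, `bct_tags`).
#' @export
select_variant <- function(intent, catalog = default_catalog(), prev_id = NULL,
                           seed = NULL) {
  assert_that(intent %in% names(catalog), sprintf("intent '%s' not in catalog", intent))
  variants <- catalog[[intent]]
  ids <- vapply(variants, `[[`, character(1), "id")
  pool <- seq_along(variants)
  if (length(pool) >= 2 && !is.null(prev_id) && prev_id %in% ids) {
    pool <- pool[ids != prev_id]
  }
  pick <- function() if (length(pool) == 1) pool else sample(pool, 1)
  i <- if (is.null(seed)) pick() else withr::with_seed(as.integer(seed), pick())
  variants[[i]]
}

#' Usage history of the trial so far
#'
#' @param weekly_sessions integer vector: completed sessions per elapsed week.
#' @return A `usage_history` with per-week counts and the cumulative total.
#' @export
usage_history <- function(weekly_sessions = integer()) {
  assert_that(all(weekly_sessions >= 0), "session counts must be non-negative")
  structure(list(weekly_sessions = as.integer(weekly_sessions),
                 cumulative = sum(as.integer(weekly_sessions))),
            class = "usage_history")
}

#' Usage-based session progression
#'
#' After the first week, and once the patient has completed at least one
#' session, tutorials become skippable and explanations are shortened. The
#' returned configuration also carries the cumulative-session progress
#' message (an early progress visualization, BCT 19).
#'
#' @param history a [usage_history()].
#' @param week current week (1-based); defaults to the week after the history.
#' @param catalog a [load_catalog()] catalog.
#' @return List with `tutorial` ("full"/"skippable"), `explanations`
#'   ("full"/"short") and `progress_message` (a `coach_message`, BCT 19).
#' @export
progression_rules <- function(history, week = length(history$weekly_sessions) + 1L,
                              catalog = default_catalog()) {
  assert_that(week >= 1, "week must be >= 1")
  familiar <- week >= 2 && history$cumulative >= 1
  v <- catalog[["progress"]][[1]]
  progress_message <- new_message(sprintf(v$text, history$cumulative), "ar",
                                  v$bct_tags, "session start progress recap", v$id)
  list(tutorial = if (familiar) "skippable" else "full",
       explanations = if (familiar) "short" else "full",
       progress_message = progress_message)
}
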