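#' Adaptive visual-acuity examination engine
#'
#' The exam descends the chart one single optotype at a time (only the first
#' character of each row is shown) until the patient misses one, then
#' presents the full five-optotype row of the last correctly identified
#' single.  A row passes when more than half its optotypes are read; passing
#' advances to the next smaller row, failing fixes the score at the smallest
#' passed row with per-letter adjustments (-m letters missed on the recorded
#' row, +k extra letters on the next smaller row).  Eyes are tested right
#' first; an eye that does not achieve 6/9 unaided is re-tested through a
#' pinhole occluder.
#'
#' @name exam_engine
NULL

EXAM_PHASES <- c("IDLE", "INSTRUCT", "RIGHT_UNAIDED", "LEFT_UNAIDED",
                 "RIGHT_PINHOLE", "LEFT_PINHOLE", "COMPLETE", "ASSIST")
ACTIVE_PHASES <- c("RIGHT_UNAIDED", "LEFT_UNAIDED", "RIGHT_PINHOLE",
                   "LEFT_PINHOLE")
PHASE_POSE <- c(RIGHT_UNAIDED = "Right", LEFT_UNAIDED = "Left",
                RIGHT_PINHOLE = "Right_ph", LEFT_PINHOLE = "Left_ph")

# Deterministic session clock: one second per tick.  Injectable so event
# timestamps (and therefore logs) are reproducible.
counter_clock <- function(start = 0, step = 1) {
  t <- start - step
  function() { t <<- t + step; t }
}

add_event <- function(state, kind, payload = NULL) {
  state$events[[length(state$events) + 1L]] <-
    list(t = state$clock(), phase = state$phase, kind = kind,
         payload = payload)
  state
}

#' Start an examination session
#'
#' The session opens in the INSTRUCT phase; the first OK confirmation moves
#' it to RIGHT_UNAIDED at the largest line in single-optotype mode.  All row
#' contents for every potential phase are derived from `seed` up front, so
#' identical seeds replay identical stimulus sequences.
#'
#' @param chart A [chart_spec()].
#' @param seed Integer session seed.
#' @param session_id Opaque session identifier (stands in for the scanned
#'   identity card).
#' @param clock Zero-argument function returning the current time in
#'   seconds; defaults to a deterministic one-second counter.
#' @return An object of class `exam_state`.
#' @export
start_exam <- function(chart = default_chart(), seed = 1L,
                       session_id = "session-1", clock = NULL) {
  stopifnot(inherits(chart, "chart_spec"))
  nl <- length(chart$lines)
  rows <- lapply(seq_along(ACTIVE_PHASES), function(p)
    lapply(seq_len(nl), function(l)
      generate_row(chart$lines[[l]], chart,
                   derive_seed(seed, p * 100L + l))))
  names(rows) <- ACTIVE_PHASES
  state <- structure(
    list(chart = chart, seed = as.integer(seed), session_id = session_id,
         phase = "INSTRUCT", resume_phase = NULL,
         mode = "SINGLE", line_idx = 1L,
         last_single_pass = NA_integer_,
         best_pass_idx = NA_integer_, best_pass_misses = NA_integer_,
         below_correct = NA_integer_, backing_up = FALSE,
         phase_done = FALSE, worse_flag = FALSE,
         scores = list(), rows = rows,
         required_pose = NA_character_,
         events = list(), clock = clock %||% counter_clock()),
    class = "exam_state")
  add_event(state, "COMMAND", list(note = "session opened, awaiting OK"))
}

#' @export
print.exam_state <- function(x, ...) {
  cat(sprintf("<exam_state %s> phase %s", x$session_id, x$phase))
  if (x$phase %in% ACTIVE_PHASES)
    cat(sprintf(", %s mode at %s", x$mode, format(x$chart$lines[[x$line_idx]])))
  cat(sprintf(", %d events\n", length(x$events)))
  invisible(x)
}

current_row <- function(state) state$rows[[state$phase]][[state$line_idx]]

reset_phase_trackers <- function(state, start_idx) {
  state$mode <- "SINGLE"
  state$line_idx <- start_idx
  state$last_single_pass <- NA_integer_
  state$best_pass_idx <- NA_integer_
  state$best_pass_misses <- NA_integer_
  state$below_correct <- NA_integer_
  state$backing_up <- FALSE
  state$phase_done <- FALSE
  state$worse_flag <- FALSE
  state
}

#' Next stimulus to present
#'
#' @param state An `exam_state` in an active phase.
#' @return A `stimulus` object: list with `kind` (`"SINGLE_OPTOTYPE"` or
#'   `"FULL_ROW"`), `line` and `symbols` (length 1, the row's first symbol,
#'   or the full row).
#' @export
next_stimulus <- function(state) {
  if (!state$phase %in% ACTIVE_PHASES)
    stop_domain("no stimulus: exam phase is ", state$phase)
  if (state$phase_done)
    stop_domain("phase already finalized; call advance_phase()")
  row <- current_row(state)
  if (state$mode == "SINGLE")
    structure(list(kind = "SINGLE_OPTOTYPE", line = row$line,
                   symbols = row$symbols[1L]), class = "stimulus")
  else
    structure(list(kind = "FULL_ROW", line = row$line,
                   symbols = row$symbols), class = "stimulus")
}

#' @export
format.stimulus <- function(x, ...) {
  paste0(format(x$line), " [", paste(x$symbols, collapse = " "), "]")
}

# Number of row positions read correctly, positional comparison; short
# responses leave trailing positions incorrect, extras are ignored.
positional_correct <- function(response_symbols, row_symbols) {
  k <- min(length(response_symbols), length(row_symbols))
  if (k == 0L) return(0L)
  sum(response_symbols[seq_len(k)] == row_symbols[seq_len(k)])
}

finalize_with <- function(state, worse = FALSE) {
  state$phase_done <- TRUE
  state$worse_flag <- worse
  score <- finalize_phase(state)
  state$scores[[state$phase]] <- score
  add_event(state, "SCORE",
            list(score = format(score), logmar = score$logmar))
}

#' Apply a parsed response to the exam state
#'
#' Implements the adaptive protocol: single-optotype descent, row
#' confirmation anchored at the last single pass (backing up a line at a
#' time while no row has passed), the more-than-half pass rule, and the
#' REPEAT / BLURRED / SKIP command semantics (REPEAT re-presents the same
#' stimulus; BLURRED and SKIP count as unable to read).  Out-of-vocabulary
#' symbols are rejected with a re-prompt event and not tallied.
#'
#' @param state An `exam_state` (INSTRUCT or active phase).
#' @param response A [parsed_response()].
#' @return The updated `exam_state`.
#' @export
apply_response <- function(state, response) {
  stopifnot(inherits(state, "exam_state"), inherits(response, "parsed_response"))
  state <- add_event(state, "RESPONSE", list(value = format(response)))
  if (state$phase == "INSTRUCT") {
    if (response$kind == "COMMAND" && response$command == "OK") {
      state$phase <- "RIGHT_UNAIDED"
      state$required_pose <- PHASE_POSE[["RIGHT_UNAIDED"]]
      state <- reset_phase_trackers(state, 1L)
      state <- add_event(state, "COMMAND", list(note = "confirmed, exam started"))
    }
    return(state)
  }
  if (!state$phase %in% ACTIVE_PHASES || state$phase_done)
    stop_domain("no active stimulus to respond to (phase ", state$phase, ")")

  if (response$kind == "COMMAND") {
    if (response$command == "REPEAT" || response$command == "OK") {
      return(add_event(state, "COMMAND", list(note = "re-present stimulus")))
    }
    # BLURRED / SKIP: cannot read the current stimulus.
    response <- NULL
  } else {
    bad <- setdiff(response$symbols, state$chart$vocab)
    if (length(bad))
      return(add_event(state, "COMMAND",
                       list(note = "out-of-vocabulary response, re-prompt")))
  }

  row <- current_row(state)
  if (state$mode == "SINGLE") {
    correct <- !is.null(response) &&
      length(response$symbols) >= 1L &&
      response$symbols[1L] == row$symbols[1L]
    if (correct) {
      state$last_single_pass <- state$line_idx
      if (state$line_idx == length(state$chart$lines)) {
        state$mode <- "ROW"            # smallest line: confirm with full row
      } else {
        state$line_idx <- state$line_idx + 1L
      }
    } else if (!is.na(state$last_single_pass)) {
      state$mode <- "ROW"              # anchor at last single pass
      state$line_idx <- state$last_single_pass
    } else if (state$line_idx > 1L) {
      # Phase started mid-chart (pinhole shortcut): larger lines untried, so
      # anchor the row search here and let the back-up rule resolve it.
      state$mode <- "ROW"
    } else {
      return(finalize_with(state, worse = TRUE))
    }
    return(state)
  }

  # ROW mode
  n_correct <- if (is.null(response)) 0L
               else positional_correct(response$symbols, row$symbols)
  rl <- row$line$row_length
  passed <- n_correct > rl / 2
  if (passed) {
    state$best_pass_idx <- state$line_idx
    state$best_pass_misses <- rl - n_correct
    if (state$backing_up || state$line_idx == length(state$chart$lines)) {
      return(finalize_with(state))
    }
    state$line_idx <- state$line_idx + 1L   # descend to next smaller row
    return(state)
  }
  # row failed
  state$below_correct <- n_correct
  if (!is.na(state$best_pass_idx)) {
    return(finalize_with(state))            # descending run ends
  }
  if (state$line_idx == 1L) {
    return(finalize_with(state, worse = TRUE))
  }
  state$line_idx <- state$line_idx - 1L     # back up to a larger row
  state$backing_up <- TRUE
  state
}

#' Final VA score of the current phase
#'
#' The score line is the smallest passed row.  If that row was read with
#' `m` in 1..2 misses the adjustment is `-m`; if it was read clean (5/5) and
#' the next smaller row yielded `k` in 1..2 correct, the adjustment is `+k`
#' (k >= 3 would have passed that row, so +k is structurally limited to
#' +1/+2); otherwise 0.
#'
#' @param state An `exam_state` whose current phase has terminated.
#' @return A [va_score()]; the worse-than-chart sentinel when no row could
#'   be passed.
#' @export
finalize_phase <- function(state) {
  if (!state$phase_done)
    stop_domain("phase not finalized: no terminating row outcome yet")
  if (state$worse_flag)
    return(va_score(NULL, chart = state$chart, worse_than_chart = TRUE))
  i <- state$best_pass_idx
  if (is.na(i)) stop_domain("no row was ever presented")
  m <- state$best_pass_misses
  k <- state$below_correct
  adj <- if (m > 0L) -m
         else if (!is.na(k) && k >= 1L && k <= 2L) k
         else 0L
  va_score(state$chart$lines[[i]], adjustment = adj)
}

#' Does an unaided score trigger pinhole testing?
#'
#' An eye that failed to achieve 6/9 or better unaided is re-tested with a
#' pinhole: the trigger is strict, `logMAR > log10(9/6)` (a score of exactly
#' 6/9 does not trigger), compared on the adjusted logMAR.
#'
#' @param unaided A [va_score()].
#' @param chart The chart in use (supplies the 6/9 reference).
#' @return Logical.
#' @examples
#' pinhole_needed(va_score(optotype_line(12)))  # TRUE
#' pinhole_needed(va_score(optotype_line(9)))   # FALSE
#' @export
pinhole_needed <- function(unaided, chart = default_chart()) {
  stopifnot(inherits(unaided, "va_score"))
  unaided$logmar > snellen_to_logmar(9, 0L)
}

# Start line for a pinhole phase: two lines above the unaided achieved line
# (clamped to the chart top); worse-than-chart restarts at the top.
pinhole_start_idx <- function(unaided, chart) {
  if (unaided$worse_than_chart) return(1L)
  lms <- chart_logmars(chart)
  i <- which.min(abs(lms - unaided$line$logmar))
  max(1L, i - 2L)
}

#' Advance to the next phase
#'
#' Phase order: RIGHT_UNAIDED, LEFT_UNAIDED, then RIGHT_PINHOLE and/or
#' LEFT_PINHOLE for each eye whose unaided score triggers
#' [pinhole_needed()], then COMPLETE.  Pinhole phases re-run the full
#' single-then-row protocol starting two lines above the unaided achieved
#' line.
#'
#' @param state An `exam_state` whose current phase is finalized.
#' @return The updated `exam_state`.
#' @export
advance_phase <- function(state) {
  if (!state$phase_done) stop_domain("current phase not finalized")
  nxt <- switch(state$phase,
    RIGHT_UNAIDED = "LEFT_UNAIDED",
    LEFT_UNAIDED = if (pinhole_needed(state$scores[["RIGHT_UNAIDED"]], state$chart))
        "RIGHT_PINHOLE"
      else if (pinhole_needed(state$scores[["LEFT_UNAIDED"]], state$chart))
        "LEFT_PINHOLE"
      else "COMPLETE",
    RIGHT_PINHOLE = if (pinhole_needed(state$scores[["LEFT_UNAIDED"]], state$chart))
        "LEFT_PINHOLE"
      else "COMPLETE",
    LEFT_PINHOLE = "COMPLETE",
    stop_domain("cannot advance from phase ", state$phase))
  state$phase <- nxt
  if (nxt == "COMPLETE") {
    state$required_pose <- NA_character_
    return(add_event(state, "COMMAND", list(note = "exam complete")))
  }
  state$required_pose <- PHASE_POSE[[nxt]]
  start <- if (nxt %in% c("RIGHT_PINHOLE", "LEFT_PINHOLE")) {
    unaided <- state$scores[[sub("PINHOLE", "UNAIDED", nxt)]]
    pinhole_start_idx(unaided, state$chart)
  } else 1L
  state <- reset_phase_trackers(state, start)
  add_event(state, "COMMAND", list(note = paste("entering", nxt)))
}

#' Gate stimulus presentation on the occluder pose
#'
#' Presentation is allowed only when the (debounced) pose classification
#' matches the pose the current phase requires; otherwise the exam pauses
#' and the caller should issue guidance.
#'
#' @param state An `exam_state` in an active phase.
#' @param pose A `pose_classification` or a pose label string.
#' @return Logical; `FALSE` carries attribute `"required"`.
#' @export
gate_on_pose <- function(state, pose) {
  if (!state$phase %in% ACTIVE_PHASES)
    stop_domain("pose gating only applies to active phases")
  label <- if (inherits(pose, "pose_classification")) pose$label else as.character(pose)
  if (identical(label, state$required_pose)) TRUE
  else structure(FALSE, required = state$required_pose)
}

#' Pause for staff assistance / resume
#'
#' Staff intervention suspends the current phase without terminating the
#' session; resuming re-presents the pending stimulus.
#'
#' @param state An `exam_state`.
#' @return The updated `exam_state`.
#' @export
request_assist <- function(state) {
  if (!state$phase %in% c(ACTIVE_PHASES, "INSTRUCT"))
    stop_domain("assist only available during an active session")
  state$resume_phase <- state$phase
  state$phase <- "ASSIST"
  add_event(state, "ASSIST", list(note = "staff assistance requested"))
}

#' @rdname request_assist
#' @export
resume_exam <- function(state) {
  if (state$phase != "ASSIST") stop_domain("session is not paused")
  state$phase <- state$resume_phase
  state$resume_phase <- NULL
  add_event(state, "ASSIST", list(note = "session resumed"))
}

#' Session summary report
#'
#' @param state An `exam_state` (normally COMPLETE; otherwise the report is
#'   flagged aborted).
#' @return An object of class `session_report`: session id, per-phase
#'   [va_score()]s, per-phase durations (seconds, from event timestamps),
#'   event counts by kind, and the full event log.
#' @export
generate_report <- function(state) {
  ev <- state$events
  phases <- vapply(ev, `[[`, character(1), "phase")
  times <- vapply(ev, `[[`, numeric(1), "t")
  kinds <- vapply(ev, `[[`, character(1), "kind")
  durations <- vapply(names(state$scores), function(p) {
    tt <- times[phases == p]
    if (length(tt)) diff(range(tt)) else 0
  }, numeric(1))
  structure(
    list(session_id = state$session_id,
         aborted = state$phase != "COMPLETE",
         scores = state$scores,
         durations_s = durations,
         event_counts = table(kinds),
         seed = state$seed,
         events = ev),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report %s>%s\n", x$session_id,
              if (x$aborted) " [ABORTED]" else ""))
  for (p in names(x$scores))
    cat(sprintf("  %-14s %-16s logMAR %6.3f  (%gs)\n", p,
                format(x$scores[[p]]), x$scores[[p]]$logmar,
                x$durations_s[[p]]))
  invisible(x)
}

#' One CSV row per eye for the agreement-statistics suite
#'
#' @param report A `session_report`.
#' @return data.frame with columns `session_id`, `eye`, `unaided_logmar`,
#'   `pinhole_logmar`, `duration_s`.
#' @export
report_to_csv_rows <- function(report) {
  eye_row <- function(eye, unaided, pinhole) {
    data.frame(
      session_id = report$session_id, eye = eye,
      unaided_logmar = if (is.null(unaided)) NA_real_ else unaided$logmar,
      pinhole_logmar = if (is.null(pinhole)) NA_real_ else pinhole$logmar,
      duration_s = sum(report$durations_s[grepl(
        if (eye == "OD") "^RIGHT" else "^LEFT", names(report$durations_s))]),
      stringsAsFactors = FALSE)
  }
  rbind(eye_row("OD", report$scores[["RIGHT_UNAIDED"]],
                report$scores[["RIGHT_PINHOLE"]]),
        eye_row("OS", report$scores[["LEFT_UNAIDED"]],
                report$scores[["LEFT_PINHOLE"]]))
}
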