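#' End-to-end sessions: simulated, interactive, and pose-table validation
#'
#' The session runner wires the exam engine to a response source (simulated
#' patient through the recognizer contract, or terminal input) and to the
#' pose engine, producing a JSON-Lines event log and a summary report.  It
#' is a deterministic single-threaded event loop: same configuration and
#' seed, byte-identical log.
#'
#' @name session_cli
NULL

POSE_FIXTURE_FOR_LABEL <- c(Left = 1L, Right = 2L, Left_ph = 3L, Right_ph = 4L)

event_to_json <- function(ev) {
  jsonlite::toJSON(ev, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Serialise a session's event log as JSON Lines
#'
#' One event per line, fields `t`, `phase`, `kind`, `payload`.
#'
#' @param report A `session_report` (or `exam_state`).
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of JSON lines (invisibly when written).
#' @export
session_log_lines <- function(report, path = NULL) {
  lines <- vapply(report$events, function(e) as.character(event_to_json(e)),
                  character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Run a fully simulated examination session
#'
#' Drives the exam engine with responses from a [patient_profile()].  With
#' `recognizer = "mock"` each response is rendered to text, passed through
#' the deterministic mock recognizer and re-parsed under the vocabulary
#' constraint — the same path a live microphone transcript would take; the
#' `"direct"` path injects parsed symbols straight into the engine.  Before
#' every stimulus the required occluder pose is synthesised and checked
#' through the pose engine; `pose_error_rate` injects invalid frames that
#' pause the exam with a guidance event.
#'
#' @param profile A [patient_profile()].
#' @param chart A [chart_spec()].
#' @param seed Session seed (drives rows, responses, pose jitter).
#' @param session_id Session identifier string.
#' @param recognizer `"direct"` or `"mock"`.
#' @param log_path,report_path Optional output paths (JSONL log, JSON
#'   report).
#' @param max_events Safety bound on the event loop.
#' @return A `session_report`.
#' @export
run_simulated_session <- function(profile, chart = default_chart(),
                                  seed = 1L, session_id = "sim-1",
                                  recognizer = c("direct", "mock"),
                                  log_path = NULL, report_path = NULL,
                                  max_events = 2000L) {
  recognizer <- match.arg(recognizer)
  stopifnot(inherits(profile, "patient_profile"))
  state <- start_exam(chart, seed = derive_seed(seed, 1L),
                      session_id = session_id)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  set.seed(derive_seed(seed, 2L))
  pose_seed <- derive_seed(seed, 3L)
  frame <- 0L
  n_ev <- 0L
  while (state$phase %in% ACTIVE_PHASES && n_ev < max_events) {
    n_ev <- n_ev + 1L
    # pose check before each presentation
    frame <- frame + 1L
    bad_pose <- profile$pose_error_rate > 0 &&
      stats::runif(1) < profile$pose_error_rate
    if (bad_pose) {
      cls <- classify_pose(synth_pose_fixture(9L, seed = pose_seed + frame))
      stopifnot(!isTRUE(gate_on_pose(state, cls)))
      state <- add_event(state, "POSE",
                         list(label = cls$label, gate = "paused",
                              required = state$required_pose))
      frame <- frame + 1L
    }
    fixture_id <- POSE_FIXTURE_FOR_LABEL[[state$required_pose]]
    cls <- classify_pose(synth_pose_fixture(fixture_id, seed = pose_seed + frame))
    if (!isTRUE(gate_on_pose(state, cls)))
      stop_domain("pose fixture failed to satisfy gate for ",
                  state$required_pose)
    state <- add_event(state, "POSE", list(label = cls$label, gate = "ok"))
    stim <- next_stimulus(state)
    state <- add_event(state, "STIMULUS",
                       list(kind = stim$kind, line = format(stim$line),
                            symbols = paste(stim$symbols, collapse = " ")))
    resp <- respond(stim, profile, state$phase, chart$vocab)
    if (recognizer == "mock") {
      rec <- mock_recognizer(format(resp), seed = derive_seed(seed, 100L + n_ev))
      tr <- rec()
      toks <- normalize_transcript(tr, vocab_mode = chart$vocab_mode)
      resp <- parse_response(toks, chart$vocab)
    }
    state <- apply_response(state, resp)
    if (state$phase_done) state <- advance_phase(state)
  }
  report <- generate_report(state)
  if (!is.null(log_path)) session_log_lines(report, log_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(report_summary_list(report), report_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

report_summary_list <- function(report) {
  scores <- lapply(report$scores, function(s)
    list(snellen = format(s), logmar = s$logmar,
         worse_than_chart = s$worse_than_chart))
  list(session_id = report$session_id, aborted = report$aborted,
       seed = report$seed, scores = scores,
       durations_s = as.list(report$durations_s),
       event_counts = as.list(unclass(report$event_counts)))
}

#' Run an interactive text-mode session
#'
#' Prompts on the terminal: stimuli are printed, responses typed (symbols
#' separated by spaces, or the commands ok / blurred / skip / repeat).
#' End-of-input aborts the session, which is then reported as aborted.
#'
#' @param chart A [chart_spec()].
#' @param seed Session seed.
#' @param session_id Session identifier.
#' @param con Input connection (defaults to [stdin()]).
#' @return A `session_report`.
#' @export
run_interactive_session <- function(chart = default_chart(), seed = 1L,
                                    session_id = "interactive-1",
                                    con = stdin()) {
  state <- start_exam(chart, seed = derive_seed(seed, 1L),
                      session_id = session_id)
  cat("Say OK to begin.\n")
  repeat {
    if (state$phase == "INSTRUCT") {
      line <- readLines(con, n = 1L)
      if (!length(line)) return(generate_report(state))
      state <- apply_response(state,
                              parse_response(normalize_transcript(line,
                                chart$vocab_mode), chart$vocab))
      next
    }
    if (!state$phase %in% ACTIVE_PHASES) break
    stim <- next_stimulus(state)
    cat(sprintf("[%s] %s -> ", state$phase, format(stim)))
    line <- readLines(con, n = 1L)
    if (!length(line)) {
      cat("\n(end of input: aborting session)\n")
      return(generate_report(state))
    }
    resp <- parse_response(normalize_transcript(line, chart$vocab_mode),
                           chart$vocab)
    state <- apply_response(state, resp)
    if (state$phase_done) state <- advance_phase(state)
  }
  report <- generate_report(state)
  print(report)
  report
}

#' Validate the pose engine against the golden nine-pose table
#'
#' Synthesises the nine occluder poses (four valid, five faults) across
#' `seeds` jitter seeds and classifies each through [classify_pose()],
#' comparing against the expected final-pose column.
#'
#' @param seeds Number of jitter seeds per pose (default 1).
#' @return data.frame with one row per pose: `pose_id`, `validity`, `pose`,
#'   `detected_ids`, `expected`, `got` (unique observed labels), `matches`
#'   out of `seeds`.  Attribute `"all_match"` is `TRUE` when every check
#'   agrees.
#' @export
validate_pose_table <- function(seeds = 1L) {
  tab <- pose_table()
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    got <- vapply(seq_len(seeds), function(s)
      classify_pose(synth_pose_fixture(tab$pose_id[i], seed = s))$label,
      character(1))
    data.frame(pose_id = tab$pose_id[i], validity = tab$validity[i],
               pose = tab$pose[i],
               detected_ids = paste(tab$ids[[i]], collapse = ","),
               expected = tab$expected[i],
               got = paste(unique(got), collapse = "/"),
               matches = sum(got == tab$expected[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_match") <- all(out$matches == seeds)
  out
}
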