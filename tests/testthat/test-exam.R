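test_that("exam waits for OK confirmation before starting", {
  state <- start_exam(default_chart(), seed = 7)
  expect_identical(state$phase, "INSTRUCT")
  state <- apply_response(state, parsed_response("SYMBOLS", symbols = "C"))
  expect_identical(state$phase, "INSTRUCT")
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  expect_identical(state$phase, "RIGHT_UNAIDED")
  expect_identical(state$mode, "SINGLE")
  stim <- next_stimulus(state)
  expect_identical(stim$kind, "SINGLE_OPTOTYPE")
  expect_equal(stim$line$denominator, 120)  # largest optotype first
  expect_length(stim$symbols, 1L)
})

test_that("single mode shows one symbol, row mode the full row", {
  chart <- default_chart()
  state <- start_exam(chart, seed = 3)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  s1 <- next_stimulus(state)
  expect_identical(s1$symbols, state$rows$RIGHT_UNAIDED[[1]]$symbols[1])
  # fail the first single on line 2: row anchors at line 1 (last single pass)
  state <- apply_response(state, parsed_response("SYMBOLS",
                                                 symbols = s1$symbols))
  s2 <- next_stimulus(state)
  wrong <- setdiff(chart$vocab, s2$symbols[1])[1]
  state <- apply_response(state, parsed_response("SYMBOLS", symbols = wrong))
  expect_identical(state$mode, "ROW")
  expect_identical(state$line_idx, 1L)
  s3 <- next_stimulus(state)
  expect_identical(s3$kind, "FULL_ROW")
  expect_length(s3$symbols, 5L)
})

test_that("identical seeds replay identical stimulus sequences", {
  resp <- threshold_responder(0.301, 0.0)
  r1 <- drive_exam(resp, seed = 11, collect_stimuli = TRUE)
  r2 <- drive_exam(resp, seed = 11, collect_stimuli = TRUE)
  expect_identical(attr(r1, "stimuli"), attr(r2, "stimuli"))
})

test_that("row pass rule is strictly more than half, for every tally", {
  chart <- default_chart()
  for (n_correct in 0:5) {
    # drive one phase to a 6/60 row, answer with exactly n_correct correct
    state <- start_exam(chart, seed = 2)
    state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
    # pass single at 6/120, fail single at 6/60 -> row anchored at 6/120
    state <- apply_response(state, parsed_response(
      "SYMBOLS", symbols = next_stimulus(state)$symbols))
    wrong1 <- setdiff(chart$vocab, next_stimulus(state)$symbols[1])[1]
    state <- apply_response(state, parsed_response("SYMBOLS", symbols = wrong1))
    row <- next_stimulus(state)$symbols
    ans <- vapply(seq_along(row), function(i) {
      if (i <= n_correct) row[i] else setdiff(chart$vocab, row[i])[1]
    }, character(1))
    state <- apply_response(state, parsed_response("SYMBOLS", symbols = ans))
    passes <- n_correct > 2.5
    if (passes) {
      expect_false(state$phase_done, info = n_correct)
      expect_identical(state$line_idx, 2L)  # advanced to next smaller row
    } else {
      # anchor row failed at the top line -> worse than chart
      expect_true(state$phase_done, info = n_correct)
      expect_true(finalize_phase(state)$worse_than_chart)
    }
  }
})

test_that("REPEAT re-presents the identical stimulus without tallying", {
  state <- start_exam(default_chart(), seed = 4)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  before <- next_stimulus(state)
  state <- apply_response(state, parsed_response("COMMAND", command = "REPEAT"))
  after <- next_stimulus(state)
  expect_identical(before, after)
  expect_identical(state$mode, "SINGLE")
  expect_identical(state$line_idx, 1L)
})

test_that("out-of-vocabulary symbols are rejected with a re-prompt, not tallied", {
  state <- start_exam(default_chart(), seed = 4)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  before <- next_stimulus(state)
  state <- apply_response(state, parsed_response("SYMBOLS", symbols = "Q"))
  expect_identical(next_stimulus(state), before)
})

test_that("deterministic threshold patients recover every chart line exactly", {
  chart <- default_chart()
  for (i in seq_along(chart$lines)) {
    L <- chart$lines[[i]]$logmar
    for (eye in c("right", "left")) {
      resp <- if (eye == "right") threshold_responder(L, 0)
              else threshold_responder(0, L)
      rep <- drive_exam(resp, chart = chart, seed = 20 + i)
      sc <- rep$scores[[if (eye == "right") "RIGHT_UNAIDED" else "LEFT_UNAIDED"]]
      expect_false(sc$worse_than_chart)
      expect_equal(sc$line$logmar, L, info = paste(eye, format(chart$lines[[i]])))
      expect_identical(sc$adjustment, 0L)
    }
  }
})

test_that("adjustments: misses on the recorded line and extras on the next", {
  chart <- default_chart()
  # responder scripted per (line, mode): threshold at 6/9 with m misses on the
  # 6/9 row and k correct on the 6/6 row
  run_mk <- function(m, k) {
    responder <- function(state, stim) {
      lm9 <- snellen_to_logmar(9, 0)
      if (stim$kind == "SINGLE_OPTOTYPE") {
        ok <- stim$line$logmar >= lm9 - 1e-9
        syms <- if (ok) stim$symbols else setdiff(state$chart$vocab, stim$symbols)[1]
        return(parsed_response("SYMBOLS", symbols = syms))
      }
      n_ok <- if (abs(stim$line$logmar - lm9) < 1e-9) 5L - m
              else if (stim$line$logmar < lm9) k
              else 5L
      syms <- vapply(seq_along(stim$symbols), function(i) {
        if (i <= n_ok) stim$symbols[i]
        else setdiff(state$chart$vocab, stim$symbols[i])[1]
      }, character(1))
      parsed_response("SYMBOLS", symbols = syms)
    }
    drive_exam(responder, chart = chart, seed = 31)$scores$RIGHT_UNAIDED
  }
  # enumerate all (m, k) combinations: m misses in 0..2, k extras in 0..2
  for (m in 0:2) for (k in 0:2) {
    sc <- run_mk(m, k)
    expect_equal(sc$line$denominator, 9, info = sprintf("m=%d k=%d", m, k))
    expected_adj <- if (m > 0) -m else if (k > 0) k else 0
    expect_identical(sc$adjustment, as.integer(expected_adj),
                     info = sprintf("m=%d k=%d", m, k))
    expect_equal(sc$logmar, snellen_to_logmar(9, expected_adj))
  }
  # worked examples: "6/9 -1" takes precedence, "6/12 +2" from a clean row
  expect_equal(format(run_mk(1, 1)), "6/9 -1")
})

test_that("a clean 6/12 row followed by 2 letters on 6/9 scores 6/12 +2", {
  chart <- default_chart()
  lm12 <- snellen_to_logmar(12, 0)
  responder <- function(state, stim) {
    if (stim$kind == "SINGLE_OPTOTYPE") {
      ok <- stim$line$logmar >= lm12 - 1e-9
      syms <- if (ok) stim$symbols else setdiff(state$chart$vocab, stim$symbols)[1]
      return(parsed_response("SYMBOLS", symbols = syms))
    }
    n_ok <- if (stim$line$logmar >= lm12 - 1e-9) 5L else 2L
    syms <- vapply(seq_along(stim$symbols), function(i) {
      if (i <= n_ok) stim$symbols[i]
      else setdiff(state$chart$vocab, stim$symbols[i])[1]
    }, character(1))
    parsed_response("SYMBOLS", symbols = syms)
  }
  rep <- drive_exam(responder, chart = chart, seed = 33)
  expect_equal(format(rep$scores$RIGHT_UNAIDED), "6/12 +2")
  expect_equal(rep$scores$RIGHT_UNAIDED$logmar, snellen_to_logmar(12, 2))
})

test_that("pinhole trigger is strict: worse than 6/9 only", {
  chart <- default_chart()
  expect_true(pinhole_needed(va_score(optotype_line(12)), chart))
  expect_false(pinhole_needed(va_score(optotype_line(9)), chart))
  expect_false(pinhole_needed(va_score(optotype_line(6)), chart))
  # adjustment participates in the comparison
  expect_true(pinhole_needed(va_score(optotype_line(9), -1L), chart))
  expect_false(pinhole_needed(va_score(optotype_line(9), 1L), chart))
  expect_true(pinhole_needed(va_score(NULL, chart = chart,
                                      worse_than_chart = TRUE), chart))
})

test_that("phase order runs right eye first and pinhole only when triggered", {
  # both eyes 6/6: two phases, no pinhole
  rep <- drive_exam(threshold_responder(0, 0), seed = 41)
  expect_setequal(names(rep$scores), c("RIGHT_UNAIDED", "LEFT_UNAIDED"))
  # right 6/18, left 6/6: right pinhole only
  rep <- drive_exam(threshold_responder(snellen_to_logmar(18), 0), seed = 42)
  expect_setequal(names(rep$scores),
                  c("RIGHT_UNAIDED", "LEFT_UNAIDED", "RIGHT_PINHOLE"))
  # both worse than 6/9: all four phases
  rep <- drive_exam(threshold_responder(snellen_to_logmar(24),
                                        snellen_to_logmar(12)), seed = 43)
  expect_setequal(names(rep$scores), ACTIVE)
  phases <- vapply(rep$events, `[[`, character(1), "phase")
  first_seen <- phases[!duplicated(phases)]
  active_order <- intersect(first_seen, ACTIVE)
  expect_identical(active_order, c("RIGHT_UNAIDED", "LEFT_UNAIDED",
                                   "RIGHT_PINHOLE", "LEFT_PINHOLE"))
})

test_that("monotone thresholds yield monotone measured acuities", {
  set.seed(55)
  thresholds <- sort(runif(6, -0.05, 1.35))
  measured <- vapply(thresholds, function(L)
    drive_exam(threshold_responder(L, 0), seed = 56)$scores$RIGHT_UNAIDED$logmar,
    numeric(1))
  expect_true(all(diff(measured) >= -1e-12))
})

test_that("a patient who cannot read the top single is worse than chart", {
  chart <- default_chart()
  rep <- drive_exam(threshold_responder(2.0, 0), seed = 61)
  sc <- rep$scores$RIGHT_UNAIDED
  expect_true(sc$worse_than_chart)
  expect_equal(sc$logmar, log10(120 / 6) + 0.1)
  expect_identical(format(sc), "worse than chart")
})

test_that("no smaller line after a failed row; SINGLE never re-entered", {
  set.seed(77)
  chart <- default_chart()
  for (trial in 1:30) {
    responder <- function(state, stim) {
      syms <- vapply(stim$symbols, function(s) {
        if (runif(1) < 0.5) s else setdiff(chart$vocab, s)[1]
      }, character(1))
      parsed_response("SYMBOLS", symbols = syms)
    }
    rep <- drive_exam(responder, chart = chart, seed = 70 + trial,
                      collect_stimuli = TRUE)
    stims <- attr(rep, "stimuli")
    for (ph in unique(vapply(stims, `[[`, character(1), "phase"))) {
      ph_stims <- Filter(function(s) s$phase == ph, stims)
      modes <- vapply(ph_stims, `[[`, character(1), "mode")
      # once in ROW mode, never back to SINGLE
      expect_true(all(diff(match(modes, c("SINGLE", "ROW"))) >= 0), info = ph)
      rows <- Filter(function(s) s$mode == "ROW", ph_stims)
      if (length(rows) >= 2) {
        dens <- vapply(rows, function(s) s$stim$line$denominator, numeric(1))
        lms <- log10(dens / 6)
        # a smaller (harder) row is only ever presented after a passed row,
        # and line changes move by one chart step at a time
        expect_true(all(abs(diff(match(dens, c(120, 60, 36, 24, 18, 12, 9, 6)))) <= 1),
                    info = ph)
      }
    }
    expect_false(rep$aborted)
  }
})

test_that("exam terminates within the event bound for any response sequence", {
  set.seed(88)
  chart <- default_chart()
  bound <- (2 * 8 + 8 * 5) * 4  # (2 x lines + rows x row_length) x phases
  for (trial in 1:20) {
    responder <- function(state, stim) {
      p <- runif(1)
      if (p < 0.1) return(parsed_response("COMMAND", command = "BLURRED"))
      syms <- vapply(stim$symbols, function(s) {
        if (runif(1) < 0.6) s else setdiff(chart$vocab, s)[1]
      }, character(1))
      parsed_response("SYMBOLS", symbols = syms)
    }
    rep <- drive_exam(responder, chart = chart, seed = 90 + trial)
    expect_false(rep$aborted)
    n_resp <- sum(vapply(rep$events, `[[`, character(1), "kind") == "RESPONSE")
    expect_lte(n_resp, bound)
  }
})

test_that("pinhole phases restart two lines above the unaided achieved line", {
  chart <- default_chart()
  lm24 <- snellen_to_logmar(24)
  rep <- drive_exam(threshold_responder(lm24, 0, right_ph = 0), seed = 95,
                    collect_stimuli = TRUE)
  stims <- attr(rep, "stimuli")
  ph <- Filter(function(s) s$phase == "RIGHT_PINHOLE", stims)
  # unaided achieved 6/24 (index 4) -> pinhole starts at 6/60 (index 2)
  expect_equal(ph[[1]]$stim$line$denominator, 60)
  expect_identical(ph[[1]]$stim$kind, "SINGLE_OPTOTYPE")
  expect_equal(rep$scores$RIGHT_PINHOLE$logmar, 0)
})

test_that("gate_on_pose admits only the phase-required pose", {
  state <- start_exam(default_chart(), seed = 5)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  expect_true(gate_on_pose(state, "Right"))
  g <- gate_on_pose(state, "Invalid")
  expect_false(as.logical(g))
  expect_identical(attr(g, "required"), "Right")
  expect_false(as.logical(gate_on_pose(state, "Left")))
  cls <- classify_pose(synth_pose_fixture(2, seed = 1))
  expect_true(gate_on_pose(state, cls))
})

test_that("assist pauses and resumes without losing the pending stimulus", {
  state <- start_exam(default_chart(), seed = 6)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  before <- next_stimulus(state)
  state <- request_assist(state)
  expect_identical(state$phase, "ASSIST")
  expect_error(next_stimulus(state), "no stimulus")
  state <- resume_exam(state)
  expect_identical(state$phase, "RIGHT_UNAIDED")
  expect_identical(next_stimulus(state), before)
})

test_that("report conserves phase scores and flags incomplete sessions", {
  resp <- threshold_responder(snellen_to_logmar(12), 0,
                              right_ph = snellen_to_logmar(9))
  rep <- drive_exam(resp, seed = 99)
  expect_false(rep$aborted)
  expect_equal(rep$scores$RIGHT_UNAIDED$logmar, snellen_to_logmar(12))
  expect_equal(rep$scores$RIGHT_PINHOLE$logmar, snellen_to_logmar(9))
  expect_true(all(rep$durations_s >= 0))
  rows <- report_to_csv_rows(rep)
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$unaided_logmar[rows$eye == "OD"],
               rep$scores$RIGHT_UNAIDED$logmar)
  expect_equal(rows$pinhole_logmar[rows$eye == "OS"], NA_real_)
  # aborted path
  state <- start_exam(default_chart(), seed = 1)
  partial <- generate_report(state)
  expect_true(partial$aborted)
})
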