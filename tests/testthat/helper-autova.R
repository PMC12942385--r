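# Shared fixtures and independent oracles, built in code at test time.

ACTIVE <- c("RIGHT_UNAIDED", "LEFT_UNAIDED", "RIGHT_PINHOLE", "LEFT_PINHOLE")

# Deterministic threshold responder: reads any optotype whose logMAR is at
# or above the eye/condition threshold, fails everything smaller.
threshold_responder <- function(right, left, right_ph = right, left_ph = left) {
  thr <- c(RIGHT_UNAIDED = right, LEFT_UNAIDED = left,
           RIGHT_PINHOLE = right_ph, LEFT_PINHOLE = left_ph)
  function(state, stim) {
    ok <- stim$line$logmar >= thr[[state$phase]] - 1e-9
    syms <- if (ok) stim$symbols
            else vapply(stim$symbols,
                        function(s) setdiff(state$chart$vocab, s)[1],
                        character(1))
    parsed_response("SYMBOLS", symbols = syms)
  }
}

# Drive a whole exam with a responder(state, stimulus) -> parsed_response.
drive_exam <- function(responder, chart = default_chart(), seed = 1L,
                       collect_stimuli = FALSE) {
  state <- start_exam(chart, seed = seed)
  state <- apply_response(state, parsed_response("COMMAND", command = "OK"))
  stimuli <- list()
  guard <- 0L
  while (state$phase %in% ACTIVE) {
    guard <- guard + 1L
    stopifnot(guard < 1000L)
    stim <- next_stimulus(state)
    if (collect_stimuli)
      stimuli[[length(stimuli) + 1L]] <-
        list(phase = state$phase, mode = state$mode, stim = stim)
    state <- apply_response(state, responder(state, stim))
    if (state$phase_done) state <- advance_phase(state)
  }
  rep <- generate_report(state)
  if (collect_stimuli) attr(rep, "stimuli") <- stimuli
  rep
}

# Exhaustive edit-script enumeration: walks every monotone alignment path
# and returns the minimum cost and, among minimum-cost scripts, the maximum
# substitution count (the tie-break the aligner must honour).
wer_enum_oracle <- function(ref, hyp) {
  best <- NULL
  rec <- function(i, j, S, I, D) {
    if (i > length(ref) && j > length(hyp)) {
      cost <- S + I + D
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && S > best$S))
        best <<- list(cost = cost, S = S, I = I, D = D)
      return(invisible(NULL))
    }
    if (i <= length(ref) && j <= length(hyp))
      rec(i + 1L, j + 1L, S + (ref[i] != hyp[j]), I, D)
    if (i <= length(ref)) rec(i + 1L, j, S, I, D + 1L)
    if (j <= length(hyp)) rec(i, j + 1L, S, I + 1L, D)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  best
}

# All token sequences of length n over an alphabet.
all_seqs <- function(n, alphabet) {
  if (n == 0L) return(list(character()))
  g <- do.call(expand.grid, c(rep(list(alphabet), n), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
}

# Exact signed-rank two-sided p by full 2^n enumeration of sign assignments.
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(grid %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Expected golden pose table (id set -> final pose) used across tests.
golden_expected <- c("Left", "Right", "Left_ph", "Right_ph",
                     "Invalid", "Invalid", "Left", "Right", "Invalid")
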