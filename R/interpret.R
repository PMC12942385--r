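#' Vocabulary-constrained response interpretation and WER
#'
#' Recognizer backends deliver free-text transcripts; the interpreter
#' canonicalises them against the restricted test vocabulary (nine letters or
#' the digits 0-9 plus the commands OK / BLURRED / SKIP / REPEAT), and the
#' word error rate (WER) quantifies recognizer quality:
#' `WER = 100 (S + I + D) / N` from a minimum-edit alignment with unit costs.
#'
#' @name response_interpreter
NULL

#' Construct a transcript
#'
#' @param text Raw recognizer text.
#' @param segment_start_s,segment_end_s Segment boundaries in seconds
#'   (`end >= start`).
#' @param backend_id Identifier of the producing backend.
#' @return An object of class `transcript`.
#' @export
transcript <- function(text, segment_start_s = 0, segment_end_s = 0,
                       backend_id = "unknown") {
  if (segment_end_s < segment_start_s)
    stop_domain("segment end before start")
  structure(list(text = as.character(text),
                 segment_start_s = segment_start_s,
                 segment_end_s = segment_end_s,
                 backend_id = backend_id),
            class = "transcript")
}

default_homophones <- function() {
  path <- system.file("extdata", "homophones.csv", package = "autova")
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Normalise a transcript into canonical tokens
#'
#' Uppercases, strips punctuation, splits on whitespace, and maps spelled-out
#' homophones ("bee" -> B; "zero" -> 0; "oh" -> 0 in NUMBERS mode) through a
#' configurable table.  Tokens that map to nothing are retained but tagged
#' unknown (attribute `"unknown"`, a logical vector).  Idempotent.
#'
#' @param x A [transcript()] or a character string.
#' @param vocab_mode `"LETTERS"` or `"NUMBERS"` (selects mode-specific
#'   homophone rows).
#' @param homophones Data frame with columns `spoken`, `symbol`, `mode`
#'   (`ALL`, `LETTERS` or `NUMBERS`); defaults to the shipped table.
#' @return Character vector of tokens with attribute `"unknown"`.
#' @examples
#' normalize_transcript("c d h")
#' normalize_transcript("zero five", vocab_mode = "NUMBERS")
#' @export
normalize_transcript <- function(x, vocab_mode = c("LETTERS", "NUMBERS"),
                                 homophones = default_homophones()) {
  vocab_mode <- match.arg(vocab_mode)
  text <- if (inherits(x, "transcript")) x$text else as.character(x)
  text <- toupper(paste(text, collapse = " "))
  text <- gsub("[^A-Z0-9 ]+", " ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks))
    return(structure(character(), unknown = logical()))
  tab <- homophones[homophones$mode %in% c("ALL", vocab_mode), , drop = FALSE]
  map <- stats::setNames(tab$symbol, tab$spoken)
  out <- character(length(toks)); unknown <- logical(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[i]
    if (tk %in% COMMAND_WORDS) {
      out[i] <- tk
    } else if (tk %in% names(map)) {
      out[i] <- unname(map[tk])
    } else if (grepl("^[A-Z0-9]$", tk)) {
      out[i] <- tk
    } else {
      out[i] <- tk; unknown[i] <- TRUE
    }
  }
  structure(out, unknown = unknown)
}

#' Construct a parsed response
#'
#' @param kind `"SYMBOLS"` or `"COMMAND"`.
#' @param symbols Character vector of vocabulary symbols (kind `"SYMBOLS"`).
#' @param command One of `"OK"`, `"BLURRED"`, `"SKIP"`, `"REPEAT"`.
#' @param reason Optional tag explaining a fallback (e.g. `"ambiguous"`).
#' @return An object of class `parsed_response`.
#' @export
parsed_response <- function(kind = c("SYMBOLS", "COMMAND"), symbols = NULL,
                            command = NULL, reason = NULL) {
  kind <- match.arg(kind)
  if (kind == "SYMBOLS") {
    stopifnot(is.character(symbols), length(symbols) >= 1L)
    command <- NULL
  } else {
    command <- match.arg(command, COMMAND_WORDS)
    symbols <- NULL
  }
  structure(list(kind = kind, symbols = symbols, command = command,
                 reason = reason), class = "parsed_response")
}

#' @export
format.parsed_response <- function(x, ...) {
  if (x$kind == "SYMBOLS") paste(x$symbols, collapse = " ") else x$command
}

#' Parse normalised tokens into an exam response
#'
#' A command word in a token list containing no vocabulary symbols yields a
#' COMMAND response; otherwise the vocabulary symbols (unknown tokens
#' dropped) form a SYMBOLS response.  A mix of command and symbols is
#' ambiguous and, like empty usable content, surfaces as a REPEAT re-prompt.
#'
#' @param tokens Output of [normalize_transcript()] (or plain character).
#' @param vocab Active vocabulary (character vector of single symbols).
#' @return A [parsed_response()].
#' @export
parse_response <- function(tokens, vocab) {
  tokens <- as.character(tokens)
  cmds <- tokens[tokens %in% COMMAND_WORDS]
  syms <- tokens[tokens %in% vocab]
  if (length(cmds) && length(syms))
    return(parsed_response("COMMAND", command = "REPEAT", reason = "ambiguous"))
  if (length(cmds))
    return(parsed_response("COMMAND", command = cmds[[1L]]))
  if (length(syms))
    return(parsed_response("SYMBOLS", symbols = syms))
  parsed_response("COMMAND", command = "REPEAT", reason = "empty")
}

#' Word error rate from a minimum-edit alignment
#'
#' Dynamic-programming alignment with unit substitution/insertion/deletion
#' costs; cost ties are resolved preferring substitutions over
#' insertion+deletion pairs.  `WER = 100 (S + I + D) / N`, where `N` is the
#' reference length; values above 100 are possible.
#'
#' @param reference Character vector of reference tokens (non-empty).
#' @param hypothesis Character vector of hypothesis tokens.
#' @return An object of class `wer_result`: list with integers `S`, `I`,
#'   `D`, `N` and `wer_percent`.
#' @examples
#' wer(c("A", "B", "C"), c("A", "X", "C"))  # S=1, WER 33.33
#' @export
wer <- function(reference, hypothesis) {
  ref <- as.character(reference); hyp <- as.character(hypothesis)
  m <- length(ref); n <- length(hyp)
  if (m == 0L) stop_domain("reference must be non-empty")
  # C[i+1, j+1] = min edit cost for ref[1..i] vs hyp[1..j]; Smax tracks the
  # maximum substitution count among minimum-cost alignments (lexicographic
  # objective, additive along the alignment path).
  C <- matrix(0L, m + 1L, n + 1L)
  Smax <- matrix(0L, m + 1L, n + 1L)
  C[, 1L] <- 0:m
  C[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- ref[i] != hyp[j]
      cd <- C[i, j] + as.integer(sub)
      cdel <- C[i, j + 1L] + 1L
      cins <- C[i + 1L, j] + 1L
      best <- min(cd, cdel, cins)
      s <- -1L
      if (cd == best) s <- Smax[i, j] + as.integer(sub)
      if (cdel == best) s <- max(s, Smax[i, j + 1L])
      if (cins == best) s <- max(s, Smax[i + 1L, j])
      C[i + 1L, j + 1L] <- best
      Smax[i + 1L, j + 1L] <- s
    }
  }
  cost <- C[m + 1L, n + 1L]
  S <- Smax[m + 1L, n + 1L]
  I <- (cost - S - (m - n)) %/% 2L
  D <- I + (m - n)
  structure(list(S = S, I = I, D = D, N = m,
                 wer_percent = 100 * (S + I + D) / m),
            class = "wer_result")
}

#' @export
format.wer_result <- function(x, ...) {
  sprintf("WER %.2f%% (S=%d I=%d D=%d N=%d)", x$wer_percent, x$S, x$I, x$D, x$N)
}

#' @export
print.wer_result <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Evaluate WER over files of reference/hypothesis utterances
#'
#' One utterance per line, whitespace-separated tokens; lines are paired.
#'
#' @param ref_path,hyp_path Text files with equal line counts.
#' @return A data.frame with one row per utterance plus a pooled row
#'   (`line = "pooled"`), columns `S`, `I`, `D`, `N`, `wer_percent`.
#' @export
wer_files <- function(ref_path, hyp_path) {
  refs <- readLines(ref_path); hyps <- readLines(hyp_path)
  if (length(refs) != length(hyps))
    stop_domain("reference and hypothesis files differ in line count")
  rows <- lapply(seq_along(refs), function(i) {
    r <- wer(strsplit(trimws(refs[i]), "\\s+")[[1]],
             strsplit(trimws(hyps[i]), "\\s+")[[1]])
    data.frame(line = as.character(i), S = r$S, I = r$I, D = r$D, N = r$N,
               wer_percent = r$wer_percent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- colSums(out[, c("S", "I", "D", "N")])
  rbind(out, data.frame(line = "pooled", S = pooled["S"], I = pooled["I"],
                        D = pooled["D"], N = pooled["N"],
                        wer_percent = 100 * sum(pooled[c("S", "I", "D")]) / pooled["N"],
                        row.names = NULL, stringsAsFactors = FALSE))
}

#' Deterministic mock speech-recognizer backend
#'
#' Stands in for the VAD + ASR pipeline contract (audio stream -> transcript
#' stream).  Each call to the returned function yields the next
#' [transcript()] from the script, with per-token confusions applied by a
#' seeded generator: substitution within a confusion set at `sub_rate`, token
#' drops at `drop_rate`, duplications at `dup_rate`.  With all rates zero the
#' transcripts equal the scripted utterances exactly.
#'
#' @param script Character vector of true utterances (whitespace-separated
#'   tokens).
#' @param seed Integer seed; output is a pure function of `script` and
#'   `seed`.
#' @param confusions Named list mapping a token to its candidate
#'   substitutions; tokens without an entry are never substituted.
#' @param sub_rate,drop_rate,dup_rate Per-token probabilities in `[0, 1]`.
#' @return A function `()` returning the next `transcript`, or `NULL` when
#'   the script is exhausted.
#' @export
mock_recognizer <- function(script, seed = 1L, confusions = list(),
                            sub_rate = 0, drop_rate = 0, dup_rate = 0) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, drop_rate >= 0, drop_rate <= 1,
            dup_rate >= 0, dup_rate <= 1)
  i <- 0L
  t0 <- 0
  function() {
    i <<- i + 1L
    if (i > length(script)) return(NULL)
    toks <- strsplit(trimws(script[[i]]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    out <- with_seed(derive_seed(seed, i), {
      res <- character()
      for (tk in toks) {
        if (drop_rate > 0 && stats::runif(1) < drop_rate) next
        emit <- tk
        if (sub_rate > 0 && stats::runif(1) < sub_rate) {
          cands <- confusions[[tk]]
          if (!is.null(cands) && length(cands))
            emit <- if (length(cands) == 1L) cands else sample(cands, 1L)
        }
        res <- c(res, emit)
        if (dup_rate > 0 && stats::runif(1) < dup_rate) res <- c(res, emit)
      }
      res
    })
    start <- t0; t0 <<- t0 + 2
    transcript(paste(out, collapse = " "), start, start + 1.5, "mock")
  }
}
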