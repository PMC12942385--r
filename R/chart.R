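#' Optotype chart model and Snellen/logMAR conversion
#'
#' The chart is an ordered set of Snellen lines, largest (6/120) to smallest
#' (6/6), each holding `row_length` optotypes drawn from a restricted
#' vocabulary (nine letters, or the digits 0-9).  Acuity is expressed either
#' as a Snellen fraction with a per-letter adjustment ("6/12 -1") or as
#' logMAR, where each letter on a 5-letter row is worth 0.02 logMAR.
#'
#' @name chart_model
NULL

# Sloan letter set minus "O" (avoids confusion with spoken "oh"/zero): the
# nine-letter vocabulary used by default.
SLOAN9 <- c("C", "D", "H", "K", "N", "R", "S", "V", "Z")

COMMAND_WORDS <- c("OK", "BLURRED", "SKIP", "REPEAT")

#' Construct an optotype line
#'
#' @param denominator Positive Snellen 6/x denominator in metre-equivalents.
#' @param row_length Number of optotypes on the full row (default 5).
#' @return An object of class `optotype_line` with fields `denominator`,
#'   `logmar` (`log10(denominator/6)`) and `row_length`.
#' @examples
#' optotype_line(12)
#' @export
optotype_line <- function(denominator, row_length = 5L) {
  if (!is_scalar_number(denominator) || denominator <= 0)
    stop_domain("`denominator` must be a positive number")
  row_length <- as.integer(row_length)
  if (is.na(row_length) || row_length < 1L)
    stop_domain("`row_length` must be >= 1")
  structure(
    list(denominator = as.numeric(denominator),
         logmar = log10(denominator / 6),
         row_length = row_length),
    class = "optotype_line")
}

#' @export
format.optotype_line <- function(x, ...) {
  den <- x$denominator
  den_chr <- if (den == round(den)) format(as.integer(den)) else format(den)
  paste0("6/", den_chr)
}

#' @export
print.optotype_line <- function(x, ...) {
  cat(format(x), sprintf("(logMAR %.3f)\n", x$logmar))
  invisible(x)
}

#' Construct a chart specification
#'
#' @param denominators Ordered Snellen denominators, largest to smallest.
#' @param vocab_mode `"LETTERS"` or `"NUMBERS"`.
#' @param vocab Optional character vector of allowed symbols; defaults to the
#'   nine-letter Sloan subset (letters) or `0:9` (numbers).
#' @param distance_m Test distance in metres, in `[4, 6]`.
#' @param row_length Optotypes per full row.
#' @return An object of class `chart_spec`.
#' @examples
#' default_chart()
#' @export
chart_spec <- function(denominators = c(120, 60, 36, 24, 18, 12, 9, 6),
                       vocab_mode = c("LETTERS", "NUMBERS"),
                       vocab = NULL,
                       distance_m = 6,
                       row_length = 5L) {
  vocab_mode <- match.arg(vocab_mode)
  if (length(denominators) < 1L || any(denominators <= 0))
    stop_domain("`denominators` must be positive")
  if (any(diff(denominators) >= 0))
    stop_domain("`denominators` must strictly decrease (largest line first)")
  if (!is_scalar_number(distance_m) || distance_m < 4 || distance_m > 6)
    stop_domain("`distance_m` must lie in [4, 6]")
  if (is.null(vocab))
    vocab <- if (vocab_mode == "LETTERS") SLOAN9 else as.character(0:9)
  vocab <- toupper(as.character(vocab))
  if (anyDuplicated(vocab)) stop_domain("`vocab` must not contain duplicates")
  ok <- if (vocab_mode == "LETTERS") grepl("^[A-Z]$", vocab) else grepl("^[0-9]$", vocab)
  if (!all(ok))
    stop_domain("`vocab` symbols must be single ", tolower(vocab_mode))
  lines <- lapply(denominators, optotype_line, row_length = row_length)
  if (any(vapply(lines, `[[`, 1, "row_length") > length(vocab)))
    stop_domain("vocabulary smaller than row length")
  structure(
    list(lines = lines, vocab_mode = vocab_mode, vocab = vocab,
         distance_m = distance_m),
    class = "chart_spec")
}

#' Default 8-line letter chart (6/120 to 6/6)
#' @return A `chart_spec`.
#' @export
default_chart <- function() chart_spec()

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf("<chart_spec> %d lines, %s vocab {%s}, %g m\n",
              length(x$lines), x$vocab_mode,
              paste(x$vocab, collapse = ""), x$distance_m))
  for (ln in x$lines)
    cat(sprintf("  %-6s logMAR %+.3f\n", format(ln), ln$logmar))
  invisible(x)
}

chart_logmars <- function(chart) vapply(chart$lines, `[[`, 1, "logmar")
chart_denominators <- function(chart) vapply(chart$lines, `[[`, 1, "denominator")

#' Convert a Snellen fraction with letter adjustment to logMAR
#'
#' logMAR = `log10(denominator/6) - 0.02 * adjustment`.  A `+k` adjustment
#' (k extra letters read on the next smaller line) improves acuity by
#' 0.02 k; `-m` (m letters missed on the recorded line) worsens it by 0.02 m.
#'
#' @param denominator Positive Snellen 6/x denominator.
#' @param adjustment Integer in `-2..2` (letters beyond/missing).
#' @return logMAR value at full precision.
#' @examples
#' snellen_to_logmar(6)        # 0
#' snellen_to_logmar(60)       # 1
#' snellen_to_logmar(12, -1)   # log10(2) + 0.02
#' @export
snellen_to_logmar <- function(denominator, adjustment = 0L) {
  if (!is_scalar_number(denominator) || denominator <= 0)
    stop_domain("`denominator` must be positive")
  if (!is_scalar_number(adjustment) || adjustment != round(adjustment) ||
      abs(adjustment) > 2)
    stop_domain("`adjustment` must be an integer in [-2, 2]")
  log10(denominator / 6) - 0.02 * adjustment
}

#' Map a logMAR value back to the nearest chart line and adjustment
#'
#' Picks the chart line minimising `|logmar - line.logmar|`, with
#' `adjustment = round((line.logmar - logmar)/0.02)` clamped to `[-2, 2]`.
#' Round-trips exactly on values produced by [snellen_to_logmar()] for chart
#' lines with `|adjustment| <= 2`.
#'
#' @param logmar logMAR value.
#' @param chart A [chart_spec()].
#' @return A list with `line` (an `optotype_line`, or `NULL`),
#'   `adjustment` (integer) and `worse_than_chart` (logical sentinel, `TRUE`
#'   when `logmar` exceeds the largest line's value by more than 0.04).
#' @examples
#' logmar_to_snellen(0.0, default_chart())
#' @export
logmar_to_snellen <- function(logmar, chart = default_chart()) {
  if (!inherits(chart, "chart_spec") || length(chart$lines) == 0L)
    stop_domain("`chart` must be a non-empty chart_spec")
  if (!is_scalar_number(logmar)) {
    return(list(line = NULL, adjustment = 0L, worse_than_chart = TRUE))
  }
  lms <- chart_logmars(chart)
  if (logmar > max(lms) + 0.04 + 1e-9)
    return(list(line = NULL, adjustment = 0L, worse_than_chart = TRUE))
  i <- which.min(abs(logmar - lms))
  adj <- as.integer(round((lms[i] - logmar) / 0.02))
  adj <- max(-2L, min(2L, adj))
  list(line = chart$lines[[i]], adjustment = adj, worse_than_chart = FALSE)
}

#' Construct a VA score
#'
#' @param line An `optotype_line`, or `NULL` with `worse_than_chart = TRUE`.
#' @param adjustment Integer in `-2..2`.
#' @param chart Chart, used to value the worse-than-chart sentinel
#'   (chart-top logMAR + 0.1, one full line worse).
#' @param worse_than_chart Sentinel flag: acuity below the largest line.
#' @return An object of class `va_score` with fields `line`, `adjustment`,
#'   `logmar`, `worse_than_chart`.
#' @export
va_score <- function(line, adjustment = 0L, chart = NULL,
                     worse_than_chart = FALSE) {
  adjustment <- as.integer(adjustment)
  if (abs(adjustment) > 2L) stop_domain("`adjustment` must be in [-2, 2]")
  if (worse_than_chart) {
    if (is.null(chart)) stop_domain("`chart` needed for the sentinel value")
    lm <- max(chart_logmars(chart)) + 0.1
    return(structure(list(line = NULL, adjustment = 0L, logmar = lm,
                          worse_than_chart = TRUE), class = "va_score"))
  }
  if (!inherits(line, "optotype_line")) stop_domain("`line` must be an optotype_line")
  structure(
    list(line = line, adjustment = adjustment,
         logmar = line$logmar - 0.02 * adjustment,
         worse_than_chart = FALSE),
    class = "va_score")
}

#' @export
format.va_score <- function(x, ...) {
  if (x$worse_than_chart) return("worse than chart")
  adj <- if (x$adjustment == 0L) "" else sprintf(" %+d", x$adjustment)
  paste0(format(x$line), adj)
}

#' @export
print.va_score <- function(x, ...) {
  cat(format(x), sprintf("(logMAR %.3f)\n", x$logmar))
  invisible(x)
}

#' Generate a deterministic optotype row for a chart line
#'
#' Rows never repeat a symbol, so a spoken response maps unambiguously to
#' row positions.  The first symbol doubles as the single-optotype stimulus.
#'
#' @param line An `optotype_line`.
#' @param chart A `chart_spec` providing the vocabulary.
#' @param seed Integer seed; the same seed always yields the same row.
#' @return An object of class `optotype_row`: list with `line`, `symbols`
#'   (length `row_length`, distinct, drawn from the chart vocabulary) and
#'   `seed`.
#' @examples
#' generate_row(optotype_line(12), default_chart(), seed = 1)
#' @export
generate_row <- function(line, chart, seed) {
  if (!inherits(line, "optotype_line")) stop_domain("`line` must be an optotype_line")
  if (length(chart$vocab) < line$row_length)
    stop_domain("vocabulary smaller than row length")
  symbols <- with_seed(seed, sample(chart$vocab, line$row_length))
  structure(list(line = line, symbols = symbols, seed = as.integer(seed)),
            class = "optotype_row")
}

#' @export
format.optotype_row <- function(x, ...) {
  paste0(format(x$line), ": ", paste(x$symbols, collapse = " "))
}

#' @export
print.optotype_row <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Read / write a chart specification as YAML
#'
#' The file holds a `chart:` block with `denominators`, `vocab_mode`,
#' `vocab`, `distance_m` and `row_length`.
#'
#' @param path File path.
#' @param chart A `chart_spec`.
#' @return `read_chart_yaml` returns a `chart_spec`; `write_chart_yaml`
#'   returns `path` invisibly.
#' @export
read_chart_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- y$chart %||% y
  chart_spec(denominators = as.numeric(ch$denominators %||% c(120, 60, 36, 24, 18, 12, 9, 6)),
             vocab_mode = ch$vocab_mode %||% "LETTERS",
             vocab = ch$vocab,
             distance_m = ch$distance_m %||% 6,
             row_length = ch$row_length %||% 5L)
}

#' @rdname read_chart_yaml
#' @export
write_chart_yaml <- function(chart, path) {
  yaml::write_yaml(list(chart = list(
    denominators = chart_denominators(chart),
    vocab_mode = chart$vocab_mode,
    vocab = as.list(chart$vocab),
    distance_m = chart$distance_m,
    row_length = chart$lines[[1]]$row_length)), path)
  invisible(path)
}
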