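#' Simulated patients and paired cohorts
#'
#' The simulator stands in for live participants: each eye has a true
#' logMAR threshold and responds through a logistic psychometric function
#' with a guessing floor (slope 0 selects a deterministic threshold reader).
#' Pinhole thresholds model refractive error correctable by the pinhole.
#' Cohort generation produces paired manual/automated acuity tables for the
#' agreement-statistics suite.
#'
#' @name patient_simulator
NULL

#' Construct a simulated patient profile
#'
#' @param true_logmar_right,true_logmar_left True unaided thresholds
#'   (logMAR).
#' @param pinhole_logmar_right,pinhole_logmar_left Thresholds through the
#'   pinhole; default equal to the unaided values, and may never exceed them
#'   (a pinhole cannot worsen modeled acuity).
#' @param guess_rate Probability of naming an unreadable optotype correctly
#'   by chance; defaults to 1/vocabulary size downstream (see
#'   [p_correct()]); here stored explicitly, default `1/9`.
#' @param slope Psychometric slope in logMAR units; 0 gives the
#'   deterministic threshold responder.
#' @param speech_sub_rate Probability a spoken symbol is mis-recognised.
#' @param pose_error_rate Probability a stimulus presentation is preceded by
#'   an invalid occluder pose frame.
#' @param blurred_rate Probability a fully failed row is reported as the
#'   BLURRED command instead of wrong symbols.
#' @param seed Profile seed (recorded; session RNG is managed by the
#'   session runner).
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(true_logmar_right, true_logmar_left,
                            pinhole_logmar_right = true_logmar_right,
                            pinhole_logmar_left = true_logmar_left,
                            guess_rate = 1 / 9, slope = 0,
                            speech_sub_rate = 0, pose_error_rate = 0,
                            blurred_rate = 0, seed = 1L) {
  stopifnot(guess_rate >= 0, guess_rate < 1, slope >= 0,
            speech_sub_rate >= 0, speech_sub_rate <= 1,
            pose_error_rate >= 0, pose_error_rate <= 1)
  if (pinhole_logmar_right > true_logmar_right + 1e-12 ||
      pinhole_logmar_left > true_logmar_left + 1e-12)
    stop_domain("pinhole thresholds may not be worse than unaided thresholds")
  structure(
    list(true_logmar_right = true_logmar_right,
         true_logmar_left = true_logmar_left,
         pinhole_logmar_right = pinhole_logmar_right,
         pinhole_logmar_left = pinhole_logmar_left,
         guess_rate = guess_rate, slope = slope,
         speech_sub_rate = speech_sub_rate,
         pose_error_rate = pose_error_rate,
         blurred_rate = blurred_rate, seed = as.integer(seed)),
    class = "patient_profile")
}

profile_threshold <- function(profile, eye, pinhole) {
  if (eye == "right") {
    if (pinhole) profile$pinhole_logmar_right else profile$true_logmar_right
  } else {
    if (pinhole) profile$pinhole_logmar_left else profile$true_logmar_left
  }
}

#' Probability of correctly identifying one optotype
#'
#' With threshold `L` for the given eye/pinhole condition: slope 0 returns 1
#' when the optotype's logMAR is at or above `L` (readable) and the guess
#' rate otherwise; slope > 0 returns
#' `guess + (1 - guess) * logistic((logmar - L)/slope)`.
#'
#' @param optotype_logmar Size of the presented optotype (logMAR).
#' @param profile A [patient_profile()].
#' @param eye `"right"` or `"left"`.
#' @param pinhole Is the pinhole in use?
#' @return Probability in `[0, 1]`.
#' @export
p_correct <- function(optotype_logmar, profile, eye = c("right", "left"),
                      pinhole = FALSE) {
  eye <- match.arg(eye)
  L <- profile_threshold(profile, eye, pinhole)
  g <- profile$guess_rate
  if (profile$slope == 0)
    return(if (optotype_logmar >= L - 1e-12) 1 else g)
  g + (1 - g) * stats::plogis((optotype_logmar - L) / profile$slope)
}

phase_eye <- function(phase) if (grepl("^RIGHT", phase)) "right" else "left"
phase_pinhole <- function(phase) grepl("PINHOLE$", phase)

#' Simulate a patient's response to a stimulus
#'
#' Each displayed symbol is read correctly with probability [p_correct()];
#' misread symbols are replaced by a uniform draw from the rest of the
#' vocabulary.  When every symbol fails and the profile's blurred
#' probability fires, the whole response becomes the BLURRED command.
#' Speech-recognition confusions then substitute each emitted symbol at
#' `speech_sub_rate`.  Draws come from the current RNG stream, so seeding
#' the session makes responses deterministic.
#'
#' @param stimulus A `stimulus` from [next_stimulus()].
#' @param profile A [patient_profile()].
#' @param phase Active exam phase (selects eye and pinhole condition).
#' @param vocab Active vocabulary.
#' @return A [parsed_response()].
#' @export
respond <- function(stimulus, profile, phase, vocab) {
  eye <- phase_eye(phase)
  ph <- phase_pinhole(phase)
  p <- p_correct(stimulus$line$logmar, profile, eye, ph)
  true_syms <- stimulus$symbols
  ok <- stats::runif(length(true_syms)) < p
  out <- character(length(true_syms))
  for (i in seq_along(true_syms)) {
    out[i] <- if (ok[i]) true_syms[i]
              else sample(setdiff(vocab, true_syms[i]), 1L)
  }
  if (!any(ok) && profile$blurred_rate > 0 &&
      stats::runif(1) < profile$blurred_rate)
    return(parsed_response("COMMAND", command = "BLURRED"))
  if (profile$speech_sub_rate > 0) {
    flip <- stats::runif(length(out)) < profile$speech_sub_rate
    for (i in which(flip))
      out[i] <- sample(setdiff(vocab, out[i]), 1L)
  }
  parsed_response("SYMBOLS", symbols = out)
}

#' Specify a simulated paired-measurement cohort
#'
#' @param n_participants Number of participants (two eyes each).
#' @param logmar_mean,logmar_sd Mean and SD of the truncated-Normal manual
#'   acuity distribution on `[logmar_min, logmar_max]` (defaults emulate a
#'   tertiary-clinic mix: mean 0.2, sd 0.25 on `[0, 1.1]`).
#' @param logmar_min,logmar_max Truncation bounds (logMAR).
#' @param bias Systematic automated-minus-manual difference (logMAR).
#' @param noise_sd Per-eye measurement noise SD (logMAR).
#' @param outlier_fraction Fraction of eyes given an added discrepancy of
#'   magnitude `>= 0.4` logMAR.
#' @param pinhole_fraction Fraction of participants with pinhole
#'   measurements on both eyes.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, logmar_mean = 0.2, logmar_sd = 0.25,
                        logmar_min = 0, logmar_max = 1.1,
                        bias = 0, noise_sd = 0, outlier_fraction = 0,
                        pinhole_fraction = 0, seed = 1L) {
  stopifnot(n_participants >= 1, noise_sd >= 0,
            outlier_fraction >= 0, outlier_fraction <= 1,
            pinhole_fraction >= 0, pinhole_fraction <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Snap to the 0.02-logMAR per-letter grid.
snap_letter_grid <- function(x) round(x * 50) / 50

#' Generate a paired manual/automated cohort table
#'
#' Two eye-rows per participant.  Manual acuities are drawn from the spec's
#' truncated Normal; automated values add the systematic bias and
#' Normal(0, noise_sd) noise; both are snapped to the 0.02 per-letter grid.
#' An `outlier_fraction` of eyes receives an extra automated-side shift of
#' magnitude at least 0.4 logMAR (flagged in `planted_outlier`).
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `participant_id`, `eye`,
#'   `manual_logmar`, `automated_logmar`, `manual_pinhole_logmar`,
#'   `automated_pinhole_logmar`, `planted_outlier`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_eyes <- 2L * spec$n_participants
  with_seed(spec$seed, {
    manual <- rtruncnorm(n_eyes, spec$logmar_mean, spec$logmar_sd,
                         spec$logmar_min, spec$logmar_max)
    auto <- manual + spec$bias + stats::rnorm(n_eyes, 0, spec$noise_sd)
    planted <- stats::runif(n_eyes) < spec$outlier_fraction
    if (any(planted)) {
      # shifts live on the letter grid so the planted discrepancy survives
      # grid snapping exactly
      shift <- snap_letter_grid(0.4 + abs(stats::rnorm(sum(planted), 0, 0.1))) *
        sample(c(-1, 1), sum(planted), replace = TRUE)
      auto[planted] <- auto[planted] + shift
    }
    has_ph <- rep(stats::runif(spec$n_participants) < spec$pinhole_fraction,
                  each = 2L)
    manual_ph <- ifelse(has_ph, pmax(spec$logmar_min, manual - 0.1), NA_real_)
    auto_ph <- ifelse(has_ph,
                      manual_ph + spec$bias + stats::rnorm(n_eyes, 0, spec$noise_sd),
                      NA_real_)
    data.frame(
      participant_id = rep(sprintf("P%04d", seq_len(spec$n_participants)),
                           each = 2L),
      eye = rep(c("OD", "OS"), spec$n_participants),
      manual_logmar = snap_letter_grid(manual),
      automated_logmar = snap_letter_grid(auto),
      manual_pinhole_logmar = snap_letter_grid(manual_ph),
      automated_pinhole_logmar = snap_letter_grid(auto_ph),
      planted_outlier = planted,
      stringsAsFactors = FALSE)
  })
}

#' Read / write cohort CSV in the stats-module schema
#'
#' @param cohort A cohort data.frame (as from [generate_cohort()]).
#' @param path CSV path.
#' @return `read_cohort_csv` returns a data.frame; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
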