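---
title: "Automated visual-acuity testing: models, protocol and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated visual-acuity testing: models, protocol and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autova)
```

# The measurement problem

Clinic visual-acuity (VA) testing asks a patient to read progressively
smaller standardised optotypes at a fixed distance with one eye occluded,
and records the smallest line read correctly.  A self-administered station
must automate three things an optometrist normally does: verify the correct
eye is covered (and whether a pinhole occluder is in use), interpret the
spoken responses against the small test vocabulary, and run the adaptive
protocol that decides which stimulus to show next and how to score the
result.  `autova` implements all three as a hardware-free, fully
deterministic engine, together with the simulated-patient harness and the
method-agreement statistics used to validate such systems against manual
testing.

# Chart model and scoring

The default chart holds the eight Snellen lines 6/120, 6/60, 6/36, 6/24,
6/18, 6/12, 6/9, 6/6.  A line's logMAR value is $\log_{10}(d/6)$ for
denominator $d$, so 6/6 is 0.0 and 6/60 is 1.0.  Rows carry five optotypes;
on the standard 0.1-per-line progression each letter is therefore worth
0.02 logMAR.  A recorded score "6/12 −1" means the 6/12 row was read with
one miss: $\log_{10}(2) + 0.02$.  The sign convention is that $-m$ adds
$0.02m$ (worse) and $+k$ subtracts $0.02k$ (better, $k$ letters read on the
next smaller line).

Only the endpoints of the line set and the row length are fixed by the
protocol the package models; the intermediate lines and the nine-letter
vocabulary are configurable through `chart_spec()`.  The default vocabulary
is the Sloan letter set minus O (C D H K N R S V Z): Sloan letters are the
standard equal-legibility choice, and O is dropped because spoken "oh" is
ambiguous with zero.  Rows never repeat a symbol so that a spoken response
maps unambiguously to row positions.

`logmar_to_snellen()` inverts the conversion by nearest (line, adjustment)
pair; values more than 0.04 logMAR beyond the largest line return a
worse-than-chart sentinel, which the engine values at chart-top logMAR +
0.1 (one full line worse) so that reports and the pinhole trigger stay
numeric.

# The adaptive examination

Each phase (eye × unaided/pinhole) runs the same two-stage protocol:

1. **Single-optotype descent.**  Only the first character of each row is
   shown, starting at the largest line, descending while the patient
   identifies it.
2. **Row confirmation.**  On the first single miss, the full row of the
   last correctly identified single is shown.  A row passes when *more than
   half* its optotypes are read (≥ 3 of 5).  Passing advances to the next
   smaller row; the first row failure after a pass fixes the score.

If the anchor row itself fails before any row has passed, the engine backs
up one larger line at a time until a row passes (or the chart top fails,
scoring worse-than-chart).  This back-up rule is a design choice: the
documented score must be a *passed row*, so a failed anchor cannot simply
terminate the phase.  For the same reason a phase that starts mid-chart
(see pinhole below) treats a first-single miss as an anchor at the current
line rather than an immediate worse-than-chart: larger lines exist that
were never tried.

Adjustments are derived from the terminal rows: $m \in \{1,2\}$ misses on
the recorded row give $-m$; a clean 5/5 recorded row followed by
$k \in \{1,2\}$ correct on the next smaller row gives $+k$ ($k \ge 3$ would
have passed that row, so $+k$ is structurally limited to +2).  Misses take
precedence over extras because $+k$ is only meaningful relative to a fully
read line.

**Eye order and pinhole.**  Phases run right eye first, then left; an eye
whose unaided score is strictly worse than 6/9 (logMAR $> \log_{10}(9/6)$,
adjustment included) is re-tested through the pinhole.  The boundary is
strict — exactly 6/9 does not trigger — reading "failed to achieve 6/9 or
better" as the trigger condition.  Pinhole phases re-run the full protocol
starting two lines above the unaided achieved line, a standard clinical
shortcut that keeps the descent short without assuming the pinhole result.

**Commands.**  REPEAT re-presents the identical stimulus without tallying
(the rows are precomputed per phase and line from the session seed, so
re-presentation is exact).  BLURRED and SKIP both mean "cannot read" and
count as a miss.  Out-of-vocabulary symbols are rejected with a re-prompt
event and never tallied.  Staff assistance pauses the session and resumes
at the pending stimulus.

Timestamps come from an injectable clock (default: a one-second counter),
so event logs are byte-reproducible from the configuration and seed.

# Occluder pose validation

The occluder carries four fiducial markers: 1 and 2 on the base plates that
cover the right eye (left-eye test) and the left eye (right-eye test), and
3 and 4 on the pinhole flaps.  Pose labels name the eye *under test*:
`{1} → Left`, `{2} → Right`, `{1,3} → Left_ph`, `{2,4} → Right_ph`.  A lone
pinhole-flap marker maps to the base pose of its side (`{4} → Right`,
generalised symmetrically to `{3} → Left`); the empty set and any mix of
left- and right-family ids are Invalid, the latter being physically
impossible with one occluder.

Marker identity alone cannot detect a partially lowered occluder, so a
candidate pose is confirmed by the iris landmarks: the covered eye's iris
must fall inside the occluder region (the base-plate marker boxes inflated
by 10% of their diagonal), and the tested eye's iris must lie outside it.
A *missing* covered-eye landmark counts as covered — full occlusion hides
the iris, and the four valid poses must classify valid.  A partially
lowered pinhole flap on the tested side still classifies as the base eye
pose, reproducing the validation table as printed (the flap region does not
veto the tested eye; only base-plate markers define the covered region).

Frame streams are stabilised with `debounce()`: a valid label is emitted
only after `k = 5` consecutive identical frames (no stability criterion is
inherent to per-frame classification, so the default is a deliberate
engineering choice), while any Invalid frame is emitted immediately and
resets the run — fail-fast, so testing never proceeds on a doubtful pose.
Face-metric streams driving camera framing use a trailing moving average.

`synth_pose_fixture()` builds observations realising each of the nine
golden poses on a 640 × 480 frame with seed-controlled pixel jitter (±4 px)
small enough to preserve all inside/outside relations; the golden-table
property (9 poses × 100 seeds classified exactly) is the pose engine's
acceptance gate.  The fixtures are synthetic conventions: the physical
marker-corner assignment of the real occluder is not modelled, and no claim
is made about illumination robustness or real detector behaviour.

# Response interpretation and WER

Recognizer backends are a contract (`() → transcript`); no audio processing
is implemented, because recognition quality is a property of model weights
and recordings that live outside the package.  The deterministic
`mock_recognizer()` implements the contract with scripted utterances and
seeded per-token confusions (substitute within a confusion set, drop,
duplicate), and is the backend all tests use.  With zero confusion rates a
mock-driven session scores identically to direct symbol injection — an
end-to-end invariant in the test suite.

`normalize_transcript()` uppercases, strips punctuation and maps spelled-out
homophones through an editable table shipped at
`inst/extdata/homophones.csv` ("bee" → B, "zero" → 0; "oh" → O in letters
mode, 0 in numbers mode).  Unknown tokens are retained but tagged, then
dropped by `parse_response()`, which maps command words (OK, BLURRED, SKIP,
REPEAT) to commands, vocabulary symbols to a positional response, and
anything ambiguous or empty to a REPEAT re-prompt.  Row marking is
positional: response symbol $i$ is compared to row position $i$, missing
trailing positions count as misses, extras are ignored.  Positional
matching is an assumption (a live system might match as a multiset when a
participant skips mid-row); it is the stricter and better-defined choice.

Word error rate is $100 (S + I + D) / N$ from a unit-cost minimum-edit
alignment; cost ties prefer substitutions over insertion+deletion pairs,
chosen for determinism.  The aligner is checked exhaustively against an
independent Levenshtein oracle on all token pairs of length ≤ 5 over a
3-symbol alphabet, and its (S, I, D) split against full edit-script
enumeration on all pairs of length ≤ 3.

# Simulated patients

`patient_profile()` gives each eye a true unaided and pinhole threshold and
responds through
$P(\text{correct}) = g + (1 - g)\,\text{logistic}((x - L)/s)$ for optotype
size $x$, threshold $L$, guessing floor $g$ and slope $s$ (in logMAR);
$s = 0$ selects the deterministic threshold reader used for exact
parameter-recovery tests.  The guessing floor defaults to $1/9$, the
reciprocal of the letter vocabulary size.  Misread symbols are uniform
draws from the rest of the vocabulary; speech confusions corrupt emitted
symbols at a stated rate; pose errors inject invalid occluder frames that
pause the session.

`generate_cohort()` emulates the paired manual/automated tables the
statistics suite consumes: manual acuities from a truncated Normal on
[0, 1.1] logMAR (mean 0.2, SD 0.25 — a plausible tertiary-clinic mix,
chosen once as a fixture convention, not a calibrated fact), automated
values adding a systematic bias and Normal noise, everything snapped to the
0.02 letter grid.  Planted outliers add a grid-aligned shift of at least
0.4 logMAR so they survive snapping exactly.  What the simulator does *not*
model: fatigue and learning effects, accent phonetics, response latency,
and any calibrated correspondence to a real clinic population — passing
recovery tests shows the pipeline is correct, not that real patients behave
like the model.

# Agreement statistics

The validation suite mirrors standard method-comparison practice, with eyes
treated as independent units:

* **Bland–Altman**: bias = mean difference, limits of agreement = bias ±
  1.96 × SD (sample SD, fixed 1.96 multiplier rather than a t quantile,
  matching the conventional printed arithmetic).
* **ICC**: Shrout–Fleiss ICC(2,1) — two-way random effects, absolute
  agreement, single measure — computed from the two-way ANOVA mean squares
  with the F-based confidence interval.  ICC(2,1) is the right form for
  inter-method agreement of single measurements; ICC(3,1) (consistency) is
  available via `model = "ICC3"`, and the result records which was used.
  The implementation is cross-checked against an independent reference
  value frozen into the tests.
* **Wilcoxon signed-rank**: zeros dropped, mid-ranks for ties; exact
  permutation p for n ≤ 25 via convolution over doubled ranks (doubling
  makes mid-ranks integral), normal approximation with tie-corrected
  variance $\sum r_i^2 / 4$ (no continuity correction) above that.
* **Shapiro–Wilk** delegates to the vetted Royston implementation in
  `stats`; **Spearman** is mid-rank-then-Pearson with a t-approximate p.
* **Outlier filter**: a participant is excluded when either eye differs by
  ≥ 0.4 logMAR between methods; both eyes move together.  The boundary is
  inclusive and compared with a 10⁻⁹ tolerance because letter-grid
  differences (e.g. 0.84 − 0.44) can fall one ulp below 0.4 in floating
  point.

# Numerical and design notes

* All randomness flows through seeds; helpers restore the caller's RNG
  state, and session sub-streams (rows, responses, poses, recognizer) are
  derived from the one session seed.
* Threshold comparisons use a 10⁻⁹ tolerance so that "optotype at
  threshold" is readable regardless of floating-point representation.
* Problem sizes in the validation suite — 900 pose checks, exhaustive
  line × eye × pinhole recovery, 132,132 WER pairs, 10,000 Bland–Altman
  differences, 4 × 200 ICC simulations at n = 500 — were chosen as the
  smallest sizes at which the properties are exhaustive or statistically
  decisive.
* Known limitations: no real detector or recognizer backends are included
  (both are injected contracts); the nine-letter vocabulary and
  intermediate chart lines are conventions; repeated-measures covariate
  modelling of test duration is out of scope, as is any reproduction of
  clinical cohort values — the statistics here are validated on simulated
  cohorts with known truth.

# A worked session

```{r}
prof <- patient_profile(
  true_logmar_right = snellen_to_logmar(12),   # right eye 6/12
  true_logmar_left = 0,                        # left eye 6/6
  pinhole_logmar_right = snellen_to_logmar(9), # improves to 6/9 with pinhole
  guess_rate = 0)
report <- run_simulated_session(prof, seed = 42)
report
```

The right eye scores 6/12 unaided, which is worse than 6/9, so a right
pinhole phase runs and recovers 6/9; the left eye ends at 6/6 and no left
pinhole phase is scheduled.

```{r}
co <- generate_cohort(cohort_spec(60, bias = -0.06, noise_sd = 0.1,
                                  outlier_fraction = 0.05, seed = 7))
agreement_report(co)
```
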