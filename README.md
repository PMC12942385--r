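# autova

Automated visual-acuity (VA) testing, hardware-free: the adaptive Snellen
examination engine, occluder-pose validity checking, vocabulary-constrained
speech-response interpretation with word-error-rate (WER) evaluation, a
simulated-patient harness, and the method-agreement statistics used to
validate automated VA stations against manual testing.

It is aimed at developers and evaluators of self-administered vision-testing
systems who need a deterministic, fully testable reference for the protocol
logic and the validation statistics, without cameras, microphones or
patients.

## What it implements

**Chart and scoring.** Snellen lines 6/120 … 6/6 with
logMAR = log₁₀(d/6); five optotypes per row, 0.02 logMAR per letter.
Scores carry per-letter adjustments: "6/12 −1" = log₁₀(2) + 0.02.
`snellen_to_logmar()` / `logmar_to_snellen()` form a monotone bijection on
(line, adjustment) pairs.

**Adaptive exam.** Single-optotype descent from the largest line, full-row
confirmation anchored at the last correct single, pass iff more than half
the row is read, right eye first, and a pinhole re-test for any eye scoring
strictly worse than 6/9 (logMAR > log₁₀(9/6)). REPEAT re-presents, BLURRED
and SKIP count as misses, staff assistance pauses without terminating.
Event logs are JSON Lines and byte-reproducible from seed + config.

**Pose engine.** Marker-id sets map to the pose label of the tested eye
({1}→Left, {2}→Right, {1,3}→Left_ph, {2,4}→Right_ph, ∅ or mixed
sides→Invalid); an iris-region check demotes partial covers to Invalid;
`debounce()` stabilises frame streams and fails fast on Invalid frames.
`synth_pose_fixture()` reproduces the nine-pose golden validation table.

**Response interpretation.** Transcript normalisation against a
nine-letter/digit vocabulary with a homophone table, command parsing
(OK/BLURRED/SKIP/REPEAT), and WER = 100 (S + I + D)/N from a minimum-edit
alignment (substitution-preferred tie-break). A deterministic
`mock_recognizer()` implements the pluggable recognizer contract.

**Simulation + statistics.** Logistic psychometric patients with guessing
floor and pinhole-correctable thresholds; paired manual/automated cohort
generation on the 0.02 letter grid; Bland–Altman (bias ± 1.96 SD),
Shrout–Fleiss ICC(2,1) with F-based CI, exact Wilcoxon signed-rank,
Shapiro–Wilk, Spearman, and the ≥ 0.4 logMAR participant-level outlier
filter.

## Worked example

```r
library(autova)

prof <- patient_profile(
  true_logmar_right = snellen_to_logmar(12),    # right eye truly 6/12
  true_logmar_left = 0,                         # left eye 6/6
  pinhole_logmar_right = snellen_to_logmar(9),  # pinhole corrects to 6/9
  guess_rate = 0)
run_simulated_session(prof, seed = 42)
#> <session_report sim-1>
#>   RIGHT_UNAIDED  6/12             logMAR  0.301  (28s)
#>   LEFT_UNAIDED   6/6              logMAR  0.000  (28s)
#>   RIGHT_PINHOLE  6/9              logMAR  0.176  (22s)
```

The right eye is scored 6/12 unaided — worse than 6/9, so the engine
schedules a right pinhole phase, which recovers 6/9 (logMAR 0.176); the
left eye reads down to 6/6 and needs no pinhole. Durations come from the
deterministic session clock.

```r
co <- generate_cohort(cohort_spec(60, bias = -0.06, noise_sd = 0.1,
                                  outlier_fraction = 0.05, seed = 7))
agreement_report(co)
#> Agreement report (unaided VA, 108 eyes, 12 flagged eyes excluded)
#> Bland-Altman (n = 108): bias -0.041, SD 0.095, 95% LoA [-0.227, 0.146]
#> ICC2 = 0.864 (95% CI 0.772-0.915), n = 108
#> Wilcoxon signed-rank: V = 1316.5, p = 3.219e-05 (normal approximation)
#> Shapiro-Wilk on differences: W = 0.969, p = 0.01179
#> Spearman rho (diff vs mean) = 0.160, p = 0.09741
```

Here the simulated automated method reads better than manual on average
(negative bias, as planted), the ICC indicates strong inter-method
agreement, and the outlier filter removed the six planted discrepant
participants (12 eyes).

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/autova.R run --patient profile.yml --seed 9 --log out.jsonl
Rscript inst/cli/autova.R pose-validate --seeds 100
Rscript inst/cli/autova.R wer --ref ref.txt --hyp hyp.txt
Rscript inst/cli/autova.R simulate-cohort --spec cohort.yml --out cohort.csv
Rscript inst/cli/autova.R stats --in cohort.csv --out report.json
```

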