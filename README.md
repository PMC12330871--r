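# tloadback

Adaptive calibration and test–retest reliability analysis for the
TloadDback dual working-memory task, in R.

The TloadDback presents an alternating stream of letters and digits: the
participant presses the space bar whenever a letter repeats its immediate
predecessor (1-back updating) and classifies every digit as even or odd
(parity keys). Task difficulty is controlled by a single knob, the
**stimulus time duration (STD)** — how long each item stays on screen.
The fastest STD at which someone still sustains criterion accuracy is an
individualized measure of maximal cognitive load, used downstream to
induce cognitive fatigue at a matched load per person. This package is
for researchers who use that calibration procedure and want to (a) run or
replay it as an auditable state machine, (b) simulate observer cohorts to
study the procedure's statistical behaviour, and (c) analyze multi-session
calibration data for test–retest reliability.

## The procedure and statistics at its core

Performance on a 60-item combined block (30 letters, 30 numbers) is the
weighted composite

    composite = 0.65 · letter accuracy + 0.35 · number accuracy,

and a block passes at composite ≥ 0.85. Calibration descends from
1,400 ms in 100 ms steps — each passed block speeds the next up by one
step — until a block fails; the last passed speed is then verified by
repetition until it has accumulated **three** passes at that speed
(the descent pass counts as the first). The calibrated STD is that
verified speed.

The reliability battery covers the analyses such a three-session design
needs: the tie-corrected Friedman test (χ² = (k−1) Σ(Rⱼ − n(k+1)/2)² /
(A − C) on within-subject midranks), Durbin–Conover pairwise comparisons
(t = (Rᵢ − Rⱼ) / √(2n(A − B)/((n−1)(k−1))) on (n−1)(k−1) df), the
Bonferroni-adjusted threshold (0.05/3 = 0.0167), Spearman correlation
matrices, Cronbach's α ≡ ICC(3,k), change-score frequency distributions
on the 100 ms grid, and a one-way repeated-measures ANOVA by time of day.

## Worked example

```r
library(tloadback)

# Calibrate one simulated observer whose expected composite crosses 0.85
# at 850 ms (nominal grid threshold: 900 ms)
res <- run_calibration(profile_responder(observer_profile(theta_ms = 850)),
                       seed = 5)
res
#> calibrated STD: 900 ms after 9 blocks
head(res$trajectory)
#>   block_no std_ms letter_accuracy number_accuracy composite passed   phase
#> 1        1   1400       0.9333333       1.0000000 0.9566667   TRUE descent
#> 2        2   1300       1.0000000       1.0000000 1.0000000   TRUE descent
#> 3        3   1200       0.9666667       1.0000000 0.9783333   TRUE descent
#> ...

# A 51-participant, three-session cohort with between-session learning,
# and its full reliability report
cohort <- simulate_cohort(cohort_design(n_participants = 51), seed = 2)
report <- analyze_cohort(cohort)
report
#> Reliability report (n = 51 complete participants)
#>   session mean STDs: 1022, 947, 933 ms
#>   Friedman chi2(2) = 20.52, p = 3.507e-05
#>   sessions 1-2: t(100) = 3.95, p = 0.0001445 (sig. at 0.0167)
#>   sessions 1-3: t(100) = 4.65, p = 1.003e-05 (sig. at 0.0167)
#>   sessions 2-3: t(100) = 0.70, p = 0.4848
#>   Cronbach's alpha = 0.931 (ICC(3,k) = 0.931)
#>   mean change session 1->2: 74.5 ms; 2->3: 13.7 ms
#>   time of day: F(2, 100) = 0.023, p = 0.977
```

Reading the report: the calibrated STD drops by ~75 ms on average between
sessions 1 and 2 (participants get faster), the sessions 1–2 and 1–3
contrasts clear the 0.0167 Bonferroni threshold while 2–3 does not, the
three sessions' STDs are strongly consistent (α ≈ 0.93), and time of day
has no effect — the pattern the default simulated learning model encodes.

A command-line surface wraps the same functions
(installed at `exec/tloadback`, or call `tloadback::cli()`):

```sh
tloadback simulate --n 51 --seed 1 -o cohort.csv
tloadback analyze cohort.csv --report report.json --figures figs/
tloadback calibrate-demo --threshold 800 --deterministic
tloadback reproduce --seed 1 --out out/        # simulate + analyze
tloadback reproduce --osf export.csv           # analyze a deposited table
```

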