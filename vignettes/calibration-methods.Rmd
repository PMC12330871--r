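---
title: "Calibrating cognitive load with tloadback: model, simulator and reliability battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cognitive load with tloadback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tloadback)
```

## The task and the quantity being calibrated

The TloadDback is a dual working-memory task: a stream of letters and
digits alternates on screen (letter, digit, letter, digit, ...), and the
participant performs two sub-tasks at once — press the space bar whenever a
letter repeats its immediate predecessor (a 1-back updating task), and
classify every digit as even or odd with the parity keys. The single
experimenter-controlled difficulty knob is the stimulus time duration
(STD): how long each item stays on screen. Shorter STDs leave less time to
process each item, so the STD at which a person can just barely keep
performing well is a per-individual measure of maximal sustainable
cognitive load. Calibrating that STD, and asking how repeatable the
calibrated value is across days, is what this package implements.

Letters are drawn from A, C, E, L, N, P, R, T, U; digits from 1–9 without
5 (dropping 5 equalises the even and odd digit pools and avoids visual
confusion with "S"). Performance on a 60-item combined block is a weighted
composite,

$$\mathrm{composite} = 0.65\,p_\mathrm{letter} + 0.35\,p_\mathrm{number},$$

with the letter channel weighted more heavily because the 1-back updating
component is the harder, memory-loaded sub-task. A block *passes* when the
composite reaches 0.85 — inclusive, since sustaining 85% *is* the
criterion performance.

## The calibration staircase

Calibration descends from 1,400 ms in 100 ms steps: each passed block
speeds the next block up by one step; the first failed block ends the
descent. The last passed speed then becomes the *verification candidate*:
blocks repeat at that speed until it has accumulated three passes in
total. The package counts the descent pass at the candidate speed as the
first of the three, so verification normally adds two blocks.

Two situations the procedure description leaves open are resolved as
explicit engine rules:

* **A failed verification block** promotes the candidate one step slower
  (its previously recorded passes are kept). This guarantees termination
  and never returns a speed whose observed failures outweigh its passes.
  A candidate promoted beyond 1,500 ms — or any run exceeding a 60-block
  safety cap — ends the run as ineligible.
* **A failure on the very first calibration block** (1,400 ms) promotes
  the candidate to 1,500 ms, the familiarization speed. Verification there
  requires the full three passes: the familiarization pass belongs to a
  different phase and is not entered in the calibration ledger.

The engine (`calibration_step()`) is a pure transition function on an
explicit state — current STD, phase, a per-speed pass/fail ledger, and the
block-by-block trajectory — so a logged session can be replayed exactly
(`replay_calibration()`), and the whole staircase is property-testable:
for a deterministic observer whose pass threshold lies on the grid,
recovery is exact at every grid point.

## The simulated observer

No human item-level data ships with the package, so simulated observers
drive everything. Each observer answers items independently with
probability logistic in the STD:

$$p_c(s) = \gamma_c + (1 - \lambda - \gamma_c)\,
  \mathrm{logit}^{-1}\!\big((s - \mu_c)/\beta\big),$$

per channel $c$, with guessing floor $\gamma_c$ (default 0.5 — both
channels are binary decisions), lapse rate $\lambda$ (default 0.02,
capping accuracy at $1-\lambda$), slope scale $\beta$ (default 60 ms;
$\beta \to 0$ is a step observer) and a channel threshold gap (default
80 ms) that makes letters harder than numbers at equal STD. The anchor
parameter `theta_ms` is defined on the *composite* scale: the internal
offset is solved (by `uniroot`) so that the expected composite at
`theta_ms` equals the pass criterion exactly. That makes `theta_ms` the
observer's nominal calibration threshold up to grid rounding, which is
what lets tests state parameter-recovery properties crisply
(`nominal_threshold()` is an explicit grid search, used as the oracle).

Incorrect items are realised as the error modes the scoring rule actually
distinguishes: missed space presses on targets, spurious presses on
non-targets, and (for digits) wrong-key commissions in a 70/30 mixture
with omissions. Correct responses land at a latency uniform in the
presentation window.

Between-session learning is additive on the threshold: session 2 and 3
thresholds are shifted by draws from categorical distributions on the
100 ms grid. The session 1→2 default assigns probability 19/51 to a
100 ms improvement, 14/51 to no change, 8/51 to 200 ms, 4/51 to 300 ms,
4/51 to a 100 ms worsening and 2/51 to a 200 ms worsening — expectation
≈76.5 ms. Participants who worsened "beyond 100 ms" are modelled at
−200 ms, the smallest grid value consistent with that description. The
session 2→3 default (probability 0.60 at no change, 0.25 at +100, 0.15 at
−100) encodes slight, non-significant continued improvement (+10 ms in
expectation). Both distributions are configurable in `cohort_design()`.

## The cohort generator

`simulate_cohort()` draws one observer per participant with
$\theta \sim N(900, 200)$ ms truncated to [250, 1350] — an invented but
realistic spread: it keeps every simulated participant comfortably inside
the representable staircase range, as human cohorts calibrating this task
are. Each participant completes the full staircase three times (their
threshold shifted by their delta draws), yielding the calibrated STD and
the number of blocks used per session. Time-of-day orders are assigned
round-robin over the six permutations of morning/afternoon/evening, so
every participant sees each time of day exactly once and order counts
differ by at most one.

Covariates — previous-night sleep hours ($N(7.5, 1)$ truncated to 3–12 h),
number of wakeups (Poisson(1)), subjective sleep quality (integers 1–5),
Karolinska Sleepiness Scale (integers, default range 2–7 of the 1–9
scale), and a 0–100 visual-analog fatigue score — are drawn independently
of performance by default. That null coupling is deliberate: it matches
the empirical finding that these covariates do not track calibration
changes, and it makes the simulator a proper null model for checking the
type-I behaviour of the downstream correlation battery. A
`covariate_coupling` coefficient can induce dependence for power studies.

What the simulator does *not* emulate: within-session fatigue or practice
drift (accuracy is exchangeable across blocks at fixed STD), reaction-time
structure (scoring is accuracy-only), circadian modulation (the empirical
time-of-day effect was null, so the default is null), and any age/sex
structure. Passing simulation-based tests therefore says the *procedure*
behaves correctly under a plausible observer model — not that human data
will show any particular effect size.

## The reliability battery

`analyze_cohort()` reproduces a three-session test-retest analysis:

* **Friedman test** on the participants × sessions STD matrix. STDs live
  on a 100 ms grid, so ties are pervasive; ranks are midranks and the
  statistic uses the tie-corrected denominator
  $\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$, the form computed
  by the common GUI statistics packages (and by base R's
  `friedman.test`, which serves as an independent oracle in the tests).
* **Durbin–Conover pairwise comparisons**, Conover's rank-sum post-hoc:
  $t = (R_i - R_j)\big/\sqrt{2n(A - B)/((n-1)(k-1))}$ with
  $B = \sum_j R_j^2 / n$, on $(n-1)(k-1)$ degrees of freedom. Raw p
  values are reported against the Bonferroni-adjusted threshold
  ($0.05/3 = 0.0167$ for three comparisons) rather than as adjusted p
  values, matching how such analyses are conventionally reported.
* **Spearman correlations** (midrank Pearson, t-approximation p values)
  among the session STDs, and — uncorrected, as is conventional for a
  screening battery — between STDs and every covariate.
* **Cronbach's α and ICC(3,k)** (two-way mixed, consistency, average
  measures — the Shrout–Fleiss cell implied by a fixed set of raters
  analysed by mean values). The two are algebraically identical; the test
  suite asserts agreement to 1e-9 and both against an `aov`-based oracle.
* **Change-score frequency distributions** (sessions 1–2 and 2–3) on the
  100 ms grid, with the convention that positive change = faster later
  session.
* **A one-way repeated-measures ANOVA** of STD by time of day (each
  participant contributes one value per time of day thanks to the
  counterbalanced design).

Degenerate inputs are flagged, not thrown: a zero-variance matrix yields
Friedman $\chi^2 = 0, p = 1$; α, ICC and Spearman return
`undefined = TRUE` so that batch analyses over simulated cohorts keep
running.

## Numerical and design choices

* **Grid and windows.** All STDs are positive multiples of 100 ms in
  [100, 1500]. A response is creditable in the half-open window
  $[\mathrm{onset}, \mathrm{onset} + \mathrm{STD})$; with continuous
  presentation there is no inter-stimulus interval. Cross-channel presses
  (space during a digit, parity key during a letter) are ignored; the
  first creditable press per item wins.
* **Target placement.** Combined blocks carry exactly 10 repeat targets
  among the 29 eligible letter positions (one third of letters — the
  density of the canonical example stream), sampled uniformly with no two
  adjacent targets, so no symbol ever appears three times in a row; the
  non-adjacency constraint is relaxed only if a custom configuration
  requests more targets than it permits. Single-task letter blocks carry
  5 targets. Chance performance stays far below the 0.85 criterion under
  these defaults.
* **Reproducibility.** Every stochastic entry point takes a `seed`; the
  RNG state is restored afterwards, and nested seeds are derived inside
  the seeded context, so cohorts, calibrations and CLI outputs are
  byte-reproducible.
* **Simulation sizes.** The type-I calibration study uses 1,000 null
  cohorts of 24 participants (a multiple of six keeps counterbalancing
  exact; the size keeps the χ² reference accurate despite grid ties); the
  learning-model study uses 200 cohorts of 51. These run in minutes on one
  core.

## Worked example

```{r example, eval = FALSE}
# one simulated participant
res <- run_calibration(profile_responder(observer_profile(theta_ms = 850)),
                       seed = 5)
res$final_std_ms

# a full three-session cohort and its reliability report
cohort <- simulate_cohort(cohort_design(n_participants = 51), seed = 2)
report <- analyze_cohort(cohort)
report
```

## Known limitations

One conservatism of the cohort generator deserves emphasis. Its default
between-session change distributions are *observed* change-score
frequencies from a real cohort, but the generator applies them to the
observers' *latent* thresholds and then re-measures every session through
the stochastic staircase. An observed change already embeds two sessions'
worth of measurement noise, so simulated cohorts carry that ordering
noise twice: their session effects (e.g. the Friedman statistic) are
systematically somewhat weaker than those of a real cohort whose observed
changes follow the same distribution. Users who want the simulator to hit
a target strength of session ordering should either narrow the delta
distributions (treating them as latent learning) or use deterministic
observers.

The observer model is a stand-in, not a fit: no parameter was estimated
from human item-level data, and the logistic-with-lapse form is a
convention of psychophysics rather than a validated model of this task.
The change-score distributions are read off a single empirical cohort and
treated as exact categoricals. Verification behaviour after a failed
verification block is an engine decision (promote and retain passes) that
other implementations of the task may resolve differently; anyone
comparing trajectories against other software should check that rule
first. The package deliberately does not model the fatigue-induction
session that a calibrated STD is ultimately used for.
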