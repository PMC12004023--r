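---
title: "Task protocols, validity indices, and the synthetic cohort: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task protocols, validity indices, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navcog)
```

`navcog` is a headless engine for serious-game spatial-cognition assessment.
It generates and scores three gamified task protocols — an allocentric
hidden-goal navigation task, a forced-choice mental-rotation task, and a
Corsi block-tapping span procedure — and implements the measurement-property
toolkit used to validate such instruments: content-validity indices with
chance correction, Aiken's V with confidence intervals, rank-biserial and
Cramér's V effect sizes, and a two-round Delphi comparison. A synthetic
cohort simulator with known ground truth ties the pieces together so the
whole pipeline can be exercised end to end without any recorded data.

This vignette explains the models and scoring rules, the tunable parameters
and their defaults, the numerical choices, and what the simulator does and
does not emulate.

## The hidden-goal navigation task

Each trial briefly shows a goal location (5 s by default) inside a circular
arena, then asks the participant to relocate it using only two distal
landmarks. The arena is a unit-radius circle centred at the origin, with
Cartesian y-up coordinates and angles in degrees (counterclockwise
positive). The canonical layout — start `(0, -0.8)`, landmarks
`(-0.6, 0.55)` and `(0.6, 0.55)`, goal `(0.15, 0.1)` — is a design choice of
this package: hidden-goal paradigms conventionally use circular arenas, and
no published coordinates exist for the instrument family this models. All
four points are constructor arguments, so any layout within the arena can
be declared.

A protocol contains 8 trials. Trial geometry is the canonical layout
rotated rigidly about the arena centre by one of the eight multiples of
45°, in a seeded pseudorandom order. Rigid rotation is the only
transformation family that yields exactly eight distinct positions on a
circle while preserving *all* mutual spatial relationships among start,
landmarks, and goal — which is the property the scoring relies on, and
which the test suite checks to 1e-9 across trials. Requesting more than 8
trials requires an explicit flag, since offsets must then repeat.

Scoring a trial takes a timestamped trajectory (any strictly increasing
time grid; the producer's sampling rate carries no semantic load) and
computes:

* `distance_error` — Euclidean distance from the final response point to
  the goal;
* `path_length` — summed segment lengths;
* `ideal_length` — straight start-to-goal distance;
* `efficiency = ideal / max(path, ideal)`, in (0, 1].

### Anomaly detection

The engine flags three unusual patterns, with thresholds that are declared
defaults rather than published constants (the patterns are documented for
this instrument class; numbers are not):

* **TOWARD_LANDMARK** — the length-weighted mean heading over the first
  25% of the path points at the nearest landmark (cosine similarity at
  least `cos 20°`) *and* the final position is nearer that landmark than
  the goal. The conjunction matters: a wiggly but goal-directed path never
  trips it.
* **LONG_PATH** — path length above 3 times the ideal length.
* **EXTREME_DEVIATION** — final error above half the arena radius.

All four constants live in `anomaly_thresholds()`. Relaxing the path-ratio
or deviation threshold can only remove flags, never add them (a property
the suite tests on randomized paths). During a session's tutorial phase a
non-empty flag set raises `repeat_tutorial`, mirroring how such games
re-run their tutorial when early behavior suggests the instructions were
not understood.

## The mental-rotation task

Three angular conditions (0°, 90°, 180°), 16 trials each, four response
options per trial. The original stimulus order for the instrument this
models is not published, so the builder accepts a fixture table (CSV:
`condition, trial, stimulus_id, opt1..opt4, correct_index`) and reproduces
it verbatim when one is supplied. Without a fixture it generates a
deterministic seeded order in which each answer slot is correct exactly
`trials_per_condition / 4` times per condition — so a fixed-slot responder
scores exactly 0.25, and position bias cannot masquerade as accuracy. The
bundled `inst/extdata/mrt_order_synthetic.csv` is such a generated order,
synthetic by construction, usable as a stable fixture in examples.

Scoring reports per-condition counts, proportion correct, and the median
reaction time over correct trials, plus per-trial correct/incorrect
feedback events (the headless counterpart of the game's audiovisual
feedback). Condition labels, not stimulus geometry, drive scoring.

## The Corsi block-tapping task

Nine locations, forward and backward blocks. Lengths ascend 2..9 with two
trials per length (both bounds and the trial count are arguments);
sequences are seeded draws from 1..9 with no immediate repetition, and each
trial carries a `counter` equal to its length, as shown on screen. A trial
is correct only if the response reproduces the expected sequence exactly
(the reverse of the displayed sequence in the backward block). A block ends
after two consecutive failed attempts at sequences of the same length;
responses past the stop point are ignored. The span is the longest length
with at least one correct trial, and the product score is span times the
number of correct trials in that direction — the standard administration
consistent with the preserved stop rule. The scorer is verified against an
independent step-by-step replay oracle on a thousand random response
patterns.

## Content validity

For a panel of `N` experts rating an item on an ordinal 1..`c` scale:

* **I-CVI** = `A / N`, where `A` counts ratings at or above the relevance
  cut (3 on a 1-4 scale by default — the conventional dichotomization;
  configurable).
* **Chance agreement** `p_c = choose(N, A) * 0.5^N`: the binomial
  probability that exactly `A` of `N` raters would agree were each judging
  relevant/not-relevant at random.
* **Modified kappa** `= (I-CVI - p_c) / (1 - p_c)`, labelled *excellent*
  above 0.88 and *good* above 0.72, band edges exclusive.
* **Aiken's V** `= sum(r_i - floor) / (n (c - 1))`: the mean elevation
  above the scale floor as a proportion of its maximum, using the full
  ordinal scale — informative even for small panels.

The V confidence interval is the score-type (Wilson) interval treating
`k = n (c - 1)` as the effective number of Bernoulli units:

```
L, U = (2kV + z^2 -/+ z * sqrt(4kV(1 - V) + z^2)) / (2 (k + z^2))
```

With 8 raters on a 4-category scale this gives `(0.80, 0.99)` for
`V = 23/24` and `(0.86, 1.00)` for `V = 1` at 95% — the two intervals a
unanimous and a seven-top/one-second panel produce. A Wald interval is
available as an alternative (`method = "wald"`), mainly to show how badly
it behaves near the boundary. Indices are computed at full precision and
rounded to 2 decimals only for display.

## Effect sizes

**Rank-biserial.** `r_rb = 1 - 2U/(n1 n2)` with the Mann-Whitney `U`
counting pairs favorable to the second group, ties as one half; positive
when the first group is stochastically larger, with the unsigned magnitude
reported alongside for comparison against conventionally unsigned ranges.
The estimate equals the favorable-minus-unfavorable pair proportion, which
the suite verifies by brute-force enumeration. The default interval is a
seeded percentile bootstrap (2000 replicates), resampling within groups;
`method = "normal"` uses the large-sample SE
`sqrt((n1 + n2 + 1) / (3 n1 n2))`. The bootstrap default reflects that no
standard closed-form interval exists for this statistic; its empirical
coverage is checked by simulation (below).

**Cramér's V.** `V = sqrt(chi2 / (N min(r-1, c-1)))` with the Pearson
statistic, zero-margin rows and columns dropped with a warning. The
interval inverts the noncentral chi-square distribution on the
noncentrality parameter `lambda` (bisection via `uniroot`, verified
against a grid search) and maps bounds through
`V = sqrt(lambda / (N min_dim))`, floored at 0 and capped at 1. This is a
declared convention — several variants circulate (some add `df` back to
`lambda`) and none is canonical; the point estimate, not the interval, is
the quantity this package treats as exactly reproducible.

**Delphi rounds.** Paired criteria are compared with the Wilcoxon
signed-rank test using the normal approximation with continuity correction
— ordinal ratings always tie, which rules the exact distribution out — and
a matched-pairs rank-biserial `(T+ - T-)/(T+ + T-)` over nonzero
differences. Criteria with no changed ratings get effect 0 and p = 1 by
convention. With tied ordinal data the approximation is mildly
conservative; the suite checks the null rejection rate stays near, and not
materially above, the nominal level.

## Questionnaire scoring

The 15-item usability questionnaire scores three factors (items 1-6
system usefulness, 7-12 information quality, 13-15 interface quality — the
conventional mapping, supplied as an argument because adapted instruments
sometimes remap) plus an overall score over all 15 items. Two
percent-of-maximum rules are provided, because instruments in this family
print percentages without always printing the transform: the default
`(mean - 1)/6 * 100` maps the scale anchors to exactly 0 and 100;
`mean / 7 * 100` is selectable. Both are strictly monotone in the raw
mean, so respondent orderings never depend on the choice. A factor whose
items are more than half missing scores `NA` — never zero — and otherwise
averages the observed items; with 3-6 items per factor, imputation
machinery would be pretense.

The digital-ergonomics questionnaire scores eight interface-design
criteria (compatibility, orientation/guidance, workload, adaptability,
consistency, significance of codes, explicit control, error management)
as the mean of their items on the 1-7 scale, with percent `score/7 * 100`
— anchored so that a score of 5.25 is exactly 75%, the acceptability
threshold conventionally quoted for such instruments.

Group summaries report median and IQR per score, and pairwise unsigned
rank-biserial contrasts with intervals, flagging the contrasts involving a
designated focus group (typically the clinical group of interest).

## The synthetic cohort simulator

Every simulator is a pure function of (profile, seed): identical calls are
byte-identical, and the global RNG state of the caller is never disturbed.

* **Expert panels** — `unanimous_top` yields all-maximum ratings (V = 1,
  kappa = 1 downstream); `one_step_down` lowers one seeded rater by one
  category on designated items (V = 23/24 with 8 raters on 1-4); `mixed`
  draws from a declared category distribution.
* **Navigation agents** — walk from the start toward a goal estimate
  scattered isotropically with SD `nav_noise_sd`, so the mean radial error
  is `sd * sqrt(pi/2)` (Rayleigh), which the suite recovers within 3%.
  Excess path is a perpendicular zig-zag whose amplitude makes the path
  exactly `nav_path_wobble` times the direct distance; trajectories are
  piecewise linear at a nominal 10 samples/s with the zig-zag vertices
  retained so the constructed length survives resampling.
* **Mental rotation** — correct with the profile's per-condition
  probability, else uniform over the three foils; lognormal reaction times
  slower at larger angles.
* **Corsi** — a participant-level latent span is drawn from
  `Normal(mean, sd)`; a length-`L` trial is passed with probability
  `pnorm((span - L + 0.5) / slope)` with slope 0.5 by default. The smooth
  link (rather than a hard cutoff) gives parameter-recovery tests a
  gradient; failures perturb one element so they never match by accident.
  The backward block lowers the span by a configurable penalty
  (default 1).
* **Likert cohorts** — item ratings discretize latent
  `Normal(group shift, 1)` draws through shared strictly increasing
  cutpoints (six for a 7-point scale). The default cutpoints are
  `qnorm(i/7) - 1`, placing an unshifted responder in the upper half of
  the scale, as usability data for acceptable software typically sits.

The default group profiles (e.g. a lowered-span, higher-noise,
negative-shift clinical group) are illustrative fixtures: no trial-level
data is published for the populations they are named after, so nothing
here is an estimate of a real cohort. What passing tests demonstrate is
that the *pipeline* recovers known ground truth — noise scales, accuracy
maps, span means, shift orderings — not that the generator reproduces real
patient behavior. Real data differ in ways the simulator deliberately
omits: respondent-level random effects and item idiosyncrasies in
questionnaires, learning and fatigue across trials, device and motor
artifacts in trajectories.

## Simulation sizes and numerical choices

Study sizes used by the verification suite, chosen as the package's own
standing conditions: cohort-ordering checks use 200 simulated cohorts with
group sizes drawn uniformly in 20..80 (the range typical of usability
validation groups) and a focal latent shift of -0.6; null calibration uses
60 per group, where the average signed contrast should vanish (note the
*expected absolute* null contrast at this size is about 0.084 by the
large-sample SE — a mean-|r| criterion below that would be unattainable by
construction, which is why calibration is asserted on the signed average).
Bootstrap coverage uses 1000 replicates of two n = 50 groups with a
continuous latent shift of 0.5, where the true rank-biserial has the
closed form `2 pnorm(delta/sqrt(2)) - 1`, and 1000 bootstrap draws per
interval.

Other numerical conventions: display rounding is half-up at 2 decimals
(matching how validation tables are conventionally printed) while all
computation keeps full precision; the noncentrality inversion brackets by
doubling and solves to 1e-10; degenerate inputs (zero-length paths,
all-tied groups, chance-level agreement, empty factor scores) are defined
outcomes, not errors, except where a value would be meaningless
(`p_c = 1`), which raises a typed error. Session writes go through a
temporary file and an atomic rename, so a crash mid-write can never leave
a half-document; readers validate and report every schema violation at
once, and reject rather than repair.

## Known limitations

* The canonical arena layout, anomaly thresholds, ergonomics criterion
  list, and usability factor map are declared defaults, not published
  constants; all are constructor arguments.
* The rank-biserial and Cramér's V interval methods are conventions chosen
  here; published tables in this field rarely state theirs, so interval
  endpoints should not be expected to match other software to the digit.
* The Delphi comparison assumes the same raters in both rounds; it has no
  machinery for panel attrition beyond explicit masking.
* The simulator's group profiles are for pipeline testing, not for power
  analysis of real studies.
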