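---
title: "Models and methods behind trygiveup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trygiveup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trygiveup)
library(data.table)
```

## The task environment

A round presents two matrices of `n_keys = 12` unmarked keys. Each key's
latent outcome is drawn independently at round start — *Give-Up* keys pay
+1 or +2 with probability .5 each; *Try* keys pay +1 with probability .9,
+14 with probability .1 — and stays fixed for the rest of the round. The
first press of a key within a round costs 2 points; later presses of the
same key are free. A round lasts 12 trials; a block is 15 rounds; an
experiment is three blocks (baseline, treatment, baseline).

A treatment scheme is an additive transformation of this structure: a
per-matrix, per-level outcome delta plus a per-matrix exploration cost.
Every trial record decomposes its payoff as

```
net_points = raw_outcome + scheme_delta - cost_charged
```

which is what makes incentive stripping (below) exact rather than
approximate.

Two representational choices deserve a note:

* **`plus_try_explore` is modeled as a cost waiver.** Its displayed
  outcomes are unchanged and the Try exploration cost is 0, which is
  net-equivalent (for Try presses) to a +2 bonus on first presses. The
  waiver applies to the Try matrix only; Give-Up keys keep their cost. The
  alternative reading — that the scheme removed *all* exploration costs — is
  plausible from a table layout but not from the rule's stated scope, which
  rewards choices "in the Try set".
* **`minus_giveup_minus_trylow` penalizes low Try *outcomes*.** The −2
  applies to any low Try outcome, including one produced by a first-press
  exploration that happened to reveal a low key. Penalizing outcomes rather
  than intentions is the operational reading of a payoff-table definition;
  a classifier-based penalty ("punish choices inconsistent with optimal
  search") would be unimplementable for a participant-facing payoff rule,
  since a fresh exploration's outcome is unknown at choice time.

## The optimal-strategy benchmark

Keys are i.i.d. within a matrix, so observing outcomes never updates
beliefs about unexplored keys; only two things matter per matrix: the best
level revealed so far and how many keys remain unexplored. The solver's
state is therefore

```
(trials_remaining, best_try, best_giveup, unexplored_try, unexplored_giveup)
```

— at most 13 × 3 × 3 × 13 × 13 states — and `solve_dp()` fills the value
and action arrays by backward induction. Exploration's successor
distribution uses the matrix's `p_high`; exploitation targets the best
revealed level. Ties are broken by a fixed action order (exploit Try-high,
explore Try, exploit Give-Up-high, explore Give-Up, exploit Give-Up-low,
exploit Try-low), so solved policies are deterministic.

Two caveats are deliberate:

* Exploit actions only target the *best* revealed level of a matrix.
  Exploiting a worse revealed key is dominated whenever effective outcomes
  preserve the low ≤ high ordering, which all five shipped schemes do; the
  randomized oracle tests generate schemes under the same constraint.
* Levels are classified by outcome *value*. In the degenerate case
  `low_value == high_value` every revealed key reads as high; the solver,
  the brute-force oracle and the simulator all share this convention
  (`class_p_high()`), which keeps the three routes exactly consistent.

`brute_force_value()` certifies the belief abstraction: it recurses over
full information sets (per-key revealed values, every concrete key press,
every outcome realization) with no abstraction at all, and refuses
instances beyond 4 trials or 3 keys per matrix. The test suite checks
`|solve_dp − brute_force| ≤ 1e-9` on dozens of randomized instances; the
acceptance script repeats this on 50.

## The threshold family and the switch point

The restricted strategy family `S_m` formalizes "search Try, then settle":
explore fresh Try keys until a +14 is found (then exploit it to the round's
end) or until `m` explorations have failed; then explore fresh Give-Up keys
until a +2 is found and exploit that. `benchmark_strategy_comparison()`
evaluates every `m` exactly by a closed-form recursion over binomial
failure runs (simulation with standard errors is available as a
cross-check), and also computes, for every failure count `f`, the value of
switching now versus the best continuation that keeps exploring.

Under the default structure the result is one-sided: expected payoff is
strictly increasing in `m` (19.0 points per round at `m = 0` up to 69.7 at
`m = 12`), and at every failure count the keep-exploring continuation
dominates switching (for example, with three trials left after nine
failures: 4.87 versus 1.63 expected points). The intuition: a Try
exploration has positive immediate expected value (+0.3) *and* carries the
option value of finding a +14 worth 14 points per remaining trial, while a
Give-Up search must first pay the same exploration cost for at most 2
points per trial afterwards. A horizon effect does exist — the unrestricted
policy stops exploring on the *last* trial, exploiting a known +1 rather
than exploring (1 > 0.3) — but it never favors moving to the Give-Up
matrix. The familiar claim that optimal play shifts to Give-Up search after
nine failed explorations is therefore not supported by exact evaluation of
this family, and the benchmark report prints the full per-failure-count
comparison so the disagreement is visible rather than silently resolved.
The switch machinery itself is not vacuous: with a rarer high outcome,
richer Give-Up matrix or steeper Try cost, a genuine interior switch point
appears, and the tests exercise that case.

One consequence adopted throughout: the *choice classifier* used for the
dependent variables is the simple search-then-exploit rule (a fresh Try
press is benchmark-consistent while no +14 is known; exploiting a known +14
is benchmark-consistent; everything else is not), not the full solved
policy. The analysis window of the first nine trials exists precisely
because the simple rule and horizon-sensitive play can diverge late in the
round.

## Agents

Fixed agents operationalize the task's two local maxima — the
`giveup_searcher` (find a +2, milk it) and the `trylow_settler` (reveal one
Try key, exploit it regardless) — plus the `threshold_try(m)` family and
the `dp_optimal` agent that plays the solved policy. Agents receive only
the revealed-outcome map, never latent values.

The `adaptive_learner` models decisions-from-experience at the strategy
level rather than the key level: each round it picks one meta-strategy
(Give-Up search, Try-low settling, Try search) by softmax over propensities
with temperature `tau`, plays it for the whole round, then moves the chosen
propensity toward the realized round payoff by learning rate `alpha`. When
the scheme changes between blocks, propensities decay toward their initial
values by `rho` — the retention knob. A trial-level learner would be a
reasonable extension, but the phenomena of interest here (settling into a
local maximum, treatment-block shifts, partial retention) live at the
strategy level, and round-level credit assignment keeps the parameter space
small and recoverable.

This learner also reproduces underweighting of rare events without any
probability-weighting machinery: a Try-search round most often ends at −12
(twelve failed explorations), so early bad draws depress the try-search
propensity even though its true mean (~70) is far higher, and many agents
settle on Give-Up search (~19 per round) or Try-low settling (~10).

## The synthetic cohort

`generate_cohort()` emulates the full experimental design: four
between-subject conditions of 53, 55, 54 and 54 participants, each playing
baseline / treatment / baseline blocks of 15 rounds × 12 trials — 116,640
trial rows. Each participant is an independent learner whose `alpha`,
`tau`, `rho` are drawn from truncated normals (inverse-CDF draws, so the
stream is reproducible); defaults are `alpha ~ N(0.35, 0.15)` on
[0.05, 0.90], `tau ~ N(5, 2)` on [1, 12], `rho ~ N(0.40, 0.20)` on
[0, 0.95], initial propensities (14, 10, 6) for Give-Up search / settling /
Try search. The initial ordering encodes that safe options look best before
learning; magnitudes are on the round-payoff scale the update rule uses.
These population parameters were chosen once so a default cohort exhibits
the qualitative pattern the analysis assumes — Give-Up rates decline within
the pretreatment block, every treatment reduces Give-Up rates in block 2,
and rewarding any Try choice inflates Try-low exploitation where rewarding
exploration does not — and they are deliberately *not* estimates of human
parameters: the generator makes no quantitative claim about human effect
sizes.

What passing cohort tests do and do not show: they validate the analysis
pipeline end-to-end on data with the right design, learning structure and
qualitative treatment response; they do not validate any numeric human
effect size, reaction-time structure, within-round position effects, or
individual strategies outside the three meta-strategies.

Reproducibility is structural: every participant, block and round seed is
derived from the master seed by an integer hash (`derive_seed()`), so any
sub-unit can be regenerated in isolation and identical designs and seeds
give byte-identical CSV logs.

## Metrics and inference

`compute_rates()` computes, per participant × block over the first nine
trials of each round (135 choices): the Give-Up rate, Try-low exploitation
rate, Try-explore and Try-high shares (the four categories partition
choices and their shares sum to 1), the benchmark-consistent rate, and mean
payoffs per trial. The windowed *choice count* is the denominator
throughout — rates count choices, not opportunities — so a participant who
finds a +14 early still has nine classified choices per round.

`strip_incentives()` recomputes every trial's payoff under the baseline
scheme (raw outcome minus the baseline cost on first presses). Because
schemes are additive and outcome-level, this equals a baseline replay of
the identical choice sequence exactly, a property the tests assert as
equality, not tolerance.

`difference_scores()` forms per-participant block-2 − block-1 (treatment)
and block-3 − block-1 (retention) differences and summarizes them per
condition with normal-approximation 95% CIs (`mean ± 1.96·SE`); a
percentile bootstrap is available behind a flag since the CI convention for
such tables is rarely stated. `anova_oneway()` wraps the standard
`lm`/`anova` decomposition with two guards: groups with fewer than two
observations refuse inference, and an all-constant-groups response reports
a divergent `F = Inf` with a warning instead of an unstable ratio.
`dv_correlation()` reports per-condition Pearson correlations and their
Fisher-z average, clamping |r| below 1 − 1e−12 so a perfect anticorrelation
stays finite under the transform. Multivariate inference (MANOVA) is left
to general-purpose statistics software; the pipeline emits the per-DV
difference table such software consumes.

## Numerical choices and problem sizes

* DP ties are broken by the fixed action-priority order; all comparisons
  are strict, so exact ties resolve to the higher-priority action.
* The brute-force oracle's guard (≤ 4 trials, ≤ 3 keys per matrix) keeps
  exhaustive recursion around 20k paths.
* Monte-Carlo consistency checks use 3-standard-error bands: 10,000 rounds
  in the unit tests, 100,000 in the acceptance script.
* The default test cohorts are scaled down (10 participants per condition)
  for the property tests; the acceptance checks run the full 216-participant
  design.
* Degenerate inputs: zero-trial configs give trivial value 0; `p_high` of
  0 or 1 are exact; equal low/high values follow the value-classification
  convention above; unknown scheme names, out-of-range probabilities and
  out-of-bounds keys raise errors naming the offending field.

## Known limitations

* The learner is a three-strategy round-level chooser; it cannot express
  within-round strategy switches (e.g. exploring Try early and settling
  mid-round), which real participants plausibly do.
* The benchmark classifier treats any fresh Try press as consistent while
  no +14 is known, including presses an unrestricted horizon-aware policy
  would not make on the final trial.
* Normal-approximation CIs can dip below 0 or above 100 percentage points
  for rates near the boundary; use the bootstrap flag where that matters.
* The cohort generator models no dropout, attention lapses, or
  position/layout effects (keys are indices; on-screen layout is treated as
  presentation only).
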