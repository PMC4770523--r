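---
title: "Modeling advance care planning as staged behavior change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling advance care planning as staged behavior change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpabm)
```

## The model

Advance care planning (ACP) — deciding, discussing and documenting
end-of-life treatment preferences ahead of incapacitation — is hard to
study longitudinally: behavior unfolds over years and is difficult to
intervene on experimentally. `acpabm` implements a dynamic agent-based
model of ACP adoption built on the Transtheoretical Model (TTM) of
behavior change, collapsed to four stages:

> pre-contemplation (0) → contemplation (1) → preparation (2) →
> action-maintenance (3)

Each agent carries, besides its stage, an integer *propensity score* on a
0–100 scale. Experiences and interactions add or subtract points; when the
score reaches the threshold to enter the next stage the agent advances
deterministically, and its score is reset to the destination stage's
baseline. After every advancement the new stage is immediately
re-evaluated, so one large award can chain through several stages (this
matters for the second preset, where the contemplation baseline equals the
preparation entry threshold). Accumulated *negative* influence that would
push the score below zero instead knocks the agent one stage down — at
most one stage per tick — again resetting to the destination baseline.
Action-maintenance is absorbing under positive influence.

One tick is one day; published runs last 1825 ticks (five years). Within a
tick the phases run in a fixed order: stage snapshot → movement → patch
events → social influence → transition evaluation → recording. The fixed
order, identifier-ordered processing and a single seeded RNG stream make
runs bit-reproducible.

### Experiences: event patches

Agents live on a toroidal cell grid holding three disjoint rectangular
event patches, each with an effect probability and a point award:

| event | probability | points (sim1 / sim2) | rationale |
|---|---|---|---|
| personal ICU stay | 33% | 4 / 6 | rare, high impact |
| loved one's critical illness/death | 67% | 3 / 4 | common, lesser impact |
| primary-care visit | 10% | 1 / 1 | frequent setting, low urgency |

An agent whose occupied cell lies inside a footprint experiences the event
with that probability and, if susceptible, receives the award. The ICU
footprint is smaller than the loved-one footprint (one is only one person,
but knows many), and the primary-care patch sits nearer the ICU patch than
the loved-one patch, reflecting post-ICU follow-up care.

### Social interactions

Agents sharing a cell "talk". With a stage gap $g \ge 1$, the lower-stage
agent gains `social_up`·$g$ points and the higher-stage agent loses
`social_down`·$g$ points (linear gap scaling is the default: greater
disparity, greater influence; a flat mode is available). Two gates apply
per agent: only susceptible agents receive outcomes, and pre-contemplation
agents are never influenced upward — someone who has never considered ACP
is not moved by others' enthusiasm. Negative social influence is the only
backsliding channel. Stage comparisons use the start-of-tick snapshot, so
outcomes are independent of pair processing order.

### Susceptibility

An immutable Bernoulli trait assigned at initialization. Non-susceptible
agents are unaffected by *all* influencing factors — patches and
interactions alike — so their (stage, score) is frozen for the whole run.
This is what pins the residual pre-contemplation and contemplation
fractions in the second experiment near half of their initial shares.

### Movement

Two regimes. *Random networks* (`teleport`): each tick every agent
relocates uniformly over the grid, fully mixing the population.
*Local networks* (`local`): each tick an agent draws a uniform heading and
steps exactly 0.15 cell-lengths, wrapping toroidally, so its social
surroundings stay relatively stable. The rate 0.15 is read as
cell-lengths per tick.

## The two presets

`acp_preset("sim1")` is the idealized completion experiment: everyone
starts in pre-contemplation at score 0, everyone is susceptible,
thresholds (60, 20, 100), all baselines 0, points (ICU 4, loved-one 3,
PCP 1, social up 3, down 1), teleport movement. All 200 agents complete
the process within five years; the contemplation count wavers (rises and
dips) early — interactions between the first two stages — before the
population drains quickly through preparation into action-maintenance.

`acp_preset("sim2")` mimics observed population rates: initial
distribution (40, 40, 20, 0)%, baselines (100, 50, 0, 50), thresholds
(100, 50, 100), points (ICU 6, loved-one 4, PCP 1, social up 2, down 2),
susceptibility 50%, local movement at 0.15. Note the arithmetic this
encodes: a susceptible pre-contemplator sits at the clamp (baseline 100 =
entry threshold), so its *first* experience chains it through
contemplation (reset to 50, which is exactly the preparation threshold)
straight into preparation; advancement therefore requires `score >=
threshold`, not a strict inequality, or the whole population would freeze.
Transitions are evaluated only for agents that received a non-zero point
delta in the tick — evaluating unconditionally would advance every
pre-contemplator at initialization, susceptible or not.

## Calibration note: grid and footprint geometry

The published parameter table fixes thresholds, baselines, points,
probabilities and susceptibility, but not the grid size, patch footprints
or population size. These free geometry parameters were calibrated once
against the published outcome distribution and then frozen into both
presets:

* grid 120 × 44 cells, N = 200 agents;
* LOVED_ONE 60 × 44 at (0, 0); PRIMARY_CARE 2 × 2 at (60, 21);
  ICU 58 × 44 at (62, 0).

Two quantities drive the calibration. First, the *patch point flux* — the
expected points per tick for a uniformly placed susceptible agent,
$\sum_k \text{area}_k\, p_k\, \text{pts}_k / (WH)$ — must be large enough
that five years of exposure carries an agent through all thresholds
(~1.6 points/tick here for sim1). Tiny decorative footprints (a 1 × 1 ICU
on a 33 × 33 grid) give a flux of ~0.02 points/tick, under which nobody
can even leave pre-contemplation in 1825 ticks. Second, the *social drag*
on high-stage agents scales with agent density (N−1)/(WH); with half the
population frozen in low stages (sim2), a dense grid makes the drag on
action-maintenance agents exceed their patch gains and the population
churns instead of settling near the published ~51% adoption. The frozen
layout keeps patch coverage near-total (the only patch-free cells are a
two-column strip around primary care) while keeping density low
(~0.04 agents/cell), so nearly all susceptible agents complete the process
and the frozen half supplies the residual lower-stage mass. Smaller
same-proportion layouts (44 × 20, 80 × 30) reproduce the same pattern with
slightly more churn in preparation.

## Numerical choices

* **Scores are integers.** All published awards are integers; integer
  arithmetic avoids tolerance questions at thresholds.
* **Comparison operator.** Advancement uses `>=` (see above).
* **Threshold reading.** The three threshold values are the scores
  required to *enter* contemplation, preparation and action-maintenance
  from the stage below; the single action-maintenance value (100) applies
  to both presets.
* **Score reset.** Every stage change, up or down, resets the score to
  the destination stage's baseline — this is what the per-stage baseline
  values mean after initialization.
* **Backslide granularity.** One stage down per tick, no cascades, and no
  re-advancement in the same evaluation.
* **Apportionment.** Initial stage counts use largest-remainder
  apportionment of the percentage distribution; remainder ties go to the
  lower stage.
* **Interaction locus.** Same occupied cell only (patch-mates). Pairs
  always interact on co-location; no additional probability roll.
* **Annual-update relapse** (action-maintenance agents who fail to update
  their plan relapsing into preparation) is implemented as an optional
  Bernoulli check every 365 ticks, off by default: backsliding through
  negative interaction already provides the relapse channel in the
  published experiments.
* **RNG.** One stream per run seeded from the caller; replicate *r* of a
  batch uses `base_seed + r`. Within a tick randomness is consumed in a
  fixed order (movement, then patch rolls in ICU/loved-one/primary-care
  order, then relapse if enabled).

## Validation against an exact Markov chain

Under teleport movement with social influence off, agents are independent
and identically distributed: per tick an agent occupies patch *k* with
probability area$_k$/(WH) and its (stage, score) evolves on the 404-state
space {0..3} × {0..100}. `markov_oracle()` computes the exact per-tick
stage distribution of this chain by dynamic programming and mixes in the
frozen non-susceptible mass. The test suite and acceptance script compare
a 2000-agent simulation with the oracle at ticks 100, 500 and 1825 and
require agreement within 3 binomial standard errors per stage — an
end-to-end check of movement, patch encounters, susceptibility gating and
the transition rules. The oracle shares only the scalar stage-machine
operations with the engine; the engine's vectorized kernel is itself
checked against an independently coded brute-force reference over the full
(stage, score, delta) grid.

## What the tests do and do not show

The simulated population is a deliberately minimal abstraction: agents
have no families, persistent networks, ages, health states or
demographics, and only three of the many influences on ACP are modeled.
Reproducing the published outcome distributions therefore shows the
*mechanism* is sufficient to generate population-level patterns, not that
it is the mechanism operating in real populations. Trajectory shapes
(early pre-contemplation/contemplation wavering, fast preparation transit)
are checked qualitatively only; the published figure curves are not
numeric targets.

Problem sizes used by the test suite: full-length (1825-tick) runs for
the preset reproductions (5 replicates of sim1, 20 of sim2) and the
oracle comparison (N = 2000); shortened runs (40–400 ticks) for
structural properties, where the property holds tick-by-tick and run
length adds nothing.

## A worked run

```{r example, fig.width = 7, fig.height = 4}
params <- acp_preset("sim1")
run <- acp_run(params, seed = 1)
round(run$final_percent, 1)
plot(run, main = "Simulation 1: idealized completion")
```

```{r sim2, eval = FALSE}
# The population-rate experiment, summarized over replicates:
summ <- run_replicates(acp_preset("sim2"), n_reps = 20, base_seed = 1)
summ
compare_to_expected(summ) # mean |obs - expected| vs (40, 10, 3, 47)
```
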