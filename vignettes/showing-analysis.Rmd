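---
title: "Detecting and modelling showing behavior in dog-owner dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling showing behavior in dog-owner dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canishow)
```

## The problem

In hidden-object tasks a dog watches a toy being hidden in one of four boxes
while the owner is out of the room; the owner then has to find the toy using
only the dog's behavior. Dogs solve this with *showing*: a communicative act
that combines a **directional component** referencing the hiding place
(gazing at, moving towards, staying near, jumping/standing upright at, or
opening a box) with an **attention-getting component** directed at the owner
(gazing at the owner, moving towards the owner, or vocalizing). The two
components count as one showing when they overlap in time, or when one
follows the other within two seconds (the classic gaze-alternation rule,
generalized to all 5 x 3 = 15 component combinations).

`canishow` implements the full analysis chain for such experiments: event-log
ingestion and validation, showing detection, observation-level scoring
(accuracy, choice rate, effort), and the inferential layer (t tests against
chance, binomial mixed models for success, Gaussian mixed models for effort,
AIC-based model selection). A synthetic dyadic generator reproduces the
statistical structure of the design so that every stage is testable without
video-coded data.

## Event model and detection rules

Coded behavior is a list of events on a 0.20 s grid (the coder's temporal
sensitivity), with half-open intervals `[onset, offset)` in seconds from
phase start. The conventions, and why they were chosen:

* **Half-open intervals** make abutting events (one ends exactly where the
  next begins) non-overlapping, which matches frame-based coding.
* **Point events** (a single bark) occupy one 0.20 s frame, so frequency and
  duration coding share one representation.
* **Times are canonicalized** to the nearest decimal double at construction;
  identical coded times then compare exactly no matter how they were
  computed, and write/read round trips are bit-identical.
* A **`retrieve`** event (the dog fetches the toy itself) truncates the
  analyzable window of its phase at its onset: after retrieval the trial
  outcome is fixed, so later behavior is not communication about the
  hiding place.
* All owner behaviors collapse into the single composite code
  `owner_behavior`, analysed by frequency only.

Detection pairs every directional dog event with every attention-getting dog
event that overlaps it, or alternates with it within the window
(default 2 s). Three decisions here were genuinely open and are fixed as
follows:

* **The 2 s bound is inclusive** (a gap of exactly 2.0 s qualifies), and the
  gap runs from the earlier component's offset to the later component's
  onset. Component order never matters.
* **All-pairs counting, not one-to-one matching**: a long state event (e.g.
  ten seconds spent near a box) forms one showing with *each* attention
  event that qualifies. This reproduces the high observed frequencies of
  near-box showings; a greedy matching would undercount them.
* A pair that qualifies both by overlap and by gap is counted **once, as
  overlap** — overlap is the stronger relation, and double counting would
  inflate frequencies.

No intervening-event rule is applied ("followed directly" is
operationalized purely by the 2 s bound): the alternative would need an
arbitrary definition of which events may intervene, and the bound alone is
reproducible. Output order is canonical (anchor, type id, referent), so runs
are byte-identical.

`brute_force_detect()` is a deliberately literal quadratic re-implementation
kept solely as an independent oracle; the test suite checks multiset
equivalence with `detect_showings()` on a thousand random logs, including
logs off the 0.20 s grid and logs with retrieve truncation.

## Derived scores

One **observation cell** is one pair x session x trial x phase. Per cell:

* `prop_correct_showing` — showings at the target box over all showings.
  Cells with **zero showings are missing, not zero**: a ratio of nothing is
  not evidence of incorrect showing. Missing values propagate into models as
  listwise row exclusion.
* `effort` — high-effort showings over high + low. Low effort is gaze
  alternation (type 1); high effort comprises the three jumping/standing
  pairings and move-towards-box + move-towards-owner (added because many
  dogs never jump). Cells with neither low- nor high-effort showings have
  undefined effort.
* `success` — the phase's choice equals the target box. A phase-1
  questionnaire with no box marked is coded 0 and is always a failure. If
  the dog retrieved in phase 1, the retrieved box stands as the choice of
  both phases.

The per-type summary (mean frequency per cell, accuracy, choice rate)
mirrors the usual 15-row table; a type that never occurs is flagged rather
than shown as 0/0. Choice rate uses the phase-matched choice by default —
whether the phase-1 rate should instead use the finally opened box is not
decidable from the design, so `use_phase2_choice = TRUE` exposes the
alternative.

For the accuracy-versus-time correlation, each showing's time is its anchor
second within the trial; phase-2 anchors are offset by the phase-1 duration.

Inter-coder reliability is Spearman's rank correlation per behavior, with
the conventional Cicchetti interpretation bands fixed at 0.40 / 0.60 / 0.75
(poor / fair / good / excellent).

## The model layer

Success is binary, so communication success is modelled as a binomial-logit
GLMM with a **random intercept per pair** — the pair is the repeated unit,
and nothing in the design motivates random slopes; the simplest structure
consistent with the sampling is used. Fixed effects are configurable;
the canonical models use the correct-showing proportion, condition
(close/far box spacing), and *time*. Time is the nested phase-in-trial-in-
session factor, coded as a session main effect plus a centered linear trial
term within each session plus a phase-2 dummy within each session — this
matches the way nested temporal contrasts ("trial in session 1", "phase in
session 2") are conventionally reported for this design. Estimation is
Laplace-approximate ML via lme4; on a convergence warning the model is
automatically refit with BOBYQA, and a fit that still fails is flagged, not
silently returned.

Showing effort is a proportion but is modelled on the raw scale with a
Gaussian LMM (REML), as is conventional for this literature; p-values use
**Satterthwaite denominator degrees of freedom**. Because no
Satterthwaite implementation is available in the dependency set, the
package computes them directly for the single-random-intercept model class
it fits: the marginal covariance is block-diagonal
(`V_j = sigma^2 I + tau^2 J`), so the REML criterion and `Var(beta)` have
closed block forms, and the df are
`2 f^2 / (g' W g)` with `g` the finite-difference gradient of
`f = Var(beta_i)` in `(tau^2, sigma^2)` and `W` twice the inverse
finite-difference Hessian of the criterion. At a boundary estimate
(`tau^2 ~ 0`) the classical residual df are returned. A balanced-design
check in the test suite confirms that within-pair contrasts get df near the
residual dimension `n - J`.

Model selection follows the smallest-AIC rule with ties broken by
declaration order, plus the chi-square likelihood-ratio test
(`chi^2 = 2 dlogLik`, `df = dk`) for declared nested pairs; fits on
different row sets are rejected as incomparable. Note that LRTs comparing
fixed effects require ML fits (`REML = FALSE`); the package warns otherwise.

One-sample tests of per-pair success percentages run against the 25%
chance level of a four-box choice. Cohen's d is the mean deviation over the
sample SD, with its confidence interval by noncentral-t inversion (no CI
method is canonical here; the noncentral-t interval is exact under
normality). For paired tests both the change-score d (`mean diff / SD of
diffs`) and the pooled-SD d are reported. A caveat worth recording: for
this design the published phase-level statistics of the motivating
experiments are consistent with a test against 0 rather than against the
25% chance level (e.g. M = 53.75, SD = 24.82, n = 30 gives t = 6.34
against 25 but t = 11.86 against 0); `canishow` always tests against the
stated chance level, and the test suite pins both values of that example.

## What the generator emulates — and what it does not

`simulate_dataset()` states the design world: 30 pairs, 2 sessions of 4
trials x 2 phases of 60 s, one condition per session with order alternating
across pairs, each box target twice per pair, never twice in consecutive
trials of a session, and the first target box cycling over pairs.
Behavior streams are Poisson onsets with exponential durations snapped to
the grid (minimum one frame); same-code (and same-referent) state events
are placed without overlap, since a coder cannot code one behavior as
active twice at once. Event rates and durations are loosely anchored to the
observed per-cell showing frequencies of this paradigm (gaze alternation
~9 per cell, near-box showings the most common, jumping ~0.5 and box
opening ~0.05 per cell); they are stated once as defaults, not fitted.
`p_correct = 0.35` puts realized showing accuracy in the observed 0.25-0.45
band.

Success is drawn from `logistic(beta0 + beta_correct * p)` where `p` is the
**realized** correct-showing proportion of the generated cell — not a
latent tendency — so the GLMM's estimand equals the generator slope exactly
and parameter recovery is a clean test. Defaults `beta0 = -2.2`,
`beta_correct = 6.8` give an overall success rate near the observed ~55%.
Cells without showings fall back to the chance accuracy 0.25, which makes
the null configuration (`beta_correct = 0`, `beta0 = logit(0.25)`) exactly
chance-level everywhere. On failure the choice is a uniform wrong box, or,
in phase 1 with small probability, no box at all (coded 0).

The generator deliberately has **no behavioral realism beyond this
statistical structure**: no bout structure, no dog-state dynamics, no
coupling between behaviors, no owner-dog feedback loop. A green
recovery test therefore establishes that the pipeline measures what the
models assume — not that real dogs behave like the generator.

The row-level companion `simulate_observation_rows()` skips the event
streams and draws observation cells directly (binomial accuracy around
`p_correct`, Gaussian pair-effect model for effort with a phase effect,
default -0.05 on the proportion scale); it exists for model-recovery
studies where the event layer only adds runtime.

## Numerical choices and degenerate inputs

* Grid snapping rounds half up (`snap_to_grid(0.5)` is 0.6) and is
  idempotent; a 1e-9 epsilon absorbs float droop at exact midpoints.
* The alternation bound uses a 1e-9 tolerance so a gap stored as
  2.0000000000004 s still qualifies.
* Zero-variance inputs error in the t tests (a t statistic would be
  infinite), but yield *flagged undefined* results in correlations and
  reliability — there the undefined value is a legitimate data outcome
  (e.g. a showing type that is always correct), not a misuse.
* Tied AICs select the first-declared model; the detector breaks ordering
  ties by type id, referent, then source event ids, so output never depends
  on hash order.
* Finite-difference steps in the Satterthwaite code are 1e-4 of each
  variance estimate; degrees of freedom are clamped to `[1, n - p]`.

## Scale of the shipped checks

The acceptance-level tests run the heavy checks at the stated scale
(1,000 random logs for detector equivalence; 100 simulated studies for GLMM
slope recovery; 100 replicates for the LMM phase effect; 200 replicates for
null calibration and LRT uniformity). Two of the null-calibration halves
are scaled to keep runtime bounded: the chance-success check runs the full
event-level simulator with rates at 40% of the defaults (under
`beta_correct = 0` success is Bernoulli(0.25) regardless of the event
streams, so only runtime changes), and the LRT-uniformity check uses
Gaussian ML fits at 20 pairs. Both choices are visible in the test code.

## Known limitations

* Effort is a proportion modelled with a Gaussian LMM; a beta or binomial
  model would respect the scale but would not match the conventional
  analysis this package reproduces.
* The Satterthwaite implementation covers exactly the model class the
  package fits (one scalar random intercept); any other structure is
  rejected rather than approximated.
* `validate_dataset()` cannot detect all coding pathologies (e.g. a gaze
  coded at two boxes at once is representable and legal).
* The owner's behavior enters only as a per-cell count; its sub-codes and
  any sequential structure of the dyadic interaction are out of scope.
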