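---
title: "Mechanisms, fitting, and design choices in spriming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanisms, fitting, and design choices in spriming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spriming)
```

## The task and the three mechanisms

Every model in this package performs a stylized prime–target trial: it
comprehends a prime sentence realizing one member of a structural
alternation (active/passive, or double-object/prepositional-dative), then
produces a description, emitting a structure label or `"unknown"`. The
measured quantity is the per-condition proportion of productions
congruent with the prime, and the phenomenon of interest is how that
proportion changes when the prime contains a grammatical error.

**Activation.** Structures are declarative chunks. Comprehension
re-presents the primed chunk (once at parse, once more on successful
cued retrieval), production retrieves the most active chunk under
base-level learning `B = ln Σ t_j^(-d)` plus logistic noise. The error
is assumed never to be parsed, so the code path literally does not read
the grammaticality flag: blindness is structural, and the test suite
verifies it by flipping every flag under an identical RNG stream.

**Associative.** As above, plus spreading activation. An ungrammatical
prime places a shared error-context chunk in the buffer context with
weight `ga`; at production it spreads `ga · max(0, mas − ln fan)` to the
structure it co-occurred with. Two design points deserve explanation:

* *The error–structure association is episodic.* The spreading source
  boosts only the structure primed on the current trial. An earlier
  design in which the association was permanent turned out to be
  self-defeating: once both structures had ever co-occurred with an
  error, the shared source spread equally to both and the differential
  effect cancelled, making the mechanism unidentifiable from the
  activation model. The episodic reading also matches the underlying
  theory — it is the current imaginal-buffer episode, not the lifetime
  association, that directs attention.
* *Fan grows with pairing history.* Persistent, retrieval-ineligible
  episode chunks (one per structure the error context has ever paired
  with) make `fan` grow, so the boost shrinks as error–structure
  pairings become common. This implements the inverse-frequency
  intuition: rarer pairings spread more.
* Association strengths are clamped at zero from below; a high-fan
  source stops helping rather than inhibiting, a regime the theory
  never discusses.

The direction of the resulting modulation (amplification of priming
after errors, under the defaults) is a model output, not an assertion:
surprise-based accounts predict amplification while feedback-based
accounts predict dampening, and the package records the simulated
direction per configuration rather than hard-coding either.

**Reinforcement.** Structures are productions with utilities updated by
`U ← U + α(R − U)`; feedback `r+`/`r−` arrives at the end of
comprehension and credits exactly the production that fired during the
prime (target-time production is not rewarded by default — the minimal
credit-assignment assumption; a flag extends it). No temporal reward
discounting is applied: the update rule is implemented exactly as
stated, with discounting available behind a configuration option.

**Sequential reinforcement.** The feedback respects word order. Incorrect
passives reveal their structure (the auxiliary) before the error, so the
structure production has fired and absorbs `r−`; incorrect actives
surface the error at or before the point where the structure becomes
identifiable, so the structure production escapes punishment and still
collects `r+` on successful completion. On the A/P design this predicts
modulation only for passive primes; on a design where all errors precede
structure identification (the DO/PD design), it reduces to
grammaticality blindness.

## Parameters, defaults, and the time base

Grid value sets (`default_parameter_grid(..., reduced = FALSE)`):
activation `ans` × `bll` × `lf` (6 × 5 × 5, k = 3); associative adds
`ga` and `mas` with a shorter `lf` set (6 × 5 × 4 × 4 × 3, k = 5);
reinforcement `egs` × `alpha` × `r+` × `r−` (5 × 5 × 6 × 6, k = 4).
Defaults sit mid-set: `ans = 0.5`, `bll = 0.5`, `lf = 0.5` (0.9 for the
associative variant, whose `lf` set starts at 0.5), `ga = 1`,
`mas = 3.2`, `egs = 0.5`, `alpha = 0.3`, `r+ = 1`, `r− = −1`. The
retrieval threshold is `rt = 0` and noise is logistic — the standard
convention for both activation and utility noise, with scale parameters
`ans` and `egs`.

Power-law decay needs a time base, which the behavioral task does not
pin down. The package uses a 10 s inter-trial interval and a 5 s
prime-to-target gap (verification response, waiting period, picture
encoding). The gap is load-bearing: at a gap of zero the just-presented
prime chunk has age ≈ 0, its recency term diverges, and every
declarative-variant condition saturates at 1. Retrieval latency
`F·e^(−A)` additionally advances the clock, which is what gives the
latency factor `lf` a causal role in the choice proportions.

Baseline knowledge is seeded deterministically: the first alternation
member's chunk receives 16 presentations and the second 6, evenly
spaced over a 100 s pre-experiment window. The 16:6 ratio fixes the
baseline base-level gap at `ln(16/6) ≈ 0.98`, which under the default
noise yields the strong first-member production bias seen in behavioral
response distributions (actives and double-objects dominate).
Utilities start equal at 0 by default (an asymmetric start is available
to encode bias procedurally).

## Trial schedules and condition summaries

`make_schedule("exp1")` builds 36 active/passive trials (18 per
structure, one third ungrammatical, semantic flag balanced within each
cell; incorrect actives carry pre-structure errors, incorrect passives
post-structure ones). `"exp2"` builds 20 DO/PD trials, 5 per cell, all
errors pre-structure. `"paper40"` provides the 40-trial, 10-per-cell
protocol used in pure simulation studies. The semantic-correctness flag
is carried through generation and I/O but consumed by no model: no
semantic mechanism is implemented, keeping the generator faithful to
the design without inventing one.

`simulate_condition_summary()` runs the model `n_runs` times (50 by
default, matching the simulation protocol) on independently seeded
copies and reports per-cell means and SDs of the congruent-production
proportion. By default each run re-randomizes the trial order: with a
single fixed order, condition cells confound with schedule position and
even the grammaticality-blind model shows a spurious modulation — an
artifact of the list, not the mechanism, which the experiments
themselves avoided by counterbalancing. `"unknown"` productions are
excluded from denominators, mirroring the exclusion of uncodable
responses from the behavioral analyses; an all-unknown cell flags the
summary degenerate rather than silently producing `NaN`.

## The empirical likelihood, BIC, and group comparison

A parameter point's summary defines a normal predictive density per
condition; a participant's observed congruent proportions `x_i` score

`logL = Σ_i log φ((x_i − x̄_i)/σ_i) − Σ_i log σ_i`,

a true log-density (the Jacobian term is included; `density = FALSE`
drops the constant and Jacobian for sensitivity analysis). Predictive
SDs are floored at 0.01: a noise-free parameter point has σ = 0 and
would otherwise dominate every comparison with an unbounded density.
`BIC = −2 logL + k ln n` uses `n = 4` — the four fitted condition
proportions per participant. Tying `n` to the number of simulation runs
instead is arithmetically possible but conflates the analyst's
simulation budget with the participant's data; with `n` fixed within a
model, BIC ranking reduces to likelihood ranking, and no claim is made
of matching any absolute BIC value.

`fit_cohort()` exploits the fact that summaries depend on the model,
parameters, schedule and seeds but not on the participant: each grid
point is simulated once and scored against every participant (an
optional cache directory persists the summaries). Ties in BIC break by
first-in-grid order. Grid-point seeds advance in non-overlapping blocks
(`seed + (g−1)·n_runs`), so every point sees independent runs — the
repetitions are per parameter point, not shared.

Group comparison sums each model's best-fit per-participant
log-likelihoods and forms `GBF = e^d` from the difference; `format_bf()`
renders the factor in base-10 E-notation from the log difference
without exponentiating, so astronomically large factors print exactly.
Evidence bands are lower-inclusive ([3.2, 10) substantial, [10, 100)
strong, ≥ 100 decisive): strict inequalities would leave boundary
values unclassified.

## The synthetic cohort generator

`generate_cohort()` emulates a coded response table: per participant a
logit-scale random intercept `b ~ N(0, sd²)` (default sd = 1,
reflecting the large individual differences such experiments show;
intraclass correlations are not matched exactly — the heterogeneity
magnitude is an exposed knob), per trial a first-member response with
probability `plogis(shift_cell + b)`, and uncodable responses at rates
1.42% / 7.46% for the two calibrations. The cell shifts are solved
numerically (quadrature plus root-finding, tolerance 1e-10) so that the
population-average proportion equals the specified cell probability
exactly despite the logit nonlinearity; the naive `qlogis(p)` shift
would bias every cell toward 0.5. The default calibrations are the two
experiments' published per-cell response proportions, with 89 and 125
participants (post-exclusion counts).

What the generator deliberately does not emulate: trial-order effects,
cumulativity within a session, lexical boost, response times, semantic
confusion, or any mechanistic grammaticality process — its
grammaticality structure is entirely carried by the four cell
probabilities. Passing tests on synthetic cohorts therefore validate
the statistical pipeline (generation → descriptive statistics →
fitting → comparison), not any claim that real participants are
logit-normal responders. One consequence worth knowing: because the
generator's priming is grammaticality-symmetric apart from the small
marginal shift, synthetic cohorts are typically best fit by the
grammaticality-blind activation model — unlike real cohorts, whose
individual-level modulation is exactly what the model comparison is
designed to detect.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen as the package's
own defaults: reduced grids (≤ 3 values per parameter, every value drawn
from the full sets and containing the default point), 20–50 runs per
point, 200 replicate cohorts for the behavioral summaries, and
12-participant model-generated cohorts for the recovery experiment (5
seeded replicates per generating mechanism, with the recovered-model
check demanding a majority per mechanism). The full grids (up to 1440 points for the associative model)
remain available behind `reduced = FALSE` and `--full-grid`.

Other numerical conventions: retrieval and selection ties break
uniformly at random; chunk histories are kept strictly increasing (a
presentation landing on a non-advanced clock is nudged by 1 µs);
retrieval activations are evaluated 1 ns after `now` so that
presentations stamped at the current instant count as past; all
stochastic entry points take explicit seeds and derive non-overlapping
per-run seeds from them.

## Known limitations

* The models are trial-level, not word-by-word: no incremental parsing,
  no lexical representations, hence no lexical-boost or cross-linguistic
  predictions.
* The empirical likelihood treats the four condition proportions as
  independent normals; with 5–12 trials per cell the normal
  approximation is coarse, and the likelihood surface is accordingly
  flat — parameter recovery is reliable at the level of predictive
  distributions, not of individual parameter values (the test suite
  checks exactly that).
* Group comparison uses best-fit (maximum) likelihoods, not
  marginalized ones, so it shares the optimism of all profile-likelihood
  Bayes factors; the BIC's complexity penalty applies within models,
  not between them.
* Absolute group log-likelihoods depend on cohort size and the σ floor;
  only differences (Bayes factors) are interpretable, and the reference
  table shipped in `inst/extdata/` is used for arithmetic cross-checks
  of the comparison machinery, not as a fitting target.
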