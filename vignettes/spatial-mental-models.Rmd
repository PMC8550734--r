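---
title: "Mental-model simulation and individual-level evaluation of spatial reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mental-model simulation and individual-level evaluation of spatial reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmm)
```

## The problem

People who read "the apple is to the left of the mango; the apple is to the
left of the pear" appear to build a *mental model* — a concrete spatial
arrangement of the objects — inspect it, and sometimes search for alternative
arrangements. Several computational theories make this precise in different
ways: as incremental placement on a coordinate lattice, as a spatial array
manipulated by a focus with operation costs, or as a linked queue of objects
built by language-driven insertion rules. These theories have traditionally
been compared by whether they reproduce aggregate effects (error-rate
differences between problem types). This package instead supports the
stricter question: how well does each model predict the *individual*
responses of single reasoners, trial by trial?

The package provides

* a shared qualitative vocabulary and task dialect (`premise()`,
  `problem()`, `parse_task()`),
* a logic oracle (`compose_relations()`, `enumerate_models()`,
  `verify_conclusion()`, `closure_table()`),
* three cognitive model families (`spatial_reasoner()`, `prism_model()`,
  `verbal_model()`) and five baselines (`random_model()`, `mfa_model()`,
  `closure_model()`, `best_model()`, `optimal_model()`),
* synthetic generators for four classic benchmark designs
  (`gen_figural()`, `gen_continuity()`, `gen_cardinal()`,
  `gen_smalllarge()`) with simulated responders
  (`simulate_responses()`), and
* a coverage-style evaluation (`coverage()`) with co-optimality analysis.

## Relation semantics

Two disjoint vocabularies are supported: one-dimensional `left`/`right` and
the eight cardinal directions. Every relation is encoded as a sign pair
`(dx, dy)` in a frame where x grows eastward and y northward; "A north B"
means `x(A) = x(B)` and `y(A) > y(B)` — each relation constrains *both*
axes (exact-axis semantics). Experimental instructions rarely state whether
participants read "north" exactly like this or as a broad sector; we fix the
exact-axis reading throughout and expose nothing else, because it makes
composition purely sign-arithmetical and reproduces the familiar
indeterminacy of opposite-relation problems (south-west followed by
north-east admits all eight conclusions). All benchmark problems are
generated under the same semantics, so the choice is internally consistent;
comparisons against human data collected under a different reading would
conflate semantics with model quality.

## The logic oracle

`enumerate_models()` lists every qualitative arrangement of the terms that
satisfies the premises, with terms on distinct lattice cells. Because only
per-axis rank orders matter under exact-axis semantics, enumeration works
directly over dense-rank assignments per axis (weak orders) and crosses the
two axes, discarding assignments that would stack two terms on one cell.
This is equivalent to scanning a sufficiently wide lattice and
canonicalizing by rank pattern, but stays feasible in pure R up to the six
terms the package supports. Models are translated so the first term sits at
the origin.

`compose_relations()` composes two relations axis-wise: an axis is
determined when its two signed constraints agree or one is zero, opposite
signs leave it unconstrained, and the result is every relation matching all
determined axes. The test suite checks exhaustively that composition and
enumeration agree on all 64 ordered cardinal pairs, and `closure_table()`
(iterated composition, i.e. path consistency) agrees with enumeration on the
chain-structured problems the benchmarks use. `verify_conclusion()` is
always enumeration-based, so oracle verdicts never depend on the
propagation shortcut.

Oracle models keep terms on distinct cells. The coordinate reasoner below
may stack terms *temporarily* while searching; a returned model never does.

## SpatialReasoner: four outcomes, four policies

`sr_build_model()` builds the deterministic *initial model*: the first term
at the origin, every new term at the first free cell scanning outward from
its reference term in the premise direction. `sr_integrate()` classifies a
putative assertion into one of four outcomes: `truth` (holds in every
model), `falsity` (in none), `weak_falsification` (holds in the initial
model but is refutable), `weak_truthification` (fails in the initial model
but some reinterpretation of the premises satisfies it). The published
description of weak falsification is elliptical ("the constructed model was
previously true"); we adopt the initially-true-but-refutable reading, which
is the one consistent with the initial-acceptance policy accepting exactly
the first and third outcome.

The search for alternative models delegates to the oracle's enumeration
rather than reproducing the original program's revision moves: at the scale
of these tasks (at most six terms) the input–output behavior is identical
and the oracle is independently tested. The z coordinate is carried (terms
live at `(x, y, 0)`) but never used by the 1D/2D benchmark tasks.

The prediction policies accept: `skeptical` only `truth`; `initial`
`truth` and `weak_falsification`; `credulous` everything except `falsity`.
This makes skeptical acceptance coincide with oracle validity and credulous
acceptance with oracle satisfiability — a property the test suite asserts on
500 random problems. `adapted` picks, per participant, the fixed policy
with the highest accuracy on that participant's own trials, breaking ties
skeptical > initial > credulous (the most conservative policy wins when the
data cannot distinguish them).

## PRISM: preferred models by construction cost

`prism_construct()` inserts premises into an unbounded discrete array via a
focus. Under first-free-fit (`fff`) the focus scans from the reference term
in the premise direction to the first genuinely free cell; under first-fit
(`ff`) the new term takes the adjacent cell and the contiguous run of
occupants is shifted outward. When a premise direction collides with an
occupied cell (e.g. opposite cardinal relations), the focus simply continues
in the insertion direction — this concretization of "search the first free
position" is what gives the model a *concrete* preferred conclusion on
logically indeterminate problems, its signature preference-effect
prediction.

Construction difficulty is a weighted operation count. The theory specifies
only that difficulty tracks the number of focus operations, not the weights;
we charge 1 per focus step (diagonal steps count once), 1 per write, and 2
per relocated term (pick up + put down), configurable via `prism_costs()`.
Under these defaults the first-fit construction of the five-fruit worked
problem costs 15 against 12 for first-free-fit, preserving the intended
ordering (relocations make ff dearer) without committing to more than the
published claim.

`prism_vary()` returns alternative oracle models ordered by revision
distance (number of terms whose per-axis rank changed), with a
lexicographic signature as the deterministic tie-break. `mix` is treated as
an *arrangement class*, not a third deterministic constructor: for
arrangement verification it accepts anything constructible by some
per-premise ff/fff choice sequence, while production and plain verification
use the fff construction. Fitting (`fit_person()`) grid-searches strategy
`{fff, ff, mix}` times depth `{0, 1, 2, 3}`; ties prefer lower depth, then
fff, ff, mix — simpler explanations win. Variation never overturns a
preferred-model "True": the published account describes variation as a
search for *supporting* alternatives during verification, so we never let
it falsify an initially accepted conclusion.

## The verbal model: queues, costs, encodings

`verbal_candidates()` builds both orientations of the first premise (either
object may be inserted first and becomes the queue's start). A new object is
appended at the end of the queue when its direction agrees with the queue
direction at the reference object (dot product >= 0; the boundary case —
orthogonal directions — appends, per the rule's "otherwise" clause), and is
spliced in directly before the reference object otherwise, severing an
existing link if there is one. Creating a link costs 1 and breaking one
costs 2 by default; the theory fixes only the inequality (breaking >
creating), and `verbal_model()` exposes both. `verbal_preferred()` keeps
the cheaper construction; ties fall to the culturally preferred left-to-right
orientation.

Conclusions differ by vocabulary, mirroring how the cardinal extension was
grafted onto the original one-dimensional model:

* 1D queues have no direction encodings in the original account; the queue
  order *is* the spatial order, and a conclusion is accepted iff it matches
  that order.
* Cardinal queues accumulate each premise's direction encoding: every
  inserted object's position is its reference's position plus the premise
  vector, and a query decodes the sign of the position difference. On fully
  indeterminate problems (opposite relations) the sums cancel to the zero
  vector and a forced-choice fallback fires: by default the decoded encoding
  of the link incident to the reference term (a local-information
  heuristic), with a seeded-random alternative available. The experimental
  task offered no "anything is possible" option, so some forced-choice
  policy is unavoidable; the published account does not specify one, and the
  fallback is deliberately pluggable.

Two small structural caveats are documented rather than resolved, because no
benchmark task exercises them: for queues longer than one link the "queue
direction" at an interior reference is ambiguous (we use the link on the
start side), and inserting in front of the traversal head moves the start
pointer away from the queue end.

## Baselines and the coverage protocol

`coverage()` implements the two fitting phases: for each participant every
model is pre-trained on all *other* participants' trials, then fitted on the
target participant's own trial–response pairs, and finally predicts exactly
those trials in presentation order. A trial-by-trial adaption hook exists in
the interface but no model here uses it, so within-participant trial order
cannot affect accuracies. The most-frequent-answer baseline is trained on
the pre-train split only (leave-one-out); training it on the target
participant's own data would blur the line between an aggregate ceiling and
an individualized model, so we take the conservative reading.

All stochastic models draw from one seeded generator stream split per
(model, participant) by hashing the identifiers, which makes results
invariant under participant reordering — a property the tests assert.
Summaries report the median and the raw median absolute deviation of
participant accuracies on the percent scale (no 1.4826 consistency factor;
the MAD here is a descriptive dispersion statistic, not a robust sigma
estimate). The co-optimality matrix gives, conditional on model i being
correct on a trial, the fraction of those trials where model j is also
correct; it is asymmetric by construction and has a unit diagonal whenever
the row model is ever correct.

`best_model()` picks the pool member with the highest accuracy on the
participant's own trials (ties by pool order); `optimal_model()` is correct
on a trial iff *any* pool member is. Optimal therefore dominates every pool
member by construction, and BestModel dominates them in the coverage
setting — both are invariants in the test suite, not empirical findings.

## What the generators emulate — and what they do not

Each generator reproduces the structure of one published design:

* **figural** — 16 two-premise verification problems per participant, the
  four term-order figures four times each, 8 consistent and 8 inconsistent,
  fruit vocabulary.
* **continuity** — 48 four-term problems per participant, 16 per assertion
  order (continuous, semi-continuous, discontinuous), 24 consistent and 24
  inconsistent, with the conclusion relating the first and last *introduced*
  terms. For the semi-/dis-continuous orders that pair coincides with a
  premise pair, so the inconsistent items state a premise with its terms
  swapped; these trivially falsifiable items are flagged `-filter` in the
  condition column. Under this structural reading they make up a third of
  the trials, a little above the "about a quarter" reported for the original
  set, whose exact composition is not published.
* **cardinal** — 64 single-choice problems per participant, one per ordered
  relation pair, querying the pair (C, A) with all eight options, building
  vocabulary.
* **smalllarge** — four structurally distinct four-premise problems over
  five terms (the first is the classic apricot/pear/fig/kiwi/cherry item;
  two use fruit vocabulary, two tree vocabulary), each with six candidate
  arrangements: the ff, fff and mixed-strategy constructions plus three
  inconsistent foils (the lexicographically first inconsistent orders, so
  they are deterministic), 24 combinations presented twice.

Consistency labels always come from the oracle at generation time, never
from the construction — a mislabelled item would be caught by the
generator's own tests. `simulate_responses()` answers every trial with a
configured generating model and replaces the answer, with probability
`error_rate`, by a uniform draw over the *other* options; the expected
accuracy of the generating model on its own data is therefore exactly
`1 - error_rate`.

Simulated responders are the point where the synthetic benchmark stops
emulating reality. Real participants are not noisy instances of any single
model in the pool: they mix strategies, drift over time, and show reading-
and response-time structure that these generators do not attempt to produce.
Passing the recovery tests therefore shows that the evaluation pipeline can
identify a generating model under calibrated noise — it does not show that
any of these models describes human reasoners.

## Numerical choices and problem sizes

All constructions and fits are deterministic given the seed; every tie has
a documented break (choice order for equally acceptable conclusions,
skeptical-first for policy fits, lower-depth-then-fff for PRISM fits, pool
order for BestModel, lexicographically smaller response for MFA,
left-to-right orientation for verbal queues). Degenerate inputs are handled
explicitly: inconsistent premises yield flagged models and `falsity`
outcomes, empty fitting data falls back to the most conservative
parameterization, a single-participant dataset leaves pre-training empty
and the MFA falls back to seeded guessing.

The test suite and the acceptance script size their simulations for a
single desk CPU: 500 random problems for the policy-containment property,
30 simulated participants with 48 trials each at 10% response noise for the
coverage-recovery study, and exhaustive checks where the space is small
(all 64 relation pairs, all construction-strategy sequences). Enumeration
is limited to six terms — ample for every benchmark design, which use at
most five.

## Known limitations

* Exact-axis semantics is an assumption, not an established fact about how
  participants read cardinal directions; sector semantics would need a
  different composition table.
* On two-premise cardinal problems the fff-constructed PRISM, the verbal
  model with the link fallback, and the initial-model policy converge on
  identical predictions under our concretizations; datasets of that design
  alone cannot separate them, and only the first-fit strategy and deeper
  variation break the tie. This mirrors the published observation that some
  designs are not diagnostic between model families.
* The interval, topological and three-dimensional relation families are out
  of scope, as is any modeling of reading or response times.
* The package reimplements the published contracts of the original
  programs; it does not interoperate with their sources.
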