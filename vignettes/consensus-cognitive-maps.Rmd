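---
title: "Consensus cognitive maps from expert panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus cognitive maps from expert panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmpanel)
```

## The modelling problem

When quantitative data on a complex system are scarce — as for the
post-migration determinants of unaccompanied minor refugees' mental
health, the application the package ships as example data — structured
expert elicitation can substitute for measurement. A fuzzy cognitive map
(FCM) represents the experts' shared understanding as a weighted directed
graph: nodes are factors, an edge *s → t* says "more of *s* causes more
(or, with a negative sign, less) of *t*", and the weight grades the
strength of that causal belief. `fcmpanel` covers the path from raw
workshop output to an analysable map: factor consolidation, consensus
aggregation of individual ratings, structural metrics, and activation
dynamics.

## Factor consolidation

Panels elicit factors independently, so labels overlap, duplicate and
vary in grain. Consolidation is a human judgement; the package only makes
it explicit, checkable and reproducible. Every raw factor must be covered
by exactly one action — `keep` (1 label → 1 main factor), `merge`
(n → 1), `split` (1 → n distinct), `exclude` (1 → 0) — and
`validate_mapping()` reports any uncovered or doubly covered factor,
malformed action or declared-but-unreachable main factor.
Labels are matched case-insensitively with collapsed whitespace because
they originate from hand-written moderation cards. Actions from different
panels that name the same target are unified, which is how a factor named
by both panels becomes a single node. The number of main factors is, by
construction, the number of distinct targets over non-exclude actions.

Consolidation produces only the node set. Influence and impact ratings
are collected *against the main factors* in a later round, so a split
factor's earlier relations are never copied mechanically to its
offspring.

The packaged mapping (`fcm_example("umr_consolidation.yaml")`) encodes
the published three-workshop consolidation; applied to the two raw factor
lists it yields the study's 11 main factors. One row is genuinely
ambiguous in the source: *contact with family and family remittances* is
tabulated under income security but described in prose as subsumed and
later excluded. The fixture follows the table and carries a comment at
the ambiguous action.

## The consensus rule

Each of K experts rates every ordered factor pair on a 0–10 scale (0 = no
influence). A pair becomes an edge only if

1. **quorum** — at least ⌈q·K⌉ experts rate it strictly above 0
   (default q = 2/3; for K = 6 this is the "at least four persons" rule),
   and
2. **mean** — the group mean rating strictly exceeds μ (default 5.0).

The retained weight *is* the mean, so weights stay on the rating scale
and every retained edge weight is exactly the configured mean of its
rating vector. Both inequalities are strict, following the protocol's
wording ("higher than 0", "higher than 5.0").

**Which mean?** The protocol speaks of the group's "aggregated average
score" without saying whether experts who rated 0 enter the denominator.
`fcm_consensus(mean_over =)` implements both readings:

* `"all_experts"` (default): mean over the whole group, zeros included.
  This is the literal reading and the package default.
* `"raters_only"`: mean over the experts who rated above zero. If a zero
  means "I did not consider this pair" rather than "no influence", the
  all-experts mean under-estimates the true strength by the factor
  (1 − dropout rate); the rater mean is then the unbiased estimate.

This distinction has a measurable consequence in the recovery benchmark
below, which is why the benchmark is scored under the rater-mean
convention while the default stays faithful to the published rule.

A second, purely presentational threshold marks edges for **display**
(default 5.0, `display = FALSE` below it): published final models
typically draw only relations of weight 5.0 or higher, but the weaker
consensus relations remain in the object and all writers preserve them
with an explicit attribute.

Node impact scores are plain means of the 0–10 impact ratings divided
by 10 — the conventional 0–1 impact scale. No quorum is applied to
impacts: the protocol states none, and an impact rating of 0 is a
substantive "no impact" judgement, not a missed detection.

**Categories.** Weights are reported in the standard bins: below 5.0,
medium \[5.0, 6.0), strong \[6.0, 7.0), powerful \[7.0, 10\]. The source
convention labels "powerful" as "> 7.0", leaving 6.9–7.0 unassigned;
closed-left bins make the categories a partition, and the choice is
consistent with an impact of 0.72 being described as powerful. The same
bins apply to impact × 10.

## Network metrics

`degree_table()` reports, per factor, the absolute in/out degree and the
weighted degree as a percentage of the *total* edge weight of the model
(so each percentage column sums to exactly 100 at full precision;
rounding to integer per cent happens only at render time in
`write_metrics(digits =)`). The total-weight normalisation is the reading
under which published tables' columns sum to ~100 as printed. By default
the metrics run on display edges only, mirroring published tables; pass
`display_only = FALSE` to include the weaker consensus edges.

`motif_census()` enumerates mutual dyads, directed 3-cycles (counting
each orientation of a triple separately) and fully reciprocal triples by
direct adjacency-matrix enumeration — at 11 nodes there is nothing to
optimise. The test suite cross-checks the counts against matrix-trace
identities (tr A³/3 directed triangles, tr M³/6 on the symmetrised
adjacency) and igraph's mutuality detection. `influence_paths()`
enumerates simple directed paths up to a length cap and scores each by
the product of its edge weights rescaled by 1/10. The product score is a
package convention for ranking indirect influence, not an elicited
quantity.

## Scenario dynamics

The elicitation study itself stops at the static map; the dynamics module
is the package's documented extension, implementing the canonical FCM
inference so that the map's feedback structure can be exercised. The
update for unclamped factor i is

a′ᵢ = σ( λ · ( Σⱼ signⱼᵢ · (wⱼᵢ/10) · aⱼ + m · (2aᵢ − 1) ) )

with σ the logistic function, λ > 0 the squashing steepness (default 1),
and m ∈ \[0, 1\] an optional self-memory weight on the node's own
*recentred* activation (default 0). Design choices:

* Weights are divided by 10 so a full-strength edge contributes its
  source's activation unattenuated; signs come from the map.
* With m = 0 a node with no inputs settles at σ(0) = 0.5, which we read
  as "no information" — the natural neutral point of a logistic map.
  Recentring the memory term (2a − 1 ∈ \[−1, 1\]) preserves that neutral
  point for m > 0.
* As λ → 0 every unclamped steady state tends to 0.5; large λ approaches
  a binary threshold map.
* Interventions are modelled by clamping factors to fixed activations;
  clamped entries are copied through every update.

`run_scenario()` iterates synchronously until the max-norm change falls
below `tol` (default 1e−6; `converged`), a state recurs (`limit_cycle`),
or `max_iter` = 200 updates have run. Cycle detection hashes states
rounded to 12 decimals — coarse enough to be robust to floating-point
jitter once an attracting cycle has been reached, fine enough (four
orders of magnitude below `tol`) never to confuse slow convergence with
cycling. On all-positive maps started from the neutral state the update
is monotone, so trajectories are componentwise monotone and convergence
is guaranteed; this also yields the clamp-monotonicity property (a higher
clamp never lowers any steady activation) that the tests assert.

`compare_scenarios()` reports steady-state deltas plus an
impact-weighted composite Σ impactᵢ·Δaᵢ. The modeled outcome (mental
health in the shipped example) is not itself a node, so the composite is
a read-out convention: it weights factor shifts by their elicited impact
on the outcome, it does not simulate the outcome.

## The synthetic panel generator

Because the raw individual ratings behind the shipped example were never
published, the pipeline is validated end-to-end on synthetic panels with
known ground truth. `generate_truth()` draws an Erdős–Rényi directed
graph (default density 0.25 — the density scale of the published final
model: 24–29 edges on 110 ordered pairs) with true weights uniform on
(5, 10\] and impacts uniform on \[0.5, 0.8\] (the observed impact range).
Truth weights are kept above the mean threshold deliberately: noise-free
recovery then isolates the quorum-and-mean mechanism rather than the
display cutoff.

`simulate_panel()` models three failure modes of elicitation, applied
independently per expert and pair:

* **rating noise** — Gaussian with `rating_noise_sd` (default 1 rating
  unit), clipped to \[0, 10\];
* **detection dropout** — a true edge is rated 0 with `miss_prob`
  (default 0.1);
* **false positives** — a non-edge gets a rating drawn uniformly from
  (0, 5\] with `false_pos_prob` (default 0.1); spurious beliefs are weak,
  hence bounded by the mean threshold.

Ratings are continuous by default (`round_ratings = TRUE` mimics experts
using whole numbers; the elicitation instrument does not fix a
granularity). All randomness flows from a single seed; identical seeds
reproduce entire sweeps.

What the generator does **not** emulate: expert correlation and herding
(workshop group dynamics), systematic per-expert bias (leniency or
severity), and any dependence of errors on the factor semantics. Passing
recovery benchmarks therefore shows that the consensus rule works for
*independent* noisy raters — not that six real, mutually acquainted
experts behave like them.

**Recovery benchmark.** With no noise, the rule recovers the truth
exactly (sensitivity = specificity = 1). Under the benchmark condition
(noise sd 1, 10 % dropout, 10 % false positives, 6 experts, 10 factors,
200 replicates) mean sensitivity and specificity both exceed 0.9 when
scored under the rater-mean convention. The choice of convention is
analytic, not empirical tuning: under dropout rate d the all-experts mean
of an edge with true weight w has expectation (1 − d)·w, so every true
edge with w < μ/(1 − d) (≈ 5.56 at d = 0.1) is expected to fall below
the threshold — about 11 % of a (5, 10\] uniform weight law — capping
all-experts sensitivity near 0.85 regardless of panel size. The rater
mean estimates w without that attenuation. We report the benchmark under
the estimator that measures what the benchmark is about (edge detection
against a known truth) and keep the package default on the published
rule.

## Numerical and interface conventions

* Deterministic ordering everywhere: nodes and edges lexicographic by id,
  (source, target); metric rows by impact descending with ties broken by
  factor id.
* Retained edge weights are the exact configured mean (no rounding);
  percentages are exact at full precision and rounded only on output.
* Ratings outside \[0, 10\], self-pairs, duplicate ratings and unknown
  factors are rejected at construction/parse time with row references.
* GraphML and DOT writers emit weight, sign, category, display and impact
  attributes with `%.15g` precision and round-trip through the package's
  own readers.
* Signed qualitative workshop models (symbolic `+++` / `−` or numeric
  −1..1 dialects, never mixed in one file) are supported by
  `read_qualitative()`; symbolic strengths map to 0.33 / 0.66 / 1.0 of
  scale for display only and never enter consensus aggregation.

## Fixture provenance and limitations

The shipped final-model fixtures include only the edges attested in the
study's prose; a handful of edges visible only in its published figure
are omitted (the degree table of the fixture therefore undercounts a few
factors' ties relative to the published table, while the text-attested
quantities — e.g. social contacts' six incoming ties — match exactly).
Numeric edge weights were never published: the fixture encodes the
attested strength category at its bin midpoint (5.5 / 6.5 / 7.5) and
uses 6.0 where no category is stated, with an `category_attested` column
making the distinction explicit. Scenario results on this fixture are
therefore qualitatively meaningful (signs, orderings, relative response)
but their decimals inherit the weight convention. Relations reported to
exist below the display threshold ship separately
(`umr_subthreshold_edges.csv`), without weights.

Problem sizes in the test suite are chosen for sharp checks at desk
scale: exhaustive consensus-rule enumeration over rating grids {0, 3, 6,
9} for up to 4 experts; 500 random panels for threshold monotonicity;
1000 random graphs for degree conservation; 200 replicates for the noisy
recovery benchmark; 100 random all-positive maps for clamp monotonicity.
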