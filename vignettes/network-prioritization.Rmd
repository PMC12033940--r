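---
title: "Condition-specific PPI networks and propagation-based candidate prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific PPI networks and propagation-based candidate prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionet)
```

## The problem

Multiplex secretome panels and mass-spectrometry proteomes measure a limited,
technology-biased slice of a tissue's biology. Guilt-by-association
prioritization extends those measurements: proteins that interact tend to act
in the same processes, so relevance scores placed on measured "seed" proteins
and propagated over a protein-protein interaction (PPI) network highlight
unmeasured candidates consistent with the phenotype. `prionet` implements this
workflow as it is used for intervertebral-disc (nucleus pulposus) secretome
and proteome studies: per experimental case, a condition-specific network is
carved out of a global interactome, seeds are scored from the data, the
scores are propagated, and the top-ranked fraction of the network becomes the
candidate list that is compared across cytokine-stimulation conditions.

## Network construction

Each case network is built in three steps from a scored reference interactome
(a HIPPIE-style edge list: two symbols plus a confidence in [0, 1]):

1. **Universe filtering** — the induced subgraph on the proteins detected in
   the tissue (the MS proteome, or the secretome analyte panel). Filtering is
   by protein identity only; the confidence column is carried as metadata and
   no confidence threshold is applied by default (`min_confidence = 0`,
   configurable), because the construction is defined by which proteins were
   observed, not by interaction quality cut-offs.
2. **Condition neighbourhood** — the stimulus proteins (IL-4, IL-10, IL-1B in
   the shipped study design) plus their first neighbours in the reference are
   added, and the network is closed over all reference edges among its nodes;
   a subnetwork conventionally retains every known interaction among its
   members. Whether seed proteins are likewise expanded is exposed as
   `include_seeds` (default `FALSE`): the stimuli are the proteins whose
   network context is being injected, while seeds are already part of the
   measured universe.
3. **Shortest-path enrichment** — while the network is fragmented, the two
   components whose closest pair of nodes is at minimal unweighted
   shortest-path distance in the reference are merged by adding the interior
   nodes of one such path, so the final network is a single component
   whenever the reference allows it. Hop count (not confidence-weighted
   length) defines "shortest", and one path — not all tied paths — is added
   per merge, keeping the enrichment minimal.

Ties are resolved deterministically: component pairs by (distance, then
lexicographically smallest endpoint pair), tied paths by the
lexicographically smallest interior sequence, with C-collation sorting so the
result does not depend on the session locale. If the reference itself cannot
connect the nodes, a partial result is returned with `connected = FALSE` and
a warning rather than an error, and every merge step is recorded so tests can
verify each bridge node sits on a true reference shortest path.

## Seed scoring

Two scoring modes mirror the two data types:

* **Mass-spectrometry cases** score each seed present in the network as 1 and
  every other node 0; stimulus proteins are additionally scored 1 under their
  conditions.
* **Secretome cases** average the biological replicates per analyte, min-max
  scale the means over the measured panel,
  $X_{sc} = (X - X_{min}) / (X_{max} - X_{min})$, restrict to network nodes
  (unmeasured nodes score 0), and finally force each stimulus protein to 1 —
  the score of the most expressed protein — emphasizing the in-vitro /
  ex-vivo stimulation. Scaling happens over the measured panel *before*
  restriction to the network, and per condition (each condition's own
  profile is used), so a case's scores are invariant to shifting or
  rescaling all concentrations. A degenerate panel (all means equal) maps to
  all zeros with a warning instead of dividing by zero.

## Propagation

Scores spread by a NetScore-style hop-limited message passing. Per
repetition, every node $u$ collects from all origins $o$ within $h$ hops
(including itself at distance 0):

$$s'(u) = \frac{1}{|O(u)|} \sum_{o \in O(u)} \frac{s(o)}{d(u,o) + 1},$$

with $d$ the unweighted shortest-path distance; each repetition optionally
ends by dividing by the maximum score, and the updated scores re-seed the
next repetition. Defaults are 3 repetitions of 2 iterations, the GUILD
reference defaults. The $1/(d+1)$ decay, self-inclusion at $d = 0$, mean
aggregation and per-repetition max-normalization together define this
package's concrete variant; each choice is exposed in
`propagation_config()`. The contract this variant guarantees — and the test
suite checks against an exhaustive message-enumeration oracle — is that seed
proximity dominates rank, influence travels at most $h \times r$ hops (nodes
beyond that score exactly 0), and edge confidences play no role in
propagation. Because the published algorithm is specified only as "default
parameters" of its reference implementation, rank-level rather than
score-level agreement with other NetScore implementations is the intended
validation surface.

Ranking sorts by descending score with lexicographic tie-breaks, so ranks
are 1-based, distinct and reproducible.

## Candidate selection and comparison

`select_top()` takes the first $\lfloor k/100 \times N \rfloor$ ranked nodes
— the floor makes sizes exact and reproducible (782 nodes give 39 candidates
at 5 % and 15 at 2 %), and smaller percentages are always nested inside
larger ones. `compare_conditions()` reports candidates shared by all compared
conditions and unique per condition, in two modes: unique against all sibling
conditions (default) or against the first condition only (the no-treatment
baseline), because published "unique" columns can be read either way.
Stimulus proteins are not excluded from candidate lists — they are genuine,
maximally scored network nodes — though callers can drop them downstream.
`categorize()` tallies candidates against a local protein-to-category
annotation table with an open label vocabulary; remote knowledgebase lookups
are deliberately out of scope.

## Network statistics

The five printed statistics are average degree $2E/N$, average clustering
coefficient (per-node $C_i = 2T_i / k_i(k_i - 1)$, defined 0 for degree < 2,
averaged over all $N$ nodes), density $2E/N(N-1)$, modularity

$$Q = \frac{1}{2E} \sum_{ij} \left[ A_{ij} - \frac{k_i k_j}{2E} \right]
\delta(c_i, c_j),$$

maximized by the Louvain heuristic, and the diameter (longest shortest path,
computed on the largest component with a warning when disconnected — the
literal longest simple path is NP-hard and clearly not what a network
description table means). Modularity is computed by this package in the
equivalent per-community form and cross-checked in the tests against both a
direct double-sum oracle and igraph's implementation; the Louvain
maximization itself is delegated to igraph with the RNG seeded per call so Q
is reproducible.

## Synthetic data and what it shows

Because the original interactome and measurement inputs are not
redistributable, the package generates all inputs with known ground truth:

* `generate_interactome()` draws a planted-partition (stochastic block)
  graph — default 400 nodes in 4 equal communities, within-community edge
  probability 0.3, between 0.01 — designates one community as the disease
  module and samples 5 seed proteins inside it. Confidences are uniform on
  [0.5, 1]. Module structure, not degree realism, is the interpretive unit
  of the analysis, which is why a block model is the default; a log-normal
  degree-propensity tilt (`degree_heterogeneity`) is available when
  hub-dominated topology matters. Pair enumeration is $O(n^2)$, fine at the
  benchmark scale of hundreds of nodes.
* `generate_secretome_panel()` emulates the 73-analyte, 3-replicate
  multiplex panel with log-normal baselines (Luminex concentrations are
  right-skewed), per-protein multiplicative condition effects and log-normal
  replicate noise.
* `generate_ms_universe()` emulates the ~14,000-protein MS universes as
  identifier sets containing required proteins (the packaged 25 seeds).

The end-to-end benchmark — binary seeds in one planted module, default
propagation, top-5 % selection — recovers the disease module far above its
0.25 background fraction in every seeded run. What this shows is that the
pipeline's plumbing is correct and that propagation concentrates rank inside
a planted dense module; it does not show performance on real interactomes,
whose literature bias, hubs and incompleteness the generator deliberately
does not emulate.

## Problem sizes and numerical choices

The shipped tests run the oracles at small scale by design: metric oracles
on 200 graphs of up to 30 nodes, exhaustive Louvain comparisons on all
partitions of up to 8 nodes, propagation oracles on 100 graphs of up to 12
nodes across all configurations, and 40 planted-module runs of 400 nodes —
sizes at which brute-force enumeration is exact and fast. Floating-point
comparisons against oracles use 1e-12 tolerances; rank and set outputs are
compared exactly. Degenerate inputs are kept total rather than fatal where a
pipeline should continue (empty parse results warn, constant panels scale to
zero with a warning, unconnectable components return `connected = FALSE`)
and error where silence would corrupt results (duplicate concentration rows,
negative concentrations, missing cells, stimuli absent from the network,
zero seeds in the network, empty universes).

## Known limitations

* Propagation ignores edge confidences by design; a confidence-weighted
  variant would need a different shortest-path semantics.
* The Louvain maximization is a heuristic; on adversarial graphs its Q can
  sit below the true optimum (tests bound the gap at small scale).
* The synthetic generator does not reproduce scale-free degree
  distributions quantitatively, so absolute metric values on synthetic
  networks are not comparable to values on curated interactomes.
* Identifier handling is a deliberate simplification: symbols are upper-cased
  and otherwise taken at face value, with a user-supplied two-column map for
  database-native identifiers.
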