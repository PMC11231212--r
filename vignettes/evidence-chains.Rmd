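---
title: "Evidence chains for drug repositioning: model, filters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence chains for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgevidence)
```

## The problem

Rule-based knowledge-base completion over a biomedical knowledge graph can
both predict that a compound may treat a disease and say *why*: each
prediction is supported by path rules whose groundings are concrete
compound-to-disease paths ("evidence chains") through genes, pathways,
phenotypes and related diseases. The difficulty is volume. Even a
moderately connected disease yields many thousands of chains per drug, most
of them mechanistically uninformative — chains that wander through the
disease-ontology hierarchy, or that lean on speculative clinical-trial
edges. This package implements the full workflow (rule learning,
prediction, grounding) together with an automatic filter cascade whose
purpose is to shrink the chain space without losing the biologically
meaningful explanations.

## Graph model

A graph is a set of typed entities (eight node types: Compound, Disease,
Gene, Protein, Pathway, Mechanism, ATC, Phenotype) and directed labelled
triples *(head, relation, tail)*, loaded from headerless TSV plus a
node-type table (`load_triples()`). Duplicate triple rows are collapsed
rather than rejected, because real graph exports routinely contain them.
Node types come from the explicit table, never inferred from relation
signatures — inference would make typing depend on graph content and
be untestable in isolation.

Chain length is measured in **edges**. Every worked example chain in the
package has three edges, and the default `path_policy(max_edges = 3)`
follows that; hop terminology is avoided because "2-hop" counting (number
of intermediate nodes) and edge counting disagree by one and are easy to
confuse. Paths are simple (no repeated node) and may traverse each triple
in either direction; the orientation is recorded per edge, since printed
chains freely mix forward and reverse arrows (a gene is *bound by* one
compound and *activated by* another).

## Rule learning

Rules are cyclic path rules: `treats(X,Y) <= b1(...), ..., bn(...)`, the
body a relation chain connecting the head variables. The learner is a
simplified anytime bottom-up procedure:

1. sample a `treats` triple uniformly;
2. random-walk from its head towards its tail (at most `max_body_len`
   edges, never the sampled triple itself, simple paths, up to
   `walk_attempts = 10` restarts);
3. generalize the ground path to a rule by replacing nodes with variables;
4. score the rule once, on first encounter.

Acyclic and constant-bearing rules are out of scope: every rule this
pipeline consumes is a path rule, and restricting the language keeps
scoring exact and cheap.

**Confidence.** We score `confidence = support / (body_count + smoothing)`
where `body_count` counts distinct (X, Y) endpoint pairs with at least one
body grounding and `support` those pairs whose head triple exists.
Counting *pairs* rather than raw groundings keeps confidence inside [0, 1]
and immune to multiplicity inflation when many intermediate routes connect
the same pair. (Definitions of confidence as a ratio of groundings are
sometimes stated with numerator and denominator interchanged; the
pair-based support/body ratio used here is the standard resolution.) For
scoring, variable assignments are unrestricted — nodes may repeat along a
grounding — which is what makes the relational-join implementation exact;
evidence chains, by contrast, are always simple paths. `smoothing`
(default 0) adds a constant to the denominator for the usual
pessimistic-confidence effect; tests exercise it but the default pipeline
does not use it.

**Budgets and determinism.** The production mode is wall-clock spans
(`time_span`, `total_budget`); the test mode is a fixed iteration count
plus a seed, which makes runs exactly reproducible and gives the anytime
property a checkable form: a longer iteration budget yields a superset of
the rules of a shorter one at the same seed. Rules need
`min_support >= 2` to be kept — a rule witnessed by a single pair carries
no generalisable signal.

## Prediction and ranking

`apply_rules()` proposes every entity connected to the query disease by at
least one rule body; each candidate accumulates the confidences of all
suggesting rules. `rank_candidates()` orders candidates by lexicographic
comparison of those descending confidence vectors — maximum first, ties
resolved by the second-best rule, and so on; a candidate that runs out of
rules loses to one that has more. Remaining full ties are broken by
ascending entity id, a deliberate extra rule so that the ranking is a
deterministic total order. Held-out `treats` edges removed before learning
are never re-added, so recovering the known treatments of a disease
(`evaluate_holdout_recall()`, default cutoff top 100) is a fair test.
Candidates already linked to the disease by weaker relations (e.g. in
trial) are *not* excluded by default; predicting a drug already in trials
is informative, not an error.

## The filter cascade

Stage order is fixed — rule filter, grounding, significant-path filter,
deductive builder, gene/pathway filter — mirroring the workflow the
reduction report describes. Stages can be disabled individually but not
reordered; the later stages' semantics (domination, canonical chains)
assume they see the earlier stages' output.

**Rule filter.** A rule is discarded when its body has more than
`max_ancestor_atoms = 1` disease-hierarchy atoms or more than
`max_relaxed_atoms = 2` relaxed atoms. Ancestor and descendant atoms share
one counter: two hierarchy hops in any combination lose the disease of
interest (the canonical uninformative chain wanders from a rare disease up
to "rare genetic disease" and back down to an unrelated condition). The
relaxed set — `in_trial_for`, `in_vivo_preclinical_trial_for`,
`has_orphan_designation_for` — describes programmes that frequently fail;
one such edge is evidence, three are noise.

**Significant-path filter.** Within the chains of one (drug, disease)
pair, chain C is dropped when a chain C′ has the identical node sequence
and orientation everywhere, matches C's relation at every slot except that
C has a relaxed relation where C′ has `treats`, with at least one such
replacement. "Same entities" is interpreted as the same ordered node pair
with the same orientation, and the pairwise rule is generalized to
whole-chain domination so that multi-slot cases compose consistently with
the deductive builder's notion of specificity.

**Deductive builder.** Chains are grouped by node sequence. The canonical
chain of a group uses `treats` at every slot where the graph contains that
edge between the node pair in an orientation the group exhibits there;
otherwise the slot keeps an existing relation — the lexicographically
first observed, forward orientation preferred, a deterministic tie-break
for the rare case of parallel non-specific edges. Only this single most
specific canonical chain is added (origin `"deduced"`), not every
intermediate relation combination; adding the full lattice would recreate
the blow-up the cascade exists to prevent. With
`drop_dominated_after_deduction = TRUE` (default) the group is then pruned
by domination, so deduction is a net refinement; with the flag off it is
purely additive, which is the configuration of the four-chain worked
example (`levofloxacin_fixture()`), where the builder contributes the
all-`treats` chain for five chains total.

**Gene/pathway filter.** `strict` keeps chains containing at least one
curated gene or enriched pathway node; this is the default, and deduced
chains are not exempt — a deduced chain that touches no disease biology is
as uninformative as an extracted one. `lenient` additionally keeps chains
with no Gene- or Pathway-typed node at all, for graphs where purely
clinical chains (disease–phenotype–disease) are wanted; `off` disables the
stage. Strict mode with an empty relevance set is a configuration error —
it would silently discard everything.

**Reduction report.** `compute_reduction(all, rule_derived, filtered)`
validates `all >= rule_derived >= filtered >= 0` and reports
`100·(1 − filtered/rule_derived)` and `100·(1 − filtered/all)`. In
`run_pipeline()` the rule-derived count is the number of unique chains
grounded from the *unfiltered* rule set — that is the space a reviewer
would face without the cascade — and the exhaustive baseline enumeration
is run with `max_edges` at least the longest rule body, so the three
counts are measured on comparable path spaces.

## Biological relevance

Disease genes are selected by multi-source voting over a five-source
presence matrix (PanelApp, Open Targets, Pharos, Geneshot and a
knowledge-graph export in the reference workflow): a gene needs
`min_sources = 4` of 5. Pathway enrichment is a one-sided Fisher's exact
test per pathway — the p-value is the hypergeometric upper tail
P(X ≥ k) for overlap k, pathway size K, query size n, universe N —
followed by Benjamini–Hochberg adjustment and an adjusted-p threshold
`alpha = 0.01`. Two choices are worth making explicit because enrichment
results depend on them:

* the **universe** is the set of genes carrying at least one pathway
  annotation in the GMT file — the standard over-representation
  background, stated here because no background is universal;
* the test is **one-sided** in the enrichment direction; depletion is not
  of interest when building a relevance set.

The manual curation that a disease-landscape study would add on top is
represented as optional include/exclude override lists on
`relevance_set()`, not automated.

## The synthetic generator

`generate_kg()` emits graphs shaped like the eight-type biomedical
meta-graph (`kg_meta_graph()`: 12 printed relation names with typed
endpoints), with three layers:

* **background edges** drawn per meta-edge (defaults around 10–20 per
  relation on a ~190-node graph) — enough connectivity for random walks to
  find non-trivial paths, sparse enough that exhaustive oracles stay
  cheap;
* **planted motifs**: a rule template instantiated with fresh entities.
  Training instances (default 20) point at randomly chosen background
  diseases and carry the head `treats` edge for the configured confidence
  fraction; held-out instances (default 10) point at the disease of
  interest and always carry their head edge, which is exactly what
  `remove_target_edges()` strips and the prediction stage must recover.
  After assembly, accidental body groundings created by background edges
  receive the head edge with the configured probability ("saturation"), so
  the planted rule's measured confidence matches the configured value
  rather than drifting with background density. Background `treats` edges
  avoid the disease of interest so the held-out list coincides exactly
  with the planted manifest;
* **planted uninformative chains**: double-ancestor detours attached to
  the held-out drugs, so the cascade demonstrably encounters and removes
  them.

What the generator does **not** emulate: the degree distribution, scale
(hundreds of triples, not 10^5), relation inventory (12 of the full
meta-graph's 29 edge types — the ones the worked examples print) or
source heterogeneity of a production biomedical graph. Passing tests on
synthetic graphs therefore demonstrate algorithmic correctness — each
stage equals its brute-force oracle, planted signal survives, planted
noise is removed — not retrieval quality on real data.

## Numerical and testing choices

* Deterministic tie-breaks everywhere randomness is not intended:
  candidate ranking falls back to entity id; the canonical-chain builder
  to sorted relation names; chain de-duplication keeps first occurrence
  and unions rule provenance.
* Degenerate inputs are defined, not errors: unreachable pairs give empty
  chain sets, an empty rule set predicts nothing (with a warning), a
  zero-count generator config yields an empty graph, `k = 0` enrichment
  gives p = 1.
* Test problem sizes: property suites run on random graphs of 5–30 nodes
  (~35 edges) where exhaustive enumeration of paths, groundings and
  variable assignments is feasible as an independent oracle; Fisher
  p-values are checked against direct binomial-coefficient summation for
  universes up to N = 60; learner checks use 200–300 iteration budgets on
  ~300-triple synthetic graphs. These sizes make the whole suite run in
  about a minute while keeping every check exact.
* Rule files print confidences with 17 significant digits so
  read/write/read round-trips are bit-exact.

## Limitations

* Chains carry no learned ranking or combined confidence score; the
  cascade filters but does not order its survivors. Rule confidences are
  known not to track biological importance, which is the reason the
  cascade exists.
* The learner's sampling distribution is a plain uniform random walk; it
  recovers motifs reliably on planted graphs but is not tuned for the
  degree skew of production graphs.
* The deductive builder upgrades edges only towards the single specific
  relation `treats`; a general specificity lattice over several relations
  is out of scope.
* No ontology reasoning, no ETL from source databases, no graph database
  backend: inputs are triple files, and scaling beyond in-memory
  data.table joins is future work.
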