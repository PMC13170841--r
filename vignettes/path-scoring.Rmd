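---
title: "Scoring mechanistic paths in a cross-medicine knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mechanistic paths in a cross-medicine knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmkg)
```

## The problem

Heterogeneous biomedical knowledge graphs that bridge traditional-medicine
entities (herbs, ingredients, syndromes) and modern-medicine entities
(compounds, diseases, pathways) through shared gene targets support two
complementary tasks: *link prediction* — ranking candidate drugs against a
disease with embedding models — and *mechanistic explanation* — exhibiting
concrete entity/relation paths that make a predicted link biologically
plausible. Embedding scores alone are black boxes; raw path enumeration
drowns users in high-frequency generic routes. This package implements a
unified path score that puts search-derived and rule-derived paths on one
scale and rewards biologically specific evidence.

## The unified path score

A mechanistic path $P = (e_0, r_1, e_1, \dots, r_L, e_L)$ from a candidate
drug $e_0$ to a disease $e_L$ receives

$$\mathrm{Score}(P) \;=\; \mathrm{BaseScore} \times \mathrm{Decay}(L)
\times C_{\mathrm{effective}} \times \mathrm{Bonus}.$$

**BaseScore** is the geometric mean
$\bigl(\prod_{i=1}^{L} w_{r_i}\, w_{e_i}\bigr)^{1/L}$ of the relation and
entity weights along the path. The head entity $e_0$ is excluded: the
product runs over the $L$ edges and the entities they lead to, and the
geometric mean keeps any single high-weight node from dominating. Weights
encode domain priors: mechanism-associated entity types (Herb, Ingredient,
Gene, Compound) and experimentally evidenced gene–gene relations
(`experiments`, `experiments_transferred`) carry weight 1.0, other
gene–gene relations 0.9, and everything else a baseline `w_base = 0.7`.
The base score is accumulated in log domain, so products of many small
weights lose no precision.

**Ingredient specificity (ISI).** Ubiquitous ingredients (palmitic acid,
quercetin, ...) appear in a large fraction of herbs and carry little
disease-specific signal. Borrowing the inverse-document-frequency idea,
an Ingredient node's weight is scaled by

$$\max\!\Bigl(0.01,\ \frac{\ln\bigl(N/(df_i + 1)\bigr)}{\ln N}\Bigr),$$

where $N$ is the number of herb entities and $df_i$ the number of distinct
herbs containing ingredient $i$ (counted over all Herb→Ingredient edges
regardless of relation name). An ingredient found in no herb keeps full
weight; one found in nearly all herbs is floored at 0.01. Setting the
floor to 1.0 disables the mechanism entirely (the "no ISI" ablation).
The index requires $N \ge 2$ so that $\ln N > 0$.

**Hybrid confidence.** Rule-derived paths carry the confidence of the Horn
rule that produced them, clamped at 1. Search-derived (DFS) paths have no
native confidence; they take $\min(1, \mathrm{BaseScore} \times
\lambda_{\mathrm{DFS}})$ with $\lambda_{\mathrm{DFS}} = 0.2$ by default.
The calibration factor exists because raw DFS base scores systematically
exceed mined rule confidences; without it the top of any merged ranking is
all search paths (`lambda_sweep()` exhibits exactly this at
$\lambda = 1$), while a very small $\lambda$ suppresses search discoveries
entirely. The sweep grid default `{0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0}`
covers both failure modes.

**Length decay.** Paths are capped at 4 hops (the shortest-path heuristic
of molecular pharmacology); $\mathrm{Decay}(L) = 1$ for $L \le 2$ and
$0.9^{\,L-2}$ beyond.

**Bonus.** Paths containing a Gene node or a *specific* ingredient (ISI
factor at least 0.5), or an edge with experimental evidence or the
herb–ingredient `includes` relation, receive a multiplicative bonus. Two
tiers are used — structural 1.2 and evidence 1.5 — whose product is capped
at 1.8. How multiple triggers combine inside the published range
$[1.2, 1.8]$ is a genuinely open design point; the two-tier-with-cap
composition is this package's choice, and every tier is configurable.

A worked example under the baseline configuration, a 4-hop
herb→gene→gene→gene→disease chain:

```{r}
cfg <- scoring_config()
idx <- frequency_index(100)
p <- kg_path(c("HEB1435", "G1", "G2", "G3", "DM06"),
             c("act_on", "synergizewith", "synergizewith", "dysregulate"),
             c("Herb", "Gene", "Gene", "Gene", "DiseaseMM"), origin = "DFS")
score_path(p, cfg, idx)
```

The components: base $(0.7 \cdot 0.9 \cdot 0.9 \cdot 0.49)^{1/4} = 0.7260$,
decay $0.9^2 = 0.81$, DFS confidence $0.7260 \times 0.2 = 0.1452$,
structural bonus 1.2 (gene nodes), product $0.1025$.

## Ranking and tie-breaking

`rank_paths()` merges rule- and DFS-derived collections. A path found by
both routes is kept once with rule provenance — rules carry an explicit,
data-derived confidence that should not be displaced by the calibrated
search estimate. Sorting is by score descending; exact ties break toward
shorter paths, then lexicographic node sequences, so rankings are fully
deterministic. Scores are kept at full precision internally and reported
to 4 decimals.

## Rules: dialect, mining, grounding

Rules are Horn chains `head(X,Y) <= b1(X,A), b2(A,Y)` in a tab-separated
4-field dialect (`support`, `body_count`, `confidence`, rule text) that
round-trips through `parse_rules()`/`write_rules()`. Only chain-shaped
rules with variable endpoints are used for grounding; constant-bound rule
classes parse but are skipped with a count. Body atoms may traverse an
edge against its direction, marked by a `::inv` relation suffix — without
this, gene-chain paths running against edge orientation could not be
grounded.

`mine_rules()` samples a random triple as a head grounding and enumerates
the bounded simple paths between its endpoints as candidate bodies; each
becomes a rule whose support (head-satisfying endpoint pairs) and body
count (distinct endpoint pairs satisfying the body) are then recomputed
exactly by a brute-force relational join. Confidence is their ratio. The
budget is expressed in samples rather than wall-clock seconds so results
are reproducible; the rule set is deterministic given the seed and grows
monotonically with the budget.

## Embedding models

Four scoring functions are provided: TransE $-\|h + r - t\|$, DistMult
$\sum_i h_i r_i t_i$, ComplEx $\mathrm{Re}\langle h, r, \bar t\rangle$ and
RotatE $-\|h \circ r - t\|$ with unit-modulus relation coordinates.
Training uses pairwise margin-ranking loss with uniform negative sampling
(filtering is applied only at evaluation, as is standard), plain SGD with
analytic gradients, weight decay on all embedding parameters, and
re-normalization of RotatE phases after every update. Initialization is
uniform in $[-6/\sqrt{d}, 6/\sqrt{d}]$; RotatE phases uniform in
$[-\pi, \pi]$. Evaluation follows the filtered protocol: candidates
forming other known-true triples are removed before ranking, and tied
scores receive average ranks to avoid optimistic bias. DistMult's
symmetry is exact by construction (the head–tail product is computed
before multiplying by the relation, so the expression is bit-identical
under swapping).

Paper-scale defaults (dimension 400, batch 1024, 200 negatives) are kept
in `train_config()` for documentation fidelity; tests and the bundled
benchmark use desk-scale settings (dimension 32, batch 128, 16
negatives). The margin (default 6, benchmark 2) and the optimizer are
package choices — the published protocol names the loss but not these
values. `antisymmetric_benchmark()` plants a purely directional relation
(a circular order, entity $i$ precedes $i+1..i+k$) on 100 entities /
2000 triples: complex-space models infer the held-out forward band from
the rotational structure, while DistMult cannot separate forward from
reverse neighbors, reproducing the qualitative model ordering at desk
scale. Learning rates and epochs are tuned per model (as in the published
protocol): 0.1/300 for DistMult and ComplEx, 1.0/100 for RotatE, weight
decay $10^{-2}$ at this scale.

## Candidate ranking

`rank_candidates()` scores every Herb and Compound against a disease
through its gene bridge (all genes adjacent to the disease) under six
meta-path relations. How the gene × relation score grid collapses into
one candidate score is unspecified in the source protocol; the package
takes the mean of the top $m = 5$ grid values — rewarding multi-target
support while resisting single-pair outliers — with plain mean
($m = \infty$) and max as alternatives. Known triples are not excluded
from scoring by default (`exclude_known` offers the filtered variant).

## The synthetic generator

`generate_cmkg()` emulates the schema of a gene-bridged cross-medicine
graph: Herb→Ingredient (`includes`) edges with controllable document
frequency (a configurable fraction of near-ubiquitous ingredients, the
rest rare), drug→gene edges (`act_on`, `bind`, `upregulate`,
`downregulate`), gene–gene interactions with a configurable fraction of
evidence labels, gene→disease edges, symptom attachments, planted
drug→gene→…→disease mechanism chains, and planted Horn rules with exact
target confidences. Rules are planted on relations (`alleviate`,
`inhibit`, `affect`, …) the noise generator never emits, so their
support and body counts are exact by construction; noise edges are drawn
after planting so planted structures are never destroyed. The manifest
records every planted artefact, and everything round-trips through
plain-text fixtures (`write_fixture()`/`read_fixture()`).

What the generator does *not* emulate: the scale and degree distribution
of real multi-database graphs, correlated noise across sources, or
name-level messiness requiring fuzzy alignment. Passing tests on this
substrate therefore demonstrate correctness of the algorithms, not
real-data recall.

## Numerical and design choices

* Entity ordering for custom-ID assignment: case-insensitive name, then
  source database, then original id. Any fixed order would do;
  determinism is the requirement.
* Fusion survivor: the relation with the larger pair set, ties
  lexicographic. Merge chains are resolved by union-find; conflicting
  chains are an error, not silently resolved.
* Fusion candidates are compared only within the same (head type, tail
  type) signature.
* Name alignment: case-fold, collapse whitespace, strip terminal
  punctuation; no fuzzy matching.
* Percentages: two decimals for source contributions, one decimal for
  shared-target system shares, matching their usual presentation.
* Degenerate inputs raise classed conditions (`cmkg_format_error`,
  `cmkg_integrity_error`, `cmkg_lookup_error`, `cmkg_config_error`,
  `cmkg_argument_error`) rather than returning sentinels.
* `avg_isi` in ablation reports averages ISI factors over Ingredient node
  occurrences only; a list whose paths contain no ingredients reports 0.
  The evidence ratio counts edges, not paths.
* DFS traverses edges forward; relations declared symmetric in the
  configuration (the undirected gene–gene interaction relations by
  default) may be walked both ways.

## Problem sizes

Tests and the acceptance script use desk-scale inputs chosen to exercise
every code path while keeping the whole suite fast: stores of tens to
hundreds of entities, the 2000-triple benchmark ring, 1000-path scoring
oracles, and mining budgets of a few thousand samples. The headline
claims these sizes support are qualitative (model orderings, monotone
responses, exact closures), not the absolute metric values of
cluster-scale runs.

## Known limitations

* The published per-path scores of full-scale runs are not reproducible
  from the printed formula components; the bonus composition above is one
  consistent reading of the stated range, not a recovered constant.
* The miner enumerates bodies exhaustively per sampled head triple; on
  dense graphs with high-degree hubs a beam cap would be needed.
* Pure-R SGD is adequate for desk-scale graphs; paper-scale training
  (millions of triples, dimension 400) would require a compiled or
  GPU-backed implementation.
* Whether ambiguous gene–gene relations (e.g. `synergizewith`) should
  count as transferred experimental evidence is configuration, not fact;
  the default treats only `experiments`/`experiments_transferred` as
  evidence.
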