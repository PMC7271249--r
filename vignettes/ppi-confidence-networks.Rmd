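---
title: "Evidence-scored PPI reference networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-scored PPI reference networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiref)
```

## The problem

Experimentally measured protein–protein interactions (PPIs) for the mouse
are scattered across many molecular-interaction providers, reported with
provider-specific identifiers, heterogeneous detection techniques and very
unequal amounts of supporting evidence. ppiref assembles such records into
a single scored reference network: every unordered protein pair gets one
evidence bundle and one confidence score, and the network can then be
sliced by tissue, function, interaction type and confidence, and decorated
with inferred signaling directionality.

## The confidence model

Each interaction's score is a weighted sum of three sub-scores,

$$S = w_s\,s_s + w_o\,s_o + w_t\,s_t, \qquad w_s + w_o + w_t = 1,$$

where each sub-score is the saturating logistic transform

$$s_i(n) = \frac{2}{1 + e^{-\alpha_i n}} - 1 \in [0, 1),$$

equivalently $\tanh(\alpha_i n / 2)$ — the identity the test suite uses as
an independent oracle. The evidence quantity $n$ differs per component:

| sub-score | evidence quantity $n$                         | weight | rate  |
|-----------|-----------------------------------------------|--------|-------|
| $s_s$     | number of supporting studies                  | 0.6    | 1     |
| $s_o$     | number of non-mouse species with interacting homologs (interologs) | 0.1 | 1.5 |
| $s_t$     | summed reliability of the distinct detection techniques | 0.3 | 0.5 |

The rates place saturation where the evidence becomes convincing: three
studies ($\alpha_s = 1$), two species ($\alpha_o = 1.5$), or two
mid-reliability techniques summing to about 10 ($\alpha_t = 0.5$).
Technique reliabilities are expert-assigned 0–10 weights: structure-level
assays such as NMR or light scattering carry 10, two-hybrid and
co-immunoprecipitation 5, microscopy- and RNAi-based approaches 1. The
shipped `default_reliability()` table carries these anchor classes keyed
by PSI-MI detection-method codes; a full provider table can be loaded and
passed to `score_config()`, and `rescore()` recomputes the whole network
under any valid parameterisation. A detection-method code missing from
the table contributes the lowest anchor class (1), with a warning — an
unrecognised assay is weak but not zero evidence; the fallback is
configurable.

Because all three sub-scores live in $[0,1)$ and the weights sum to one,
$S \in [0,1)$; adding a study, a species or a technique can only increase
it. These invariants are enforced by property tests.

### Confidence levels

Named thresholds are quartiles of the score distribution: medium = median,
high = upper quartile (`confidence_levels()`, linear-interpolation type-7
quantiles — the most common statistical default; the choice is not
prescribed by the scoring model). The published reference snapshot fixes
these at 0.53 and 0.60, shipped verbatim as `confidence_presets()`. They
are constants of that snapshot, not recomputation targets: the underlying
provider data change continuously, so the package treats them as named
presets. Scores are kept at full precision; rounding to two decimals is a
display concern only.

## Evidence aggregation

`parse_mitab()` reads 15-column PSI-MITAB 2.5 (extra columns are ignored —
the lowest common denominator across providers). Ingest keeps the four
interaction-type categories association (MI:0914), physical association
(MI:0915), direct interaction (MI:0407) and colocalization (MI:0403);
descendants of these codes are accepted when an MI ontology is supplied.
Rows in which either interactor fails to map to a positive Entrez ID are
discarded and tallied. Aggregation is set-union per unordered pair:
duplicates — identical (pair, study, method) triples — collapse without
effect, whereas distinct studies or methods for the same pair are
evidence, not duplicates. The MITAB missing token `"-"` contributes
nothing rather than aborting a row. Self-interactions are retained as
single-node bundles: homodimer evidence is legitimate, and a protein can
only enter the network through an interaction, so isolated nodes cannot
exist by construction. When two provider identifiers map to the same
Entrez ID their rows merge — deduplication happens at the Entrez level.

## Annotation

An interaction carries an ontology term when **both** interactors are
annotated with the term or with one of its descendants. The closure
follows `is_a` and `part_of` edges downward (configurable): the broader
closure matches common GO-slim practice even though plain subsumption
only requires `is_a`. Upward propagation (annotating ancestors) is
deliberately not performed. MeSH-style tree hierarchies are converted to
the same child–parent DAG abstraction at load time.

Tissue assignment uses joint presence calls: a gene is present in a
context when its expression is at least 1 TPM (inclusive — the
conventional calling threshold), and an interaction is assumed possible
in every context where both partners are present. Genes absent from the
expression matrix are conservatively present nowhere. A homodimer's
tissue set is its gene's own presence set.

## Queries

`network_query()` mirrors the REST-style contract: `layers = 0` restricts
to interactions within the input set, `layers = 1` adds first-level
neighbors; a neighbor survives only if it interacts with at least
`min_connections` input proteins; edges among surviving neighbors are
included by default (`include_neighbor_edges` toggles this — the
behaviour was genuinely open, and conditioning inclusion on surviving the
neighbor filter keeps the output monotone in `min_connections`).
Explicitly queried pairs with no reported interaction appear with the
pseudo-score −1; pseudo rows are user-requested absences, so they are
exempt from confidence filtering and excluded from all graph statistics
(degree, mean score).

The confidence filter keeps `score >= threshold`. The comparison is
inclusive because "above the threshold" is ambiguous at the boundary and
inclusive semantics keep a median-scored edge inside the
medium-confidence set, consistent with the preset definitions. Identifier
resolution tries all-digit strings as Entrez, then exact symbol, MGI and
UniProt; ambiguous symbols are an error listing the candidates rather
than a silent pick.

## Directionality inference

Given source and sink sets (defaults: receptors and transcription factors
present in the subnetwork — signal flows from the cell surface to the
nucleus), all minimum-hop paths between every (source, sink) pair are
enumerated. An edge traversed by at least one path is oriented
source-to-sink; an edge traversed in both directions across any paths is
a conflict and stays undirected (flagged as on-path). "Conflict" is read
as conflicting traversal directions, not activation/inhibition signs —
regulatory signs come from the curated effect overlay, which overrides
inference outright and marks pairs listed in both orientations as
undirected with both effect labels.

The weighted variant keeps, per (source, sink) pair, only the minimum-hop
path with the highest cumulative confidence score. "Shortest" is still
minimum-hop — confidence breaks ties among equal-length paths rather than
redefining length; a true $-\log(\text{score})$ Dijkstra variant is
available behind `mode = "dijkstra"` but is not the default. Score-sum
ties are broken by the lexicographically smallest node-ID sequence so
runs are bit-reproducible. Disconnected pairs contribute nothing.
Correctness is checked against an exhaustive DFS path-enumeration oracle
on random graphs of up to 12 nodes.

## Synthetic fixtures

`generate_corpus()` emulates a provider corpus end to end: a protein
universe with all four identifier types, MITAB rows with controllable
duplicate and unmappable rates, per-pair study counts (1 + Poisson),
technique draws from the reliability pool, interolog coverage, a rooted
ontology with gene annotations, a TPM matrix with a presence probability,
and role/effect tables. Its defaults (60 proteins, 120 pairs, 10%
duplicates, 10% unmappable, ~2 studies/pair, 40% interolog coverage, 6
tissues at 50% presence) are sized so that evidence counts straddle the
sub-score saturation points — enough spread to exercise every scoring
regime while staying instant to generate. Crucially, the generator also
writes a ground-truth sidecar computed by direct bookkeeping, so the
ingest–score pipeline can be checked for *exact* recovery — a
deterministic accounting identity, not a statistical comparison.

What the generator does **not** emulate: provider-specific MITAB dialect
quirks, realistic TPM distributions, scale-free degree structure, or
correlated annotation patterns. Passing tests therefore demonstrate the
machinery's correctness, not robustness to the messiness of real
provider feeds.

`hippo_fixture()` is a hand-built, fully deterministic corpus around the
Hippo kinase cascade (Stk4/Sav1 → Lats2 → Yap1/Wwtr1 → Tead4) with two
expression contexts. Tead4 is expressed only in the trophoblast context,
so the trophoblast subnetwork supports a directed Stk4 → … → Tead4 chain
while the stem-cell subnetwork lacks the Yap1–Tead4 edge — the
qualitative signature of active versus weak Hippo signaling in early
mouse development. Every edge's evidence is chosen so its score (≈ 0.90)
clears the medium preset, keeping the use case stable under confidence
filtering. Gene symbols and Entrez IDs are real; accessions, publications
and expression values are synthetic, and Stk4's receptor-role entry is a
synthetic convenience so default endpoint selection works on the fixture.

## Numerical and degenerate-input choices

- Weights must sum to 1 within 1e−9; the score decomposition holds to
  1e−12 and the tanh oracle agrees to better than 1e−12.
- Empty evidence sets give sub-score 0 exactly; an empty score multiset
  is a domain error for `confidence_levels()`.
- At extreme evidence ($\alpha n \gtrsim 40$) the sub-score saturates to
  1.0 at double precision; the mathematical bound is open but the
  floating-point image is closed.
- Zero-row inputs (empty MITAB bodies, empty subnetworks, empty effect
  tables) are legal everywhere and produce empty outputs, not errors.

## Problem sizes

The test suite and the reproduction script run on deliberately small
instances: 1000-point oracle grids, corpora of a few hundred evidence
rows (60 proteins, ~220 pairs), 50-term ontologies, and 100 random
graphs of ≤ 12 nodes for the directionality oracle — the regime where
exhaustive path enumeration is exact and instant. The algorithms
themselves have no such limits; igraph's geodesic machinery carries the
heavy lifting at scale.

## Known limitations

- Interolog support is consumed as a precomputed pair → taxa table; no
  orthology inference is performed.
- The reliability table covers the anchor classes; full provider tables
  must be supplied by the user.
- Ontology input is the 3-column triple format, not full OBO/MeSH ASCII.
- Directionality is purely topological (shortest paths); no probabilistic
  or flow-based orientation is attempted.
- Enrichment statistics, web rendering and database persistence are out
  of scope; the JSON graph export stands in for interactive
  visualization.
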