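---
title: "Immune cell knowledge graphs: models, reasoning, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune cell knowledge graphs: models, reasoning, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ickgr)
```

## The problem and the model

Knowledge about immune cell states and gene regulation is scattered across
thousands of publications. `ickgr` turns an abstract corpus into a
cell-type-specific **knowledge graph** whose nodes are typed biomedical
entities (genes, diseases, cell types, pathway concepts) and whose directed
edges carry one of two biologically interpretable relations, *activate* or
*inhibit*. Each edge is weighted by the number of **distinct abstracts**
supporting that (source, target, direction) relation, and the supporting
abstract identifiers travel with the edge as provenance, so every inference
downstream can be traced back to literature.

Two modelling commitments shape everything else:

* **Parallel signed edges.** An activate and an inhibit edge may coexist
  between the same ordered node pair. We deliberately do not net-sum them:
  literature disagreement is data. When the reasoning layer needs a single
  transition weight it sums the parallel weights and keeps the dominant
  sign (larger weight; ties resolve to activate) as metadata.
* **Nodes are unique by (name, type).** Names are case-folded before
  merging — gene symbols uppercased (through an alias table when
  available), other types lowercased. A string tagged as a pathway in one
  abstract and a cell type in another yields two nodes, keyed
  `name|type`; no precedence rule between types is assumed.

## Pipeline stages and their contracts

Extraction is organised as pluggable **backends behind fixed contracts**,
because the heavyweight components (neural taggers, large language models)
are deployment choices, not part of the package's logic:

* *Entity tagging*: `tag_entities()` accepts any `function(text) ->
  mentions`. The packaged `gazetteer_tagger()` matches a surface
  dictionary case-insensitively at word boundaries; overlapping mentions
  of the same type collapse to the longest span. NER evaluation
  (`evaluate_ner()`) uses entity-level exact span-and-type matching by
  default; a token-level mode is available behind a flag because published
  corpus benchmarks do not always state the granularity.
* *Phrase mining*: `extract_candidate_phrases()` takes a chunking backend;
  the default `rule_chunker()` splits sentences at a frozen
  function-word/verb lexicon and strips stop words from chunk edges,
  keeping only multi-token noun phrases. Candidates then pass lexical
  filters (`filter_biomedical_phrases()`): normalized Levenshtein
  similarity to a vocabulary (default threshold 0.85, configurable — the
  notion of a "close match" has no canonical value), biomedical suffixes,
  and biomedical substrings. The two-letter suffix "in" is restricted to
  head tokens of length at least 4, otherwise prepositions and short words
  flood the results; the other suffixes may match any token ("caspase
  cascade" passes via *-ase*). `refine_phrases()` models an LLM review
  pass as a subset contract: whatever the backend returns, terms not in
  the input are discarded with a warning, so a hallucinating reviewer can
  only shrink the candidate list.
* *Relation extraction*: for each abstract, all `n(n-1)` ordered pairs of
  distinct normalized entities are enumerated (lexicographically, for
  determinism), a versioned zero-shot prompt is rendered per pair
  (directionality instruction, three-way answer set including the literal
  "no association", the abstract text), and the backend's raw response is
  parsed by first directional keyword — multi-label responses resolve to
  the earliest match and anything unparseable is the safe default "none".
  Only activate/inhibit relations are materialized. The packaged
  `verb_lookup_backend()` is a deterministic mock keyed to the synthetic
  corpus templates; a live LLM plugs in behind the same
  `function(prompt) -> response` contract.

## Reasoning

**Personalized PageRank** (`personalized_pagerank()`) is the workhorse:
restart probability `1 - alpha` (default damping `alpha = 0.85`), restart
mass uniform over the seed nodes, edge weights as transition weights, and
dangling-node mass redistributed to the restart vector. Sign is ignored at
this stage by design — inhibition re-enters only through explanation
paths. The implementation solves the stationary equations exactly by a
dense linear solve (a rank-one correction folds in the dangling term), so
its accuracy is limited only by floating point; graphs beyond 800 nodes
fall back to edge-list power iteration at tolerance `1e-12`. The test
suite checks the solve against an independently written dense
power-iteration oracle on random digraphs (L1 agreement below `1e-8`).

**Permutation significance** (`permutation_test()`): a node's p-value is
`n / n_perm` where `n` counts permutations — random same-size seed sets —
whose score meets or exceeds the observed score, with the 95% CI taken
from the 2.5th/97.5th percentiles of the permutation distribution
(defaults: 1000 permutations). Two deliberate choices:

* The permutation pool is the set of nodes sharing the observed seed
  set's type(s): random *gene* sets for gene seeds, and by extension
  random same-type concept seeds when a single cell-type or disease node
  seeds `concept_associated_genes()`. The pool contains the observed set
  itself, so with a small pool the p-value is floored near 1/pool-size;
  fixtures and users should provide enough same-type nodes for the
  resolution they need.
* `p = 0` is reported as computed (`n = 0`); the positively biased
  `(n+1)/(n_perm+1)` variant is available behind the `p_floor` flag for
  users who need strictly positive p-values.

**Adjusted random walk** (`adjusted_random_walk()`): fixed-length walks
(defaults 1000 walks of 20 steps per start node) whose per-step transition
probability to an out-neighbor is the temperature softmax
`exp(w/T) / sum(exp(w/T))` of collapsed edge weights; walks end early at
sinks. Node importance is the normalized visit frequency over all walk
positions, including the start position. As `T` grows the transitions
approach uniform over out-neighbors; as `T` shrinks they concentrate on
the heaviest edge.

**In-silico perturbation** (`in_silico_perturbation()`) seeds PageRank on
one gene and ranks all other reachable gene nodes. Each ranked gene
carries an inferred sign from its explanation path: the parity of
inhibiting hops (even = activated, odd = inhibited). Paths come from
`explain_paths()`: one shortest path per target by hop count, ties broken
by the larger minimum edge weight along the path, then lexicographically
by predecessor key — a deterministic rule so explanations are
reproducible. The explanation subgraph retains every parallel signed edge
of each traversed hop with full provenance.

**Controls.** `shuffle_graph()` implements a degree-preserving
double-edge-swap null (10 × |E| attempted swaps; swaps creating
self-loops or duplicate signed edges are rejected), preserving in/out
degree sequences, the weight multiset, the sign multiset and node types.
A plain edge shuffle would be a weaker control; degree preservation is the
stricter and more informative baseline for "does the wiring matter".

**Annotation** (`annotate_gene_set()`) seeds PageRank on the mapped query
genes (aliases tried when a symbol does not match), restricts the output
to pathway-type nodes, attaches permutation p-values and CIs, and reports
unmapped symbols. Query genes never appear in their own annotation.
Concept similarity (`concept_similarity_matrix()`) is the Jaccard index
of significantly associated gene sets, with a unit diagonal for non-empty
sets and 0 for empty ones (the empty-set Jaccard convention is 0
throughout the package).

## The synthetic corpus: what it emulates, and what it does not

`generate_synthetic_corpus()` plants a known relation graph into template
abstracts ("SYG01 activates SYG02 in NK cells.") with disjoint
activate/inhibit trigger-verb sets, one abstract per (relation, support)
pair, so the gazetteer tagger plus the verb-lookup backend recover exactly
the planted triples and every assembled edge weight equals its planted
distinct-abstract support count. Defaults chosen once as study
conditions: background relations are activations with probability 0.72
(mirroring the roughly 3:1 activate:inhibit ratio of literature-derived
immune graphs), years uniform on 2020–2024 (the abstract retention
window), two supporting abstracts per relation.

Two optional planted structures support the benchmark analyses: a hub
gene activating a fixed set of downstream targets, and a pathway concept
activated by a dedicated set of member genes. The hub and its targets are
excluded as *sources* of background relations so that the hub's true
downstream set is closed — exactly the planted targets. Without this, a
background edge out of a target creates genes that genuinely are
downstream of the perturbation yet absent from the nominal truth set, and
recovery scores would penalize correct predictions.

What the generator does **not** emulate: linguistic variety (negation,
hedging, coreference, multi-sentence reasoning), tagger errors, LLM
misclassification, entity ambiguity across abstracts, citation-count skew,
and real corpus scale. Passing the planted-recovery tests therefore
demonstrates that the pipeline's plumbing — tagging, pair enumeration,
prompt/parse, assembly, weighting, provenance — is exact, not that
real-world extraction is error-free. Real-graph performance is bounded by
the live tagger and LLM backends, which this package treats as replaceable
contracts.

## Evaluation machinery

Benchmarking components mirror how such graphs are validated against
reference databases: reference interaction subtypes are simplified to the
two directions (`simplify_kegg_interaction()`: three activation subtypes,
four inhibition subtypes, everything else excluded); predicted and
reference pairs are matched after alias normalization of both endpoints
and only the overlapping pairs populate the 2x2 directional confusion
matrix (A = agree-activate, B = predicted-activate/reference-inhibit,
C = predicted-inhibit/reference-activate, D = agree-inhibit), from which
precision `A/(A+B)`, recall `A/(A+C)` and the harmonic F1 follow, with
zero denominators mapping to 0. A pair carrying both directions on one
side resolves to the majority direction and is dropped on a tie —
ambiguous evidence should not populate an agreement table.

Performance distributions are dichotomized with a two-component Gaussian
mixture (`gmm_dichotomize()`; the higher-mean component is "High"),
fitted with a conjugate prior so perfectly separated zero-variance
clusters — common in small benchmark sets — remain fittable.
Protein-interaction structure is summarized by density, average local
clustering (isolated and degree-1 nodes count 0) and the modularity of a
greedy modularity partition (the partition algorithm is a documented
choice; the metric, not the algorithm, is the target). Embedding
coherence uses within-cluster sum of squares and centroid distances in
the embedding space; the 2-component principal projection is for plotting
only and never feeds the metrics. The embedding backend is a contract;
the packaged deterministic hashing embedder exists so the metrics are
testable offline, and makes no claim to semantic fidelity.

## Numerical and degenerate-input choices

* PageRank: exact solve for `n <= 800`, else power iteration
  (`tol = 1e-12`, `max_iter = 1000`); scores renormalized to sum to 1.
* Softmax transitions subtract the maximum exponent before
  exponentiating, so large weights or small temperatures cannot overflow.
* Quantile-based edge thresholds (`top_edge_subgraph()`) use the default
  type-7 quantile and keep ties, so "all weights equal" retains the whole
  graph at any fraction.
* Empty inputs: empty corpora load to empty record sets; an empty graph
  has zero counts and an empty centrality map; Jaccard of two empty sets
  is 0; `ppi_network_metrics()` of an empty edge list reports density and
  clustering 0.
* Errors are classed (`ickg_input_error`, `ickg_validation_error`,
  `ickg_nomap_error`) so the command-line dispatcher can map them to
  stable exit codes (2 and 3).

## Problem sizes used by the test and verification suites

The suites run entirely on synthetic data at desk scale, chosen to make
the statistical checks sharp: the PageRank oracle comparison uses 100
random digraphs of 5–50 nodes; the exhaustive permutation oracle uses a
6-gene toy graph (15 seed subsets) against 1000 Monte-Carlo draws, with
uniformity checked over 200 replicate p-values; single-step walk
frequencies use 10,000 draws; and the perturbation/annotation benchmarks
use 100 planted graphs of 50 genes, 10 pathways, an 8-target hub and a
4-gene pathway, with 1000 permutations each. Headline corpus-scale
quantities (graph sizes in the tens of thousands of edges, benchmark
precision against curated databases) depend on live neural taggers, a
70B-parameter LLM and external atlases, and are out of scope for the
offline suites by design.

## Known limitations

* The rule-based chunker is a deliberately simple stand-in for a
  syntactic parser; its recall on complex noun phrases is limited, which
  is acceptable because the chunking backend is a contract.
* Relation extraction is within-abstract only; cross-document inference
  happens through graph assembly, not through pairing entities across
  abstracts.
* Sign handling is path-parity over one selected shortest path; competing
  paths of mixed sign are visible in the explanation subgraph but do not
  blend into a probabilistic sign.
* The permutation null permutes seed identity, not graph structure; it
  answers "is this node unusually relevant to these seeds", not "is the
  graph unusual".
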