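---
title: "Seed-gene interactome analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene interactome analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rettnet)
```

## The analysis in one paragraph

`rettnet` asks a network question about Rett syndrome genetics: do the
genes behind Rett-syndrome-like (RTT-L) presentations sit close, in
protein-interaction space, to the canonical Rett (RTT) genes? The
package takes two curated seed lists — 4 RTT genes (MECP2, CDKL5,
FOXG1, NTNG1) and 60 distinct RTT-L genes (58 from the literature plus
8 from a sequenced cohort, with 6 genes in both) — expands them to
their first-order interaction partners in an experimentally validated
interactome, characterises the topology of that network, restricts it
to a tissue by a protein-expression rule, extracts seed-mediated
sub-networks and the interactors common to both seed classes, and runs
hypergeometric over-representation analysis of the seed set against
multi-source gene-set collections.

## The network model

**First-order expansion.** The network retains exactly the
interactions with at least one seed endpoint that pass the evidence
filter (default: `experimental` only, the IID evidence class backed by
curated experiments; `predicted` and `orthologous` are excluded). The
result is a simple undirected graph. Three conventions are deliberate:

* *Self-loops* are excluded from the edge set but counted. The
  centrality conventions below assume a simple graph, and a self-loop
  carries no between-gene information.
* *Isolated seeds* — seeds with no retained interaction — are reported,
  not silently dropped. Losing a seed is a finding in its own right:
  the brain filter removes CDKL5-like seeds precisely because protein
  evidence is missing, and that must stay visible.
* *Class precedence*: a symbol listed as both an RTT and an RTT-L gene
  is labelled `RTT_SEED`. RTT is the stricter diagnostic class; the
  choice only affects labelling, never which edges are retained, and is
  confined to one helper should a user want the opposite.

**Centralities.** Degree, betweenness and closeness are the three
measures used to find hub-like genes.

* Betweenness is reported as *raw unordered-pair counts with endpoints
  excluded*: `BC(v) = Σ_{s<t, s≠v≠t} σ_st(v)/σ_st`, where `σ_st` counts
  shortest paths. This matches the NetworkAnalyzer convention most
  interactome studies report; the normalized variant divides by
  `(N−1)(N−2)/2`. The computation is Brandes' dependency accumulation
  (via igraph); the test suite verifies it against an independent
  brute-force oracle that enumerates shortest paths from BFS distance
  and path-count matrices, exactly (≤ 1e−9) on hundreds of random
  graphs up to 50 nodes.
* Closeness uses the component-scaled Wasserman–Faust form
  `CC(v) = ((n_c−1)/Σ_u d(v,u)) · ((n_c−1)/(N−1))` with `n_c` the size
  of `v`'s component. The first-order interactome is in general
  disconnected — NTNG1 famously forms a small satellite with its four
  partners — and plain closeness is undefined across components. The
  scaling penalises small components, so a satellite hub never outranks
  a main-component gene of equal local efficiency;
  `closeness_mode = "component"` gives the unscaled within-component
  form. Isolated nodes get 0.
* Quartile summaries (the box-plot view per node class) use
  linear-interpolation (type-7) quantiles, R's default; box plots of
  published figures are not numerically reproducible anyway, so the
  choice is stated rather than fitted.
* Hub ranking breaks metric ties by ascending symbol, making every
  top-k list deterministic and prefix-consistent.

**Tissue restriction.** A protein is considered expressed in a tissue
when it has an expression record at any ordinal level other than
`not_detected` (HPA-style scale `not_detected < low < medium < high`);
duplicate records aggregate by maximum. Symbols with *no* record for
the tissue are treated as not expressed and dropped — this reproduces
the observed behaviour of seeds with inadequate protein-level evidence
(`keep_uncovered = TRUE` flips it). Filtering keeps a node iff
expressed and an edge iff both endpoints survive, so it is idempotent
and monotone in the expression table; both properties are tested. An
alternative edge-flag mode keeps an edge iff its own interaction record
is flagged for the tissue. Partner sets exclude seeds themselves: the
201/1563-style Venn counts are counts of *interactors* adjacent to each
seed class, and the common set is their intersection.

**Sub-networks.** The sub-network around anchor seeds is the induced
subgraph on anchors plus first-order neighbors. Induced is the default
because neighbor–neighbor edges are what make a cluster dense; a
non-induced star view is available. Dense-cluster exploration is
composed from `rank_hubs()` + `extract_subnetwork()` rather than
re-implementing any interactive tool's proprietary score menu.

## Enrichment

Over-representation uses the hypergeometric distribution: for a
universe of `N` genes, a term with `K` members and a query of `n`
genes overlapping in `k`, the enrichment p-value is `P(X ≥ k)`. Tail
probabilities come from R's `phyper`, which computes in a numerically
stable way; the suite verifies both tails against exhaustive
enumeration of all draws for every universe up to `N = 12` at relative
error ≤ 1e−12.

Open choices and how they were fixed:

* *Sidedness.* The default is the upper tail — over-representation is
  the question being asked, and reported terms are over-represented
  ones. A literal two-sided mode (minimum-likelihood: sum all outcomes
  at most as probable as `k`) is provided for fidelity to workflows
  described as two-sided.
* *Correction scope.* Bonferroni, `p_adj = min(1, m·p_raw)`, with `m`
  counted per source by default (each database corrected by its own
  term count, the g:Profiler behaviour); a global-`m` option exists.
* *Universe.* Defaults to the union of all member symbols in the
  loaded sources; alternatives are the network's node set or any
  user-supplied list. Published adjusted p-values depend on the
  database snapshot and universe and are therefore not reproducible
  targets at desk scale.
* *Untested terms.* Terms with background members but zero query
  overlap count toward `m` yet are excluded from the output (standard
  ORA practice; keeps `m` stable across queries). Terms with no
  background members are untestable and ignored.

Pathway mapping (`map_pathway`) reports, for one chosen pathway, the
seed members per class and the pathway members that are simultaneously
common interactors of both classes — the handful of proteins inside
the pathway that bridge the two gene sets.

## Synthetic data: what it emulates, and what it does not

The generators exist so the full pipeline runs, deterministically,
without database downloads. A configuration fixes everything; the same
seed reproduces every file byte for byte.

* **Interactome.** A preferential-attachment backbone over the
  interactor proteins gives connected, heavy-tailed degree structure —
  the regime in which hub analysis is meaningful. Seeds are wired to
  class-reserved partner pools with log-normal neighborhood sizes
  (median 20 partners, `sdlog = 1`: a realistic spread for
  disease-gene degree in curated interactomes, spanning a few to a few
  hundred) biased toward backbone hubs. Exactly `planted_common_k`
  interactors are wired to at least one seed of *each* class; every
  other interactor is wired to one class only, so the common-interactor
  count is exact by construction. Planting adds edges rather than
  rewiring, preserving backbone structure at the cost of slightly
  raising planted nodes' degree.
* **Expression.** Each symbol is uncovered (no record) with probability
  `p_uncovered = 0.05`, otherwise `not_detected` with
  `p_not_detected = 0.15`, otherwise uniform over low/medium/high —
  incomplete coverage at roughly the rate that makes seed drop-out
  visible without gutting the network. A named seed can be forced
  uncovered to reproduce the CDKL5 scenario.
* **Gene sets.** One planted term with stated size `K = 20` and query
  overlap `k = 15` among 50 random terms of sizes 10–50: with a
  1000-gene universe and a 20-gene query the planted overlap is
  overwhelming, and recovery (planted term attains the smallest raw p)
  is expected in ≥ 95% of replicates.

Defaults mirror the study conditions: 4 RTT and 58 RTT-L generated
seeds (or the packaged catalogs' 4 + 60 when a catalog is supplied),
2254 total proteins, 63 planted common interactors.

What the generator does **not** emulate: the true size and density of
the curated human interactome (≈ 2900 seed-incident interactions among
≈ 2200 neighbors in the published snapshot), database-specific biases
(study bias toward famous genes, detection-method cliques),
correlated expression across tissues, or GO-style term nesting (terms
are flat, independent draws). Passing tests therefore demonstrate that
the *algorithms* are correct and the pipeline is deterministic — not
that any particular database snapshot's counts will be reproduced.
Database-dependent published counts (interaction totals, partner
counts, sub-network sizes, adjusted p-values) are inputs-dependent and
are deliberately not test targets.

## Numerical and degenerate-input choices

* Symbols are uppercased, trimmed, internal whitespace removed; no
  alias/HGNC resolution (it would import an external database and
  silently alter curated lists). A published symbol that looks like a
  typo is left exactly as printed.
* Edge canonicalisation orders endpoints lexicographically; duplicate
  records merge source and tissue sets, and conflicting evidence
  resolves to the strongest class (experimental > predicted >
  orthologous).
* Betweenness normalisation for graphs with `N ≤ 2` is defined as 0.
* Empty inputs: an empty expression table filters to an empty network
  with a warning (not an error — a legitimate, if extreme, tissue);
  an empty seed catalog is an error; an empty network writes
  header-only export files.
* All file outputs are sorted (nodes and edges lexicographically,
  results by corrected p then term id), so re-runs are byte-identical
  and diffs are meaningful.
* Every random choice in the generators flows from one integer seed,
  with sub-streams derived by fixed small offsets per generator so the
  interactome, expression and gene-set draws are decoupled.

## Problem sizes used in the checks

The shipped verification suite runs the catalog parsers on the
packaged tables (71 seed records, 8 patients); the centrality oracle
comparison on 200 random graphs of 5–50 nodes; hypergeometric
enumeration exhaustively for all universes up to `N = 12`; the tissue
and planting contracts on seeded interactomes of 120–400 proteins
(including the 63-planted-common condition); planted-term recovery
over 100 replicates at universe 1000 / query 20; and full-pipeline
determinism at the default 2254-protein configuration. These sizes
give exhaustive or high-replicate coverage of each property while the
whole suite stays fast enough to run on every change.

## Known limitations

* No second-order expansion; the network is strictly seeds plus direct
  partners, so interactor–interactor paths longer than one edge are
  only visible inside induced sub-networks.
* No edge confidence weighting; evidence is a categorical filter.
* Enrichment treats terms as flat sets — no GO-graph propagation, no
  ordered queries, no g:SCS-style multiple-testing geometry.
* The expression rule is binary on an ordinal scale; no quantitative
  (TPM-style) thresholds.
* Published database-snapshot counts cannot be reproduced without the
  corresponding snapshots; the package reproduces the *method*, and
  its synthetic conditions make every internal count checkable.
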