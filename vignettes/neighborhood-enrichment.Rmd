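---
title: "First-neighbor subnetworks and pathway overrepresentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-neighbor subnetworks and pathway overrepresentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pathneighbor` estimates the signaling impact of perturbing one or more
proteins. The procedure has four stages, composed by `run_analysis()`:

1. **Resolution.** Query terms — gene or protein names, synonyms, or drug
   names — are mapped to canonical accessions through a scored synonym
   table. In *quick* mode the highest-scoring candidate per term is taken
   automatically; in *advanced* mode the caller supplies explicit
   selections from the candidate lists. A term found in the drug-target
   table expands to the drug's full target set. Resolution results are
   memoized in a cache that can be persisted between runs
   (`write_synonym_cache()`), so repeated lookups are byte-identical.
2. **Neighborhood extraction.** From the integrated interaction network,
   every edge whose source databases intersect the source filter *and*
   whose evidence types intersect the evidence filter qualifies. The first
   neighbors are the endpoints of qualifying edges incident to the query;
   the *displayed set* is the query plus those neighbors, and the reported
   subnetwork contains all qualifying edges among displayed proteins,
   including neighbor–neighbor edges.
3. **Annotation.** Every displayed protein is labeled with its
   signaling-pathway memberships, per pathway source database.
4. **Scoring.** For each (source database, pathway) with `K` members in a
   universe of `M` species proteins, with `n` displayed proteins of which
   `N` are pathway members, the overrepresentation p-value is the
   hypergeometric upper tail `P(X >= N)`. The family of all pathways tested
   in the run is then adjusted with the Benjamini–Hochberg step-up
   procedure.

The statistical question behind stage 4 is: if `n` proteins were drawn at
random from the species proteome, how often would at least `N` of them fall
in this pathway? A small tail probability means the neighborhood is
unexpectedly rich in that pathway's components, flagging likely signaling
side effects of the perturbation.

### Assumptions

The test treats the displayed proteins as an unordered sample from the
universe, which ignores the fact that interaction partners are correlated
(hub proteins and well-studied pathways are overrepresented in curated
interaction data to begin with). It is a screening statistic — a ranking
device to direct follow-up reading — not a calibrated error rate over
networks. Evidence filters let users restrict to, say, small-scale physical
interactions when literature bias is a concern.

## Parameters that matter

* **Universe size `M`** (dimensionless count). The background against which
  overrepresentation is judged: all proteins of the species. It can be an
  explicit accession set (then members and displayed proteins outside it
  are dropped, with warnings, so `n <= M` and `K <= M` hold by
  construction) or a declared integer. When absent entirely, `M` falls back
  to the union of network proteins and pathway members with a warning —
  a deliberately conservative, reproducible default. Larger `M` makes every
  overlap look more surprising, so `M` should be proteome-scale, not
  network-scale. The packaged fixtures declare round proteome-scale values
  (20,000 for worm, 20,200 for human).
* **Overlap mode** (`displayed` | `neighbors_only`, default `displayed`).
  Whether the query proteins themselves count in `n` and `N`. The default
  tests the queried proteins and their neighbors as one set; the
  alternative excludes the query, for users who consider the query's own
  memberships a given.
* **Significance threshold** (default 0.05) on the BH-adjusted p-value; the
  `significant` flag is just a labeling, raw and adjusted p-values are both
  reported.
* **Source and evidence filters** (default: all). Vocabulary for evidence
  is fixed (`small_scale_physical`, `high_throughput_physical`,
  `genetic`); source labels are free strings carried from the edge list.
* **Self-loops** are dropped at network construction by default (a
  self-edge would otherwise make a query its own first neighbor); a flag
  retains them.

## Design choices in open territory

* **Tie-breaks.** Quick-mode resolution sorts candidates by score
  descending, then lexicographically by accession; the enrichment table
  sorts by adjusted p, then source database, then pathway name. Both rules
  exist purely to make runs deterministic — two runs on identical inputs
  produce byte-identical JSON reports.
* **Case-folding.** Term and drug lookups are case-insensitive (gene-name
  capitalization conventions differ across organisms); accessions are
  case-sensitive and opaque.
* **Per-database testing.** A pathway curated by two source databases is
  tested once per database, never pooled; collections report per-source
  counts and the BH family spans all tests in the run.
* **Unresolved terms degrade gracefully.** They are warnings, and only a
  query with no resolvable term at all is an error. A resolved protein
  absent from the interaction network stays in the displayed set (it is
  still a protein of the species) but contributes no neighbors.
* **Multiple testing.** No particular correction is canonical for this kind
  of screen; BH at 0.05 is the default labeling because the tests within a
  run are numerous and positively dependent, and raw p-values remain
  available for any other procedure.
* **Formats.** One normalized edge-list TSV dialect replaces the zoo of
  vendor dump formats (converters are the user's responsibility; vendor
  formats drift by version). GMT was chosen for pathways as the de facto
  gene-set standard, with a `SOURCE::Pathway` name convention so one file
  carries several databases. The machine-readable report is JSON, with its
  schema shipped at `inst/extdata/report.schema.json`; subnetworks export
  to SIF and GraphML for network viewers.

## Numerical notes

The hypergeometric tail is accumulated from log-binomial coefficients
(`lchoose`), rescaled by the largest term: universes of 1e5 proteins and
overlaps deep in the tail are safe, and `P(X >= 0)` is exactly 1 by
construction. The suite checks the implementation three ways: exhaustive
enumeration of every draw for all universes `M <= 12` (to 1e-12), the
survival function `phyper` at random parameters up to `M = 1e5`, and
structural properties (strict monotonicity in `N`, pmf normalization).
Degenerate inputs — empty neighborhoods, pathways disjoint from the
displayed set (`p = 1`), a displayed set equal to a pathway — are exercised
explicitly.

## The synthetic generator

`generate_synthetic()` samples a simple undirected graph uniformly over
distinct protein pairs, tags each edge with one source and one evidence
type uniformly at random, and draws pathway memberships uniformly from the
proteins, with the universe declared as the full generated protein set. It
exists to give every stage a test surface of arbitrary size with no
external data, and is fully seed-deterministic down to the written files.

What it does **not** emulate: real interaction networks are heavy-tailed
(hubs), pathway memberships are correlated with degree and with each other,
and source databases overlap non-uniformly. Passing property tests on
synthetic networks therefore demonstrates correctness of the graph and
scoring machinery, not biological realism of any particular result.

The packaged case-study fixtures are likewise *reconstructions* built from
protein names printed in published text — placeholder interactors (X1, X2,
X3) stand in for unnamed neighbors and deliberately carry no pathway
annotations — not snapshots of any interaction database. Counts that depend
on database versions (a target's full interactor list in a given release)
are out of scope by design.

## Problem sizes

The default test suite enumerates all hypergeometric parameters up to
`M = 12`, cross-checks neighbor extraction against a naive edge scan on 100
seeded networks of up to ~180 proteins, and round-trips reports on
generated fixtures of tens of nodes; the whole suite runs in well under a
minute. These sizes were chosen because every property being checked is
size-independent: the enumeration oracle is exact at any `M` it can afford,
and the graph properties are purely combinatorial.

## Limitations

* The synonym table is a user-supplied (or packaged) offline artifact; no
  live identifier service is consulted, so coverage is exactly what the
  table contains.
* Only first-order neighborhoods are extracted; second shells, centrality
  and other topology statistics are out of scope.
* Confidence scores of predicted-interaction databases are not modeled; the
  edge dialect deliberately omits them, and users should pre-filter.
* The hypergeometric screen inherits every ascertainment bias of the input
  interaction data; its p-values rank hypotheses rather than certify them.
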