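# pathneighbor

Perturbing a protein — by knockdown, mutation, or a drug — can ripple into
signaling pathways its interaction partners belong to, and bias an
experiment in ways the protein's own annotation never hints at.
`pathneighbor` gives a first estimate of that signaling impact, offline and
reproducibly: it resolves query terms (gene/protein names, synonyms, or
drug names) to canonical accessions, extracts the query's first-neighbor
subnetwork from integrated multi-source interaction data, annotates
signaling-pathway memberships, and scores each pathway's overrepresentation
among the displayed proteins.

It is aimed at experimentalists and computational biologists who have an
interaction edge list and a pathway gene-set collection for their organism
and want a quick, scriptable answer to: *which signaling pathways does my
perturbation plausibly touch?*

## The statistic

Let the **displayed set** be the queried proteins plus their first-neighbor
interactors, `n` proteins out of a species background (universe) of `M`
proteins. For a pathway with `K` member proteins of which `N` fall in the
displayed set, the overrepresentation p-value is the upper tail of the
hypergeometric distribution,

    P(X >= N) = sum_{i=N}^{min(n,K)} C(K,i) C(M-K, n-i) / C(M,n),

computed in log-space so proteome-scale universes are numerically safe.
One test is run per (pathway source database, pathway); the family of all
tests in a run is adjusted with the Benjamini–Hochberg step-up procedure
(default threshold 0.05). Raw p-values are always reported alongside.

## Worked example

The package ships three small case-study fixtures. The `cdc25` fixture is
the neighborhood of a *C. elegans* cell-cycle phosphatase whose knockdown
is routinely used to sterilize worms:

```r
library(pathneighbor)

fx  <- load_fixture("cdc25")
rep <- run_analysis(fx$network, fx$collection, "cdc-25.1", fx$synonyms)
rep
#> <neighborhood_report> 1 query protein(s), 9 first neighbor(s), 5 pathway test(s), 5 significant at 0.05

rep$enrichment
#>   source_db pathway_name N  n K     M        p_raw        p_adj significant
#> 1 SignaLink     EGF/MAPK 2 10 5 20000 2.248313e-06 1.124156e-05        TRUE
#> 2 SignaLink          IGF 1 10 3 20000 1.499325e-03 1.874156e-03        TRUE
#> 3 SignaLink        Notch 1 10 3 20000 1.499325e-03 1.874156e-03        TRUE
#> 4 SignaLink          TGF 1 10 3 20000 1.499325e-03 1.874156e-03        TRUE
#> 5 SignaLink          WNT 1 10 4 20000 1.998650e-03 1.998650e-03        TRUE
```

The query has nine first neighbors; six of them carry signaling-pathway
memberships (insulin/IGF, TGF-beta, EGF/MAPK, WNT and Notch components),
and every one of the five pathways is significantly overrepresented in the
10-protein displayed set against a 20,000-protein worm background — the
sterilization knockdown is anything but signaling-neutral. Reports can be
written as JSON, plain text, SIF or GraphML (`write_report_json()`,
`write_report_text()`, `export_sif()`, `export_graphml()`).

The same analysis runs from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","pathneighbor.R",package="pathneighbor"))')" \
  run --fixture cdc25 --query cdc-25.1 --out report.json
```

with subcommands `run`, `fixtures generate`, `fixtures load` and
`validate`; exit codes are 0 (success), 1 (usage error), 2 (data error).
User data enters through one normalized edge-list TSV dialect
(`a b source evidence_type pubmed_ids`), GMT gene sets with a
`SOURCE::Pathway` naming convention, and TSV synonym / drug-target tables —
see the vignette for the dialects.

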