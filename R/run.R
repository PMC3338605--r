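#' Run the full neighborhood-enrichment analysis
#'
#' Composes term resolution, first-neighbor extraction, pathway-membership
#' annotation, per-pathway hypergeometric overrepresentation of the
#' displayed set (query union neighbors), and Benjamini-Hochberg
#' adjustment. Deterministic for fixed inputs: two runs with identical
#' inputs produce byte-identical JSON reports.
#'
#' Resolved query accessions absent from the network are kept in the
#' displayed set (they are still proteins of the species) but contribute no
#' neighbors; a query fully absent from the network yields a report with
#' zero neighbors and enrichment computed on the query alone.
#'
#' @param network an `integrated_network`.
#' @param collection a [pathway_collection()].
#' @param terms query terms (gene/protein names, IDs, or drug names).
#' @param synonyms a [synonym_table()].
#' @param drugs optional [drug_target_table()].
#' @param mode,selections see [resolve_terms()].
#' @param source_filter,evidence_filter see [first_neighbors()].
#' @param overlap_mode `"displayed"` tests query plus neighbors as one set;
#'   `"neighbors_only"` excludes the query proteins from the tested set.
#' @param threshold significance threshold on the BH-adjusted p-value.
#' @return a `neighborhood_report` object: query terms and resolution,
#'   neighbor and displayed sets, per-protein pathway memberships, the
#'   induced subnetwork, the enrichment table sorted by adjusted p-value
#'   (ties broken by source database then pathway name), and the full
#'   resolved configuration for reproducibility.
#' @export
run_analysis <- function(network, collection, terms, synonyms, drugs = NULL,
                         mode = c("quick", "advanced"), selections = NULL,
                         source_filter = NULL, evidence_filter = NULL,
                         overlap_mode = c("displayed", "neighbors_only"),
                         threshold = 0.05) {
  mode <- match.arg(mode)
  overlap_mode <- match.arg(overlap_mode)
  res <- with_stage("resolve", resolve_terms(terms, synonyms, drugs = drugs,
                                             mode = mode, selections = selections))
  query <- sort(unique(unlist(res$resolved)))
  in_net <- intersect(query, network$proteins$accession)
  if (length(in_net)) {
    fn <- with_stage("neighbors",
                     first_neighbors(network, in_net,
                                     source_filter = source_filter,
                                     evidence_filter = evidence_filter))
    neighbors <- fn$neighbors
    subnetwork <- fn$subnetwork
  } else {
    warn_pn("no resolved query accession present in the network")
    neighbors <- character(0)
    subnetwork <- NULL
  }
  displayed <- sort(unique(c(query, neighbors)))
  ann <- with_stage("annotate", annotate_memberships(displayed, collection))
  tested <- if (overlap_mode == "displayed") displayed else neighbors
  enrichment <- with_stage("enrich", {
    rec <- enrich_pathways(tested, collection,
                           fallback_universe = network$proteins$accession)
    adjust_pvalues(rec, threshold = threshold)
  })
  structure(list(
    query_terms = terms,
    resolved = res$resolved,
    unresolved = res$unresolved,
    query = query,
    neighbors = neighbors,
    displayed = displayed,
    memberships = ann$memberships,
    pathway_counts = ann$counts,
    subnetwork = subnetwork,
    enrichment = enrichment,
    config = list(species = network$species, mode = mode,
                  source_filter = source_filter,
                  evidence_filter = evidence_filter,
                  overlap_mode = overlap_mode,
                  mtc_method = "benjamini_hochberg",
                  threshold = threshold)
  ), class = "neighborhood_report")
}

# errors propagated from pipeline stages are tagged with the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, pn_error = function(e) {
    e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
    stop(e)
  })
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat(sprintf(paste0("<neighborhood_report> %d query protein(s), ",
                     "%d first neighbor(s), %d pathway test(s), ",
                     "%d significant at %.3g\n"),
              length(x$query), length(x$neighbors), nrow(x$enrichment),
              sum(x$enrichment$significant), x$config$threshold))
  invisible(x)
}
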