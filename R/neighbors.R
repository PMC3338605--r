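#' Extract first neighbors and the induced subnetwork
#'
#' An edge qualifies when its sources intersect `source_filter` AND its
#' evidence types intersect `evidence_filter` (a `NULL` filter means "all").
#' The neighbor set consists of the endpoints of qualifying edges incident
#' to the query, minus the query itself; the subnetwork contains every
#' qualifying edge among the displayed set (query plus neighbors), including
#' neighbor-neighbor edges.
#'
#' @param network an `integrated_network`.
#' @param query accession set; unknown accessions are warned about and
#'   dropped, and an empty query after dropping is an error.
#' @param source_filter character vector of source-database labels, or
#'   `NULL` for all sources.
#' @param evidence_filter subset of [EVIDENCE_TYPES], or `NULL` for all.
#' @return list with `query` (known query accessions), `neighbors`,
#'   `displayed` (query union neighbors, sorted) and `subnetwork`
#'   (an `integrated_network` on the displayed set).
#' @export
first_neighbors <- function(network, query, source_filter = NULL,
                            evidence_filter = NULL) {
  query <- unique(as.character(query))
  unknown <- setdiff(query, network$proteins$accession)
  if (length(unknown)) {
    warn_pn("query accession(s) not in network: %s",
            paste(unknown, collapse = ", "))
    query <- setdiff(query, unknown)
  }
  if (length(query) == 0L) stop_data("no query accession present in the network")
  if (!is.null(evidence_filter)) {
    bad <- setdiff(evidence_filter, EVIDENCE_TYPES)
    if (length(bad)) stop_data("unknown evidence type in filter: %s", bad[1L])
  }
  edges <- network$edges
  ok <- rep(TRUE, nrow(edges))
  if (!is.null(source_filter)) {
    ok <- ok & vapply(edges$sources,
                      function(s) length(intersect(s, source_filter)) > 0L, TRUE)
  }
  if (!is.null(evidence_filter)) {
    ok <- ok & vapply(edges$evidence_types,
                      function(e) length(intersect(e, evidence_filter)) > 0L, TRUE)
  }
  qual <- edges[ok, , drop = FALSE]
  touches <- qual$a %in% query | qual$b %in% query
  neighbors <- setdiff(unique(c(qual$a[touches], qual$b[touches])), query)
  displayed <- sort(unique(c(query, neighbors)))
  sub_edges <- qual[qual$a %in% displayed & qual$b %in% displayed, , drop = FALSE]
  sub_proteins <- network$proteins[network$proteins$accession %in% displayed, ,
                                   drop = FALSE]
  sub <- build_network(sub_edges, sub_proteins, allow_self_loops = TRUE)
  list(query = sort(query), neighbors = sort(neighbors), displayed = displayed,
       subnetwork = sub)
}
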