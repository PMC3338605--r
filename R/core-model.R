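#' Known evidence-type vocabulary
#'
#' Every interaction edge carries at least one provenance class: a
#' small-scale physical experiment, a high-throughput physical screen, or a
#' genetic interaction.
#'
#' @export
EVIDENCE_TYPES <- c("small_scale_physical", "high_throughput_physical", "genetic")

#' Construct a protein reference table
#'
#' @param accession character vector of canonical primary accessions
#'   (opaque, case-sensitive, unique within one network).
#' @param display_name human-readable symbols; defaults to the accessions.
#' @param species single species label applied to every protein (e.g.
#'   `"worm"`, `"fly"`, `"human"`; any label is accepted but must be uniform
#'   within a network).
#' @return data.frame with columns `accession`, `display_name`, `species`.
#' @export
protein_refs <- function(accession, display_name = accession, species = "unknown") {
  accession <- as.character(accession)
  if (any(!nzchar(accession))) stop_data("empty accession in protein list")
  if (anyDuplicated(accession)) {
    stop_data("duplicate accession in protein list: %s",
              accession[duplicated(accession)][1L])
  }
  data.frame(accession = accession,
             display_name = as.character(display_name),
             species = rep_len(as.character(species), length(accession)),
             stringsAsFactors = FALSE)
}

#' Construct an interaction table
#'
#' Edges are undirected; each row is stored with its endpoints in canonical
#' (lexicographic) order so that (a, b) and (b, a) denote the same edge.
#'
#' @param a,b endpoint accessions (character vectors of equal length).
#' @param sources list of character vectors: source-database labels per edge
#'   (e.g. `"BioGRID"`, `"STRING"`, `"WI8"`, `"DroID"`, `"HPRD"`). A plain
#'   character vector is recycled as one label per edge.
#' @param evidence_types list of character vectors, each a non-empty subset
#'   of [EVIDENCE_TYPES]; a plain character vector gives one type per edge.
#' @param pubmed_ids list of character vectors of PubMed IDs (may be empty).
#' @return data.frame with columns `a`, `b` and list columns `sources`,
#'   `evidence_types`, `pubmed_ids`.
#' @export
interactions <- function(a, b, sources, evidence_types, pubmed_ids = NULL) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  stopifnot(length(b) == n)
  as_listcol <- function(x, default = NULL) {
    if (is.null(x)) return(replicate(n, default %||% character(0), simplify = FALSE))
    if (!is.list(x)) x <- as.list(as.character(x))
    lapply(x, as.character)
  }
  sources <- as_listcol(sources)
  evidence_types <- as_listcol(evidence_types)
  pubmed_ids <- as_listcol(pubmed_ids)
  bad <- setdiff(unique(unlist(evidence_types)), EVIDENCE_TYPES)
  if (length(bad)) stop_data("unknown evidence type: %s", bad[1L])
  if (any(vapply(evidence_types, length, 1L) == 0L)) {
    stop_data("interaction with empty evidence_types")
  }
  if (any(vapply(sources, length, 1L) == 0L)) {
    stop_data("interaction with empty sources")
  }
  # canonical ordering of endpoints
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  out <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  out$sources <- sources
  out$evidence_types <- evidence_types
  out$pubmed_ids <- pubmed_ids
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build an integrated interaction network
#'
#' Merges duplicate unordered pairs by set union of their sources, evidence
#' types and PubMed IDs, drops self-loops unless permitted, and indexes
#' adjacency.
#'
#' @param edges interaction table from [interactions()] (may have zero rows).
#' @param proteins protein table from [protein_refs()]; every edge endpoint
#'   must be listed here, and all proteins must share one species.
#' @param allow_self_loops keep a--a edges? Default drops them, so a query
#'   protein is never reported as its own first neighbor.
#' @return an `integrated_network` object: a list with elements `species`,
#'   `proteins` (data.frame), `edges` (merged interaction table) and
#'   `adjacency` (named list, accession -> sorted neighbor accessions).
#' @export
build_network <- function(edges, proteins, allow_self_loops = FALSE) {
  if (is.null(proteins) || nrow(proteins) == 0L) {
    stop_data("protein list is empty")
  }
  if (anyDuplicated(proteins$accession)) {
    stop_data("duplicate accession in protein list: %s",
              proteins$accession[duplicated(proteins$accession)][1L])
  }
  sp <- unique(proteins$species)
  if (length(sp) != 1L) {
    stop_data("mixed species in protein list: %s", paste(sp, collapse = ", "))
  }
  if (is.null(edges)) edges <- interactions(character(0), character(0), list(), list())
  missing <- setdiff(unique(c(edges$a, edges$b)), proteins$accession)
  if (length(missing)) {
    stop_data("edge endpoint not in protein list: %s", missing[1L])
  }
  if (!allow_self_loops && nrow(edges)) {
    edges <- edges[edges$a != edges$b, , drop = FALSE]
  }
  merged <- merge_edges(edges)
  net <- structure(list(
    species = sp,
    proteins = proteins[order(proteins$accession), , drop = FALSE],
    edges = merged,
    adjacency = build_adjacency(merged, proteins$accession)
  ), class = "integrated_network")
  rownames(net$proteins) <- NULL
  net
}

# union-merge rows that share an unordered endpoint pair; result is sorted
# by (a, b) so equal edge sets serialize identically
merge_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$a, edges$b, sep = "\r")
  idx <- split(seq_len(nrow(edges)), key)
  idx <- idx[order(names(idx))]
  pick <- vapply(idx, `[[`, 1L, 1L)
  out <- edges[pick, c("a", "b"), drop = FALSE]
  uni <- function(col) lapply(idx, function(i) sort(unique(unlist(edges[[col]][i]))))
  out$sources <- unname(uni("sources"))
  out$evidence_types <- unname(uni("evidence_types"))
  out$pubmed_ids <- unname(uni("pubmed_ids"))
  rownames(out) <- NULL
  out
}

build_adjacency <- function(edges, accessions) {
  adj <- lapply(stats::setNames(nm = sort(accessions)), function(x) character(0))
  if (nrow(edges)) {
    from <- c(edges$a, edges$b)
    to <- c(edges$b, edges$a)
    keep <- from != to | c(edges$a == edges$b, rep(FALSE, nrow(edges)))
    by_node <- split(to[keep], from[keep])
    for (acc in names(by_node)) adj[[acc]] <- sort(unique(by_node[[acc]]))
  }
  adj
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("<integrated_network> species=%s proteins=%d edges=%d\n",
              x$species, nrow(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of one protein in a network
#' @param network an `integrated_network`.
#' @param accession a single accession.
#' @return character vector of neighbor accessions (sorted).
#' @export
network_neighbors <- function(network, accession) {
  network$adjacency[[accession]] %||% character(0)
}

#' Degree of one protein
#' @inheritParams network_neighbors
#' @export
network_degree <- function(network, accession) {
  length(network_neighbors(network, accession))
}
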