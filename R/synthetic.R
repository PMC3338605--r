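#' Generate a seeded synthetic network and pathway collection
#'
#' Samples a simple undirected graph uniformly over distinct unordered
#' protein pairs (no duplicate edges, no self-loops), assigns each edge one
#' source label and one evidence type uniformly at random, and samples
#' pathway memberships uniformly from the proteins. The universe is
#' declared as the full set of generated proteins. The same seed always
#' yields identical objects and, through the deterministic writers,
#' byte-identical files.
#'
#' @param n_proteins number of proteins (accessions `P0001`, `P0002`, ...).
#' @param n_edges number of edges; must not exceed `choose(n_proteins, 2)`.
#' @param n_pathways number of pathway sets.
#' @param pathway_size_range integer vector `c(min, max)` of members per
#'   pathway (capped at `n_proteins`).
#' @param seed mandatory RNG seed.
#' @param species species label for the generated network.
#' @param dir optional directory; when given, `edges.tsv` and
#'   `pathways.gmt` are written there.
#' @return list with `network` and `collection`.
#' @export
generate_synthetic <- function(n_proteins, n_edges, n_pathways = 0,
                               pathway_size_range = c(2, 5), seed,
                               species = "synthetic", dir = NULL) {
  if (missing(seed)) stop_usage("generate_synthetic requires a seed")
  max_edges <- choose(n_proteins, 2)
  if (n_edges > max_edges) {
    stop_data("infeasible edge count: %d > choose(%d, 2) = %d",
              n_edges, n_proteins, max_edges)
  }
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1L] > pathway_size_range[2L]) {
    stop_usage("pathway_size_range must be c(min, max) with min <= max")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  accs <- sprintf("P%04d", seq_len(n_proteins))
  sources_pool <- c("BioGRID", "STRING", "HPRD")
  a <- b <- character(0)
  if (n_edges > 0) {
    # rejection-sample distinct unordered pairs; avoids materializing all
    # choose(n, 2) pairs for large n
    seen <- character(0)
    while (length(seen) < n_edges) {
      need <- 2L * (n_edges - length(seen)) + 10L
      i <- sample.int(n_proteins, need, replace = TRUE)
      j <- sample.int(n_proteins, need, replace = TRUE)
      ok <- i != j
      key <- paste(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
      seen <- unique(c(seen, key))
    }
    ij <- do.call(rbind, strsplit(seen[seq_len(n_edges)], " "))
    a <- accs[as.integer(ij[, 1L])]
    b <- accs[as.integer(ij[, 2L])]
  }
  edges <- interactions(a, b,
                        sources = sample(sources_pool, n_edges, replace = TRUE),
                        evidence_types = sample(EVIDENCE_TYPES, n_edges,
                                                replace = TRUE))
  network <- build_network(edges, protein_refs(accs, species = species))
  collection <- NULL
  if (n_pathways > 0) {
    pool <- seq.int(pathway_size_range[1L], pathway_size_range[2L])
    sizes <- pool[sample.int(length(pool), n_pathways, replace = TRUE)]
    sizes <- pmin(sizes, n_proteins)
    members <- lapply(sizes, function(k) sample(accs, k))
    collection <- pathway_collection(rep("synthetic", n_pathways),
                                     sprintf("pathway%03d", seq_len(n_pathways)),
                                     members, universe = accs)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(network$edges, file.path(dir, "edges.tsv"))
    if (!is.null(collection)) write_gmt(collection, file.path(dir, "pathways.gmt"))
  }
  list(network = network, collection = collection)
}
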