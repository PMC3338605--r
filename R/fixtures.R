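# Packaged case-study fixtures. These are reconstructions of three small
# published neighborhoods from the protein names printed in the source
# text, NOT snapshots of any interaction database: placeholder interactors
# (X1, X2, ...) stand in for unnamed neighbors and carry no pathway
# annotations. Each fixture ships an edge list, a GMT file, a mapping
# table, optionally a drug-target table, and a manifest of expected counts
# that is verified at load time.

FIXTURE_NAMES <- c("cdc25", "c27f24", "gja1")

#' Path to a packaged fixture file
#'
#' @param name fixture name: `"cdc25"`, `"c27f24"` or `"gja1"`.
#' @param file file within the fixture directory (e.g. `"edges.tsv"`);
#'   `NULL` returns the directory.
#' @return absolute path.
#' @export
fixture_path <- function(name, file = NULL) {
  if (!name %in% FIXTURE_NAMES) {
    stop_usage("unknown fixture '%s' (expected one of %s)", name,
               paste(FIXTURE_NAMES, collapse = ", "))
  }
  dir <- system.file("extdata", "fixtures", name, package = "pathneighbor",
                     mustWork = TRUE)
  if (is.null(file)) dir else file.path(dir, file)
}

#' Load a packaged case-study fixture
#'
#' Parses the fixture's files with the package's standard readers, builds
#' the integrated network, and checks the manifest counts (edge count,
#' query degree, pathway names) before returning.
#'
#' @param name fixture name: `"cdc25"` (a worm cell-cycle phosphatase and
#'   its nine interactors, six of them signaling proteins), `"c27f24"` (a
#'   worm gene of unknown function with three interactors) or `"gja1"` (the
#'   human gap-junction protein Connexin-43, a known anti-cancer drug
#'   target, with its printed interactors and a three-drug target table).
#' @return list with `network`, `collection`, `synonyms`, `drugs` (`NULL`
#'   when the fixture has no drug table) and `manifest` (the expected
#'   counts, as a list).
#' @export
load_fixture <- function(name) {
  dir <- fixture_path(name)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  el <- read_edge_list(file.path(dir, "edges.tsv"),
                       species = manifest$species)
  network <- build_network(el$edges, el$proteins)
  collection <- read_gmt(file.path(dir, "pathways.gmt"),
                         universe_size = manifest$universe_size)
  synonyms <- read_mapping_table(file.path(dir, "mapping.tsv"))
  drug_file <- file.path(dir, "drugs.tsv")
  drugs <- if (file.exists(drug_file)) read_drug_targets(drug_file) else NULL
  check_manifest(name, manifest, network, collection)
  list(network = network, collection = collection, synonyms = synonyms,
       drugs = drugs, manifest = manifest)
}

check_manifest <- function(name, manifest, network, collection) {
  fail <- function(what, got, want) {
    stop_data("fixture '%s' violates its manifest: %s is %s, expected %s",
              name, what, got, want)
  }
  if (nrow(network$edges) != manifest$n_edges) {
    fail("edge count", nrow(network$edges), manifest$n_edges)
  }
  deg <- network_degree(network, manifest$query_accession)
  if (deg != manifest$query_degree) {
    fail(sprintf("degree(%s)", manifest$query_accession), deg,
         manifest$query_degree)
  }
  have <- sort(paste0(collection$pathways$source_db, "::",
                      collection$pathways$pathway_name))
  want <- sort(unlist(manifest$pathways))
  if (!identical(have, want)) {
    fail("pathway list", paste(have, collapse = ","),
         paste(want, collapse = ","))
  }
  invisible(TRUE)
}
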