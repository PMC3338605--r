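# Report writers: JSON (machine-readable twin of the plain-text report),
# plain text, and network exports (SIF, GraphML). The JSON layout is
# described by the schema shipped at inst/extdata/report.schema.json.

REPORT_SCHEMA_ID <- "pathneighbor-report/1"

subnetwork_to_list <- function(net) {
  if (is.null(net)) return(NULL)
  nodes <- lapply(seq_len(nrow(net$proteins)), function(i) list(
    accession = net$proteins$accession[i],
    display_name = net$proteins$display_name[i]))
  edges <- lapply(seq_len(nrow(net$edges)), function(i) list(
    a = net$edges$a[i], b = net$edges$b[i],
    sources = I(net$edges$sources[[i]]),
    evidence_types = I(net$edges$evidence_types[[i]]),
    pubmed_ids = I(net$edges$pubmed_ids[[i]])))
  list(species = net$species, nodes = nodes, edges = edges)
}

list_to_subnetwork <- function(x) {
  if (is.null(x)) return(NULL)
  acc <- vapply(x$nodes, function(n) n$accession, "")
  dn <- vapply(x$nodes, function(n) n$display_name, "")
  ed <- interactions(
    vapply(x$edges, function(e) e$a, ""),
    vapply(x$edges, function(e) e$b, ""),
    lapply(x$edges, function(e) as.character(unlist(e$sources))),
    lapply(x$edges, function(e) as.character(unlist(e$evidence_types))),
    lapply(x$edges, function(e) as.character(unlist(e$pubmed_ids))))
  build_network(ed, protein_refs(acc, dn, species = x$species %||% "unknown"),
                allow_self_loops = TRUE)
}

#' Write and read a JSON analysis report
#'
#' The JSON report is the machine-readable twin of the plain-text report;
#' its layout is documented by the schema shipped with the package
#' (`system.file("extdata", "report.schema.json", package = "pathneighbor")`).
#' Writing is deterministic: identical reports serialize to byte-identical
#' files. `read_report_json` reconstructs a `neighborhood_report` whose
#' node/edge sets and annotations equal the original's.
#'
#' @param report a `neighborhood_report` from [run_analysis()].
#' @param path output (or input) file path.
#' @return `write_report_json` returns `path` invisibly; `read_report_json`
#'   returns a `neighborhood_report`.
#' @export
write_report_json <- function(report, path) {
  enr <- report$enrichment
  enrichment <- lapply(seq_len(nrow(enr)), function(i) list(
    source_db = enr$source_db[i], pathway_name = enr$pathway_name[i],
    N = enr$N[i], n = enr$n[i], K = enr$K[i], M = enr$M[i],
    p_raw = enr$p_raw[i], p_adj = enr$p_adj[i],
    significant = enr$significant[i]))
  mem <- report$memberships
  memberships <- lapply(seq_len(nrow(mem)), function(i) list(
    accession = mem$accession[i], source_db = mem$source_db[i],
    pathway_name = mem$pathway_name[i]))
  payload <- list(
    schema = REPORT_SCHEMA_ID,
    config = list(
      species = report$config$species,
      mode = report$config$mode,
      source_filter = if (is.null(report$config$source_filter)) NULL
                      else I(report$config$source_filter),
      evidence_filter = if (is.null(report$config$evidence_filter)) NULL
                        else I(report$config$evidence_filter),
      overlap_mode = report$config$overlap_mode,
      mtc_method = report$config$mtc_method,
      threshold = report$config$threshold),
    query_terms = I(report$query_terms),
    resolved = lapply(report$resolved, I),
    unresolved = I(report$unresolved),
    query = I(report$query),
    neighbors = I(report$neighbors),
    displayed = I(report$displayed),
    memberships = memberships,
    subnetwork = subnetwork_to_list(report$subnetwork),
    enrichment = enrichment)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema, REPORT_SCHEMA_ID)) {
    stop_data("unrecognized report schema: %s", x$schema %||% "<missing>")
  }
  chr <- function(v) as.character(unlist(v)) %||% character(0)
  mem <- x$memberships
  memberships <- data.frame(
    accession = vapply(mem, function(m) m$accession, ""),
    source_db = vapply(mem, function(m) m$source_db, ""),
    pathway_name = vapply(mem, function(m) m$pathway_name, ""),
    stringsAsFactors = FALSE)
  enr <- x$enrichment
  enrichment <- data.frame(
    source_db = vapply(enr, function(e) e$source_db, ""),
    pathway_name = vapply(enr, function(e) e$pathway_name, ""),
    N = vapply(enr, function(e) as.integer(e$N), 1L),
    n = vapply(enr, function(e) as.integer(e$n), 1L),
    K = vapply(enr, function(e) as.integer(e$K), 1L),
    M = vapply(enr, function(e) as.integer(e$M), 1L),
    p_raw = vapply(enr, function(e) as.numeric(e$p_raw), 1.0),
    p_adj = vapply(enr, function(e) as.numeric(e$p_adj), 1.0),
    significant = vapply(enr, function(e) isTRUE(e$significant), TRUE),
    stringsAsFactors = FALSE)
  cfg <- list(
    species = as.character(x$config$species),
    mode = as.character(x$config$mode),
    source_filter = if (is.null(x$config$source_filter)) NULL
                    else chr(x$config$source_filter),
    evidence_filter = if (is.null(x$config$evidence_filter)) NULL
                      else chr(x$config$evidence_filter),
    overlap_mode = as.character(x$config$overlap_mode),
    mtc_method = as.character(x$config$mtc_method),
    threshold = as.numeric(x$config$threshold))
  structure(list(
    query_terms = chr(x$query_terms),
    resolved = lapply(x$resolved, chr),
    unresolved = chr(x$unresolved),
    query = chr(x$query),
    neighbors = chr(x$neighbors),
    displayed = chr(x$displayed),
    memberships = memberships,
    pathway_counts = NULL,
    subnetwork = list_to_subnetwork(x$subnetwork),
    enrichment = enrichment,
    config = cfg), class = "neighborhood_report")
}

#' Write the plain-text analysis report
#'
#' Lists the query, the first neighbors (one line each), per-protein
#' pathway memberships, and the enrichment table sorted by adjusted
#' p-value ascending.
#'
#' @param report a `neighborhood_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_text <- function(report, path) {
  out <- c(
    "# neighborhood enrichment report",
    sprintf("species: %s", report$config$species),
    sprintf("mode: %s", report$config$mode),
    "",
    sprintf("## query (%d)", length(report$query)),
    sprintf("query\t%s", report$query),
    "",
    sprintf("## first neighbors (%d)", length(report$neighbors)),
    if (length(report$neighbors)) sprintf("neighbor\t%s", report$neighbors),
    "",
    "## pathway memberships",
    if (nrow(report$memberships)) with(report$memberships, sprintf(
      "member\t%s\t%s::%s", accession, source_db, pathway_name)),
    "",
    "## enrichment (sorted by adjusted p)",
    "source_db\tpathway\tN\tn\tK\tM\tp_raw\tp_adj\tsignificant",
    if (nrow(report$enrichment)) with(report$enrichment, sprintf(
      "%s\t%s\t%d\t%d\t%d\t%d\t%.6g\t%.6g\t%s",
      source_db, pathway_name, N, n, K, M, p_raw, p_adj,
      ifelse(significant, "yes", "no"))))
  writeLines(unlist(out), path)
  invisible(path)
}

#' Export a subnetwork in SIF (Simple Interaction Format)
#'
#' One `a pp b` triple per edge, tab-separated, with the relation label
#' `"pp"`; isolated nodes are written as single-column rows, as network
#' viewers expect.
#'
#' @param network an `integrated_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(network, path) {
  lines <- character(0)
  if (nrow(network$edges)) {
    lines <- sprintf("%s\tpp\t%s", network$edges$a, network$edges$b)
  }
  isolated <- setdiff(network$proteins$accession,
                      c(network$edges$a, network$edges$b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a SIF file back into node and edge sets
#'
#' @param path SIF file path.
#' @return list with `nodes` (character vector) and `edges` (data.frame
#'   `a`, `b` in canonical order).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  a <- b <- character(0)
  nodes <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) {
      nodes <- c(nodes, f)
    } else if (length(f) >= 3L) {
      a <- c(a, rep(f[1L], length(f) - 2L))
      b <- c(b, f[-(1:2)])
    } else {
      stop_data("SIF row with 2 fields")
    }
  }
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  edges <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(unique(c(nodes, a, b))), edges = edges)
}

#' Export / import a subnetwork as GraphML
#'
#' Uses igraph's GraphML writer. Multi-valued edge annotations (sources,
#' evidence types, PubMed IDs) are carried as `|`-separated attribute
#' strings; the species label travels as a graph attribute. The round trip
#' `read_graphml(export_graphml(x))` preserves node and edge sets and their
#' annotations.
#'
#' @param network an `integrated_network`.
#' @param path GraphML file path.
#' @return `export_graphml` returns `path` invisibly; `read_graphml`
#'   returns an `integrated_network`.
#' @export
export_graphml <- function(network, path) {
  g <- network_to_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  split_bar <- function(v) lapply(v, function(s)
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1L]])
  nm <- igraph::vertex_attr(g, "name")
  dn <- igraph::vertex_attr(g, "display_name") %||% nm
  sp <- igraph::graph_attr(g, "species") %||% "unknown"
  ed <- interactions(el[, 1L], el[, 2L],
                     split_bar(igraph::edge_attr(g, "sources")),
                     split_bar(igraph::edge_attr(g, "evidence_types")),
                     split_bar(igraph::edge_attr(g, "pubmed_ids")))
  build_network(ed, protein_refs(nm, dn, species = sp), allow_self_loops = TRUE)
}

#' Convert an integrated network to an igraph graph
#'
#' @param network an `integrated_network`.
#' @return an undirected igraph graph with vertex attributes `name`,
#'   `display_name`, edge attributes `sources`, `evidence_types`,
#'   `pubmed_ids` (each `|`-separated), and graph attribute `species`.
#' @export
network_to_igraph <- function(network) {
  collapse <- function(col) vapply(col, paste, "", collapse = "|")
  ed <- network$edges
  edf <- data.frame(from = ed$a, to = ed$b,
                    sources = collapse(ed$sources),
                    evidence_types = collapse(ed$evidence_types),
                    pubmed_ids = collapse(ed$pubmed_ids),
                    stringsAsFactors = FALSE)
  vdf <- data.frame(name = network$proteins$accession,
                    display_name = network$proteins$display_name,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::graph_attr(g, "species") <- network$species
  g
}
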