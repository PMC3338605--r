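# Normalized interaction edge-list dialect:
#   tab-separated columns: a, b, source, evidence_type, pubmed_ids
#   '#' comment lines; optional header detected by first-line match;
#   pubmed_ids is a '|'-separated list (may be empty)
# Converters from vendor dump formats (BioGRID TAB, STRING, HPRD, ...) are
# the user's responsibility; vendor formats drift by version.

EDGE_COLUMNS <- c("a", "b", "source", "evidence_type", "pubmed_ids")

#' Read an interaction edge list
#'
#' Parses the package's normalized TSV dialect (columns a, b, source,
#' evidence_type, pubmed_ids; `#` comments; optional header; PubMed IDs
#' separated by `|`). One interaction per data row; merging of duplicate
#' pairs happens later in [build_network()]. Proteins are inferred from the
#' endpoints with display names defaulting to the accession.
#'
#' @param path file path (or connection) of the edge list.
#' @param species species label applied to the inferred proteins.
#' @return list with `edges` (interaction table) and `proteins`
#'   (protein table).
#' @export
read_edge_list <- function(path, species = "unknown") {
  lines <- readLines(path)
  n_total <- length(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && identical(tolower(strsplit(lines[1L], "\t")[[1L]]),
                                 EDGE_COLUMNS)) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  a <- b <- character(length(lines))
  src <- ev <- pm <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 4L) f <- c(f, "")   # empty pubmed list allowed
    if (length(f) != 5L) {
      stop_data("expected 5 tab-separated columns, found %d", length(f),
                line = lineno[i])
    }
    if (!f[4L] %in% EVIDENCE_TYPES) {
      stop_data("unknown evidence type '%s' (expected one of %s)", f[4L],
                paste(EVIDENCE_TYPES, collapse = ", "), line = lineno[i])
    }
    if (!nzchar(f[1L]) || !nzchar(f[2L])) {
      stop_data("empty endpoint accession", line = lineno[i])
    }
    a[i] <- f[1L]; b[i] <- f[2L]
    src[[i]] <- f[3L]
    ev[[i]] <- f[4L]
    pm[[i]] <- if (nzchar(f[5L])) strsplit(f[5L], "|", fixed = TRUE)[[1L]] else character(0)
  }
  edges <- interactions(a, b, src, ev, pm)
  accs <- sort(unique(c(a, b)))
  list(edges = edges,
       proteins = protein_refs(accs, species = species))
}

#' Write an interaction edge list
#'
#' Inverse of [read_edge_list()]; multi-valued sources/evidence types are
#' expanded to one row per (source, evidence) combination so the output
#' stays within the dialect.
#'
#' @param edges interaction table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  rows <- character(0)
  if (nrow(edges)) {
    rows <- unlist(lapply(seq_len(nrow(edges)), function(i) {
      pm <- paste(edges$pubmed_ids[[i]], collapse = "|")
      combos <- expand.grid(source = edges$sources[[i]],
                            evidence = edges$evidence_types[[i]],
                            stringsAsFactors = FALSE)
      paste(edges$a[i], edges$b[i], combos$source, combos$evidence, pm,
            sep = "\t")
    }))
  }
  writeLines(c(paste(EDGE_COLUMNS, collapse = "\t"), rows), path)
  invisible(path)
}
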