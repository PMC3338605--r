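#' Construct a pathway collection
#'
#' Named protein sets grouped by pathway source database, plus the species
#' background universe against which overrepresentation is judged. The
#' universe may be an explicit accession set (then `M = |universe|` and
#' pathway members outside it are dropped with a warning) or a declared
#' integer size; if neither is given, analyses fall back to the union of
#' network proteins and pathway members, with a warning.
#'
#' @param source_db character vector: pathway source database per set
#'   (e.g. `"KEGG"`, `"Reactome"`, `"SignaLink"`).
#' @param pathway_name pathway name per set.
#' @param members list of member accession vectors. Duplicate
#'   (source, name) pairs are merged by member union; empty sets are
#'   rejected.
#' @param universe optional explicit background accession set.
#' @param universe_size optional declared background size M (ignored when
#'   `universe` is given).
#' @return a `pathway_collection` object with data.frame `pathways`
#'   (columns `source_db`, `pathway_name`, list column `members`),
#'   `universe` and `universe_size`.
#' @export
pathway_collection <- function(source_db, pathway_name, members,
                               universe = NULL, universe_size = NULL) {
  stopifnot(length(source_db) == length(pathway_name),
            length(members) == length(pathway_name))
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  if (any(vapply(members, length, 1L) == 0L)) {
    stop_data("pathway with empty member set: %s",
              pathway_name[vapply(members, length, 1L) == 0L][1L])
  }
  key <- paste(source_db, pathway_name, sep = "\r")
  idx <- split(seq_along(key), key)
  idx <- idx[order(names(idx))]
  pick <- vapply(idx, `[[`, 1L, 1L)
  pw <- data.frame(source_db = as.character(source_db)[pick],
                   pathway_name = as.character(pathway_name)[pick],
                   stringsAsFactors = FALSE)
  pw$members <- unname(lapply(idx, function(i) sort(unique(unlist(members[i])))))
  rownames(pw) <- NULL
  if (!is.null(universe)) {
    universe <- sort(unique(as.character(universe)))
    outside <- lapply(pw$members, setdiff, y = universe)
    n_out <- sum(vapply(outside, length, 1L))
    if (n_out > 0L) {
      warn_pn("%d pathway member(s) outside the explicit universe dropped", n_out)
      pw$members <- lapply(pw$members, intersect, y = universe)
      empty <- vapply(pw$members, length, 1L) == 0L
      pw <- pw[!empty, , drop = FALSE]
      rownames(pw) <- NULL
    }
    universe_size <- length(universe)
  }
  if (!is.null(universe_size)) {
    universe_size <- as.integer(universe_size)
    big <- max(c(0L, vapply(pw$members, length, 1L)))
    if (universe_size < big) {
      stop_data("universe size %d smaller than largest pathway (%d members)",
                universe_size, big)
    }
  }
  structure(list(pathways = pw, universe = universe,
                 universe_size = universe_size),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways from %d source(s); universe %s\n",
              nrow(x$pathways), length(unique(x$pathways$source_db)),
              if (!is.null(x$universe_size)) sprintf("M=%d", x$universe_size)
              else "undeclared"))
  invisible(x)
}

#' Read a GMT gene-set file into a pathway collection
#'
#' Standard GMT rows: name TAB description TAB member1 TAB member2 ... By
#' convention the name is `SOURCE::PathwayName`, so one file can carry sets
#' from several pathway databases; a name without `::` falls under source
#' `"unknown"`. Duplicate (source, name) rows merge by member union.
#'
#' @param path GMT file path.
#' @param universe,universe_size background, as in [pathway_collection()].
#' @return a `pathway_collection`.
#' @export
read_gmt <- function(path, universe = NULL, universe_size = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  src <- nm <- character(length(lines))
  mem <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_data("GMT row needs name, description and at least one member (%d field(s))",
                length(f), line = lineno[i])
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop_data("GMT row with empty member list", line = lineno[i])
    }
    if (grepl("::", f[1L], fixed = TRUE)) {
      parts <- strsplit(f[1L], "::", fixed = TRUE)[[1L]]
      src[i] <- parts[1L]
      nm[i] <- paste(parts[-1L], collapse = "::")
    } else {
      src[i] <- "unknown"
      nm[i] <- f[1L]
    }
    mem[[i]] <- members
  }
  pathway_collection(src, nm, mem, universe = universe,
                     universe_size = universe_size)
}

#' Write a pathway collection as GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  pw <- collection$pathways
  rows <- vapply(seq_len(nrow(pw)), function(i) {
    paste(c(paste0(pw$source_db[i], "::", pw$pathway_name[i]), "-",
            pw$members[[i]]), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read an identifier-synonym mapping table
#'
#' TSV with columns term, accession, score (header optional). Negative
#' scores are rejected; duplicate (term, accession) rows keep the maximum
#' score.
#'
#' @param path file path.
#' @return a [synonym_table()].
#' @export
read_mapping_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^term\taccession", tolower(lines[1L]))) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  term <- acc <- character(length(lines))
  score <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L) {
      stop_data("expected 3 tab-separated columns, found %d", length(f),
                line = lineno[i])
    }
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s)) stop_data("non-numeric score '%s'", f[3L], line = lineno[i])
    if (s < 0) stop_data("negative score %s for term '%s'", f[3L], f[1L],
                         line = lineno[i])
    term[i] <- f[1L]; acc[i] <- f[2L]; score[i] <- s
  }
  synonym_table(term, acc, score)
}

#' Read a drug-target table
#'
#' TSV with columns drug, accession (header optional); a user-supplied
#' lookup table in place of any live compound-database query.
#'
#' @param path file path.
#' @return a [drug_target_table()].
#' @export
read_drug_targets <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^drug\taccession", tolower(lines[1L]))) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  drug <- acc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) {
      stop_data("expected 2 tab-separated columns, found %d", length(f),
                line = lineno[i])
    }
    drug[i] <- f[1L]; acc[i] <- f[2L]
  }
  drug_target_table(drug, acc)
}
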