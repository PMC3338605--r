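#' Construct a synonym table
#'
#' Maps case-folded search terms to scored candidate accessions, the offline
#' counterpart of an online synonym-search service. Candidate lists are kept
#' sorted by score descending with lexicographic tie-break on accession, so
#' quick-mode resolution is deterministic. A per-table cache memoizes
#' resolutions; [write_synonym_cache()] persists it between runs.
#'
#' @param term character vector of search terms (case-folded on storage;
#'   lookups are case-insensitive).
#' @param accession candidate accession per row.
#' @param score non-negative synonym-search score per row. Scores are opaque;
#'   only their order matters. Duplicate (term, accession) rows keep the
#'   maximum score.
#' @return a `synonym_table` object.
#' @export
synonym_table <- function(term = character(0), accession = character(0),
                          score = numeric(0)) {
  term <- tolower(as.character(term))
  accession <- as.character(accession)
  score <- as.numeric(score)
  stopifnot(length(term) == length(accession), length(term) == length(score))
  if (any(score < 0)) stop_data("negative synonym score for term '%s'",
                                term[score < 0][1L])
  entries <- list()
  if (length(term)) {
    df <- data.frame(term = term, accession = accession, score = score,
                     stringsAsFactors = FALSE)
    # duplicate (term, accession): keep max score
    df <- df[order(df$term, df$accession, -df$score), , drop = FALSE]
    df <- df[!duplicated(df[c("term", "accession")]), , drop = FALSE]
    entries <- lapply(split(df, df$term), function(d) {
      d <- d[order(-d$score, d$accession), c("accession", "score"), drop = FALSE]
      rownames(d) <- NULL
      d
    })
  }
  structure(list(entries = entries, cache = new.env(parent = emptyenv())),
            class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("<synonym_table> %d terms, %d cached resolutions\n",
              length(x$entries), length(ls(x$cache))))
  invisible(x)
}

#' Construct a drug-target table
#'
#' @param drug character vector of drug/compound names or IDs (case-folded).
#' @param accession target accession per row; a drug may repeat across rows.
#' @return a `drug_target_table` object: named list drug -> sorted accession
#'   set. Empty target sets are never stored.
#' @export
drug_target_table <- function(drug = character(0), accession = character(0)) {
  drug <- tolower(as.character(drug))
  accession <- as.character(accession)
  stopifnot(length(drug) == length(accession))
  if (any(!nzchar(accession))) stop_data("empty target accession in drug table")
  targets <- lapply(split(accession, drug), function(x) sort(unique(x)))
  targets <- targets[order(names(targets))]
  structure(list(targets = targets), class = "drug_target_table")
}

#' Resolve query terms to accessions
#'
#' Quick mode picks, per term, the single highest-scoring candidate
#' (lexicographic tie-break); advanced mode returns exactly the caller's
#' selections, validated against the candidate lists. A term matching the
#' drug-target table resolves to the drug's full target set instead of a
#' synonym lookup. Unresolved terms are reported, not fatal, unless no term
#' at all resolves.
#'
#' @param terms non-empty character vector of query terms.
#' @param table a [synonym_table()].
#' @param drugs optional [drug_target_table()].
#' @param mode `"quick"` or `"advanced"`.
#' @param selections advanced mode only: named list, term -> chosen
#'   accession vector; each selection must be a subset of that term's
#'   candidates.
#' @return list with `resolved` (named list term -> accession set) and
#'   `unresolved` (character vector of terms that matched nothing).
#' @export
resolve_terms <- function(terms, table, drugs = NULL,
                          mode = c("quick", "advanced"), selections = NULL) {
  mode <- match.arg(mode)
  if (length(terms) == 0L) stop_usage("no query terms given")
  stopifnot(inherits(table, "synonym_table"))
  if (mode == "advanced" && is.null(selections)) {
    stop_usage("advanced mode requires selections")
  }
  resolved <- list()
  unresolved <- character(0)
  for (term in terms) {
    key <- tolower(term)
    hit <- NULL
    if (!is.null(drugs) && key %in% names(drugs$targets)) {
      hit <- drugs$targets[[key]]
    } else if (mode == "quick") {
      cached <- table$cache[[key]]
      if (!is.null(cached)) {
        hit <- cached
      } else {
        cand <- table$entries[[key]]
        if (!is.null(cand) && nrow(cand)) {
          hit <- cand$accession[1L]   # sorted: top score, lexicographic ties
          assign(key, hit, envir = table$cache)
        }
      }
    } else {
      sel <- selections[[term]] %||% selections[[key]]
      cand <- table$entries[[key]]
      if (!is.null(sel)) {
        bad <- setdiff(sel, cand$accession %||% character(0))
        if (length(bad)) {
          stop_data("selection for term '%s' not among candidates: %s",
                    term, bad[1L])
        }
        hit <- sort(unique(sel))
      }
    }
    if (is.null(hit) || length(hit) == 0L) {
      unresolved <- c(unresolved, term)
    } else {
      resolved[[term]] <- hit
    }
  }
  if (length(resolved) == 0L) stop_data("no query could be resolved")
  if (length(unresolved)) {
    warn_pn("unresolved query terms: %s", paste(unresolved, collapse = ", "))
  }
  list(resolved = resolved, unresolved = unresolved)
}

#' Persist or restore the synonym-resolution cache
#'
#' The cache stores prior quick-mode resolutions so repeated queries return
#' byte-identical results without re-ranking. The on-disk format is a TSV
#' with columns term and accession (one row per cached target).
#'
#' @param table a [synonym_table()].
#' @param path file path.
#' @return `write_synonym_cache` returns `path` invisibly;
#'   `read_synonym_cache` returns `table` with its cache populated.
#' @export
write_synonym_cache <- function(table, path) {
  keys <- sort(ls(table$cache))
  rows <- unlist(lapply(keys, function(k) {
    paste(k, get(k, envir = table$cache), sep = "\t")
  }))
  writeLines(c("term\taccession", rows), path)
  invisible(path)
}

#' @rdname write_synonym_cache
#' @export
read_synonym_cache <- function(table, path) {
  lines <- readLines(path)
  lines <- lines[-1L]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    term <- vapply(parts, `[[`, "", 1L)
    acc <- vapply(parts, `[[`, "", 2L)
    for (k in unique(term)) {
      assign(k, sort(acc[term == k]), envir = table$cache)
    }
  }
  table
}
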