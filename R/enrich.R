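#' Upper-tail hypergeometric probability
#'
#' The overrepresentation score: the probability of observing at least `N`
#' pathway members when drawing `n` proteins without replacement from a
#' universe of `M` proteins of which `K` belong to the pathway,
#' \deqn{P(X \ge N) = \sum_{i=N}^{\min(n,K)} \binom{K}{i}\binom{M-K}{n-i} / \binom{M}{n}.}
#' Terms are accumulated from log-binomial coefficients, so universes up to
#' at least 1e5 proteins are numerically safe.
#'
#' @param N observed overlap count, `0 <= N <= min(n, K)`.
#' @param n number of draws (size of the displayed protein set).
#' @param K pathway size within the universe.
#' @param M universe size.
#' @return `P(X >= N)`; exactly 1 when `N = 0`.
#' @export
hypergeom_upper_tail <- function(N, n, K, M) {
  for (v in c("N", "n", "K", "M")) {
    x <- get(v)
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
      stop_data("%s must be a single non-negative integer", v)
    }
  }
  if (N > n) stop_data("constraint violated: N <= n (N=%d, n=%d)", N, n)
  if (n > M) stop_data("constraint violated: n <= M (n=%d, M=%d)", n, M)
  if (K > M) stop_data("constraint violated: K <= M (K=%d, M=%d)", K, M)
  if (N > K) stop_data("constraint violated: N <= K (N=%d, K=%d)", N, K)
  if (N == 0) return(1)
  i <- seq.int(N, min(n, K))
  logterms <- lchoose(K, i) + lchoose(M - K, n - i) - lchoose(M, n)
  top <- max(logterms)
  p <- exp(top) * sum(exp(logterms - top))
  min(p, 1)
}

#' Annotate pathway memberships of a displayed protein set
#'
#' @param displayed accession set (query plus first neighbors).
#' @param collection a [pathway_collection()].
#' @return list with `memberships`, a data.frame (`accession`, `source_db`,
#'   `pathway_name`), one row per membership of a displayed protein (a
#'   protein with no memberships contributes no rows), and `counts`, a
#'   data.frame (`source_db`, `pathway_name`, `n_displayed`) of per-pathway
#'   member counts within the displayed set, consistent with `memberships`.
#' @export
annotate_memberships <- function(displayed, collection) {
  displayed <- sort(unique(as.character(displayed)))
  pw <- collection$pathways
  hits <- lapply(seq_len(nrow(pw)), function(i) {
    m <- intersect(pw$members[[i]], displayed)
    if (length(m) == 0L) return(NULL)
    data.frame(accession = m, source_db = pw$source_db[i],
               pathway_name = pw$pathway_name[i], stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  memberships <- if (length(hits)) do.call(rbind, hits) else
    data.frame(accession = character(0), source_db = character(0),
               pathway_name = character(0), stringsAsFactors = FALSE)
  memberships <- memberships[order(memberships$accession, memberships$source_db,
                                   memberships$pathway_name), , drop = FALSE]
  rownames(memberships) <- NULL
  counts <- data.frame(source_db = pw$source_db, pathway_name = pw$pathway_name,
                       n_displayed = vapply(pw$members, function(m)
                         length(intersect(m, displayed)), 1L),
                       stringsAsFactors = FALSE)
  list(memberships = memberships, counts = counts)
}

#' Score per-pathway overrepresentation of a displayed set
#'
#' For each (source database, pathway) the displayed proteins are treated as
#' `n` draws from the species universe of size `M`; the pathway contributes
#' `K` marked proteins, of which `N` fall in the displayed set. Each pathway
#' is tested once per source database; tests are never pooled across
#' sources, preserving per-database reporting. When the collection declares
#' an explicit universe set, displayed proteins outside it are dropped from
#' `n` with a warning; with no declared universe at all, `M` falls back to
#' the union of network proteins and pathway members.
#'
#' @param displayed accession set to test.
#' @param collection a [pathway_collection()].
#' @param fallback_universe accessions (typically the network's proteins)
#'   merged with pathway members to size M when the collection declares no
#'   universe.
#' @return data.frame of enrichment records: `source_db`, `pathway_name`,
#'   `N`, `n`, `K`, `M`, `p_raw` (and later `p_adj`, `significant` from
#'   [adjust_pvalues()]).
#' @export
enrich_pathways <- function(displayed, collection, fallback_universe = NULL) {
  displayed <- sort(unique(as.character(displayed)))
  pw <- collection$pathways
  if (!is.null(collection$universe)) {
    M <- length(collection$universe)
    outside <- setdiff(displayed, collection$universe)
    if (length(outside)) {
      warn_pn("%d displayed protein(s) outside the universe dropped from the test",
              length(outside))
      displayed <- intersect(displayed, collection$universe)
    }
  } else if (!is.null(collection$universe_size)) {
    M <- collection$universe_size
  } else {
    M <- length(unique(c(fallback_universe, unlist(pw$members), displayed)))
    warn_pn("no universe declared; using M = %d (network proteins + pathway members)", M)
  }
  n <- length(displayed)
  if (n > M) stop_data("displayed set (%d) larger than universe (%d)", n, M)
  rec <- data.frame(source_db = pw$source_db, pathway_name = pw$pathway_name,
                    stringsAsFactors = FALSE)
  rec$N <- vapply(pw$members, function(m) length(intersect(m, displayed)), 1L)
  rec$n <- n
  rec$K <- vapply(pw$members, length, 1L)
  rec$M <- M
  rec$p_raw <- vapply(seq_len(nrow(rec)), function(i)
    hypergeom_upper_tail(rec$N[i], n, rec$K[i], M), 1.0)
  rec
}

#' Benjamini-Hochberg adjustment of enrichment records
#'
#' Step-up FDR control over the whole family of pathways tested in one run,
#' across source databases. Raw p-values are always retained so users can
#' apply their own procedure.
#'
#' @param records data.frame from [enrich_pathways()] with a `p_raw` column.
#' @param method only `"benjamini_hochberg"`.
#' @param threshold significance threshold on the adjusted p-value.
#' @return `records` with `p_adj` and logical `significant` columns added,
#'   sorted by (`p_adj`, `source_db`, `pathway_name`).
#' @export
adjust_pvalues <- function(records, method = "benjamini_hochberg",
                           threshold = 0.05) {
  method <- match.arg(method, "benjamini_hochberg")
  stopifnot(is.data.frame(records), "p_raw" %in% names(records))
  if (nrow(records) && any(records$p_raw <= 0 | records$p_raw > 1)) {
    stop_data("p_raw outside (0, 1]")
  }
  records$p_adj <- stats::p.adjust(records$p_raw, method = "BH")
  records$significant <- records$p_adj <= threshold
  ord <- order(records$p_adj, records$source_db, records$pathway_name)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}
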