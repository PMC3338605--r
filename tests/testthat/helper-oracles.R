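# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Exhaustive upper-tail hypergeometric probability: enumerate every draw of
# size n from 1..M, marking 1..K, and count draws containing >= N marks.
enum_upper_tail <- function(N, n, K, M) {
  if (N == 0) return(1)
  if (n == 0) return(0)   # N >= 1 unreachable with zero draws
  draws <- utils::combn(M, n)
  mean(colSums(draws <= K) >= N)
}

# Naive first-neighbor scan: double loop over the raw edge rows.
naive_first_neighbors <- function(edges, query, source_filter = NULL,
                                  evidence_filter = NULL) {
  out <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (!is.null(source_filter) &&
        !any(edges$sources[[i]] %in% source_filter)) next
    if (!is.null(evidence_filter) &&
        !any(edges$evidence_types[[i]] %in% evidence_filter)) next
    a <- edges$a[i]; b <- edges$b[i]
    if (a %in% query) out <- c(out, b)
    if (b %in% query) out <- c(out, a)
  }
  sort(setdiff(unique(out), query))
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust:
# sort ascending, q_i = p_(i) * m / i, enforce monotonicity from the top.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Small labeled network shared by several tests: a star of nine neighbors
# around one hub, all edges small-scale physical.
star_network <- function(hub = "Q", n_leaves = 9) {
  leaves <- sprintf("X%d", seq_len(n_leaves))
  ed <- interactions(rep(hub, n_leaves), leaves,
                     sources = rep("BioGRID", n_leaves),
                     evidence_types = rep("small_scale_physical", n_leaves))
  build_network(ed, protein_refs(c(hub, leaves)))
}

expect_same_network <- function(x, y) {
  expect_identical(x$proteins$accession, y$proteins$accession)
  expect_identical(x$edges$a, y$edges$a)
  expect_identical(x$edges$b, y$edges$b)
  expect_identical(x$edges$sources, y$edges$sources)
  expect_identical(x$edges$evidence_types, y$edges$evidence_types)
  expect_identical(x$edges$pubmed_ids, y$edges$pubmed_ids)
}
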