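test_that("a star query returns all leaves and filters can empty it", {
  net <- star_network()
  fn <- first_neighbors(net, "Q")
  expect_length(fn$neighbors, 9)
  expect_equal(fn$displayed, sort(c("Q", sprintf("X%d", 1:9))))
  none <- first_neighbors(net, "Q", evidence_filter = "genetic")
  expect_length(none$neighbors, 0)
  by_source <- first_neighbors(net, "Q", source_filter = "HPRD")
  expect_length(by_source$neighbors, 0)
})

test_that("the induced subnetwork keeps neighbor-neighbor edges", {
  ed <- interactions(c("Q", "Q", "X1", "X2"), c("X1", "X2", "X2", "Z"),
                     sources = rep("BioGRID", 4),
                     evidence_types = rep("genetic", 4))
  net <- build_network(ed, protein_refs(c("Q", "X1", "X2", "Z")))
  fn <- first_neighbors(net, "Q")
  expect_equal(fn$neighbors, c("X1", "X2"))
  # X1-X2 retained, X2-Z excluded (Z is not displayed)
  pairs <- paste(fn$subnetwork$edges$a, fn$subnetwork$edges$b)
  expect_setequal(pairs, c("Q X1", "Q X2", "X1 X2"))
})

test_that("unknown query accessions are dropped with a warning, not fatally", {
  net <- star_network()
  expect_warning(fn <- first_neighbors(net, c("Q", "NOPE")), "NOPE")
  expect_length(fn$neighbors, 9)
  expect_error(suppressWarnings(first_neighbors(net, "NOPE")),
               class = "pn_data_error")
})

test_that("first_neighbors matches the naive edge-scan oracle under filters", {
  for (seed in c(101, 202, 303)) {
    syn <- generate_synthetic(60, 120, seed = seed)
    net <- syn$network
    set.seed(seed + 1)
    query <- sample(net$proteins$accession, 3)
    for (filters in list(
      list(src = NULL, ev = NULL),
      list(src = "BioGRID", ev = NULL),
      list(src = c("STRING", "HPRD"), ev = c("genetic", "small_scale_physical")))) {
      got <- first_neighbors(net, query, source_filter = filters$src,
                             evidence_filter = filters$ev)$neighbors
      want <- naive_first_neighbors(net$edges, query,
                                    source_filter = filters$src,
                                    evidence_filter = filters$ev)
      expect_identical(got, want)
    }
  }
})

test_that("enlarging a filter never shrinks the neighbor set", {
  syn <- generate_synthetic(50, 100, seed = 7)
  net <- syn$network
  query <- net$proteins$accession[1:2]
  small <- first_neighbors(net, query, source_filter = "BioGRID",
                           evidence_filter = "genetic")$neighbors
  wider_src <- first_neighbors(net, query,
                               source_filter = c("BioGRID", "STRING"),
                               evidence_filter = "genetic")$neighbors
  wider_ev <- first_neighbors(net, query, source_filter = "BioGRID",
                              evidence_filter = EVIDENCE_TYPES)$neighbors
  expect_true(all(small %in% wider_src))
  expect_true(all(small %in% wider_ev))
})

test_that("hypergeometric tail matches frozen enumeration values", {
  expect_identical(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
  # frozen from the exhaustive combn oracle over all C(20, 6) draws
  expect_equal(hypergeom_upper_tail(3, 6, 7, 20), 13020 / 38760,
               tolerance = 1e-12)
  expect_equal(enum_upper_tail(3, 6, 7, 20), 13020 / 38760, tolerance = 1e-12)
})

test_that("hypergeometric tail names the violated constraint", {
  expect_error(hypergeom_upper_tail(5, 4, 6, 10), "N <= n",
               class = "pn_data_error")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "n <= M",
               class = "pn_data_error")
  expect_error(hypergeom_upper_tail(1, 2, 11, 10), "K <= M",
               class = "pn_data_error")
  expect_error(hypergeom_upper_tail(3, 5, 2, 10), "N <= K",
               class = "pn_data_error")
})

test_that("hypergeometric tail agrees with the survival function at scale", {
  set.seed(42)
  for (i in 1:50) {
    M <- sample(10:100000, 1)
    K <- sample.int(M, 1)
    n <- sample.int(M, 1)
    N <- sample.int(min(n, K), 1)
    expect_equal(hypergeom_upper_tail(N, n, K, M),
                 stats::phyper(N - 1, K, M - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the tail is strictly decreasing in N and the pmf sums to one", {
  for (prm in list(c(20, 7, 6), c(50, 10, 12), c(1000, 40, 25))) {
    M <- prm[1]; K <- prm[2]; n <- prm[3]
    tails <- vapply(0:min(n, K), function(N)
      hypergeom_upper_tail(N, n, K, M), 1.0)
    expect_true(all(diff(tails) < 0))
    pmf <- c(-diff(tails), tails[length(tails)])
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the worked step-up example", {
  rec <- data.frame(source_db = "S", pathway_name = c("a", "b", "c"),
                    p_raw = c(0.01, 0.02, 0.04), stringsAsFactors = FALSE)
  adj <- adjust_pvalues(rec, threshold = 0.05)
  expect_equal(adj$p_adj[order(adj$pathway_name)], c(0.03, 0.03, 0.04))
  expect_true(all(adj$significant))
  one <- adjust_pvalues(data.frame(source_db = "S", pathway_name = "x",
                                   p_raw = 0.04), threshold = 0.05)
  expect_equal(one$p_adj, 0.04)
  expect_true(one$significant)
  flat <- adjust_pvalues(data.frame(source_db = "S",
                                    pathway_name = letters[1:4],
                                    p_raw = rep(1, 4)), threshold = 0.05)
  expect_false(any(flat$significant))
})

test_that("BH adjustment matches an independent step-up oracle on random vectors", {
  set.seed(99)
  for (i in 1:20) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    rec <- data.frame(source_db = "S", pathway_name = sprintf("pw%02d", 1:m),
                      p_raw = p, stringsAsFactors = FALSE)
    adj <- adjust_pvalues(rec)
    key <- match(rec$pathway_name, adj$pathway_name)
    expect_equal(adj$p_adj[key], bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj$p_adj >= adj$p_raw - 1e-15))
    expect_true(all(diff(adj$p_adj) >= -1e-15))   # sorted output is monotone
  }
})

test_that("membership annotation counts agree with per-protein lists", {
  fx <- load_fixture("gja1")
  fn <- first_neighbors(fx$network, "GJA1")
  ann <- annotate_memberships(fn$neighbors, fx$collection)
  egf <- ann$counts[ann$counts$pathway_name == "EGF/MAPK", "n_displayed"]
  expect_equal(egf, 6L)
  by_hand <- table(paste(ann$memberships$source_db,
                         ann$memberships$pathway_name))
  expect_equal(unname(by_hand[["KEGG EGF/MAPK"]]), 6L)
  expect_equal(nrow(annotate_memberships(character(0), fx$collection)$memberships), 0L)
})

test_that("enrichment extremes behave: disjoint pathways at p = 1, perfect overlap minimal", {
  displayed <- sprintf("D%d", 1:5)
  pc <- pathway_collection(
    rep("S", 3), c("absent", "perfect", "partial"),
    list(c("Z1", "Z2", "Z3"), displayed, c(displayed[1:2], "Z9")),
    universe_size = 1000)
  rec <- enrich_pathways(displayed, pc)
  expect_equal(rec$p_raw[rec$pathway_name == "absent"], 1)
  expect_equal(which.min(rec$p_raw),
               which(rec$pathway_name == "perfect"))
  expect_true(all(rec$N <= pmin(rec$n, rec$K)))
})

test_that("an explicit universe drops outsiders from members and draws", {
  expect_warning(
    pc <- pathway_collection("S", "pw", list(c("A", "B", "OUT")),
                             universe = c("A", "B", "C", "D")),
    "outside the explicit universe")
  expect_equal(pc$pathways$members[[1]], c("A", "B"))
  expect_equal(pc$universe_size, 4L)
  expect_warning(rec <- enrich_pathways(c("A", "ELSEWHERE"), pc),
                 "outside the universe")
  expect_equal(rec$n, 1L)
  expect_equal(rec$N, 1L)
})

test_that("run_analysis composes the stages deterministically", {
  fx <- load_fixture("cdc25")
  rep <- run_analysis(fx$network, fx$collection, "cdc-25.1", fx$synonyms)
  expect_length(rep$neighbors, 9)
  expect_equal(rep$config$overlap_mode, "displayed")
  # enrichment ordering: p_adj, then source, then pathway name
  expect_false(is.unsorted(rep$enrichment$p_adj))
  # query protein in the tested set: displayed size = 10
  expect_equal(unique(rep$enrichment$n), 10L)
  only_nbrs <- run_analysis(fx$network, fx$collection, "cdc-25.1",
                            fx$synonyms, overlap_mode = "neighbors_only")
  expect_equal(unique(only_nbrs$enrichment$n), 9L)
})

test_that("a query absent from the network still gets an enrichment report", {
  fx <- load_fixture("cdc25")
  tab <- synonym_table("phantom", "NOT-IN-NET", 1.0)
  expect_warning(rep <- run_analysis(fx$network, fx$collection, "phantom", tab),
                 "not.*in the network|no resolved query")
  expect_length(rep$neighbors, 0)
  expect_equal(rep$displayed, "NOT-IN-NET")
  expect_equal(unique(rep$enrichment$n), 1L)
})

test_that("drug queries reproduce the direct protein query", {
  fx <- load_fixture("gja1")
  via_drug <- run_analysis(fx$network, fx$collection, "methotrexate",
                           fx$synonyms, drugs = fx$drugs)
  direct <- run_analysis(fx$network, fx$collection, "gja1", fx$synonyms)
  expect_identical(via_drug$displayed, direct$displayed)
  expect_identical(via_drug$enrichment, direct$enrichment)
})

test_that("stage errors carry their stage tag", {
  fx <- load_fixture("cdc25")
  tab <- synonym_table("x", "P1", 1.0)
  expect_error(suppressWarnings(
    run_analysis(fx$network, fx$collection, "ghost", tab)),
    "\\[resolve\\]", class = "pn_data_error")
})
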