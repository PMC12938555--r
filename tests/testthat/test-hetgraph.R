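chainGraph <- function() {
  HetGraph(
    nodes = data.frame(node_id = c("d1", "t1"),
                       node_type = c("DSYN", "TARGET")),
    edges = data.frame(source_id = "d1", predicate = "affects",
                       target_id = "t1"))
}

test_that("metapath enumeration finds the single pattern of a one-relation schema", {
  g <- chainGraph()
  mp <- enumerateMetapaths(g, "DSYN", "t1", max_length = 3)
  expect_length(mp, 1L)
  expect_identical(mp[[1]]@nodeTypes, c("DSYN", "TARGET"))
  expect_identical(mp[[1]]@predicates, "affects")
})

test_that("metapath enumeration of an empty edge set is empty", {
  g <- HetGraph(nodes = data.frame(node_id = c("d1", "t1"),
                                   node_type = c("DSYN", "TARGET")))
  expect_length(enumerateMetapaths(g, "DSYN", "t1", 3), 0L)
})

test_that("enumeration errors name unknown identifiers", {
  g <- chainGraph()
  expect_error(enumerateMetapaths(g, "DSYN", "nope", 3), "nope")
  expect_error(enumerateMetapaths(g, "XXXX", "t1", 3), "XXXX")
})

test_that("pattern count matches brute-force typed-walk enumeration", {
  # 3-type schema with two predicates; count all typed walks <= 3 edges by
  # exhaustively extending schema triples.
  g <- generateToyGraph(n_per_type = 3, relation_density = 1, seed = 1)
  mp <- enumerateMetapaths(g, "DSYN", "T01", max_length = 3)
  schema <- unique(data.frame(
    s = c("DSYN", "AAPP", "AAPP"),
    p = c("affects", "interacts", "affects"),
    t = c("AAPP", "AAPP", "TARGET")))
  walks <- 0
  for (i in seq_len(nrow(schema))) {
    if (schema$s[i] != "DSYN") next
    if (schema$t[i] == "TARGET") walks <- walks + 1
    for (j in seq_len(nrow(schema))) {
      if (schema$t[i] != schema$s[j]) next
      if (schema$t[j] == "TARGET") walks <- walks + 1
      for (k in seq_len(nrow(schema))) {
        if (schema$t[j] != schema$s[k]) next
        if (schema$t[k] == "TARGET") walks <- walks + 1
      }
    }
  }
  expect_length(mp, walks)
  # deterministic lexicographic order on the (type, predicate) step sequence
  keys <- vapply(mp, function(p)
    paste(rbind(p@nodeTypes, c(p@predicates, "")), collapse = " "),
    character(1))
  expect_identical(keys, sort(keys, method = "radix"))
})

test_that("hetesim is 1 on a unique chain and 0 with no connecting instance", {
  g <- HetGraph(
    nodes = data.frame(node_id = c("s", "a", "t", "s2"),
                       node_type = c("DSYN", "AAPP", "TARGET", "DSYN")),
    edges = data.frame(source_id = c("s", "a"),
                       predicate = "affects",
                       target_id = c("a", "t")))
  p <- enumerateMetapaths(g, "DSYN", "t", 3)[[1]]
  expect_equal(hetesimPath(g, "s", "t", p), 1.0)
  expect_equal(hetesimPath(g, "s2", "t", p), 0.0)  # s2 dangles
})

test_that("hetesim equals the brute-force path-instance oracle within 1e-9", {
  for (s in 1:25) {
    g <- generateToyGraph(n_per_type = 2 + (s %% 2),
                          relation_density = 0.3 + 0.05 * (s %% 10),
                          seed = s)
    nd <- graphNodes(g)
    tid <- nd$node_id[nd$node_type == "TARGET"][1]
    mps <- enumerateMetapaths(g, "DSYN", tid, 3)
    for (p in mps) for (src in nd$node_id[nd$node_type == "DSYN"]) {
      expect_equal(hetesimPath(g, src, tid, p),
                   oracleHetesim(g, src, tid, p), tolerance = 1e-9)
    }
  }
})

test_that("hetesim is symmetric under path reversal with source/target swap", {
  for (s in 1:25) {
    g <- generateToyGraph(3, 0.5 + 0.02 * s, seed = 100 + s)
    gr <- reverseGraph(g)
    nd <- graphNodes(g)
    tid <- nd$node_id[nd$node_type == "TARGET"][1]
    for (p in enumerateMetapaths(g, "DSYN", tid, 3))
      for (src in nd$node_id[nd$node_type == "DSYN"])
        expect_equal(hetesimPath(g, src, tid, p),
                     hetesimPath(gr, tid, src, reverseMetapath(p)),
                     tolerance = 1e-12)
  }
})

test_that("score aggregation is the arithmetic mean, 0 with warning when empty", {
  expect_equal(aggregateScores(0.5), 0.5)
  expect_equal(aggregateScores(c(0.2, 0.4, 0.6)), 0.4)
  x <- withr::with_seed(5, runif(10))
  expect_equal(aggregateScores(x), sum(x) / 10)
  expect_true(aggregateScores(x) >= min(x) && aggregateScores(x) <= max(x))
  expect_warning(z <- aggregateScores(numeric()), "unreachable")
  expect_equal(z, 0)
})

test_that("rankNodes produces a normalized table from graph relevance", {
  g <- generateToyGraph(3, 1, seed = 2)
  tb <- rankNodes(g, "T01", "DSYN")
  expect_s4_class(tb, "RankedNodeTable")
  st <- scoreTable(tb)
  expect_setequal(st$node_id, c("S01", "S02", "S03"))
  expect_true(all(st$raw_score >= 0 & st$raw_score <= 1))
})

test_that("edge-list round trip preserves the graph", {
  g <- generateToyGraph(2, 1, seed = 3)
  ed <- graphEdges(g)
  nd <- graphNodes(g)
  ty <- setNames(nd$node_type, nd$node_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(source_id = ed$source_id,
                         source_type = ty[ed$source_id],
                         predicate = ed$predicate,
                         target_id = ed$target_id,
                         target_type = ty[ed$target_id]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- readHetGraph(path)
  expect_setequal(paste(graphEdges(g2)$source_id, graphEdges(g2)$target_id),
                  paste(ed$source_id, ed$target_id))
})

test_that("normalization standardizes, percentiles by mid-rank, handles ties", {
  # hand-computed mid-rank case
  nz <- normalizeScores(c(1, 2, 2, 3))
  expect_equal(nz$percentile, c(0.25, 0.625, 0.625, 1.0))
  # constant input: all standardized 0, full-tie mid-rank percentile
  nz <- normalizeScores(rep(4, 5))
  expect_equal(nz$standardized, rep(0, 5))
  expect_equal(nz$percentile, rep(0.6, 5))
  # strictly increasing input: strictly increasing percentiles, max 1
  nz <- normalizeScores(c(0.1, 0.3, 0.7, 0.9))
  expect_true(all(diff(nz$percentile) > 0))
  expect_equal(max(nz$percentile), 1.0)
  # moments for non-constant input
  x <- withr::with_seed(9, rnorm(50))
  nz <- normalizeScores(x)
  expect_lt(abs(mean(nz$standardized)), 1e-9)
  expect_lt(abs(var(nz$standardized) - 1), 1e-9)
  # re-normalizing the percentiles preserves their ordering
  nz2 <- normalizeScores(nz$percentile)
  expect_identical(order(nz2$percentile), order(nz$percentile))
})
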