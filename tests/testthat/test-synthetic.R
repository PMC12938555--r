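test_that("the generator is deterministic under a fixed seed", {
  cfg <- syntheticConfig(n_nodes = 300L)
  g1 <- generateDiseaseTables(cfg, seed = 99)
  g2 <- generateDiseaseTables(cfg, seed = 99)
  for (d in names(g1$tables))
    expect_identical(scoreTable(g1$tables[[d]]), scoreTable(g2$tables[[d]]))
  expect_identical(mappingEntries(g1$mapping), mappingEntries(g2$mapping))
  g3 <- generateDiseaseTables(cfg, seed = 100)
  expect_false(identical(scoreTable(g1$tables[[1]]),
                         scoreTable(g3$tables[[1]])))
})

test_that("zero overlap gives pairwise-disjoint tables and empty intersections", {
  cfg <- syntheticConfig(n_nodes = 200L, overlap_fraction = 0)
  gen <- generateDiseaseTables(cfg, seed = 5)
  ids <- lapply(gen$tables, function(t) scoreTable(t)$node_id)
  expect_length(intersect(ids[[1]], ids[[2]]), 0L)
  expect_length(intersect(ids[[1]], ids[[3]]), 0L)
  expect_length(intersect(ids[[2]], ids[[3]]), 0L)
  prof <- buildIntersection(gen$tables[[1]], gen$tables[[2]], gen$mapping)
  expect_equal(nrow(memberTable(prof)), 0L)
})

test_that("degenerate generator configs are rejected", {
  expect_error(syntheticConfig(n_nodes = 0), "n_nodes")
  expect_error(syntheticConfig(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(syntheticConfig(shared_core_boost = 0), "boost")
})

test_that("pairwise overlap matches the sharing rule's closed-form Jaccard", {
  # Each slot is shared with prob p from a pool of n ids, so
  # E|A∩B| ≈ p^2 n and E[Jaccard] ≈ p^2 / (2 - p^2).
  p <- 0.3
  cfg <- syntheticConfig(n_nodes = 1000L, overlap_fraction = p)
  expected <- p^2 / (2 - p^2)
  jac <- vapply(1:50, function(s) {
    gen <- generateDiseaseTables(cfg, seed = 1000 + s)
    a <- scoreTable(gen$tables[[1]])$node_id
    b <- scoreTable(gen$tables[[2]])$node_id
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  expect_lt(abs(mean(jac) - expected), 0.05)
})

test_that("generated category frequencies follow the configured profiles", {
  # pure-profile tables (no shared core) vs chi-square goodness of fit
  cfg <- syntheticConfig(n_nodes = 5000L, overlap_fraction = 0)
  pass <- vapply(1:20, function(s) {
    gen <- generateDiseaseTables(cfg, seed = 2000 + s)
    ok <- TRUE
    for (d in colnames(cfg$profiles)) {
      ann <- categorizeTable(gen$tables[[d]], gen$mapping)
      obs <- table(factor(ann$category, levels = dsynCategories()))
      prob <- cfg$profiles[, d] / sum(cfg$profiles[, d])
      ok <- ok && stats::chisq.test(obs, p = prob)$p.value > 0.01
    }
    ok
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("generated scores satisfy the normalization invariants", {
  gen <- generateDiseaseTables(syntheticConfig(n_nodes = 400L), seed = 6)
  for (t in gen$tables) {
    expect_true(validObject(t))
    st <- scoreTable(t)
    expect_true(all(st$raw_score >= 0 & st$raw_score <= 1))
    expect_lt(abs(mean(st$standardized_score)), 1e-9)
    expect_lt(abs(var(st$standardized_score) - 1), 1e-9)
  }
})

test_that("boosting the shared core raises the planted intersection share", {
  planted <- c("Metabolic", "Immune/Inflammatory/Infectious")
  mean_share <- vapply(c(1, 2, 5), function(boost) {
    cfg <- syntheticConfig(n_nodes = 1000L, shared_core_boost = boost,
                           score_shift = 0.05)
    share <- vapply(1:5, function(s) {
      gen <- generateDiseaseTables(cfg, seed = 3000 + s)
      res <- suppressWarnings(analyzeTables(gen$tables, gen$mapping))
      mean(vapply(res$intersections, function(p) {
        pct <- categoryPercents(p)
        if (!length(pct)) return(NA_real_)
        sum(pct[planted])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean(share)
  }, numeric(1))
  expect_true(all(diff(mean_share) > 0))
})

test_that("toy graphs respect density limits and the declared schema", {
  g1 <- generateToyGraph(1, 1, seed = 1)
  mp <- enumerateMetapaths(g1, "DSYN", "T01", 3)
  expect_gte(length(mp), 1L)
  expect_equal(hetesimPath(g1, "S01", "T01", mp[[1]]), 1.0)
  # deterministic under seed
  g2 <- generateToyGraph(3, 0.5, seed = 9)
  g3 <- generateToyGraph(3, 0.5, seed = 9)
  expect_identical(graphEdges(g2), graphEdges(g3))
  expect_setequal(unique(graphNodes(g2)$node_type),
                  c("DSYN", "AAPP", "TARGET"))
})

test_that("recovery suite outputs are reproducible and the null sits at chance", {
  cfg <- syntheticConfig(n_nodes = 500L)
  s1 <- suppressWarnings(plantedRecoverySuite(cfg, n_replicates = 3,
                                              seed = 42))
  s2 <- suppressWarnings(plantedRecoverySuite(cfg, n_replicates = 3,
                                              seed = 42))
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$planted_order, c("AD&FTD", "AD&ALS", "ALS&FTD"))

  # no planting (boost 1, no score shift): top-3 recovery must not exceed
  # the permutation-of-labels chance baseline by more than noise
  null_cfg <- syntheticConfig(n_nodes = 500L, shared_core_boost = 1,
                              score_shift = 0)
  s_null <- suppressWarnings(
    plantedRecoverySuite(null_cfg, n_replicates = 15, seed = 11))
  s_perm <- suppressWarnings(
    plantedRecoverySuite(null_cfg, n_replicates = 15, seed = 11,
                         permute_labels = TRUE))
  expect_lte(s_null$core_top3_rate, s_perm$core_top3_rate + 0.2)
  expect_lt(s_null$core_top3_rate, 0.5)
})
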