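test_that("harmonic mean matches hand arithmetic and the zero convention", {
  expect_equal(harmonicMean(0.6, 0.6), 0.6)
  expect_equal(harmonicMean(0, 0.9), 0)
  expect_equal(harmonicMean(0.4, 0.8), 2 / (1 / 0.4 + 1 / 0.8))
  expect_equal(harmonicMean(0.4, 0.8), 0.5333333333, tolerance = 1e-9)
  expect_error(harmonicMean(1.2, 0.5), "\\[0, 1\\]")
})

test_that("harmonic mean is bounded by min, max and the arithmetic mean", {
  pairs <- withr::with_seed(3, matrix(runif(2000), ncol = 2))
  hm <- harmonicMean(pairs[, 1], pairs[, 2])
  expect_true(all(hm >= pmin(pairs[, 1], pairs[, 2]) - 1e-12))
  expect_true(all(hm <= pmax(pairs[, 1], pairs[, 2]) + 1e-12))
  am <- rowMeans(pairs)
  expect_true(all(hm <= am + 1e-12))
  eq <- abs(pairs[, 1] - pairs[, 2]) < 1e-12
  expect_true(all(abs(hm[!eq] - am[!eq]) > 0))
})

interFixture <- function() {
  # 6 shared nodes with the worked score pairs plus one node only in A
  idsA <- c(sprintf("S%d", 1:6), "onlyA")
  idsB <- sprintf("S%d", 1:6)
  h1 <- c(0.9, 0.8, 0.6, 0.5, 0.45, 1.0, 0.2)
  h2 <- c(0.9, 0.2, 0.7, 0.5, 0.55, 0.3)
  mapping <- CategoryMapping(c(idsA, "extra"),
                             rep(c("Metabolic", "Liver"), length.out = 8))
  # tables whose *raw* scores are already in [0,1]; use raw channel so the
  # worked HM values apply exactly
  ta <- RankedNodeTable("A", idsA, raw_score = h1)
  tb <- RankedNodeTable("B", idsB, raw_score = h2)
  list(ta = ta, tb = tb, mapping = mapping, h1 = h1[1:6], h2 = h2)
}

test_that("intersection membership is exactly the HM >= threshold set, boundary inclusive", {
  f <- interFixture()
  prof <- buildIntersection(f$ta, f$tb, f$mapping, threshold = 0.5,
                            channel = "raw")
  hm <- harmonicMean(f$h1, f$h2)
  expected <- sprintf("S%d", which(hm >= 0.5))
  expect_setequal(memberTable(prof)$node_id, expected)
  # the (0.5, 0.5) pair sits exactly at the threshold and is included
  expect_true("S4" %in% memberTable(prof)$node_id)
  # counts sum to member count; percentages sum to 100
  expect_equal(sum(categoryCounts(prof)), nrow(memberTable(prof)))
  expect_equal(sum(categoryPercents(prof)), 100)
})

test_that("disjoint node sets give an empty profile", {
  m <- CategoryMapping(c("x1", "y1"), c("Metabolic", "Liver"))
  ta <- RankedNodeTable("A", "x1", raw_score = 0.9)
  tb <- RankedNodeTable("B", "y1", raw_score = 0.9)
  prof <- buildIntersection(ta, tb, m, channel = "raw")
  expect_equal(nrow(memberTable(prof)), 0L)
  expect_equal(sum(categoryCounts(prof)), 0L)
  expect_length(categoryPercents(prof), 0L)
})

test_that("raising the threshold never adds members", {
  f <- interFixture()
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(memberTable(buildIntersection(f$ta, f$tb, f$mapping,
                                       threshold = th, channel = "raw"))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("un-normalized score channels are rejected", {
  m <- CategoryMapping("x1", "Metabolic")
  ta <- RankedNodeTable("A", c("x1", "x2"), raw_score = c(0.5, 7))
  tb <- RankedNodeTable("B", c("x1", "x2"), raw_score = c(0.5, 0.6))
  expect_error(buildIntersection(ta, tb, m, channel = "raw"), "normalized")
  expect_error(buildIntersection(ta, tb, m, channel = "standardized"),
               "normalized")
})

test_that("category percentages normalize counts to 100", {
  counts <- setNames(integer(13), dsynCategories())
  counts[1:2] <- c(2L, 2L)
  pct <- categoryPercentages(counts)
  expect_equal(unname(pct[1:2]), c(50, 50))
  counts[] <- 0L; counts[5] <- 3L
  expect_equal(unname(categoryPercentages(counts)[5]), 100)
  counts[] <- 0L; counts[1:3] <- c(3L, 2L, 1L)
  expect_equal(unname(categoryPercentages(counts)[1:3]),
               c(50, 100 / 3, 100 / 6))
  counts[] <- 0L
  expect_length(categoryPercentages(counts), 0L)
})

test_that("Z enrichment matches the one-sample proportion formula", {
  cats <- dsynCategories()
  p0 <- setNames(c(0.25, 0.25, 0.5, rep(0, 10)), cats)
  baseline <- new("GlobalBaseline", proportions = p0, total = 100L,
                  mode = "union")
  counts <- setNames(c(5L, 0L, 5L, rep(0L, 10)), cats)
  z <- zEnrichment(counts, baseline)
  expect_equal(unname(z[1]), 2.5 / sqrt(10 * 0.25 * 0.75))
  expect_equal(unname(z[1]), 1.8257419, tolerance = 1e-6)
  expect_equal(unname(z[2]), -1.8257419, tolerance = 1e-6)
  # composition exactly proportional to the baseline -> all zero
  counts2 <- setNames(c(5L, 5L, 10L, rep(0L, 10)), cats)
  expect_true(all(abs(zEnrichment(counts2, baseline)) < 1e-9))
})

test_that("degenerate baseline proportions are flagged, consistent ones are 0", {
  cats <- dsynCategories()
  p0 <- setNames(c(1, rep(0, 12)), cats)
  baseline <- new("GlobalBaseline", proportions = p0, total = 10L,
                  mode = "union")
  counts <- setNames(c(10L, rep(0L, 12)), cats)
  expect_true(all(zEnrichment(counts, baseline) == 0))
  counts <- setNames(c(9L, 1L, rep(0L, 11)), cats)
  # two degenerate cells (p0 = 1 with k < n, p0 = 0 with k > 0) each warn
  w <- capture_warnings(z <- zEnrichment(counts, baseline))
  expect_match(w, "degenerate", all = TRUE)
  expect_length(w, 2L)
  expect_identical(unname(z[1]), -Inf)
  expect_identical(unname(z[2]), Inf)
})

test_that("n p0-weighted numerators cancel when counts define their own baseline", {
  counts <- withr::with_seed(8, setNames(as.integer(rmultinom(1, 200,
    prob = runif(13))), dsynCategories()))
  p0 <- counts / sum(counts)
  expect_lt(abs(sum(counts - sum(counts) * p0)), 1e-9)
})

test_that("permutation-null enrichment agrees in sign with the binomial form", {
  cats <- dsynCategories()
  withr::with_seed(21, {
    for (i in 1:10) {
      p0 <- runif(13, 0.2, 1)
      p0 <- setNames(p0 / sum(p0), cats)
      baseline <- new("GlobalBaseline", proportions = p0, total = 500L,
                      mode = "union")
      counts <- setNames(as.integer(rmultinom(1, 80, sample(p0))), cats)
      zb <- zEnrichment(counts, baseline)
      zp <- zEnrichmentPermutation(counts, baseline, n_draws = 2000,
                                   seed = i)
      big <- abs(zb) > 0.5  # sign is only meaningful away from zero
      expect_true(all(sign(zb[big]) == sign(zp[big])))
    }
  })
})

test_that("Venn regions partition the union for all inputs", {
  expect_equal(unname(overlapPartition(letters[1:4], letters[1:4],
                                       letters[1:4])),
               c(0L, 0L, 0L, 0L, 0L, 0L, 4L))
  expect_equal(unname(overlapPartition(c("a", "b"), c("c", "d", "e"),
                                       c("f", "g", "h", "i"))),
               c(2L, 3L, 4L, 0L, 0L, 0L, 0L))
  withr::with_seed(4, {
    for (i in 1:20) {
      A <- sample(letters, sample(5:15, 1))
      B <- sample(letters, sample(5:15, 1))
      C <- sample(letters, sample(5:15, 1))
      reg <- overlapPartition(A, B, C)
      expect_equal(sum(reg), length(union(union(A, B), C)))
      # brute-force region classification
      u <- union(union(A, B), C)
      key <- paste0(as.integer(u %in% A), as.integer(u %in% B),
                    as.integer(u %in% C))
      brute <- c(sum(key == "100"), sum(key == "010"), sum(key == "001"),
                 sum(key == "110"), sum(key == "101"), sum(key == "011"),
                 sum(key == "111"))
      expect_equal(unname(reg), brute)
    }
  })
})
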