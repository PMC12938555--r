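test_that("category aggregation matches independent per-category summation", {
  cats <- dsynCategories()
  ann <- data.frame(category = cats, percentile = seq(0.1, 1.3, by = 0.1))
  agg <- aggregateByCategory(ann)
  expect_equal(unname(agg), seq(0.1, 1.3, by = 0.1))
  ann2 <- data.frame(category = rep("Metabolic", 2),
                     percentile = c(0.4, 0.6))
  expect_equal(unname(aggregateByCategory(ann2)["Metabolic"]), 1.0)
  # 30-node fixture against a direct tapply oracle
  fx <- makeAnnotatedFixture(30, seed = 2)
  agg <- aggregateByCategory(fx)
  for (cc in cats)
    expect_equal(unname(agg[cc]),
                 sum(fx$percentile[fx$category == cc]))
  # empty categories aggregate to 0, and mean/count modes work
  expect_equal(unname(aggregateByCategory(fx, mode = "count")),
               as.numeric(table(factor(fx$category, levels = cats))))
})

test_that("rank 1 goes to the largest score with canonical tie-breaking", {
  cats <- dsynCategories()
  sc <- setNames(13:1, cats)
  expect_equal(unname(rankCategories(sc)), 1:13)
  expect_equal(unname(rankCategories(setNames(1:13, cats))), 13:1)
  sc <- setNames(c(5, 5, rep(1, 11)), cats)
  r <- rankCategories(sc)
  expect_equal(unname(r[1:2]), c(1L, 2L))  # tie broken by canonical order
  expect_setequal(r, 1:13)
})

test_that("hierarchy construction is invariant to input row order", {
  fx <- makeAnnotatedFixture(40, seed = 3)
  h1 <- categoryHierarchy(fx, "X")
  h2 <- categoryHierarchy(fx[sample(nrow(fx)), ], "X")
  expect_identical(categoryRanks(h1), categoryRanks(h2))
})

test_that("spearman matches the closed form and the Pearson-of-ranks oracle", {
  expect_equal(spearmanRho(1:4, 1:4), 1.0)
  expect_equal(spearmanRho(1:4, 4:1), -1.0)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  withr::with_seed(11, {
    for (i in 1:100) {
      a <- randomPermutation(13)
      b <- randomPermutation(13)
      expect_equal(spearmanRho(a, b), oracleSpearmanClosedForm(a, b),
                   tolerance = 1e-12)
      expect_equal(spearmanRho(a, b), oraclePearsonOfRanks(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("kendall matches exhaustive pair enumeration", {
  expect_equal(kendallTau(1:4, 1:4), 1.0)
  expect_equal(kendallTau(1:4, 4:1), -1.0)
  expect_equal(kendallTau(c(1, 2, 3, 4), c(1, 2, 4, 3)), 4 / 6,
               tolerance = 1e-12)
  withr::with_seed(12, {
    for (i in 1:100) {
      a <- randomPermutation(13)
      b <- randomPermutation(13)
      expect_equal(kendallTau(a, b), oracleKendallPairs(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("spearman and kendall agree in sign on tie-free permutations", {
  withr::with_seed(13, {
    for (i in 1:100) {
      a <- randomPermutation(13)
      b <- randomPermutation(13)
      s <- spearmanRho(a, b)
      k <- kendallTau(a, b)
      if (abs(s) > 0.1)  # identical sign away from the origin
        expect_equal(sign(s), sign(k))
    }
  })
})

test_that("zero-variance rank vectors are flagged undefined", {
  expect_warning(r <- spearmanRho(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(r))
})

test_that("alignment compares an intersection hierarchy to both parents", {
  cats <- dsynCategories()
  hi <- new("CategoryHierarchy", entity = "A&B", categories = cats,
            scores = as.numeric(13:1), ranks = 1:13)
  ha <- hi; ha@entity <- "A"
  hb <- new("CategoryHierarchy", entity = "B", categories = cats,
            scores = as.numeric(1:13), ranks = 13:1)
  al <- alignmentToParents(hi, ha, hb)
  expect_equal(al[["A"]][["spearman"]], 1.0)
  expect_equal(al[["B"]][["spearman"]], -1.0)
  al2 <- alignmentToParents(hi, ha, ha)
  expect_equal(unname(vapply(al2, `[[`, numeric(1), "spearman")), c(1, 1))
})

test_that("rank differences subtract elementwise and conserve to zero", {
  cats <- dsynCategories()
  mk <- function(r) new("CategoryHierarchy", entity = "e",
                        categories = cats,
                        scores = as.numeric(14 - r), ranks = as.integer(r))
  expect_true(all(rankDifferences(mk(1:13), mk(1:13)) == 0))
  d <- rankDifferences(mk(c(1, 2, 3:13)), mk(c(2, 1, 3:13)))
  expect_equal(unname(d[1:2]), c(-1L, 1L))
  withr::with_seed(14, {
    for (i in 1:50) {
      d <- rankDifferences(mk(randomPermutation(13)),
                           mk(randomPermutation(13)))
      expect_equal(sum(d), 0L)
      expect_true(all(d >= -12 & d <= 12))
    }
  })
})
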