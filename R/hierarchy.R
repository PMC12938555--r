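#' Aggregate normalized scores by ontology category
#'
#' @param annotated data.frame with a \code{category} column (output of
#'   [categorizeTable()] or the member table of an intersection).
#' @param categories category alphabet; every category gets an aggregate,
#'   empty categories aggregate to 0.
#' @param score_col name of the score column to aggregate; e.g.
#'   \code{"percentile"} for disease tables or \code{"hm"} for intersection
#'   members.
#' @param mode \code{"sum"} (default; captures both node count and
#'   strength), \code{"mean"}, or \code{"count"}.
#' @return Named numeric vector of per-category aggregates.
#' @export
aggregateByCategory <- function(annotated, categories = dsynCategories(),
                                score_col = "percentile",
                                mode = c("sum", "mean", "count")) {
  mode <- match.arg(mode)
  if (!"category" %in% names(annotated))
    morbDataStop("annotated table must have a category column")
  if (mode != "count" && !score_col %in% names(annotated))
    morbDataStop(paste0("no score column '", score_col, "' in table"))
  f <- factor(annotated$category, levels = categories)
  out <- switch(mode,
    sum = tapply(annotated[[score_col]], f, sum, default = 0),
    mean = tapply(annotated[[score_col]], f, mean, default = 0),
    count = table(f))
  out <- stats::setNames(as.numeric(out), categories)
  out[is.na(out)] <- 0
  out
}

#' Rank categories from 1 (highest importance) to K (lowest)
#'
#' Rank 1 goes to the largest aggregate; ties are broken by canonical
#' category order (the order of \code{scores}' names), so the output is
#' always a strict permutation.
#'
#' @param scores named numeric vector of category aggregates in canonical
#'   order.
#' @return Named integer vector of ranks, a permutation of 1..K.
#' @export
rankCategories <- function(scores) {
  k <- length(scores)
  o <- order(-scores, seq_len(k), method = "radix")
  r <- integer(k)
  r[o] <- seq_len(k)
  stats::setNames(r, names(scores))
}

#' Build a category hierarchy for one entity
#'
#' Convenience wrapper: [aggregateByCategory()] then [rankCategories()]
#' into a [CategoryHierarchy-class].
#'
#' @param annotated annotated table (see [aggregateByCategory()]).
#' @param entity entity label.
#' @inheritParams aggregateByCategory
#' @return A [CategoryHierarchy-class].
#' @export
categoryHierarchy <- function(annotated, entity,
                              categories = dsynCategories(),
                              score_col = "percentile", mode = "sum") {
  sc <- aggregateByCategory(annotated, categories, score_col, mode)
  new("CategoryHierarchy", entity = entity, categories = categories,
      scores = unname(sc), ranks = unname(rankCategories(sc)))
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman correlation (Pearson correlation of the rank vectors,
#' via \code{stats::cor}); for tie-free permutations this equals the
#' classical \code{1 - 6 sum(d^2) / (n (n^2 - 1))}. A zero-variance input is
#' flagged as \code{NA} with a warning rather than an error.
#'
#' @param a,b equal-length numeric vectors (ranks or scores), length >= 3.
#' @return Correlation in [-1, 1], or NA for degenerate input.
#' @export
spearmanRho <- function(a, b) {
  checkRankPair(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance rank vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Kendall rank correlation
#'
#' Concordant-minus-discordant pair statistic via \code{stats::cor(method =
#' "kendall")}, which applies the tie-adjusted (tau-b) form when ties are
#' present; for tie-free permutations this is the classical tau.
#'
#' @inheritParams spearmanRho
#' @return Correlation in [-1, 1], or NA for degenerate input.
#' @export
kendallTau <- function(a, b) {
  checkRankPair(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance rank vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "kendall")
}

checkRankPair <- function(a, b) {
  if (length(a) != length(b))
    morbDataStop("rank vectors must have equal length")
  if (length(a) < 3L)
    morbDataStop("rank correlation needs length >= 3")
  invisible(TRUE)
}

#' Rank similarity between two hierarchies
#'
#' @param a,b [CategoryHierarchy-class] objects (or named rank vectors) over
#'   the same categories.
#' @return Named numeric vector \code{c(spearman, kendall, n)}.
#' @export
rankSimilarity <- function(a, b) {
  ra <- hierarchyRanks(a)
  rb <- hierarchyRanks(b)
  if (!identical(names(ra), names(rb)))
    morbDataStop("hierarchies are over different category sets")
  c(spearman = spearmanRho(unname(ra), unname(rb)),
    kendall = kendallTau(unname(ra), unname(rb)),
    n = length(ra))
}

hierarchyRanks <- function(x) {
  if (is(x, "CategoryHierarchy")) return(categoryRanks(x))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  morbDataStop("expected a CategoryHierarchy or a named rank vector")
}

#' Intersection-to-parent alignment
#'
#' How strongly an intersection's category hierarchy tracks each parent
#' disease's hierarchy, as two [rankSimilarity()] results on equal footing.
#'
#' @param intersection a [CategoryHierarchy-class] for the intersection.
#' @param parentA,parentB hierarchies of the two parent diseases.
#' @return Named list of two similarity vectors, keyed by parent entity.
#' @export
alignmentToParents <- function(intersection, parentA, parentB) {
  out <- list(rankSimilarity(intersection, parentA),
              rankSimilarity(intersection, parentB))
  names(out) <- c(entityLabel(parentA), entityLabel(parentB))
  out
}

#' Disease-minus-intersection rank differences
#'
#' Elementwise \code{disease rank - intersection rank} per category.
#' Negative values mean the category is prioritized more within the disease
#' than in the shared-node intersection space; positive values mean it is
#' up-weighted in intersection space. For two full permutations the
#' differences always sum to zero.
#'
#' @param disease,intersection [CategoryHierarchy-class] objects (or named
#'   rank vectors) over the same categories.
#' @return Named integer vector of signed rank differences.
#' @export
rankDifferences <- function(disease, intersection) {
  rd <- hierarchyRanks(disease)
  ri <- hierarchyRanks(intersection)
  if (!identical(names(rd), names(ri)))
    morbDataStop("rank vectors are over different category sets")
  stats::setNames(as.integer(rd - ri), names(rd))
}
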