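#' Harmonic mean of two unit-interval scores
#'
#' The pairwise-intersection statistic \code{HM = 2 / (1/h1 + 1/h2)}. The
#' harmonic mean penalizes imbalance: a node strongly relevant to one
#' disease but weakly to the other scores low, so intersection membership
#' reflects balanced cross-disease relevance. If either input is 0 the HM is
#' 0 (the limit of the formula). Vectorized.
#'
#' @param h1,h2 numeric scores in [0, 1].
#' @return Harmonic means, satisfying \code{min(h1,h2) <= HM <= max(h1,h2)}
#'   and \code{HM <=} arithmetic mean.
#' @examples
#' harmonicMean(0.4, 0.8)  # 0.5333...
#' @export
harmonicMean <- function(h1, h2) {
  if (any(h1 < 0 | h1 > 1 | h2 < 0 | h2 > 1, na.rm = TRUE))
    morbDataStop("harmonicMean inputs must lie in [0, 1]")
  ifelse(h1 == 0 | h2 == 0, 0, 2 * h1 * h2 / (h1 + h2))
}

#' Build a pairwise-disease intersection profile
#'
#' Members are exactly the nodes present in both ranked tables whose
#' harmonic-mean combined score meets the threshold (inclusive, i.e.
#' \code{HM >= threshold}). Each member is annotated with its single
#' ontology category; per-category counts and within-intersection
#' percentages (summing to 100) are attached.
#'
#' @param tableA,tableB [RankedNodeTable-class] objects for the two parent
#'   diseases.
#' @param mapping a [CategoryMapping-class].
#' @param threshold HM inclusion threshold in (0, 1]; default 0.5, which for
#'   unit-interval normalized scores retains nodes with at least moderate
#'   balanced relevance to both diseases.
#' @param channel score channel fed into the HM; default
#'   \code{"percentile"} (unit interval). Channels with values outside
#'   [0, 1] are rejected.
#' @param unmapped policy for unmapped members, as in [categorizeTable()].
#' @param pairLabel label for the pair; default
#'   \code{"<entityA>&<entityB>"}.
#' @return An [IntersectionProfile-class].
#' @export
buildIntersection <- function(tableA, tableB, mapping, threshold = 0.5,
                              channel = "percentile", unmapped = "drop",
                              pairLabel = NULL) {
  stopifnot(is(tableA, "RankedNodeTable"), is(tableB, "RankedNodeTable"))
  if (threshold <= 0 || threshold > 1)
    morbConfigStop("threshold must lie in (0, 1]")
  if (is.null(pairLabel))
    pairLabel <- paste0(entityLabel(tableA), "&", entityLabel(tableB))
  sa <- scoreChannel(tableA, channel)
  sb <- scoreChannel(tableB, channel)
  if (any(sa < 0 | sa > 1) || any(sb < 0 | sb > 1))
    morbDataStop("intersection scores must be normalized to [0, 1]")
  shared <- sort(intersect(names(sa), names(sb)))
  h1 <- unname(sa[shared])
  h2 <- unname(sb[shared])
  hm <- harmonicMean(h1, h2)
  keep <- hm >= threshold
  members <- data.frame(node_id = shared[keep],
                        score_d1 = h1[keep], score_d2 = h2[keep],
                        hm = hm[keep], stringsAsFactors = FALSE)
  cat_of <- mapping@entries[members$node_id]
  miss <- is.na(cat_of)
  if (any(miss)) {
    if (unmapped == "error")
      morbStop(paste0("unmapped intersection node(s): ",
                      paste(members$node_id[miss], collapse = ", ")),
               "morbMappingError")
    if (unmapped == "bucket") {
      cat_of[miss] <- "Other/Neuro-Psych"
    } else {
      members <- members[!miss, , drop = FALSE]
      cat_of <- cat_of[!miss]
    }
  }
  members$category <- unname(cat_of)
  members <- members[, c("node_id", "category", "score_d1", "score_d2", "hm")]
  rownames(members) <- NULL
  counts <- countByCategory(members$category, mapping@categories)
  pct <- if (sum(counts) > 0) categoryPercentages(counts) else
    stats::setNames(numeric(), character())
  new("IntersectionProfile", pairLabel = pairLabel, members = members,
      counts = counts, percentages = pct, z = numeric(),
      threshold = threshold)
}

countByCategory <- function(category, alphabet) {
  stats::setNames(
    as.integer(table(factor(category, levels = alphabet))), alphabet)
}

#' Within-intersection category percentages
#'
#' Normalizes category counts to percentages summing to 100. All-zero counts
#' signal an empty profile: an empty named numeric vector is returned rather
#' than numbers.
#'
#' @param counts named integer vector of category counts.
#' @return Named numeric percentages (or empty vector for an empty profile).
#' @export
categoryPercentages <- function(counts) {
  total <- sum(counts)
  if (total == 0L) return(stats::setNames(numeric(), character()))
  100 * counts / total
}

#' Global category baseline across diseases
#'
#' The category distribution of the pooled high-importance nodes of all
#' diseases, used as the null for intersection enrichment. In \code{union}
#' mode (default) each node is counted once even when shared between
#' diseases; \code{concat} counts a node once per disease it appears in.
#'
#' @param tables list of [RankedNodeTable-class] objects.
#' @param mapping a [CategoryMapping-class].
#' @param q high-importance top fraction per disease (default 0.10).
#' @param mode \code{"union"} or \code{"concat"}.
#' @return A [GlobalBaseline-class].
#' @export
globalBaseline <- function(tables, mapping, q = 0.10,
                           mode = c("union", "concat")) {
  mode <- match.arg(mode)
  ids <- lapply(tables, highImportance, q = q)
  pooled <- if (mode == "union") unique(unlist(ids)) else unlist(ids)
  cat_of <- mapping@entries[pooled]
  cat_of <- cat_of[!is.na(cat_of)]
  if (length(cat_of) == 0L)
    morbDataStop("no mapped high-importance nodes; cannot form a baseline")
  counts <- countByCategory(cat_of, mapping@categories)
  new("GlobalBaseline", proportions = counts / sum(counts),
      total = as.integer(sum(counts)), mode = mode)
}

#' Z-score category enrichment against a global baseline
#'
#' One-sample proportion Z statistic per category:
#' \code{z = (k - n p0) / sqrt(n p0 (1 - p0))} with \code{k} the category's
#' intersection count, \code{n} the intersection size and \code{p0} the
#' baseline proportion. Positive values mean over-representation in the
#' intersection. Degenerate baselines: \code{p0 = 0} with \code{k > 0}
#' yields \code{+Inf} with a warning (and \code{p0 = 1} with \code{k < n}
#' yields \code{-Inf}); a consistent degenerate baseline yields 0.
#'
#' @param counts named integer vector of intersection category counts.
#' @param baseline a [GlobalBaseline-class] (or a named proportion vector).
#' @return Named numeric vector of signed enrichment values.
#' @export
zEnrichment <- function(counts, baseline) {
  p0 <- if (is(baseline, "GlobalBaseline")) baseline@proportions else baseline
  if (!identical(names(counts), names(p0)))
    p0 <- p0[names(counts)]
  if (anyNA(p0)) morbDataStop("baseline does not cover all categories")
  n <- sum(counts)
  if (n < 1L) morbDataStop("cannot compute enrichment for an empty profile")
  z <- numeric(length(counts))
  names(z) <- names(counts)
  ok <- p0 > 0 & p0 < 1
  z[ok] <- (counts[ok] - n * p0[ok]) / sqrt(n * p0[ok] * (1 - p0[ok]))
  deg <- which(!ok)
  for (i in deg) {
    k <- counts[i]
    if ((p0[i] == 0 && k == 0) || (p0[i] == 1 && k == n)) {
      z[i] <- 0
    } else {
      z[i] <- if (p0[i] == 0) Inf else -Inf
      warning("category '", names(counts)[i],
              "' inconsistent with a degenerate baseline proportion; ",
              "enrichment flagged as ", z[i])
    }
  }
  z
}

#' Permutation-null category enrichment
#'
#' Sensitivity alternative to the binomial-null [zEnrichment()]: draws
#' \code{n} nodes from the baseline category distribution \code{n_draws}
#' times and standardizes each observed count against the resampled mean
#' and standard deviation. Seeded and deterministic.
#'
#' @param counts named integer vector of intersection category counts.
#' @param baseline a [GlobalBaseline-class].
#' @param n_draws number of resampling draws (default 10000).
#' @param seed RNG seed.
#' @return Named numeric vector of permutation Z values.
#' @export
zEnrichmentPermutation <- function(counts, baseline, n_draws = 10000,
                                   seed = 1L) {
  p0 <- baseline@proportions[names(counts)]
  n <- sum(counts)
  if (n < 1L) morbDataStop("cannot compute enrichment for an empty profile")
  draws <- withSeed(seed, stats::rmultinom(n_draws, size = n, prob = p0))
  mu <- rowMeans(draws)
  sdev <- apply(draws, 1L, stats::sd)
  z <- ifelse(sdev > 0, (counts - mu) / sdev,
              ifelse(counts == mu, 0, sign(counts - mu) * Inf))
  stats::setNames(as.numeric(z), names(counts))
}

#' Attach enrichment values to an intersection profile
#'
#' @param profile an [IntersectionProfile-class].
#' @param baseline a [GlobalBaseline-class].
#' @param formula \code{"binomial"} (default) or \code{"permutation"}.
#' @param ... passed to [zEnrichmentPermutation()] when applicable.
#' @return The profile with its \code{z} slot filled.
#' @export
enrichProfile <- function(profile, baseline,
                          formula = c("binomial", "permutation"), ...) {
  formula <- match.arg(formula)
  if (sum(profile@counts) == 0L) return(profile)
  profile@z <- if (formula == "binomial")
    zEnrichment(profile@counts, baseline)
  else zEnrichmentPermutation(profile@counts, baseline, ...)
  profile
}

#' Three-set Venn overlap partition
#'
#' Classifies the union of three node-id sets into the 7 disjoint Venn
#' regions (three exclusive, three pairwise-only, one triple). Region counts
#' always partition the union.
#'
#' @param setA,setB,setC character vectors of node ids.
#' @param labels entity labels used in the region names.
#' @return Named integer vector of 7 region counts.
#' @export
overlapPartition <- function(setA, setB, setC,
                             labels = c("A", "B", "C")) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  u <- unique(c(setA, setB, setC))
  inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
  regions <- c(sum(inA & !inB & !inC),
               sum(!inA & inB & !inC),
               sum(!inA & !inB & inC),
               sum(inA & inB & !inC),
               sum(inA & !inB & inC),
               sum(!inA & inB & inC),
               sum(inA & inB & inC))
  names(regions) <- c(labels,
                      paste(labels[c(1, 1, 2)], labels[c(2, 3, 3)],
                            sep = "&"),
                      paste(labels, collapse = "&"))
  stats::setNames(as.integer(regions), names(regions))
}
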