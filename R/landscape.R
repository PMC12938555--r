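#' Rank-based priority score
#'
#' The landscape's rank-preserving transform \code{15 - rank}, mapping rank
#' 1 (highest importance) to priority 14 and rank 13 to priority 2.
#' Vectorized; out-of-range ranks are an error.
#'
#' @param rank integer rank(s) in 1..13.
#' @return Integer priority score(s).
#' @export
priorityScore <- function(rank) {
  if (any(rank < 1 | rank > 13 | rank != as.integer(rank)))
    morbDataStop("ranks must be integers in 1..13")
  as.integer(15 - rank)
}

#' Borda aggregation of per-disease category ranks
#'
#' Orders categories by the sum of their disease-specific ranks (ascending;
#' a lower sum means higher shared importance). Rank-sum ties are broken by
#' lower median rank, then lower minimum rank; any residual tie falls back
#' to canonical category order and is flagged in the tie trace. The result
#' is a strict permutation of 1..K.
#'
#' @param rank_matrix integer matrix, categories x diseases (typically
#'   13 x 3), rownames the category labels; every column must be a
#'   permutation of 1..K.
#' @return A [BordaResult-class].
#' @examples
#' m <- cbind(AD = c(1, 2, 3), ALS = c(2, 1, 3), FTD = c(1, 3, 2))
#' rownames(m) <- c("a", "b", "c")
#' integrativeRanking(bordaAggregate(m))
#' @export
bordaAggregate <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  k <- nrow(rank_matrix)
  if (is.null(rownames(rank_matrix)))
    morbDataStop("rank_matrix must have category rownames")
  for (j in seq_len(ncol(rank_matrix)))
    if (!isPermutation(rank_matrix[, j], k))
      morbDataStop(paste0("column ", j, " is not a permutation of 1..", k))
  cats <- rownames(rank_matrix)
  s <- rowSums(rank_matrix)
  med <- apply(rank_matrix, 1L, stats::median)
  mn <- apply(rank_matrix, 1L, min)
  o <- order(s, med, mn, seq_len(k), method = "radix")
  integrative <- integer(k)
  integrative[o] <- seq_len(k)

  # trace which rule separated the members of each rank-sum tie
  trace <- list()
  for (sv in unique(s[duplicated(s)])) {
    g <- which(s == sv)
    for (i in g) {
      others <- setdiff(g, i)
      rule <- if (!any(med[others] == med[i])) "median"
      else if (!any(med[others] == med[i] & mn[others] == mn[i])) "minimum"
      else "canonical"
      trace[[length(trace) + 1L]] <- data.frame(
        category = cats[i], rank_sum = sv, resolved_by = rule,
        stringsAsFactors = FALSE)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(category = character(), rank_sum = numeric(),
               resolved_by = character(), stringsAsFactors = FALSE)
  if (any(trace$resolved_by == "canonical"))
    warning("residual Borda tie(s) resolved by canonical category order")
  new("BordaResult", categories = cats, rankSum = unname(s),
      integrativeRank = integrative, tieTrace = trace)
}

#' Assemble the integrated priority landscape
#'
#' Collects the category hierarchies of several entities (three diseases and
#' their three pairwise intersections, in the standard analysis) into one
#' rank matrix plus its \code{15 - rank} priority transform. No averaging
#' across entities is performed: each row stays an ordinal permutation, so
#' every row of the priority matrix sums to the same constant (104 for 13
#' categories).
#'
#' @param hierarchies list of [CategoryHierarchy-class] objects over the
#'   same category alphabet.
#' @return A [PriorityLandscape-class].
#' @export
buildLandscape <- function(hierarchies) {
  if (length(hierarchies) == 0L)
    morbDataStop("no hierarchies supplied")
  cats <- hierarchies[[1L]]@categories
  for (h in hierarchies)
    if (!identical(h@categories, cats))
      morbDataStop(paste0("hierarchy for ", h@entity,
                          " uses a different category set"))
  entities <- vapply(hierarchies, entityLabel, character(1))
  if (anyDuplicated(entities))
    morbDataStop("entity labels must be unique")
  ranks <- do.call(rbind, lapply(hierarchies, function(h) h@ranks))
  new("PriorityLandscape", entities = entities, categories = cats,
      ranks = ranks, priorities = 15 - ranks)
}

#' Reference per-disease category rank matrix
#'
#' The printed 13 x 3 matrix of category ranks for Alzheimer's disease (AD),
#' amyotrophic lateral sclerosis (ALS) and frontotemporal dementia (FTD)
#' that ships with the package, together with its integrative Borda column.
#' Used in the worked examples and as the fixture for checking that
#' [bordaAggregate()] reproduces the printed integrative ordering,
#' including the Gastrointestinal/Endocrine rank-sum tie resolved by the
#' median rule.
#'
#' @return A list with \code{ranks} (13 x 3 integer matrix, rownames the
#'   canonical categories, columns AD/ALS/FTD) and \code{integrative}
#'   (named integer vector, the printed integrative ranking).
#' @export
referenceDiseaseRanks <- function() {
  path <- system.file("extdata", "table1_disease_ranks.tsv",
                      package = "MorbiMap", mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tb[, c("AD", "ALS", "FTD")])
  rownames(m) <- tb$category
  storage.mode(m) <- "integer"
  list(ranks = m,
       integrative = stats::setNames(as.integer(tb$integrative),
                                     tb$category))
}
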