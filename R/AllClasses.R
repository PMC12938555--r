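#' @import methods
NULL

#' Typed heterogeneous knowledge graph
#'
#' A small directed graph whose nodes carry a semantic type (e.g. \code{DSYN},
#' \code{PHSU}, \code{AAPP}, \code{TARGET}) and whose edges carry a predicate
#' (e.g. \code{affects}, \code{treats}). This is the substrate on which
#' metapath enumeration and HeteSim relevance are computed.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{node_type},
#'   \code{label}; node ids are unique.
#' @slot edges data.frame with columns \code{source_id}, \code{predicate},
#'   \code{target_id}; every endpoint must exist in \code{nodes}.
#'
#' @seealso [HetGraph()], [enumerateMetapaths()], [hetesimPath()]
#' @export
setClass("HetGraph", representation(nodes = "data.frame", edges = "data.frame"))

setValidity("HetGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (!all(c("node_id", "node_type", "label") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns node_id, node_type, label")
  if (!all(c("source_id", "predicate", "target_id") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns source_id, predicate, target_id")
  if (length(msgs) == 0L) {
    if (anyDuplicated(nd$node_id))
      msgs <- c(msgs, "node ids must be unique")
    missing <- setdiff(unique(c(ed$source_id, ed$target_id)), nd$node_id)
    if (length(missing))
      msgs <- c(msgs, paste0("edge endpoints not in node table: ",
                             paste(utils::head(missing, 5L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Typed metapath schema
#'
#' An ordered sequence of node types joined by predicates, e.g.
#' \code{DSYN -affects-> AAPP -affects-> TARGET}. The edge-length of the path
#' is \code{length(predicates)}.
#'
#' @slot nodeTypes character vector of L + 1 node types.
#' @slot predicates character vector of L predicates.
#' @export
setClass("Metapath",
         representation(nodeTypes = "character", predicates = "character"))

setValidity("Metapath", function(object) {
  if (length(object@nodeTypes) != length(object@predicates) + 1L)
    return("nodeTypes must be one longer than predicates")
  if (length(object@predicates) < 1L)
    return("a metapath needs at least one edge")
  TRUE
})

#' Ranked concept-node table for one disease
#'
#' Holds, for a single target disease, its associated concept nodes with raw
#' (mean-aggregated HeteSim) scores and the two normalizations used
#' downstream: the zero-mean/unit-variance standardized score and the
#' mid-rank percentile in [0, 1]. Both normalizations are recomputed by the
#' constructor, so a valid object is always internally consistent.
#'
#' @slot entity disease label, e.g. \code{"AD"}.
#' @slot table data.frame with columns \code{node_id}, \code{name},
#'   \code{source_type}, \code{raw_score}, \code{standardized_score},
#'   \code{percentile}.
#'
#' @seealso [RankedNodeTable()], [normalizeScores()]
#' @export
setClass("RankedNodeTable",
         representation(entity = "character", table = "data.frame"))

setValidity("RankedNodeTable", function(object) {
  tb <- object@table
  need <- c("node_id", "name", "source_type", "raw_score",
            "standardized_score", "percentile")
  if (!all(need %in% names(tb)))
    return(paste0("table must have columns: ", paste(need, collapse = ", ")))
  if (length(object@entity) != 1L) return("entity must be a single label")
  n <- nrow(tb)
  if (n == 0L) return(TRUE)
  msgs <- character()
  if (anyDuplicated(tb$node_id)) msgs <- c(msgs, "node ids must be unique")
  if (any(tb$percentile < 0 | tb$percentile > 1))
    msgs <- c(msgs, "percentile must lie in [0, 1]")
  o <- order(tb$raw_score)
  if (is.unsorted(tb$percentile[o]))
    msgs <- c(msgs, "percentile must be non-decreasing in raw_score")
  if (n >= 2L) {
    s <- tb$standardized_score
    if (abs(mean(s)) > 1e-9)
      msgs <- c(msgs, "standardized scores must have mean 0")
    if (stats::sd(tb$raw_score) > 0 && abs(stats::var(s) - 1) > 1e-9)
      msgs <- c(msgs, "standardized scores must have unit variance")
  }
  if (length(msgs)) msgs else TRUE
})

#' Node-to-category ontology mapping
#'
#' Assigns each concept node to exactly one category of a closed alphabet --
#' by default the 13-category mechanistic ontology of [dsynCategories()]. The
#' same class serves the pharmacologic (PHSU) channel with the mechanistic
#' class alphabet of [phsuClasses()].
#'
#' @slot entries named character vector: names are node ids, values category
#'   labels.
#' @slot categories the closed category alphabet, in canonical order.
#' @slot provenance optional named character vector of free-text notes.
#' @export
setClass("CategoryMapping",
         representation(entries = "character", categories = "character",
                        provenance = "character"))

setValidity("CategoryMapping", function(object) {
  msgs <- character()
  if (length(object@entries)) {
    if (is.null(names(object@entries)) || anyDuplicated(names(object@entries)))
      msgs <- c(msgs, "entries must be uniquely named by node id")
    bad <- setdiff(unique(object@entries), object@categories)
    if (length(bad))
      msgs <- c(msgs, paste0("labels outside the category alphabet: ",
                             paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(object@categories))
    msgs <- c(msgs, "category alphabet must not contain duplicates")
  if (length(msgs)) msgs else TRUE
})

#' Pairwise-disease intersection profile
#'
#' The multimorbidity intersection of two diseases: nodes present in both
#' ranked tables whose harmonic-mean (HM) combined score meets the threshold,
#' annotated with their ontology category, plus the per-category counts,
#' within-intersection percentages (summing to 100) and, once computed
#' against a global baseline, signed Z-score enrichment values.
#'
#' @slot pairLabel e.g. \code{"AD&ALS"}.
#' @slot members data.frame with columns \code{node_id}, \code{category},
#'   \code{score_d1}, \code{score_d2}, \code{hm}.
#' @slot counts named integer vector over the category alphabet.
#' @slot percentages named numeric vector (empty when there are no members).
#' @slot z named numeric enrichment vector (empty until computed).
#' @slot threshold the HM inclusion threshold used.
#' @export
setClass("IntersectionProfile",
         representation(pairLabel = "character", members = "data.frame",
                        counts = "integer", percentages = "numeric",
                        z = "numeric", threshold = "numeric"))

setValidity("IntersectionProfile", function(object) {
  msgs <- character()
  if (nrow(object@members) > 0 &&
      any(object@members$hm < object@threshold - 1e-12))
    msgs <- c(msgs, "all members must satisfy hm >= threshold")
  if (sum(object@counts) != nrow(object@members))
    msgs <- c(msgs, "category counts must sum to the member count")
  if (length(object@percentages) &&
      abs(sum(object@percentages) - 100) > 1e-9)
    msgs <- c(msgs, "percentages must sum to 100")
  if (length(msgs)) msgs else TRUE
})

#' Global category baseline
#'
#' The category distribution of the pooled high-importance nodes across all
#' diseases, used as the null for intersection enrichment Z-scores.
#'
#' @slot proportions named numeric vector over the category alphabet,
#'   summing to 1.
#' @slot total number of pooled nodes behind the proportions.
#' @slot mode \code{"union"} (each node counted once) or \code{"concat"}
#'   (counted once per disease it appears in).
#' @export
setClass("GlobalBaseline",
         representation(proportions = "numeric", total = "integer",
                        mode = "character"))

setValidity("GlobalBaseline", function(object) {
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("baseline proportions must sum to 1")
  if (any(object@proportions < 0 | object@proportions > 1))
    return("baseline proportions must lie in [0, 1]")
  TRUE
})

#' Category hierarchy for one entity
#'
#' Aggregated per-category scores for a disease or intersection, ranked
#' 1 (highest importance) to 13 (lowest). Ranks are a strict permutation;
#' ties in the aggregate are broken by canonical category order.
#'
#' @slot entity entity label (disease or intersection).
#' @slot categories category alphabet in canonical order.
#' @slot scores per-category aggregated scores.
#' @slot ranks integer permutation of 1..K, aligned with \code{categories}.
#' @export
setClass("CategoryHierarchy",
         representation(entity = "character", categories = "character",
                        scores = "numeric", ranks = "integer"))

setValidity("CategoryHierarchy", function(object) {
  k <- length(object@categories)
  if (length(object@scores) != k || length(object@ranks) != k)
    return("scores and ranks must align with categories")
  if (!isPermutation(object@ranks, k))
    return("ranks must be a permutation of 1..K")
  if (is.unsorted(-object@scores[order(object@ranks)]))
    return("rank order must be non-increasing in score")
  TRUE
})

#' Integrated priority landscape
#'
#' Category ranks for several entities (diseases and intersections) side by
#' side, together with the rank-preserving priority transform 15 - rank used
#' for visual comparison. No cross-entity averaging is performed; rows stay
#' ordinal.
#'
#' @slot entities entity labels (matrix rows).
#' @slot categories category alphabet (matrix columns).
#' @slot ranks integer matrix of category ranks, one row per entity.
#' @slot priorities numeric matrix, elementwise 15 - ranks.
#' @export
setClass("PriorityLandscape",
         representation(entities = "character", categories = "character",
                        ranks = "matrix", priorities = "matrix"))

setValidity("PriorityLandscape", function(object) {
  k <- length(object@categories)
  if (!identical(dim(object@ranks), dim(object@priorities)))
    return("ranks and priorities must have identical shape")
  if (nrow(object@ranks) != length(object@entities) ||
      ncol(object@ranks) != k)
    return("matrix shape must be entities x categories")
  for (i in seq_len(nrow(object@ranks)))
    if (!isPermutation(object@ranks[i, ], k))
      return("every entity's ranks must be a permutation of 1..K")
  if (any(object@priorities != 15 - object@ranks))
    return("priorities must equal 15 - ranks")
  TRUE
})

#' Borda integrative ranking
#'
#' Result of aggregating per-disease category ranks by rank sum, with ties
#' broken by lower median rank, then lower minimum rank, then canonical
#' category order (flagged in \code{tieTrace}).
#'
#' @slot categories category labels in canonical order.
#' @slot rankSum per-category sum of the disease ranks.
#' @slot integrativeRank integer permutation of 1..K.
#' @slot tieTrace data.frame recording, for each category involved in a
#'   rank-sum tie, which rule (\code{median}, \code{minimum},
#'   \code{canonical}) resolved its position.
#' @export
setClass("BordaResult",
         representation(categories = "character", rankSum = "numeric",
                        integrativeRank = "integer", tieTrace = "data.frame"))

setValidity("BordaResult", function(object) {
  k <- length(object@categories)
  if (length(object@rankSum) != k || length(object@integrativeRank) != k)
    return("rankSum and integrativeRank must align with categories")
  if (!isPermutation(object@integrativeRank, k))
    return("integrativeRank must be a permutation of 1..K")
  o <- order(object@integrativeRank)
  if (is.unsorted(object@rankSum[o]))
    return("integrative order must be non-decreasing in rankSum")
  TRUE
})
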