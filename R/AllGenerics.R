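#' Accessors for MorbiMap classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x a MorbiMap S4 object.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("entityLabel", function(x) standardGeneric("entityLabel"))
#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setGeneric("mappingEntries", function(x) standardGeneric("mappingEntries"))
#' @rdname accessors
#' @export
setGeneric("categoryAlphabet", function(x) standardGeneric("categoryAlphabet"))
#' @rdname accessors
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))
#' @rdname accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))
#' @rdname accessors
#' @export
setGeneric("categoryPercents", function(x) standardGeneric("categoryPercents"))
#' @rdname accessors
#' @export
setGeneric("categoryZ", function(x) standardGeneric("categoryZ"))
#' @rdname accessors
#' @export
setGeneric("categoryScores", function(x) standardGeneric("categoryScores"))
#' @rdname accessors
#' @export
setGeneric("categoryRanks", function(x) standardGeneric("categoryRanks"))
#' @rdname accessors
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))
#' @rdname accessors
#' @export
setGeneric("priorityMatrix", function(x) standardGeneric("priorityMatrix"))
#' @rdname accessors
#' @export
setGeneric("integrativeRanking", function(x) standardGeneric("integrativeRanking"))
#' @rdname accessors
#' @export
setGeneric("rankSums", function(x) standardGeneric("rankSums"))
#' @rdname accessors
#' @export
setGeneric("tieTrace", function(x) standardGeneric("tieTrace"))

#' @rdname accessors
#' @export
setMethod("graphNodes", "HetGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "HetGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("entityLabel", "RankedNodeTable", function(x) x@entity)
#' @rdname accessors
#' @export
setMethod("scoreTable", "RankedNodeTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("entityLabel", "CategoryHierarchy", function(x) x@entity)
#' @rdname accessors
#' @export
setMethod("entityLabel", "IntersectionProfile", function(x) x@pairLabel)
#' @rdname accessors
#' @export
setMethod("mappingEntries", "CategoryMapping", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("categoryAlphabet", "CategoryMapping", function(x) x@categories)
#' @rdname accessors
#' @export
setMethod("memberTable", "IntersectionProfile", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("categoryCounts", "IntersectionProfile", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("categoryPercents", "IntersectionProfile", function(x) x@percentages)
#' @rdname accessors
#' @export
setMethod("categoryZ", "IntersectionProfile", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("categoryScores", "CategoryHierarchy", function(x) {
  stats::setNames(x@scores, x@categories)
})
#' @rdname accessors
#' @export
setMethod("categoryRanks", "CategoryHierarchy", function(x) {
  stats::setNames(x@ranks, x@categories)
})
#' @rdname accessors
#' @export
setMethod("rankMatrix", "PriorityLandscape", function(x) {
  structure(x@ranks, dimnames = list(x@entities, x@categories))
})
#' @rdname accessors
#' @export
setMethod("priorityMatrix", "PriorityLandscape", function(x) {
  structure(x@priorities, dimnames = list(x@entities, x@categories))
})
#' @rdname accessors
#' @export
setMethod("integrativeRanking", "BordaResult", function(x) {
  stats::setNames(x@integrativeRank, x@categories)
})
#' @rdname accessors
#' @export
setMethod("rankSums", "BordaResult", function(x) {
  stats::setNames(x@rankSum, x@categories)
})
#' @rdname accessors
#' @export
setMethod("tieTrace", "BordaResult", function(x) x@tieTrace)

setMethod("show", "HetGraph", function(object) {
  cat("HetGraph with", nrow(object@nodes), "nodes (",
      paste(sort(unique(object@nodes$node_type)), collapse = ", "),
      ") and", nrow(object@edges), "edges\n")
})

setMethod("show", "Metapath", function(object) {
  steps <- paste0(object@nodeTypes[-length(object@nodeTypes)],
                  " -", object@predicates, "-> ")
  cat("Metapath (length ", length(object@predicates), "): ",
      paste0(steps, collapse = ""),
      object@nodeTypes[length(object@nodeTypes)], "\n", sep = "")
})

setMethod("show", "RankedNodeTable", function(object) {
  cat("RankedNodeTable for", object@entity, "with", nrow(object@table),
      "nodes\n")
  if (nrow(object@table)) {
    top <- utils::head(object@table[order(-object@table$raw_score), ], 5L)
    print(top, row.names = FALSE)
  }
})

setMethod("show", "CategoryMapping", function(object) {
  cat("CategoryMapping:", length(object@entries), "nodes over",
      length(object@categories), "categories\n")
})

setMethod("show", "IntersectionProfile", function(object) {
  cat("IntersectionProfile", object@pairLabel, "--", nrow(object@members),
      "members at HM >=", object@threshold, "\n")
  if (length(object@percentages)) {
    top <- sort(object@percentages, decreasing = TRUE)
    top <- top[top > 0]
    cat("  top categories:",
        paste0(names(utils::head(top, 3L)), " (",
               sprintf("%.1f", utils::head(top, 3L)), "%)",
               collapse = ", "), "\n")
  }
})

setMethod("show", "GlobalBaseline", function(object) {
  cat("GlobalBaseline over", object@total, "nodes (mode:", object@mode, ")\n")
})

setMethod("show", "CategoryHierarchy", function(object) {
  cat("CategoryHierarchy for", object@entity, "\n")
  o <- order(object@ranks)
  cat("  top 3:", paste0(object@categories[o][1:3], " (rank ",
                         object@ranks[o][1:3], ")", collapse = ", "), "\n")
})

setMethod("show", "PriorityLandscape", function(object) {
  cat("PriorityLandscape:", length(object@entities), "entities x",
      length(object@categories), "categories\n")
})

setMethod("show", "BordaResult", function(object) {
  cat("BordaResult over", length(object@categories), "categories;",
      nrow(object@tieTrace), "tie(s) resolved\n")
  o <- order(object@integrativeRank)
  cat("  integrative order:",
      paste(utils::head(object@categories[o], 4L), collapse = " > "),
      "> ...\n")
})
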