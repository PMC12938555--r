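#' Construct a typed heterogeneous graph
#'
#' @param nodes data.frame with columns \code{node_id}, \code{node_type} and
#'   optionally \code{label} (defaults to the id).
#' @param edges data.frame with columns \code{source_id}, \code{predicate},
#'   \code{target_id}. May be empty.
#' @return A [HetGraph-class] object.
#' @examples
#' g <- HetGraph(
#'   nodes = data.frame(node_id = c("d1", "t1"),
#'                      node_type = c("DSYN", "TARGET")),
#'   edges = data.frame(source_id = "d1", predicate = "affects",
#'                      target_id = "t1"))
#' g
#' @export
HetGraph <- function(nodes, edges = data.frame(source_id = character(),
                                               predicate = character(),
                                               target_id = character())) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$label)) nodes$label <- nodes$node_id
  nodes <- nodes[, c("node_id", "node_type", "label")]
  if (nrow(edges)) {
    edges <- edges[, c("source_id", "predicate", "target_id")]
    edges <- unique(edges)
    rownames(edges) <- NULL
  }
  new("HetGraph", nodes = nodes, edges = edges)
}

#' Read a typed edge list from a tab-separated file
#'
#' Expects the header \code{source_id source_type predicate target_id
#' target_type}; node types are taken from the edge rows, and an optional
#' companion node table may add isolated nodes or labels.
#'
#' @param path path to the edge-list file.
#' @param node_path optional path to a node table with columns
#'   \code{node_id}, \code{node_type} and optionally \code{label}.
#' @return A [HetGraph-class].
#' @export
readHetGraph <- function(path, node_path = NULL) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("source_id", "source_type", "predicate", "target_id",
            "target_type")
  if (!all(need %in% names(ed)))
    morbDataStop(paste0("edge list must have columns: ",
                        paste(need, collapse = ", ")))
  nodes <- unique(rbind(
    data.frame(node_id = ed$source_id, node_type = ed$source_type,
               stringsAsFactors = FALSE),
    data.frame(node_id = ed$target_id, node_type = ed$target_type,
               stringsAsFactors = FALSE)))
  if (!is.null(node_path)) {
    extra <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    nodes <- merge(nodes, extra[, intersect(names(extra),
                                            c("node_id", "label"))],
                   by = "node_id", all.x = TRUE, sort = TRUE)
    add <- extra[!extra$node_id %in% nodes$node_id,
                 intersect(names(extra), c("node_id", "node_type", "label"))]
    if (nrow(add)) nodes <- rbind(nodes[names(add)], add)
  }
  conflict <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(conflict))
    morbDataStop(paste0("node(s) declared with more than one type: ",
                        paste(unique(conflict), collapse = ", ")))
  HetGraph(nodes, ed[, c("source_id", "predicate", "target_id")])
}

nodeType <- function(graph, id) {
  i <- match(id, graph@nodes$node_id)
  if (is.na(i)) morbDataStop(paste0("unknown node id: ", id))
  graph@nodes$node_type[i]
}

# Schema triples (source_type, predicate, target_type) realized by the graph.
graphSchema <- function(graph) {
  if (nrow(graph@edges) == 0L)
    return(data.frame(source_type = character(), predicate = character(),
                      target_type = character()))
  ty <- stats::setNames(graph@nodes$node_type, graph@nodes$node_id)
  unique(data.frame(source_type = unname(ty[graph@edges$source_id]),
                    predicate = graph@edges$predicate,
                    target_type = unname(ty[graph@edges$target_id]),
                    stringsAsFactors = FALSE))
}

#' Enumerate schema-consistent metapaths to a target
#'
#' Walks the graph's type schema (the set of realized
#' source-type/predicate/target-type triples) and returns every typed path
#' pattern of edge-length at most \code{max_length} leading from a node of
#' \code{source_type} to the type of \code{target_id}. Patterns are
#' deduplicated and returned in lexicographic order of their step sequence,
#' so the result is deterministic.
#'
#' A pattern of L edges traverses L - 1 intermediate nodes, so the default
#' \code{max_length = 3} corresponds to a search depth of 2 intermediates.
#'
#' @param graph a [HetGraph-class].
#' @param source_type node type at which patterns start.
#' @param target_id the target node; patterns end at its type.
#' @param max_length maximum number of edges per pattern (default 3).
#' @return A list of [Metapath-class] objects (possibly empty).
#' @export
enumerateMetapaths <- function(graph, source_type, target_id,
                               max_length = 3L) {
  if (max_length < 1L) morbConfigStop("max_length must be >= 1")
  if (!target_id %in% graph@nodes$node_id)
    morbDataStop(paste0("unknown target_id: ", target_id))
  if (!source_type %in% graph@nodes$node_type)
    morbDataStop(paste0("unknown source_type: ", source_type))
  target_type <- nodeType(graph, target_id)
  schema <- graphSchema(graph)
  if (nrow(schema) == 0L) return(list())

  out <- list()
  # depth-first extension over schema triples
  extend <- function(types, preds) {
    cur <- types[length(types)]
    if (length(preds) > 0L && cur == target_type)
      out[[length(out) + 1L]] <<- list(types = types, preds = preds)
    if (length(preds) >= max_length) return(invisible())
    nxt <- schema[schema$source_type == cur, , drop = FALSE]
    for (i in seq_len(nrow(nxt)))
      extend(c(types, nxt$target_type[i]), c(preds, nxt$predicate[i]))
    invisible()
  }
  extend(source_type, character())

  if (!length(out)) return(list())
  keys <- vapply(out, function(p)
    paste(rbind(p$types, c(p$preds, "")), collapse = "\r"), character(1))
  keep <- !duplicated(keys)
  out <- out[keep][order(keys[keep], method = "radix")]
  lapply(out, function(p)
    new("Metapath", nodeTypes = p$types, predicates = p$preds))
}

# Row-normalized transition matrix for one typed relation step.
# Rows: nodes of from_type, cols: nodes of to_type; rows with no out-edge
# under this step stay all-zero (dangling nodes contribute nothing).
stepMatrix <- function(graph, from_type, predicate, to_type) {
  from <- graph@nodes$node_id[graph@nodes$node_type == from_type]
  to <- graph@nodes$node_id[graph@nodes$node_type == to_type]
  m <- matrix(0, length(from), length(to), dimnames = list(from, to))
  ed <- graph@edges
  ty <- stats::setNames(graph@nodes$node_type, graph@nodes$node_id)
  sel <- ed$predicate == predicate & ty[ed$source_id] == from_type &
    ty[ed$target_id] == to_type
  ed <- ed[sel, , drop = FALSE]
  if (nrow(ed)) m[cbind(ed$source_id, ed$target_id)] <- 1
  rs <- rowSums(m)
  nz <- rs > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  m
}

# Step edges (instances) for the middle-edge split of odd-length paths.
stepEdges <- function(graph, from_type, predicate, to_type) {
  ed <- graph@edges
  ty <- stats::setNames(graph@nodes$node_type, graph@nodes$node_id)
  sel <- ed$predicate == predicate & ty[ed$source_id] == from_type &
    ty[ed$target_id] == to_type
  ed[sel, , drop = FALSE]
}

#' HeteSim relevance along one metapath
#'
#' Computes the symmetric HeteSim relevance between \code{source_id} and
#' \code{target_id} along a typed metapath: the cosine similarity of the
#' source's forward reachability probability distribution and the target's
#' backward reachability distribution at the path midpoint. Transition
#' probabilities are uniform over a node's out-edges (in-edges for the
#' backward walk) within each typed relation step. For odd edge-length
#' paths the middle edge is split in the classic HeteSim fashion: each edge
#' instance of the middle relation acts as an artificial midpoint node, so
#' the meeting-in-the-middle semantics stays symmetric.
#'
#' The score is 1 exactly when the two midpoint distributions are
#' proportional and 0 when their supports are disjoint (including when
#' either side dangles off the path).
#'
#' @param graph a [HetGraph-class].
#' @param source_id,target_id node ids whose types must match the path ends.
#' @param path a [Metapath-class].
#' @return A relevance score in [0, 1].
#' @export
hetesimPath <- function(graph, source_id, target_id, path) {
  if (!is(path, "Metapath")) morbDataStop("path must be a Metapath")
  ty <- path@nodeTypes
  pr <- path@predicates
  L <- length(pr)
  if (nodeType(graph, source_id) != ty[1L])
    morbDataStop("source type does not match the start of the metapath")
  if (nodeType(graph, target_id) != ty[L + 1L])
    morbDataStop("target type does not match the end of the metapath")

  fwd <- function(id, steps) {
    # distribution over nodes of ty[length(steps)+1] reachable from id
    u <- stats::setNames(numeric(sum(graph@nodes$node_type == ty[1L])),
                         graph@nodes$node_id[graph@nodes$node_type == ty[1L]])
    u[id] <- 1
    for (i in steps) u <- drop(u %*% stepMatrix(graph, ty[i], pr[i], ty[i + 1L]))
    u
  }
  bwd <- function(id, steps) {
    # backward distribution: walk edge-reversed from the target
    v <- stats::setNames(numeric(sum(graph@nodes$node_type == ty[L + 1L])),
                         graph@nodes$node_id[graph@nodes$node_type == ty[L + 1L]])
    v[id] <- 1
    for (i in steps) {
      m <- stepMatrix(graph, ty[i], pr[i], ty[i + 1L])
      # reverse step: rows = to_type nodes, uniform over in-edges
      rmat <- t(m > 0) * 1
      rs <- rowSums(rmat)
      nz <- rs > 0
      rmat[nz, ] <- rmat[nz, , drop = FALSE] / rs[nz]
      v <- drop(v %*% rmat)
    }
    v
  }

  if (L %% 2L == 0L) {
    mid <- L %/% 2L
    u <- fwd(source_id, seq_len(mid))
    v <- bwd(target_id, rev(seq_len(L)[-seq_len(mid)]))
  } else {
    m <- (L + 1L) %/% 2L
    ua <- fwd(source_id, seq_len(m - 1L))
    vb <- bwd(target_id, rev(seq_len(L)[-seq_len(m)]))
    ed <- stepEdges(graph, ty[m], pr[m], ty[m + 1L])
    if (nrow(ed) == 0L) return(0)
    outdeg <- table(ed$source_id)
    indeg <- table(ed$target_id)
    u <- unname(ua[ed$source_id]) / as.numeric(outdeg[ed$source_id])
    v <- unname(vb[ed$target_id]) / as.numeric(indeg[ed$target_id])
    u[is.na(u)] <- 0
    v[is.na(v)] <- 0
  }
  cosineSimilarity(u, v)
}

#' Mean aggregation of per-metapath scores
#'
#' The per-node relevance is the arithmetic mean of its HeteSim scores over
#' all metapaths. An empty score list signals a node unreachable under every
#' metapath and aggregates to 0 with a warning.
#'
#' @param scores numeric vector of per-metapath scores in [0, 1].
#' @return The arithmetic mean (0 for empty input).
#' @export
aggregateScores <- function(scores) {
  if (length(scores) == 0L) {
    warning("no metapath scores to aggregate; node unreachable, score 0")
    return(0)
  }
  mean(scores)
}

#' Rank source-type nodes against a target by HeteSim
#'
#' Convenience driver over [enumerateMetapaths()], [hetesimPath()],
#' [aggregateScores()] and [normalizeScores()]: computes for every node of
#' \code{source_type} its mean HeteSim relevance to \code{target_id} across
#' all metapaths, then normalizes into a [RankedNodeTable-class].
#'
#' @param graph a [HetGraph-class].
#' @param target_id the target disease node.
#' @param source_type the source node type to rank (e.g. \code{"DSYN"}).
#' @param max_length maximum metapath edge-length (default 3).
#' @param entity label for the resulting table; defaults to the target's
#'   label.
#' @return A [RankedNodeTable-class].
#' @export
rankNodes <- function(graph, target_id, source_type, max_length = 3L,
                      entity = NULL) {
  paths <- enumerateMetapaths(graph, source_type, target_id, max_length)
  nd <- graph@nodes[graph@nodes$node_type == source_type, , drop = FALSE]
  nd <- nd[nd$node_id != target_id, , drop = FALSE]
  if (length(paths) == 0L) {
    warning("no metapaths from ", source_type, " to ", target_id,
            "; all scores 0")
    raw <- rep(0, nrow(nd))
  } else {
    raw <- vapply(nd$node_id, function(id) {
      mean(vapply(paths, function(p) hetesimPath(graph, id, target_id, p),
                  numeric(1)))
    }, numeric(1))
  }
  if (is.null(entity)) entity <- graph@nodes$label[
    match(target_id, graph@nodes$node_id)]
  RankedNodeTable(entity = entity, node_id = nd$node_id, name = nd$label,
                  source_type = source_type, raw_score = unname(raw))
}
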