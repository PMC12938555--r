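# Independent oracles used across the suite. These deliberately recompute
# quantities by a different route than the package (explicit path-instance
# enumeration, exhaustive pair counting, closed forms) so agreement is
# evidence, not tautology.

# ---- HeteSim: brute-force path-instance enumeration ------------------------

oracleForwardDist <- function(ed, ty, id, types, preds, steps) {
  dist <- stats::setNames(1, id)
  for (i in steps) {
    nxt <- new.env()
    for (u in names(dist)) {
      m <- ed[ed$source_id == u & ed$predicate == preds[i] &
                ty[ed$target_id] == types[i + 1] &
                ty[ed$source_id] == types[i], , drop = FALSE]
      if (nrow(m) == 0) next
      for (v in m$target_id) {
        prev <- mget(v, envir = nxt, ifnotfound = 0)[[1]]
        assign(v, prev + dist[[u]] / nrow(m), envir = nxt)
      }
    }
    dist <- unlist(as.list(nxt))
    if (is.null(dist) || length(dist) == 0) return(numeric())
  }
  dist
}

oracleBackwardDist <- function(ed, ty, id, types, preds, steps_desc) {
  dist <- stats::setNames(1, id)
  for (i in steps_desc) {
    nxt <- new.env()
    for (v in names(dist)) {
      m <- ed[ed$target_id == v & ed$predicate == preds[i] &
                ty[ed$source_id] == types[i] &
                ty[ed$target_id] == types[i + 1], , drop = FALSE]
      if (nrow(m) == 0) next
      for (u in m$source_id) {
        prev <- mget(u, envir = nxt, ifnotfound = 0)[[1]]
        assign(u, prev + dist[[v]] / nrow(m), envir = nxt)
      }
    }
    dist <- unlist(as.list(nxt))
    if (is.null(dist) || length(dist) == 0) return(numeric())
  }
  dist
}

oracleCosine <- function(u, v) {
  keys <- union(names(u), names(v))
  a <- stats::setNames(numeric(length(keys)), keys)
  b <- a
  a[names(u)] <- u
  b[names(v)] <- v
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

oracleHetesim <- function(g, s, t, path) {
  ed <- graphEdges(g)
  nd <- graphNodes(g)
  ty <- stats::setNames(nd$node_type, nd$node_id)
  types <- path@nodeTypes
  preds <- path@predicates
  L <- length(preds)
  if (L %% 2 == 0) {
    mid <- L / 2
    u <- oracleForwardDist(ed, ty, s, types, preds, seq_len(mid))
    v <- oracleBackwardDist(ed, ty, t, types, preds,
                            rev(seq_len(L)[-seq_len(mid)]))
    return(oracleCosine(u, v))
  }
  m <- (L + 1) / 2
  ua <- oracleForwardDist(ed, ty, s, types, preds, seq_len(m - 1))
  vb <- oracleBackwardDist(ed, ty, t, types, preds,
                           rev(seq_len(L)[-seq_len(m)]))
  me <- ed[ed$predicate == preds[m] & ty[ed$source_id] == types[m] &
             ty[ed$target_id] == types[m + 1], , drop = FALSE]
  if (nrow(me) == 0) return(0)
  ekey <- paste(me$source_id, me$target_id)
  outdeg <- table(me$source_id)
  indeg <- table(me$target_id)
  u <- stats::setNames(
    ifelse(me$source_id %in% names(ua),
           ua[me$source_id] / as.numeric(outdeg[me$source_id]), 0), ekey)
  v <- stats::setNames(
    ifelse(me$target_id %in% names(vb),
           vb[me$target_id] / as.numeric(indeg[me$target_id]), 0), ekey)
  u[is.na(u)] <- 0
  v[is.na(v)] <- 0
  oracleCosine(u, v)
}

reverseGraph <- function(g) {
  ed <- graphEdges(g)
  HetGraph(graphNodes(g),
           data.frame(source_id = ed$target_id, predicate = ed$predicate,
                      target_id = ed$source_id))
}

reverseMetapath <- function(p) {
  new("Metapath", nodeTypes = rev(p@nodeTypes),
      predicates = rev(p@predicates))
}

# ---- rank-correlation oracles ----------------------------------------------

oracleSpearmanClosedForm <- function(a, b) {
  n <- length(a)
  1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
}

oraclePearsonOfRanks <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

oracleKendallPairs <- function(a, b) {
  n <- length(a)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# ---- misc fixtures ---------------------------------------------------------

randomPermutation <- function(n) sample(n)

# a fully mapped ranked table over the 13 categories, scores seeded
makeAnnotatedFixture <- function(n = 30, seed = 1) {
  withr::with_seed(seed, {
    cats <- sample(dsynCategories(), n, replace = TRUE)
    data.frame(node_id = sprintf("N%03d", seq_len(n)),
               category = cats,
               percentile = runif(n),
               stringsAsFactors = FALSE)
  })
}

makeRankedTable <- function(entity, ids, scores) {
  RankedNodeTable(entity = entity, node_id = ids, raw_score = scores)
}
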