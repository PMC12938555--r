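#' Standardize and percentile-normalize raw relevance scores
#'
#' Applies the two score normalizations used throughout the pipeline:
#' \itemize{
#'   \item \code{standardized}: \code{(raw - mean) / sd}; when the scores are
#'     constant (sd = 0) all standardized values are 0 rather than NaN, so
#'     degenerate inputs still flow through.
#'   \item \code{percentile}: mid-rank / n, with tied raw scores sharing
#'     their average rank. This is deterministic, monotone in the raw score,
#'     and maps the (untied) top score to exactly 1.
#' }
#'
#' @param raw numeric vector of raw scores (n >= 1).
#' @return A data.frame with columns \code{standardized} and
#'   \code{percentile}, rows aligned with the input.
#' @examples
#' normalizeScores(c(1, 2, 2, 3))  # percentiles 0.25, 0.625, 0.625, 1
#' @export
normalizeScores <- function(raw) {
  if (length(raw) == 0L)
    return(data.frame(standardized = numeric(), percentile = numeric()))
  s <- if (length(raw) >= 2L) stats::sd(raw) else 0
  standardized <- if (is.na(s) || s == 0) rep(0, length(raw)) else
    (raw - mean(raw)) / s
  percentile <- rank(raw, ties.method = "average") / length(raw)
  data.frame(standardized = standardized, percentile = percentile)
}

#' Construct a ranked node table
#'
#' Builds a [RankedNodeTable-class] from raw scores, computing the
#' standardized and percentile normalizations via [normalizeScores()]. Input
#' vectors are recycled to the length of \code{node_id}.
#'
#' @param entity disease label.
#' @param node_id unique node identifiers (e.g. UMLS CUIs).
#' @param name human-readable node names (defaults to the ids).
#' @param source_type semantic source type, e.g. \code{"DSYN"} or
#'   \code{"PHSU"}.
#' @param raw_score raw (mean-aggregated HeteSim) scores.
#' @return A [RankedNodeTable-class].
#' @export
RankedNodeTable <- function(entity, node_id, name = node_id,
                            source_type = "DSYN", raw_score) {
  n <- length(node_id)
  if (anyDuplicated(node_id))
    morbDataStop(paste0("duplicate node ids in table for ", entity))
  if (length(raw_score) != n)
    morbDataStop("raw_score must align with node_id")
  nz <- normalizeScores(raw_score)
  tb <- data.frame(node_id = as.character(node_id),
                   name = rep_len(as.character(name), n),
                   source_type = rep_len(as.character(source_type), n),
                   raw_score = as.numeric(raw_score),
                   standardized_score = nz$standardized,
                   percentile = nz$percentile,
                   stringsAsFactors = FALSE)
  new("RankedNodeTable", entity = as.character(entity), table = tb)
}

#' Read / write ranked node tables
#'
#' Tab-separated with header \code{node_id name source_type raw_score
#' standardized_score percentile}. Reading re-derives the normalized columns
#' from the raw scores, so a hand-edited file cannot smuggle in inconsistent
#' normalizations.
#'
#' @param path file path.
#' @param entity entity label for the table read.
#' @param x a [RankedNodeTable-class] to write.
#' @return \code{readRankedTable} returns a [RankedNodeTable-class];
#'   \code{writeRankedTable} returns \code{path} invisibly.
#' @export
readRankedTable <- function(path, entity) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "name", "source_type", "raw_score")
  if (!all(need %in% names(tb)))
    morbDataStop(paste0("ranked table must have columns: ",
                        paste(need, collapse = ", ")))
  RankedNodeTable(entity, tb$node_id, tb$name, tb$source_type, tb$raw_score)
}

#' @rdname readRankedTable
#' @export
writeRankedTable <- function(x, path) {
  stopifnot(is(x, "RankedNodeTable"))
  utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' High-importance node subset
#'
#' The top fraction \code{q} of a disease's nodes by percentile score,
#' deterministically: rows are ordered by decreasing raw score with ties
#' broken by node id, and the first \code{ceiling(q * n)} ids are returned.
#'
#' @param x a [RankedNodeTable-class].
#' @param q top fraction to retain, in (0, 1]; default 0.10.
#' @return Character vector of node ids.
#' @export
highImportance <- function(x, q = 0.10) {
  stopifnot(is(x, "RankedNodeTable"))
  if (q <= 0 || q > 1) morbConfigStop("q must lie in (0, 1]")
  tb <- x@table
  o <- order(-tb$raw_score, tb$node_id, method = "radix")
  tb$node_id[o][seq_len(ceiling(q * nrow(tb)))]
}

#' Extract one score channel from a ranked table
#'
#' @param x a [RankedNodeTable-class].
#' @param channel \code{"percentile"} (default, unit interval),
#'   \code{"raw"}, or \code{"standardized"}.
#' @return Named numeric vector of scores keyed by node id.
#' @export
scoreChannel <- function(x, channel = c("percentile", "raw", "standardized")) {
  channel <- match.arg(channel)
  tb <- scoreTable(x)
  col <- switch(channel, percentile = "percentile", raw = "raw_score",
                standardized = "standardized_score")
  stats::setNames(tb[[col]], tb$node_id)
}
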