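#' Default pipeline configuration
#'
#' The full run configuration as a nested list, mirroring the sections of
#' the YAML config accepted by [loadConfig()]:
#' \describe{
#'   \item{scores}{\code{channel}: which normalized score feeds the
#'     harmonic-mean intersection and the category aggregation
#'     (\code{"percentile"} by default; \code{"standardized"} and
#'     \code{"raw"} available where unit-interval bounds permit).}
#'   \item{ontology}{\code{unmapped_policy}: drop / error / bucket.}
#'   \item{intersection}{\code{threshold} (HM cut, default 0.5),
#'     \code{high_importance_fraction} (top fraction defining
#'     high-importance sets, default 0.10), \code{baseline_mode}
#'     (union / concat).}
#'   \item{aggregation}{\code{mode}: sum / mean / count.}
#'   \item{enrichment}{\code{formula}: binomial / permutation;
#'     \code{permutation_draws}.}
#'   \item{synthetic}{the [syntheticConfig()] fields.}
#'   \item{seed}{run seed.}
#' }
#'
#' @return Nested configuration list.
#' @export
defaultConfig <- function() {
  list(scores = list(channel = "percentile"),
       ontology = list(unmapped_policy = "drop"),
       intersection = list(threshold = 0.5,
                           high_importance_fraction = 0.10,
                           baseline_mode = "union"),
       aggregation = list(mode = "sum"),
       enrichment = list(formula = "binomial",
                         permutation_draws = 10000L),
       synthetic = list(n_nodes = 2000L,
                        overlap_fraction = 0.3,
                        shared_core_boost = 5),
       seed = 1L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over [defaultConfig()]; unknown sections
#' are rejected and section values are validated, with violations raised as
#' \code{morbConfigError} conditions.
#'
#' @param path YAML file path, or \code{NULL} for the defaults.
#' @return Validated configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      morbConfigStop(paste0("unknown config section(s): ",
                            paste(unknown, collapse = ", ")))
    for (sec in names(user)) {
      if (is.list(cfg[[sec]])) {
        bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(bad))
          morbConfigStop(paste0("unknown key(s) in section ", sec, ": ",
                                paste(bad, collapse = ", ")))
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  validateConfig(cfg)
}

validateConfig <- function(cfg) {
  th <- cfg$intersection$threshold
  if (!is.numeric(th) || th <= 0 || th > 1)
    morbConfigStop("intersection.threshold must lie in (0, 1]")
  q <- cfg$intersection$high_importance_fraction
  if (!is.numeric(q) || q <= 0 || q > 1)
    morbConfigStop("intersection.high_importance_fraction must lie in (0, 1]")
  if (!cfg$intersection$baseline_mode %in% c("union", "concat"))
    morbConfigStop("intersection.baseline_mode must be union or concat")
  if (!cfg$scores$channel %in% c("percentile", "raw", "standardized"))
    morbConfigStop("scores.channel must be percentile, raw or standardized")
  if (!cfg$ontology$unmapped_policy %in% c("drop", "error", "bucket"))
    morbConfigStop("ontology.unmapped_policy must be drop, error or bucket")
  if (!cfg$aggregation$mode %in% c("sum", "mean", "count"))
    morbConfigStop("aggregation.mode must be sum, mean or count")
  if (!cfg$enrichment$formula %in% c("binomial", "permutation"))
    morbConfigStop("enrichment.formula must be binomial or permutation")
  cfg
}

#' Run the full cross-disease analysis in memory
#'
#' Executes every analysis stage downstream of node ranking on three
#' normalized disease tables: categorization, high-importance overlap
#' partition, global baseline, the three pairwise harmonic-mean
#' intersections with enrichment, the six category hierarchies, pairwise
#' disease similarity, intersection-parent alignment and rank differences,
#' the integrated priority landscape, and the Borda integrative ranking.
#'
#' @param tables named list of three [RankedNodeTable-class] objects.
#' @param mapping a [CategoryMapping-class] covering the tables' nodes.
#' @param config configuration list, see [defaultConfig()].
#' @param seed seed for stochastic stages (permutation enrichment only);
#'   defaults to the config seed.
#' @return A list with components \code{annotated}, \code{high_sets},
#'   \code{overlap}, \code{baseline}, \code{intersections},
#'   \code{hierarchies}, \code{similarity}, \code{alignment},
#'   \code{rank_differences}, \code{landscape}, \code{borda}, and
#'   \code{counts} (per-stage audit counts).
#' @export
analyzeTables <- function(tables, mapping, config = defaultConfig(),
                          seed = config$seed) {
  if (length(tables) != 3L || is.null(names(tables)))
    morbDataStop("analyzeTables expects a named list of three tables")
  mapping <- mergeNeuroPsych(mapping)
  diseases <- names(tables)
  channel <- config$scores$channel
  policy <- config$ontology$unmapped_policy
  q <- config$intersection$high_importance_fraction
  agg_mode <- config$aggregation$mode

  annotated <- lapply(tables, categorizeTable, mapping = mapping,
                      unmapped = policy)
  high_sets <- lapply(tables, highImportance, q = q)
  overlap <- overlapPartition(high_sets[[1]], high_sets[[2]], high_sets[[3]],
                              labels = diseases)
  baseline <- globalBaseline(tables, mapping, q = q,
                             mode = config$intersection$baseline_mode)

  pairs <- utils::combn(diseases, 2L, simplify = FALSE)
  intersections <- list()
  for (p in pairs) {
    prof <- buildIntersection(tables[[p[1]]], tables[[p[2]]], mapping,
                              threshold = config$intersection$threshold,
                              channel = channel, unmapped = policy)
    if (sum(categoryCounts(prof)) > 0L)
      prof <- enrichProfile(prof, baseline,
                            formula = config$enrichment$formula,
                            n_draws = config$enrichment$permutation_draws,
                            seed = stageSeed(seed, 5L))
    intersections[[entityLabel(prof)]] <- prof
  }

  score_col <- switch(channel, percentile = "percentile", raw = "raw_score",
                      standardized = "standardized_score")
  hier <- list()
  for (d in diseases)
    hier[[d]] <- categoryHierarchy(annotated[[d]], d,
                                   categories = mapping@categories,
                                   score_col = score_col, mode = agg_mode)
  for (lbl in names(intersections)) {
    m <- memberTable(intersections[[lbl]])
    if (nrow(m) == 0L) next
    hier[[lbl]] <- categoryHierarchy(m, lbl,
                                     categories = mapping@categories,
                                     score_col = "hm", mode = agg_mode)
  }

  similarity <- lapply(pairs, function(p)
    rankSimilarity(hier[[p[1]]], hier[[p[2]]]))
  names(similarity) <- vapply(pairs, paste, character(1), collapse = "&")

  alignment <- list()
  rank_diffs <- list()
  for (p in pairs) {
    lbl <- paste(p, collapse = "&")
    if (!lbl %in% names(hier)) next
    alignment[[lbl]] <- alignmentToParents(hier[[lbl]], hier[[p[1]]],
                                           hier[[p[2]]])
    rank_diffs[[lbl]] <- lapply(
      stats::setNames(p, p),
      function(d) rankDifferences(hier[[d]], hier[[lbl]]))
  }

  landscape <- buildLandscape(hier)
  disease_ranks <- do.call(cbind, lapply(hier[diseases],
                                         function(h) h@ranks))
  rownames(disease_ranks) <- mapping@categories
  colnames(disease_ranks) <- diseases
  borda <- bordaAggregate(disease_ranks)

  counts <- list(
    nodes_in = vapply(tables, function(t) nrow(scoreTable(t)), integer(1)),
    nodes_retained = vapply(annotated, nrow, integer(1)),
    unmapped = vapply(annotated, function(a)
      attr(a, "n_unmapped"), integer(1)),
    high_importance = vapply(high_sets, length, integer(1)),
    intersection_members = vapply(intersections, function(p)
      nrow(memberTable(p)), integer(1)))

  list(annotated = annotated, high_sets = high_sets, overlap = overlap,
       baseline = baseline, intersections = intersections,
       hierarchies = hier, similarity = similarity, alignment = alignment,
       rank_differences = rank_diffs, landscape = landscape, borda = borda,
       counts = counts)
}

#' Write the deterministic report bundle
#'
#' Emits the delimited stage tables and a JSON run summary into
#' \code{outdir}, then a manifest with an MD5 digest per file. Outputs are
#' byte-identical across repeat runs with the same inputs, config and seed
#' (no timestamps are written).
#'
#' @param result output of [analyzeTables()].
#' @param config the configuration used.
#' @param outdir output directory (created if needed).
#' @param seed the run seed, echoed into the summary.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
writeReport <- function(result, config, outdir, seed = config$seed) {
  required <- c("annotated", "overlap", "baseline", "intersections",
                "hierarchies", "similarity", "landscape", "borda", "counts")
  missing <- setdiff(required, names(result))
  if (length(missing))
    morbDataStop(paste0("incomplete pipeline state; missing stage(s): ",
                        paste(missing, collapse = ", ")))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  files <- character()
  for (d in names(result$annotated))
    files <- c(files, tsv(result$annotated[[d]],
                          paste0("ranked_", gsub("[^A-Za-z0-9]", "_", d),
                                 ".tsv")))
  for (lbl in names(result$intersections)) {
    p <- result$intersections[[lbl]]
    safe <- gsub("[^A-Za-z0-9]", "_", lbl)
    files <- c(files, tsv(memberTable(p),
                          paste0("intersection_", safe, ".tsv")))
  }
  hier_df <- do.call(rbind, lapply(result$hierarchies, function(h)
    data.frame(entity = entityLabel(h), category = h@categories,
               score = h@scores, rank = h@ranks,
               stringsAsFactors = FALSE)))
  files <- c(files, tsv(hier_df, "hierarchies.tsv"))
  land <- result$landscape
  land_df <- data.frame(entity = rep(land@entities,
                                     each = length(land@categories)),
                        category = rep(land@categories,
                                       times = length(land@entities)),
                        rank = as.vector(t(land@ranks)),
                        priority = as.vector(t(land@priorities)),
                        stringsAsFactors = FALSE)
  files <- c(files, tsv(land_df, "landscape.tsv"))
  borda_df <- data.frame(category = result$borda@categories,
                         rank_sum = result$borda@rankSum,
                         integrative_rank = result$borda@integrativeRank,
                         stringsAsFactors = FALSE)
  files <- c(files, tsv(borda_df, "borda.tsv"))

  summary <- list(
    seed = as.integer(seed),
    config = config,
    counts = result$counts,
    overlap_regions = as.list(result$overlap),
    baseline = list(mode = result$baseline@mode,
                    total = result$baseline@total,
                    proportions = as.list(result$baseline@proportions)),
    intersections = lapply(result$intersections, function(p) list(
      pair = entityLabel(p),
      n_members = nrow(memberTable(p)),
      counts = as.list(categoryCounts(p)),
      percentages = as.list(categoryPercents(p)),
      z = as.list(categoryZ(p)))),
    similarity = lapply(result$similarity, as.list),
    borda_ties = result$borda@tieTrace)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "run_summary.json")

  digests <- as.list(tools::md5sum(file.path(outdir, files)))
  names(digests) <- files
  manifest <- list(seed = as.integer(seed),
                   config_hash = configHash(config),
                   files = digests)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

configHash <- function(config) {
  unname(tools::md5sum(
    files = {
      f <- tempfile()
      writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
      f
    }))
}

#' Run the pipeline end to end
#'
#' Generates (or loads) the three disease tables, runs [analyzeTables()],
#' and writes the deterministic report bundle. Stage order: simulate,
#' normalize, categorize, intersect, enrich, hierarchy, similarity,
#' landscape, borda, report. Each stochastic stage draws its seed from the
#' run seed by a fixed derivation, so stages are reproducible in isolation.
#'
#' @param config configuration list (see [defaultConfig()]) or a YAML path.
#' @param seed run seed; overrides the config seed when given.
#' @param outdir report output directory, or \code{NULL} to skip writing.
#' @param tables optionally, pre-built named list of three
#'   [RankedNodeTable-class] to analyze instead of simulating.
#' @param mapping a [CategoryMapping-class]; required when \code{tables}
#'   is given.
#' @return A list with \code{result} ([analyzeTables()] output),
#'   \code{manifest} (when written), \code{config} and \code{seed}.
#' @export
runPipeline <- function(config = defaultConfig(), seed = NULL,
                        outdir = NULL, tables = NULL, mapping = NULL) {
  if (is.character(config)) config <- loadConfig(config)
  config <- validateConfig(config)
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  if (is.null(tables)) {
    syn <- do.call(syntheticConfig,
                   c(config$synthetic, list(seed = seed)))
    gen <- generateDiseaseTables(syn, seed = stageSeed(seed, 1L))
    tables <- gen$tables
    mapping <- gen$mapping
  } else if (is.null(mapping)) {
    morbDataStop("mapping must be supplied with pre-built tables")
  }
  result <- analyzeTables(tables, mapping, config, seed = seed)
  manifest <- NULL
  if (!is.null(outdir))
    manifest <- writeReport(result, config, outdir, seed = seed)
  invisible(list(result = result, manifest = manifest, config = config,
                 seed = seed))
}
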