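#' The 13-category mechanistic ontology
#'
#' The closed, canonically ordered category alphabet used for disease and
#' syndrome (DSYN) nodes. The order is the package's canonical reporting and
#' tie-breaking order. \code{"Other/Neuro-Psych"} absorbs the provisional
#' \code{"Neurological"} and \code{"Psychiatric"} labels (see
#' [mergeNeuroPsych()]), since those are heavily enriched in disease-defining
#' features rather than independent comorbidity.
#'
#' @return Character vector of the 13 category labels.
#' @export
dsynCategories <- function() {
  c("Metabolic",
    "Immune/Inflammatory/Infectious",
    "Cardiovascular",
    "Other/Neuro-Psych",
    "Sensory (EET)",
    "Gastrointestinal",
    "Endocrine",
    "Hematological",
    "Dermatological",
    "Liver",
    "Kidney",
    "Musculoskeletal/Orthopedic",
    "Environmental Toxins")
}

#' Broad mechanistic classes for the pharmacologic (PHSU) channel
#'
#' Unlike the DSYN ontology, this class set is open-ended: callers may pass
#' their own extended alphabet anywhere a \code{categories} argument is
#' accepted.
#'
#' @return Character vector of the default PHSU class labels.
#' @export
phsuClasses <- function() {
  c("anti-inflammatory", "antioxidant", "neuromodulatory", "cardiometabolic",
    "antimicrobial", "toxin-related", "other")
}

# Provisional labels the merge rule rewrites.
provisionalNeuroPsychLabels <- function() c("Neurological", "Psychiatric")

#' Construct a node-to-category mapping
#'
#' @param node_id character vector of node ids.
#' @param category category label per node.
#' @param categories the closed category alphabet; defaults to
#'   [dsynCategories()]. Provisional \code{Neurological}/\code{Psychiatric}
#'   labels are always admitted so that [mergeNeuroPsych()] can be applied
#'   afterwards.
#' @param provenance optional character vector of per-entry notes.
#' @return A [CategoryMapping-class].
#' @export
CategoryMapping <- function(node_id, category,
                            categories = dsynCategories(),
                            provenance = character()) {
  node_id <- as.character(node_id)
  category <- as.character(category)
  alphabet <- unique(c(categories,
                       intersect(unique(category),
                                 provisionalNeuroPsychLabels())))
  dup <- duplicated(node_id)
  if (any(dup)) {
    conflict <- unique(node_id[dup][
      vapply(node_id[dup], function(id)
        length(unique(category[node_id == id])) > 1L, logical(1))])
    if (length(conflict))
      morbStop(paste0("conflicting category assignments for node(s): ",
                      paste(conflict, collapse = ", ")),
               "morbMappingError", conflicts = conflict)
    keep <- !dup
    node_id <- node_id[keep]
    category <- category[keep]
    if (length(provenance)) provenance <- provenance[keep]
  }
  bad <- !category %in% alphabet
  if (any(bad))
    morbStop(paste0("unknown category label(s): ",
                    paste(unique(category[bad]), collapse = ", "),
                    " (rows ", paste(which(bad), collapse = ", "), ")"),
             "morbMappingError", rows = which(bad))
  if (length(provenance)) names(provenance) <- node_id
  new("CategoryMapping",
      entries = stats::setNames(category, node_id),
      categories = alphabet, provenance = provenance)
}

#' Load a node-to-category mapping table
#'
#' Reads a tab-separated two-column file (\code{node_id},
#' \code{category_label}). Header comment lines of the form
#' \code{# alias old=new} declare label aliases which are resolved before
#' validation; further aliases may be supplied programmatically. Duplicate
#' rows with conflicting categories are rejected with every conflict named.
#'
#' @param path mapping file path.
#' @param categories closed category alphabet (default [dsynCategories()]).
#' @param aliases optional named character vector \code{c(old = new, ...)}
#'   merged over the file's own alias declarations.
#' @return A [CategoryMapping-class].
#' @export
loadMapping <- function(path, categories = dsynCategories(), aliases = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  al <- character()
  for (h in grep("^#\\s*alias\\s", hdr, value = TRUE)) {
    kv <- sub("^#\\s*alias\\s+", "", h)
    eq <- regmatches(kv, regexec("^(.*)=(.*)$", kv))[[1]]
    if (length(eq) == 3L) al[trimws(eq[2])] <- trimws(eq[3])
  }
  if (!is.null(aliases)) al[names(aliases)] <- aliases
  tb <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(tb) < 2L)
    morbDataStop("mapping table needs columns node_id and category_label")
  names(tb)[1:2] <- c("node_id", "category_label")
  lab <- tb$category_label
  hit <- lab %in% names(al)
  lab[hit] <- unname(al[lab[hit]])
  CategoryMapping(tb$node_id, lab, categories = categories)
}

#' Merge provisional neuro/psych labels into Other/Neuro-Psych
#'
#' Rewrites every provisional \code{"Neurological"} or \code{"Psychiatric"}
#' assignment to \code{"Other/Neuro-Psych"}, leaving all other entries
#' untouched, and drops the provisional labels from the alphabet. Idempotent.
#'
#' @param mapping a [CategoryMapping-class].
#' @return A [CategoryMapping-class] free of provisional labels.
#' @export
mergeNeuroPsych <- function(mapping) {
  stopifnot(is(mapping, "CategoryMapping"))
  entries <- mapping@entries
  prov <- provisionalNeuroPsychLabels()
  entries[entries %in% prov] <- "Other/Neuro-Psych"
  alphabet <- setdiff(mapping@categories, prov)
  if (!"Other/Neuro-Psych" %in% alphabet)
    alphabet <- c(alphabet, "Other/Neuro-Psych")
  new("CategoryMapping", entries = entries, categories = alphabet,
      provenance = mapping@provenance)
}

#' Annotate a ranked table with ontology categories
#'
#' Joins a [RankedNodeTable-class] with a [CategoryMapping-class]. Unmapped
#' nodes are handled per policy: dropped with a count (default), raised as
#' an error naming the nodes, or bucketed into \code{Other/Neuro-Psych}.
#' Scores and row order of retained rows are preserved.
#'
#' @param x a [RankedNodeTable-class].
#' @param mapping a [CategoryMapping-class].
#' @param unmapped one of \code{"drop"}, \code{"error"}, \code{"bucket"}.
#' @return The score table with an added \code{category} column; the number
#'   of unmapped nodes is attached as attribute \code{"n_unmapped"}.
#' @export
categorizeTable <- function(x, mapping,
                            unmapped = c("drop", "error", "bucket")) {
  unmapped <- match.arg(unmapped)
  stopifnot(is(x, "RankedNodeTable"), is(mapping, "CategoryMapping"))
  tb <- scoreTable(x)
  cat_of <- mapping@entries[tb$node_id]
  miss <- is.na(cat_of)
  n_unmapped <- sum(miss)
  if (n_unmapped > 0L) {
    ids <- tb$node_id[miss]
    if (unmapped == "error")
      morbStop(paste0("unmapped node(s): ", paste(ids, collapse = ", ")),
               "morbMappingError", nodes = ids)
    if (unmapped == "bucket") {
      cat_of[miss] <- "Other/Neuro-Psych"
      miss[] <- FALSE
      message(n_unmapped, " unmapped node(s) bucketed to Other/Neuro-Psych",
              " in ", x@entity)
    } else {
      message(n_unmapped, " unmapped node(s) dropped from ", x@entity)
    }
  }
  out <- tb[!miss, , drop = FALSE]
  out$category <- unname(cat_of[!miss])
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}
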