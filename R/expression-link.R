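# Joining clonotype calls onto per-cell expression metadata.
# Integration is via plain metadata tables keyed by barcode (the same
# prefixing scheme as combineReceptors), never via expression-object
# internals, so any single-cell toolkit's metadata can be used.

#' Default clonotype-frequency bins
#'
#' Upper bounds of the frequency classes assigned by [joinExpression()].
#' Absolute mode bounds are cell counts; proportion mode bounds are clone
#' proportions of the scope unit. Frequencies beyond the last bound fall in
#' the last bin.
#'
#' @param edges Named numeric vector of strictly increasing upper bounds.
#' @return The validated bin vector.
#' @export
frequencyBins <- function(edges = c(Single = 1, Small = 5, Medium = 20,
                                    Large = 100, Hyperexpanded = 500)) {
  if (is.null(names(edges)) || any(names(edges) == "")) {
    stop("frequency bins must be named", call. = FALSE)
  }
  if (any(diff(edges) <= 0) || any(edges <= 0)) {
    stop("bin bounds must be strictly increasing and positive",
         call. = FALSE)
  }
  edges
}

#' Join clonotype calls onto cell metadata
#'
#' Left join of a [RepertoireSet-class]'s per-cell clonotype calls onto a
#' per-cell metadata table by barcode: every metadata row is retained, and
#' cells without a receptor call get missing clonotype fields. Each matched
#' cell receives its clonotype key, its clonotype `frequency` (number of
#' cells sharing the key, computed within its sample by default or across
#' all samples with `scope = "global"`) and an ordered `freq_bin` factor:
#' the first bin whose bound is >= the frequency (or >= the clone
#' proportion in proportion mode).
#'
#' @param meta `data.frame` with a unique `barcode` column (plus any
#'   categorical columns and optional embedding coordinates).
#' @param rep A `RepertoireSet` whose barcodes use the same prefixing
#'   scheme as `meta`.
#' @param callBy Clonotype key (see [clonotypeKey()]).
#' @param bins Frequency class bounds, see [frequencyBins()].
#' @param proportionMode Interpret `bins` as clone proportions of the scope
#'   unit instead of absolute cell counts.
#' @param scope `"per_sample"` or `"global"` frequency computation.
#' @return `meta` with added columns `clonotype_key`, `clone_sample`,
#'   `frequency`, `freq_bin`; row count and order unchanged.
#' @examples
#' sim <- simulateRepertoire(nCells = 100, seed = 7, sampleName = "P1")
#' rep <- combineReceptors(list(sim$contigs), samples = "P1")
#' meta <- simulateCellMeta(rep[["P1"]]$barcode, nClusters = 3, seed = 7)
#' joined <- joinExpression(meta, rep)
#' table(joined$freq_bin, useNA = "ifany")
#' @export
joinExpression <- function(meta, rep, callBy = "aa",
                           bins = frequencyBins(), proportionMode = FALSE,
                           scope = c("per_sample", "global")) {
  scope <- match.arg(scope)
  bins <- frequencyBins(bins)
  stopifnot(is.data.frame(meta), is(rep, "RepertoireSet"))
  if (!"barcode" %in% names(meta)) {
    stop("metadata must have a barcode column", call. = FALSE)
  }
  if (anyDuplicated(meta$barcode)) {
    stop("metadata barcodes must be unique", call. = FALSE)
  }
  cells <- do.call(rbind, lapply(clonotypeTables(rep), function(tab) {
    tab[, c("barcode", "sample"), drop = FALSE]
  }))
  nonempty <- sum(vapply(clonotypeTables(rep), nrow, integer(1))) > 0
  if (nonempty) {
    cells$key <- unlist(clonotypeKey(rep, callBy), use.names = FALSE)
    if (length(intersect(meta$barcode, cells$barcode)) == 0) {
      stop("no barcodes shared between metadata and clonotype calls; ",
           "check that both use the same sample/group prefixing",
           call. = FALSE)
    }
    scope_unit <- if (scope == "global") rep("all", nrow(cells)) else
      cells$sample
    freq_key <- paste(scope_unit, cells$key, sep = "\r")
    cells$frequency <- as.integer(stats::ave(freq_key, freq_key,
                                             FUN = length))
    unit_total <- as.integer(stats::ave(scope_unit, scope_unit,
                                        FUN = length))
    cells$prop <- cells$frequency / unit_total
    idx <- match(meta$barcode, cells$barcode)
  } else {
    idx <- rep(NA_integer_, nrow(meta))
    cells <- data.frame(sample = character(0), key = character(0),
                        frequency = integer(0), prop = numeric(0))
  }
  out <- meta
  out$clonotype_key <- cells$key[idx]
  out$clone_sample <- cells$sample[idx]
  out$frequency <- cells$frequency[idx]
  measure <- if (proportionMode) cells$prop[idx] else cells$frequency[idx]
  cuts <- cut(measure, breaks = c(0, utils::head(bins, -1), Inf),
              labels = names(bins), right = TRUE)
  out$freq_bin <- factor(as.character(cuts), levels = names(bins),
                         ordered = TRUE)
  out
}

#' Highlight chosen clonotypes
#'
#' Adds a `highlight` column to joined metadata: cells whose clonotype key
#' is among `sequences` are labeled with the matched sequence, all others
#' are `NA`. A sequence matching no cell raises a warning naming it.
#'
#' @param meta Metadata joined by [joinExpression()].
#' @param sequences Character vector of clonotype keys to mark.
#' @param keyCol Column holding the clonotype key.
#' @return `meta` with an added `highlight` column.
#' @export
highlightClonotypes <- function(meta, sequences, keyCol = "clonotype_key") {
  if (!keyCol %in% names(meta)) {
    stop("metadata has no column '", keyCol,
         "'; run joinExpression() first", call. = FALSE)
  }
  hit <- match(meta[[keyCol]], sequences)
  meta$highlight <- sequences[hit]
  unmatched <- setdiff(sequences, meta[[keyCol]])
  if (length(unmatched)) {
    warning("sequence(s) matching no cells: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  meta
}

#' Cluster composition by group
#'
#' Dense cross-tabulation of cells by cluster and group with within-cluster
#' proportions. With `scaled = TRUE` each group's counts are first divided
#' by that group's total cell number, so groups of unequal size contribute
#' comparably (a group absent from a cluster still appears, with
#' proportion 0). Per-cluster proportions always sum to 1.
#'
#' @param meta Per-cell metadata.
#' @param clusterCol,groupCol Names of the categorical columns to cross.
#' @param scaled Normalise by group totals before computing proportions.
#' @return `data.frame` with columns `cluster`, `group`, `count`,
#'   `proportion`.
#' @export
clusterComposition <- function(meta, clusterCol = "cluster",
                               groupCol = "group", scaled = FALSE) {
  for (col in c(clusterCol, groupCol)) {
    if (!col %in% names(meta)) {
      stop("metadata has no column '", col, "'", call. = FALSE)
    }
  }
  counts <- table(cluster = as.character(meta[[clusterCol]]),
                  group = as.character(meta[[groupCol]]))
  weights <- if (scaled) {
    sweep(counts, 2, pmax(colSums(counts), 1), "/")
  } else counts
  prop <- sweep(weights, 1, pmax(rowSums(weights), .Machine$double.eps),
                "/")
  out <- data.frame(
    cluster = rep(rownames(counts), times = ncol(counts)),
    group = rep(colnames(counts), each = nrow(counts)),
    count = as.numeric(counts),
    proportion = as.numeric(prop),
    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alluvial (axis-flow) table
#'
#' Aggregated flow weights across an ordered set of categorical axes: one
#' row per observed combination of axis values with the summed weight,
#' either the number of cells or their clonotype frequency. With
#' `weight = "cells"` the total weight equals the number of contributing
#' cells. The raw table feeds any alluvial/Sankey renderer.
#'
#' @param meta Per-cell metadata (joined when using clonotype frequency).
#' @param axes Character vector (>= 2) of categorical column names.
#' @param weight `"cells"` or `"clonotype_frequency"`.
#' @return `data.frame` with the axis columns plus `weight`.
#' @export
alluvialTable <- function(meta, axes,
                          weight = c("cells", "clonotype_frequency")) {
  weight <- match.arg(weight)
  if (length(axes) < 2) stop("need at least two axes", call. = FALSE)
  missing <- setdiff(axes, names(meta))
  if (length(missing)) {
    stop("metadata has no column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (ax in axes) {
    nlev <- length(unique(meta[[ax]]))
    if (nlev > 1000) {
      stop("axis '", ax, "' has ", nlev, " levels; an alluvial plot with ",
           "that many strata is unreadable - export the raw table instead ",
           "(e.g. with exportTable())", call. = FALSE)
    }
  }
  w <- if (weight == "cells") rep(1, nrow(meta)) else {
    if (!"frequency" %in% names(meta)) {
      stop("clonotype_frequency weighting needs a frequency column; ",
           "run joinExpression() first", call. = FALSE)
    }
    ifelse(is.na(meta$frequency), 0, meta$frequency)
  }
  key <- interaction(lapply(axes, function(ax) as.character(meta[[ax]])),
                     drop = TRUE, sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- axes
  out$weight <- as.numeric(agg)
  out <- out[do.call(order, out[axes]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split metadata by a categorical column
#'
#' Disjoint partition of a per-cell metadata table by the levels of one
#' categorical column; the union of the subsets is the input row set. Each
#' subset can be re-counted into clonotype count vectors (see
#' [metaCountVector()]) so every repertoire statistic runs per metadata
#' level, for example per expression cluster.
#'
#' @param meta Per-cell metadata.
#' @param column Name of a categorical (character/factor/logical) column.
#' @return Named list of `data.frame` subsets, one per level.
#' @export
splitByMetadata <- function(meta, column) {
  if (!column %in% names(meta)) {
    stop("metadata has no column '", column, "'", call. = FALSE)
  }
  vals <- meta[[column]]
  if (is.numeric(vals)) {
    stop("column '", column, "' is numeric, not categorical; ",
         "discretise it first", call. = FALSE)
  }
  split(meta, as.character(vals))
}

#' Count clonotypes within a metadata subset
#'
#' Tabulates the `clonotype_key` column of joined metadata into a count
#' vector, so the diversity/overlap statistics apply to any metadata
#' partition (cells without a receptor call are ignored).
#'
#' @param meta Metadata joined by [joinExpression()] (or a subset of it).
#' @param keyCol Column holding the clonotype key.
#' @return Named integer count vector.
#' @export
metaCountVector <- function(meta, keyCol = "clonotype_key") {
  if (!keyCol %in% names(meta)) {
    stop("metadata has no column '", keyCol, "'", call. = FALSE)
  }
  keys <- meta[[keyCol]]
  keys <- keys[!is.na(keys)]
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}
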