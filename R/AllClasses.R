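#' @import methods
NULL

#' ContigFilter class
#'
#' Predicate set for [filterContigs()]; construct with [contigFilter()].
#'
#' @slot productive logical; require productive rearrangements.
#' @slot highConfidence logical; require the high-confidence flag.
#' @slot isCell logical; require the called-cell flag.
#' @slot minUMIs numeric; minimum UMIs per contig.
#' @slot chains character; loci to retain (non-empty).
#' @exportClass ContigFilter
setClass("ContigFilter",
  representation(productive = "logical", highConfidence = "logical",
                 isCell = "logical", minUMIs = "numeric",
                 chains = "character"),
  prototype(productive = TRUE, highConfidence = TRUE, isCell = TRUE,
            minUMIs = 1, chains = c("TRA", "TRB")))

setValidity("ContigFilter", function(object) {
  msg <- character(0)
  if (length(object@chains) == 0) {
    msg <- c(msg, "allowed chains must be non-empty")
  }
  bad <- setdiff(object@chains, .LOCI)
  if (length(bad)) {
    msg <- c(msg, paste0("unknown chain(s): ", paste(bad, collapse = ", ")))
  }
  if (length(object@minUMIs) != 1 || object@minUMIs < 0) {
    msg <- c(msg, "minUMIs must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContigFilter", function(object) {
  cat("ContigFilter:",
      if (object@productive) "productive" else NULL,
      if (object@highConfidence) "high-confidence" else NULL,
      if (object@isCell) "is-cell" else NULL,
      sprintf("umis>=%g", object@minUMIs),
      sprintf("chains={%s}\n", paste(object@chains, collapse = ",")))
})

# Columns of a per-sample clonotype table, in export order.
.CLONOTYPE_COLS <- c("barcode", "sample", "group",
                     "chain1_genes", "cdr3_nt1", "cdr3_aa1",
                     "chain2_genes", "cdr3_nt2", "cdr3_aa2",
                     "CTgene", "CTnt", "CTaa", "CTstrict")

#' RepertoireSet class
#'
#' Named collection of per-sample clonotype tables, the central container of
#' the package. Each table holds one row per cell with the paired-chain
#' fields and the four clonotype identifier strings (`CTgene`, `CTnt`,
#' `CTaa`, `CTstrict`). Constructed by [combineReceptors()].
#'
#' @slot samples named list of per-sample clonotype `data.frame`s.
#' @slot sampleData `data.frame` with columns `sample` and `group`, one row
#'   per sample, in the order of `samples`.
#' @seealso [combineReceptors()], [countClonotypes()], [clonalDiversity()]
#' @exportClass RepertoireSet
setClass("RepertoireSet",
  representation(samples = "list", sampleData = "data.frame"))

setValidity("RepertoireSet", function(object) {
  msg <- character(0)
  nm <- names(object@samples)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    msg <- c(msg, "sample tables must have unique non-empty names")
  }
  if (!identical(sort(c("sample", "group")),
                 sort(intersect(c("sample", "group"),
                                names(object@sampleData)))) ||
      nrow(object@sampleData) != length(object@samples)) {
    msg <- c(msg, "sampleData must have columns sample, group and one row per sample")
  } else if (!identical(as.character(object@sampleData$sample), nm)) {
    msg <- c(msg, "sampleData$sample must match the sample table names in order")
  }
  for (s in nm) {
    tab <- object@samples[[s]]
    if (!is.data.frame(tab) ||
        !all(.CLONOTYPE_COLS %in% names(tab))) {
      msg <- c(msg, paste0("sample '", s, "' is not a clonotype table"))
      next
    }
    if (anyDuplicated(tab$barcode)) {
      msg <- c(msg, paste0("duplicated barcodes in sample '", s, "'"))
    }
    if (nrow(tab) && !all(tab$sample == s)) {
      msg <- c(msg, paste0("sample column mismatch in '", s, "'"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RepertoireSet-class number of samples.
#' @param x A `RepertoireSet`.
#' @export
setMethod("length", "RepertoireSet", function(x) length(x@samples))

#' Sample names of a RepertoireSet
#' @param x A `RepertoireSet`.
#' @return Character vector of sample names.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "RepertoireSet", function(x) names(x@samples))

#' Group labels of a RepertoireSet
#' @param x A `RepertoireSet`.
#' @return Named character vector mapping sample to group (`NA` when no
#'   groups were supplied).
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "RepertoireSet", function(x) {
  stats::setNames(as.character(x@sampleData$group), names(x@samples))
})

#' Per-sample clonotype tables
#' @param x A `RepertoireSet`.
#' @return Named list of clonotype `data.frame`s.
#' @export
setGeneric("clonotypeTables", function(x) standardGeneric("clonotypeTables"))

#' @rdname clonotypeTables
#' @export
setMethod("clonotypeTables", "RepertoireSet", function(x) x@samples)

#' @describeIn RepertoireSet-class extract one sample's clonotype table.
#' @param i Sample name or index.
#' @export
setMethod("[[", "RepertoireSet", function(x, i) x@samples[[i]])

setMethod("show", "RepertoireSet", function(object) {
  n <- vapply(object@samples, nrow, integer(1))
  cat("RepertoireSet with", length(object@samples), "sample(s),",
      sum(n), "cells\n")
  grp <- as.character(object@sampleData$group)
  for (k in seq_along(n)) {
    cat(sprintf("  %s%s: %d cells\n", names(n)[k],
                if (is.na(grp[k])) "" else paste0(" (", grp[k], ")"), n[k]))
  }
})

#' Write per-sample clonotype tables
#'
#' Exports each sample's clonotype table as TSV with the fixed column order
#' (barcode, sample, group, chain-1 fields, chain-2 fields, CT strings).
#'
#' @param x A `RepertoireSet`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
writeClonotypes <- function(x, dir) {
  stopifnot(is(x, "RepertoireSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sampleNames(x), function(s) {
    p <- file.path(dir, paste0(s, ".clonotypes.tsv"))
    exportTable(x[[s]][, .CLONOTYPE_COLS], p)
    p
  }, character(1))
  invisible(paths)
}
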