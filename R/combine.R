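# Paired-chain clonotype calling: merging all contigs of a cell barcode
# into one clonotype record per cell.

# V(_D)_J_C gene string per contig, "." separated; missing segments are the
# literal "NA" so keys stay splittable.
.geneStrings <- function(contigs) {
  nac <- function(x) ifelse(is.na(x), "NA", x)
  withD <- contigs$chain %in% .D_LOCI
  out <- paste(nac(contigs$v_gene), nac(contigs$j_gene),
               nac(contigs$c_gene), sep = ".")
  out[withD] <- paste(nac(contigs$v_gene[withD]),
                      nac(contigs$d_gene[withD]),
                      nac(contigs$j_gene[withD]),
                      nac(contigs$c_gene[withD]), sep = ".")
  out
}

.emptyClonotypeTable <- function() {
  out <- as.data.frame(stats::setNames(
    replicate(length(.CLONOTYPE_COLS), character(0), simplify = FALSE),
    .CLONOTYPE_COLS), stringsAsFactors = FALSE)
  out
}

# One sample's contigs -> per-cell clonotype table.
#
# Retention: when a cell holds >2 contigs of one locus, keep the two with
# the highest UMI count (ties: higher reads, then lexicographic contig id).
# Retained same-locus duplicates are then *joined* with ";" in canonical
# lexicographic CDR3-nt order, so a dual-chain clone emits the same key
# from every one of its cells regardless of per-cell UMI fluctuations.
.combineOneSample <- function(contigs, s, g, prefix, locus1, locus2,
                              removeNA, removeMulti) {
  if (nrow(contigs) == 0) return(.emptyClonotypeTable())
  loc <- ifelse(contigs$chain %in% locus1, 1L, 2L)
  grp <- paste(contigs$barcode, loc, sep = "\r")

  # per-(cell, locus) retention rank by UMI support
  o1 <- order(grp, -contigs$umis, -contigs$reads, contigs$contig_id)
  runs <- rle(grp[o1])
  n_in <- rep(runs$lengths, runs$lengths)
  rank_in <- sequence(runs$lengths)
  if (removeMulti) {
    multi_bc <- unique(contigs$barcode[o1][n_in > 2])
    keep <- !(contigs$barcode[o1] %in% multi_bc) & rank_in <= 2
  } else {
    keep <- rank_in <= 2
  }
  kept <- contigs[o1[keep], , drop = FALSE]
  kgrp <- grp[o1][keep]
  if (nrow(kept) == 0) return(.emptyClonotypeTable())

  # canonical join order within (cell, locus)
  ntkey <- ifelse(is.na(kept$cdr3_nt), "", kept$cdr3_nt)
  o2 <- order(kgrp, ntkey, kept$contig_id)
  kept <- kept[o2, , drop = FALSE]
  kgrp <- kgrp[o2]

  nac <- function(x) ifelse(is.na(x), "NA", x)
  glue <- function(x) {
    vapply(split(x, kgrp), paste, character(1), collapse = ";")
  }
  genes_by <- glue(.geneStrings(kept))
  nt_by <- glue(nac(kept$cdr3_nt))
  aa_by <- glue(nac(kept$cdr3_aa))

  bc <- sort(unique(kept$barcode))
  k1 <- paste(bc, 1L, sep = "\r")
  k2 <- paste(bc, 2L, sep = "\r")
  l1g <- unname(genes_by[k1]); l2g <- unname(genes_by[k2])
  l1n <- unname(nt_by[k1]);    l2n <- unname(nt_by[k2])
  l1a <- unname(aa_by[k1]);    l2a <- unname(aa_by[k2])
  if (removeNA) {
    both <- !is.na(l1g) & !is.na(l2g)
    bc <- bc[both]
    l1g <- l1g[both]; l2g <- l2g[both]
    l1n <- l1n[both]; l2n <- l2n[both]
    l1a <- l1a[both]; l2a <- l2a[both]
  }
  if (length(bc) == 0) return(.emptyClonotypeTable())
  strict1 <- ifelse(is.na(l1g), NA, paste(l1g, l1n, sep = ":"))
  strict2 <- ifelse(is.na(l2g), NA, paste(l2g, l2n, sep = ":"))
  out <- data.frame(
    barcode = paste(prefix, bc, sep = "_"),
    sample = s, group = g,
    chain1_genes = l1g, cdr3_nt1 = l1n, cdr3_aa1 = l1a,
    chain2_genes = l2g, cdr3_nt2 = l2n, cdr3_aa2 = l2a,
    CTgene = .naJoin(l1g, l2g),
    CTnt = .naJoin(l1n, l2n),
    CTaa = .naJoin(l1a, l2a),
    CTstrict = .naJoin(strict1, strict2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Combine contigs into per-cell clonotypes
#'
#' Pairs the receptor chains of each cell barcode within each sample and
#' builds the four clonotype identifier strings: `CTgene` (gene usage),
#' `CTnt` (CDR3 nucleotide), `CTaa` (CDR3 amino acid) and `CTstrict`
#' (gene + nucleotide). In `TCR` mode locus 1 is TRA (or TRG) and locus 2
#' is TRB (or TRD); in `BCR` mode locus 1 is IGH and locus 2 is IGK/IGL.
#' Loci are joined with `"_"`, a missing chain is the literal `"NA"` (so a
#' beta-only cell reads `"NA_<beta CDR3>"`), and same-locus duplicates (for
#' example dual-alpha T cells) are joined with `";"` in lexicographic
#' CDR3-nt order. Cells with more than two contigs of one locus keep the
#' two with the highest UMI support (ties: reads, then contig id) unless
#' `removeMulti` drops the cell entirely.
#'
#' Barcodes are prefixed with the sample name (and group, when given),
#' separated by `"_"`, to guarantee global uniqueness across samples; a
#' warning is raised when input barcodes already contain the separator.
#'
#' @param contigList List of filtered contig tables (see [readContigs()],
#'   [filterContigs()]), one per sample.
#' @param samples Character vector of distinct sample names, same length as
#'   `contigList`.
#' @param groups Optional character vector of group labels per sample.
#' @param mode `"TCR"` or `"BCR"`; selects the locus-1/locus-2 convention.
#' @param removeNA Drop cells missing either locus.
#' @param removeMulti Drop cells with more than two contigs of one locus
#'   instead of trimming to the top two.
#' @return A [RepertoireSet-class] with one clonotype row per cell.
#' @examples
#' sim <- simulateRepertoire(nCells = 100, seed = 7, sampleName = "P1")
#' rep <- combineReceptors(list(sim$contigs), samples = "P1")
#' rep
#' head(rep[["P1"]]$CTaa)
#' @export
combineReceptors <- function(contigList, samples, groups = NULL,
                             mode = c("TCR", "BCR"),
                             removeNA = FALSE, removeMulti = FALSE) {
  mode <- match.arg(mode)
  if (!is.list(contigList)) contigList <- list(contigList)
  if (length(samples) != length(contigList)) {
    stop("samples must name each contig table", call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample names: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(groups) && length(groups) != length(samples)) {
    stop("groups must be NULL or one label per sample", call. = FALSE)
  }
  locus1 <- if (mode == "TCR") c("TRA", "TRG") else "IGH"
  locus2 <- if (mode == "TCR") c("TRB", "TRD") else c("IGK", "IGL")

  tabs <- vector("list", length(samples))
  names(tabs) <- samples
  for (k in seq_along(samples)) {
    contigs <- contigList[[k]]
    s <- samples[k]
    g <- if (is.null(groups)) NA_character_ else groups[k]
    contigs <- contigs[contigs$chain %in% c(locus1, locus2), , drop = FALSE]
    if (nrow(contigs) && any(grepl("_", contigs$barcode, fixed = TRUE))) {
      warning("sample '", s, "': barcodes already contain the prefix ",
              "separator '_'; prefixed barcodes may be ambiguous to split",
              call. = FALSE)
    }
    prefix <- if (is.na(g)) s else paste(g, s, sep = "_")
    tabs[[k]] <- .combineOneSample(contigs, s, g, prefix, locus1, locus2,
                                   removeNA, removeMulti)
  }
  new("RepertoireSet", samples = tabs,
      sampleData = data.frame(
        sample = samples,
        group = if (is.null(groups)) NA_character_ else groups,
        stringsAsFactors = FALSE))
}

#' Clonotype identifier of each cell
#'
#' Returns the clonotype key column of a clonotype table (or of every table
#' in a [RepertoireSet-class]): the gene-usage, CDR3-nucleotide,
#' CDR3-amino-acid or strict (gene + nucleotide) identifier. Pure and
#' deterministic — keys are constructed once by [combineReceptors()].
#'
#' @param x A clonotype `data.frame` or a `RepertoireSet`.
#' @param callBy One of `"gene"`, `"nt"`, `"aa"`, `"strict"`.
#' @return Character vector of keys (or a named list of them for a
#'   `RepertoireSet`).
#' @export
clonotypeKey <- function(x, callBy = c("aa", "gene", "nt", "strict")) {
  callBy <- match.arg(callBy)
  col <- switch(callBy, gene = "CTgene", nt = "CTnt",
                aa = "CTaa", strict = "CTstrict")
  if (is(x, "RepertoireSet")) {
    return(lapply(clonotypeTables(x), function(tab) tab[[col]]))
  }
  if (!col %in% names(x)) stop("not a clonotype table: missing ", col,
                               call. = FALSE)
  x[[col]]
}

#' Clonotype count vectors
#'
#' Tabulates clonotype keys into abundance vectors (clonotype key to number
#' of cells bearing it), the unit consumed by all diversity, overlap and
#' clonal-space statistics. Counts within each scope unit sum to that
#' unit's cell count.
#'
#' @param x A [RepertoireSet-class].
#' @param callBy Clonotype key to count by (see [clonotypeKey()]).
#' @param scope `"per_sample"` or `"per_group"` (samples pooled by their
#'   group label).
#' @return Named list of named integer vectors.
#' @examples
#' sim <- simulateRepertoire(nCells = 100, seed = 7, sampleName = "P1")
#' rep <- combineReceptors(list(sim$contigs), samples = "P1")
#' head(sort(countClonotypes(rep)$P1, decreasing = TRUE))
#' @export
countClonotypes <- function(x, callBy = "aa",
                            scope = c("per_sample", "per_group")) {
  stopifnot(is(x, "RepertoireSet"))
  scope <- match.arg(scope)
  keys <- clonotypeKey(x, callBy)
  if (scope == "per_group") {
    grp <- sampleGroups(x)
    if (all(is.na(grp))) {
      stop("per_group scope requires group labels", call. = FALSE)
    }
    keys <- lapply(split(names(keys), grp), function(ss) {
      unlist(keys[ss], use.names = FALSE)
    })
  }
  lapply(keys, function(k) {
    tab <- table(k)
    stats::setNames(as.integer(tab), names(tab))
  })
}
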