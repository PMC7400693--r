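# Clonal-architecture statistics on clonotype count vectors.

#' Default clonal-homeostasis bins
#'
#' Named upper bounds (clone proportion of the repertoire) of the
#' homeostatic classes; bins are half-open on the left and closed on the
#' right, and the final bound must be 1.
#'
#' @param edges Named numeric vector of strictly increasing upper bounds.
#' @return The validated bin vector.
#' @export
homeostasisBins <- function(edges = c(Rare = 1e-4, Small = 0.001,
                                      Medium = 0.01, Large = 0.1,
                                      Hyperexpanded = 1)) {
  if (is.null(names(edges)) || any(names(edges) == "")) {
    stop("homeostasis bins must be named", call. = FALSE)
  }
  if (any(diff(edges) <= 0) || edges[length(edges)] != 1 || any(edges <= 0)) {
    stop("bin bounds must be strictly increasing proportions ending at 1",
         call. = FALSE)
  }
  edges
}

#' Unique-clonotype quantification
#'
#' Number of distinct clonotypes in a repertoire, optionally scaled to the
#' library size as a percentage (100 x unique / total cells). The scaled
#' value lies in (0, 100] and equals 100 exactly when every clonotype is a
#' singleton.
#'
#' @param cv Named count vector (see [countClonotypes()]).
#' @param scaled Report `100 * unique / total` instead of the raw count.
#' @return List with elements `unique`, `total` and `value`.
#' @examples
#' quantifyUnique(c(A = 5, B = 3, C = 2), scaled = TRUE)  # value 30
#' @export
quantifyUnique <- function(cv, scaled = FALSE) {
  .checkCountVector(cv)
  u <- length(cv)
  total <- sum(cv)
  list(unique = u, total = total,
       value = if (scaled) 100 * u / total else u)
}

#' Clonotype abundance table
#'
#' One row per clonotype with its cell count and relative proportion,
#' sorted by descending count with lexicographic key tie-break. Proportions
#' form a probability distribution (sum 1 within 1e-12).
#'
#' @param cv Named count vector.
#' @return `data.frame` with columns `clonotype`, `count`, `proportion`.
#' @export
abundanceTable <- function(cv) {
  .checkCountVector(cv, allow_empty = TRUE)
  if (length(cv) == 0) {
    return(data.frame(clonotype = character(0), count = numeric(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  }
  ord <- order(-cv, names(cv))
  cv <- cv[ord]
  data.frame(clonotype = names(cv), count = as.numeric(cv),
             proportion = as.numeric(cv) / sum(cv),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Lengths of the CDR3 sequences inside a CT string: split on the locus
# separator "_" and the duplicate separator ";", drop "NA" placeholders.
.ctSeqLengths <- function(ct) {
  parts <- strsplit(ct, "[_;]")
  vapply(parts, function(p) sum(nchar(p[p != "NA"])), numeric(1))
}

#' CDR3 length distribution
#'
#' Sequence-length table for the CDR3 regions of a repertoire, by
#' nucleotide or amino acid. With `perChain = TRUE` each non-missing chain
#' CDR3 contributes one row; otherwise each cell contributes the combined
#' length of its clonotype string, counting only real sequence — the `"_"`
#' separator and the `"NA"` missing-chain placeholder contribute zero, so a
#' beta-only cell's combined length is the beta CDR3 length alone. Mixing
#' single-chain and dual-chain cells makes the combined distribution
#' bimodal.
#'
#' @param x A [RepertoireSet-class].
#' @param callBy `"aa"` or `"nt"`.
#' @param perChain One row per chain CDR3 instead of per cell.
#' @return `data.frame` with columns `sample`, `sequence`, `length` (and
#'   `chain` when `perChain`).
#' @export
cdr3Lengths <- function(x, callBy = c("aa", "nt"), perChain = FALSE) {
  stopifnot(is(x, "RepertoireSet"))
  callBy <- match.arg(callBy)
  out <- lapply(sampleNames(x), function(s) {
    tab <- x[[s]]
    if (nrow(tab) == 0) return(NULL)
    if (perChain) {
      cols <- if (callBy == "aa") c("cdr3_aa1", "cdr3_aa2") else
                                  c("cdr3_nt1", "cdr3_nt2")
      res <- lapply(seq_along(cols), function(i) {
        seqs <- unlist(strsplit(tab[[cols[i]]][!is.na(tab[[cols[i]]])], ";"))
        seqs <- seqs[seqs != "NA"]
        if (!length(seqs)) return(NULL)
        data.frame(sample = s, chain = paste0("locus", i), sequence = seqs,
                   length = nchar(seqs), stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    } else {
      ct <- if (callBy == "aa") tab$CTaa else tab$CTnt
      data.frame(sample = s, sequence = ct, length = .ctSeqLengths(ct),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(sample = character(0),
                                      sequence = character(0),
                                      length = numeric(0))
  rownames(out) <- NULL
  out
}

.homeostasisOne <- function(cv, bins) {
  .checkCountVector(cv)
  p <- cv / sum(cv)
  idx <- cut(p, breaks = c(0, bins), labels = names(bins), right = TRUE)
  occ <- tapply(p, idx, sum, default = 0)
  stats::setNames(as.numeric(occ[names(bins)]), names(bins))
}

#' Clonal homeostasis
#'
#' Partition of clonal space by clone-proportion class: each clonotype's
#' repertoire proportion p falls in the first bin with p <= upper bound
#' (half-open on the left, closed on the right), and the bin value is the
#' summed proportion of its member clones. Values sum to 1 for every
#' non-empty repertoire.
#'
#' @param x A [RepertoireSet-class], a named list of count vectors, or a
#'   single count vector.
#' @param bins Named bin bounds, see [homeostasisBins()].
#' @param callBy Clonotype key used when `x` is a `RepertoireSet`.
#' @param ... Unused.
#' @return For a single count vector, a named numeric vector of clonal-space
#'   occupancies; otherwise a `data.frame` with columns `sample`, `bin`,
#'   `occupancy`.
#' @examples
#' clonalHomeostasis(c(A = 60, B = 30, C = 10))
#' @export
setGeneric("clonalHomeostasis",
           function(x, bins = homeostasisBins(), callBy = "aa", ...)
             standardGeneric("clonalHomeostasis"))

#' @rdname clonalHomeostasis
#' @export
setMethod("clonalHomeostasis", "numeric",
  function(x, bins = homeostasisBins(), callBy = "aa", ...) {
    .homeostasisOne(x, homeostasisBins(bins))
  })

#' @rdname clonalHomeostasis
#' @export
setMethod("clonalHomeostasis", "ANY",
  function(x, bins = homeostasisBins(), callBy = "aa", ...) {
    bins <- homeostasisBins(bins)
    cvs <- .asCountList(x, callBy)
    res <- lapply(names(cvs), function(s) {
      occ <- .homeostasisOne(cvs[[s]], bins)
      data.frame(sample = s, bin = names(occ), occupancy = as.numeric(occ),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$bin <- factor(out$bin, levels = names(bins), ordered = TRUE)
    rownames(out) <- NULL
    out
  })

.proportionOne <- function(cv, split) {
  .checkCountVector(cv, allow_empty = TRUE)
  split <- as.integer(split)
  if (any(split <= 0) || any(diff(split) <= 0)) {
    stop("split must be strictly increasing positive ranks", call. = FALSE)
  }
  lo <- c(1L, utils::head(split, -1) + 1L)
  labels <- sprintf("[%d:%d]", lo, split)
  if (length(cv) == 0) return(stats::setNames(numeric(length(split)), labels))
  ord <- order(-cv, names(cv))
  ranks <- seq_along(cv)
  bin <- findInterval(ranks, c(lo, split[length(split)] + 1L),
                      left.open = FALSE)
  occ <- vapply(seq_along(split), function(b) sum(cv[ord][bin == b]),
                numeric(1))
  stats::setNames(occ, labels)
}

#' Clonal proportion (rank occupancy)
#'
#' Cell counts occupied by clonotype rank ranges: clonotypes are ranked by
#' descending count (lexicographic tie-break) and the counts of ranks 1-10,
#' 11-100, ... are summed per range. Range sums add up to the repertoire's
#' total cell count; clones ranked beyond the last bound are not counted.
#'
#' @param x A [RepertoireSet-class], a named list of count vectors, or a
#'   single count vector.
#' @param split Strictly increasing rank upper bounds.
#' @param callBy Clonotype key used when `x` is a `RepertoireSet`.
#' @param ... Unused.
#' @return For a single count vector, a named numeric vector of counts per
#'   rank range; otherwise a `data.frame` (`sample`, `ranks`, `count`).
#' @examples
#' clonalProportion(c(A = 50, B = 20, C = 10, D = 10, E = 10))
#' @export
setGeneric("clonalProportion",
           function(x, split = c(10, 100, 1000, 10000, 30000, 1e5),
                    callBy = "aa", ...)
             standardGeneric("clonalProportion"))

#' @rdname clonalProportion
#' @export
setMethod("clonalProportion", "numeric",
  function(x, split = c(10, 100, 1000, 10000, 30000, 1e5),
           callBy = "aa", ...) {
    .proportionOne(x, split)
  })

#' @rdname clonalProportion
#' @export
setMethod("clonalProportion", "ANY",
  function(x, split = c(10, 100, 1000, 10000, 30000, 1e5),
           callBy = "aa", ...) {
    cvs <- .asCountList(x, callBy)
    res <- lapply(names(cvs), function(s) {
      occ <- .proportionOne(cvs[[s]], split)
      data.frame(sample = s, ranks = names(occ), count = as.numeric(occ),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$ranks <- factor(out$ranks, levels = names(.proportionOne(c(a = 1),
                                                                 split)),
                        ordered = TRUE)
    rownames(out) <- NULL
    out
  })

#' Per-sample unique-clonotype table
#'
#' [quantifyUnique()] applied across a repertoire collection; the tabular
#' equivalent of plotting scaled unique clonotypes per sample.
#'
#' @param x A [RepertoireSet-class] or named list of count vectors.
#' @param callBy Clonotype key (see [clonotypeKey()]).
#' @param scaled Report percentages of library size.
#' @return `data.frame` with columns `sample`, `unique`, `total`, `value`.
#' @export
clonalQuant <- function(x, callBy = "aa", scaled = FALSE) {
  cvs <- .asCountList(x, callBy)
  out <- do.call(rbind, lapply(names(cvs), function(s) {
    q <- quantifyUnique(cvs[[s]], scaled = scaled)
    data.frame(sample = s, unique = q$unique, total = q$total,
               value = q$value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample clonotype abundance table
#'
#' [abundanceTable()] applied across a repertoire collection.
#'
#' @inheritParams clonalQuant
#' @return `data.frame` with columns `sample`, `clonotype`, `count`,
#'   `proportion`.
#' @export
clonalAbundance <- function(x, callBy = "aa") {
  cvs <- .asCountList(x, callBy)
  out <- do.call(rbind, lapply(names(cvs), function(s) {
    tab <- abundanceTable(cvs[[s]])
    if (nrow(tab) == 0) return(NULL)
    cbind(data.frame(sample = s, stringsAsFactors = FALSE), tab)
  }))
  if (is.null(out)) out <- data.frame(sample = character(0),
                                      clonotype = character(0),
                                      count = numeric(0),
                                      proportion = numeric(0))
  rownames(out) <- NULL
  out
}

#' Export a result table as TSV
#'
#' Every metric in the package returns a plain table; this writes it as
#' tab-separated text (matrices keep their row names as a leading column).
#'
#' @param x `data.frame` or matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportTable <- function(x, file) {
  if (is.matrix(x)) {
    df <- data.frame(name = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(x, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
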