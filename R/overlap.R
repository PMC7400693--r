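# Between-sample repertoire comparison: overlap coefficients and
# Jensen-Shannon clustering of clone-size distributions.

#' Overlap coefficient of two repertoires
#'
#' |A intersect B| / min(|A|, |B|) on the clonotype key sets: 1 when one
#' repertoire's clonotypes are a subset of the other's, 0 when disjoint.
#' Abundance-blind; see [morisitaIndex()] for the abundance-weighted
#' alternative.
#'
#' @param a,b Named count vectors (see [countClonotypes()]); non-empty.
#' @return Numeric in `[0, 1]`.
#' @export
overlapCoefficient <- function(a, b) {
  .checkCountVector(a)
  .checkCountVector(b)
  shared <- length(intersect(names(a), names(b)))
  shared / min(length(a), length(b))
}

#' Morisita-Horn index of two repertoires
#'
#' Abundance-weighted similarity on relative clone abundances:
#' 2 sum x_i y_i / ((sum x_i^2 / X^2 + sum y_i^2 / Y^2) X Y), summed over
#' the union of clonotype keys with absent counts taken as 0. Equals 1 for
#' identical compositions and 0 for disjoint repertoires. This is the Horn
#' variant of the Morisita index: the classic form needs integer counts of
#' at least 2 per class and is undefined on singleton-heavy repertoires.
#'
#' @inheritParams overlapCoefficient
#' @return Numeric in `[0, 1]`.
#' @examples
#' morisitaIndex(c(A = 4, B = 1), c(A = 1, B = 4))  # 16/34
#' @export
morisitaIndex <- function(a, b) {
  .checkCountVector(a)
  .checkCountVector(b)
  keys <- union(names(a), names(b))
  x <- stats::setNames(numeric(length(keys)), keys)
  y <- x
  x[names(a)] <- a
  y[names(b)] <- b
  X <- sum(x); Y <- sum(y)
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Pairwise repertoire overlap matrix
#'
#' Applies [overlapCoefficient()] or [morisitaIndex()] to every sample
#' pair. The matrix is symmetric with unit diagonal.
#'
#' @param x A [RepertoireSet-class] or a named list of count vectors
#'   (at least two).
#' @param method `"morisita"` or `"overlap_coefficient"`.
#' @param callBy Clonotype key used when `x` is a `RepertoireSet`.
#' @param ... Unused.
#' @return Symmetric numeric matrix with sample names as dimnames.
#' @export
setGeneric("clonalOverlap",
           function(x, method = c("morisita", "overlap_coefficient"),
                    callBy = "aa", ...)
             standardGeneric("clonalOverlap"))

#' @rdname clonalOverlap
#' @export
setMethod("clonalOverlap", "ANY",
  function(x, method = c("morisita", "overlap_coefficient"),
           callBy = "aa", ...) {
    method <- match.arg(method)
    cvs <- .asCountList(x, callBy)
    if (length(cvs) < 2) stop("need at least two samples", call. = FALSE)
    fun <- if (method == "morisita") morisitaIndex else overlapCoefficient
    n <- length(cvs)
    m <- diag(1, n)
    dimnames(m) <- list(names(cvs), names(cvs))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- fun(cvs[[i]], cvs[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
    m
  })

#' Jensen-Shannon divergence of two distributions
#'
#' JSD(P, Q) = KL(P||M)/2 + KL(Q||M)/2 with M = (P + Q)/2, logarithms base
#' 2 so the value lies in `[0, 1]`: 0 for identical distributions, 1 for
#' disjoint support. Terms with p = 0 contribute 0. Inputs are normalised
#' to probability vectors; the two vectors are aligned positionally.
#'
#' @param p,q Non-negative numeric vectors of equal length, each with a
#'   positive sum.
#' @return Numeric in `[0, 1]` (bits).
#' @examples
#' jsDivergence(c(1, 0), c(0.5, 0.5))  # ~0.3113
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must align", call. = FALSE)
  if (any(p < 0) || any(q < 0) || sum(p) <= 0 || sum(q) <= 0) {
    stop("p and q must be non-negative with positive sums", call. = FALSE)
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# Clone-size distribution of one repertoire over shared log-spaced size
# bins: the fraction of clones falling in each size class.
.cloneSizeHist <- function(cv, breaks) {
  h <- graphics::hist(log(cv), breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts)
}

#' Clone-size distribution clustering by Jensen-Shannon divergence
#'
#' Summarises each repertoire by its clone-size distribution (fraction of
#' clonotypes per size class, on log-spaced bins spanning the pooled size
#' range of all samples), computes the pairwise Jensen-Shannon divergence
#' matrix (base 2, so values lie in `[0, 1]`), and clusters the samples by
#' average-linkage hierarchical clustering of that matrix. Sample order is
#' made alphabetical before clustering so leaf order is deterministic.
#'
#' @param x A [RepertoireSet-class] or a named list of count vectors (at
#'   least two).
#' @param nBins Number of log-spaced clone-size bins (>= 2; default 30).
#' @param callBy Clonotype key used when `x` is a `RepertoireSet`.
#' @param ... Unused.
#' @return List with `jsd` (symmetric divergence matrix), `sizeDist`
#'   (samples x bins probability matrix) and `dendrogram` (an
#'   [stats::hclust] tree; export as Newick with [exportDendrogram()]).
#' @export
setGeneric("cloneSizeDistribution",
           function(x, nBins = 30, callBy = "aa", ...)
             standardGeneric("cloneSizeDistribution"))

#' @rdname cloneSizeDistribution
#' @export
setMethod("cloneSizeDistribution", "ANY",
  function(x, nBins = 30, callBy = "aa", ...) {
    cvs <- .asCountList(x, callBy)
    if (length(cvs) < 2) stop("need at least two samples", call. = FALSE)
    if (nBins < 2) stop("nBins must be >= 2", call. = FALSE)
    cvs <- cvs[order(names(cvs))]
    for (s in names(cvs)) .checkCountVector(cvs[[s]])
    sizes <- unlist(cvs, use.names = FALSE)
    lo <- log(min(sizes))
    hi <- log(max(sizes))
    if (hi <= lo) hi <- lo + 1e-9
    breaks <- seq(lo - 1e-9, hi + 1e-9, length.out = nBins + 1)
    dist_mat <- t(vapply(cvs, .cloneSizeHist, numeric(nBins),
                         breaks = breaks))
    n <- length(cvs)
    jsd <- matrix(0, n, n, dimnames = list(names(cvs), names(cvs)))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- jsDivergence(dist_mat[i, ], dist_mat[j, ])
        jsd[i, j] <- v
        jsd[j, i] <- v
      }
    }
    hc <- stats::hclust(stats::as.dist(jsd), method = "average")
    list(jsd = jsd, sizeDist = dist_mat, dendrogram = hc)
  })

#' Export a dendrogram as Newick
#'
#' Writes an [stats::hclust] tree (for example the clone-size clustering of
#' [cloneSizeDistribution()]) as a Newick file.
#'
#' @param hc An `hclust` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportDendrogram <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}
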