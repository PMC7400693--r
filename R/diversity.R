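# Repertoire diversity estimators on clonotype count vectors.
#
# All four indices are invariant under clonotype relabeling and are the
# standard ecology estimators applied to clone abundances: cells are the
# individuals, clonotypes the species.

#' Shannon diversity index
#'
#' H = -sum p_i log p_i with p_i the clone proportions, natural logarithm
#' (nats). Zero for a monoclonal repertoire; ln(k) for k equally sized
#' clones. Divide by `log(2)` for bits.
#'
#' @param cv Named count vector (see [countClonotypes()]); must be
#'   non-empty.
#' @return Non-negative numeric scalar.
#' @examples
#' shannonIndex(c(A = 5, B = 3, C = 2))  # ~1.0297
#' @export
shannonIndex <- function(cv) {
  .checkCountVector(cv)
  p <- cv / sum(cv)
  -sum(p * log(p))
}

#' Inverse Simpson index
#'
#' 1 / sum p_i^2: the effective number of clones under the Simpson
#' concentration. Equals 1 for a monoclonal repertoire and k for k equal
#' clones; never exceeds the observed richness.
#'
#' @inheritParams shannonIndex
#' @return Numeric scalar >= 1.
#' @export
inverseSimpson <- function(cv) {
  .checkCountVector(cv)
  p <- cv / sum(cv)
  1 / sum(p^2)
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and
#' F2 are the numbers of clonotypes seen exactly once and twice. The
#' bias-corrected form stays defined when no doubletons exist (the classic
#' F1^2 / (2 F2) form does not). Always at least the observed richness.
#'
#' @inheritParams shannonIndex
#' @return Numeric scalar >= observed richness.
#' @examples
#' chao1Richness(c(a = 1, b = 1, c = 2, d = 3))  # 4.5
#' @export
chao1Richness <- function(cv) {
  .checkCountVector(cv)
  f1 <- sum(cv == 1)
  f2 <- sum(cv == 2)
  length(cv) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. Clones with count <= `rareThreshold`
#' form the rare class (S_rare clones, N_rare cells, F1 singletons); sample
#' coverage is C = 1 - F1 / N_rare and the rare-class coefficient of
#' variation is gamma^2 = max(S_rare / C * sum_i i(i-1) F_i /
#' (N_rare (N_rare - 1)) - 1, 0). ACE = S_abund + S_rare / C +
#' F1 gamma^2 / C. When every rare clone is a singleton the coverage is
#' zero and the estimator falls back to [chao1Richness()].
#'
#' @inheritParams shannonIndex
#' @param rareThreshold Count ceiling of the rare class (default 10, the
#'   conventional choice).
#' @return Numeric scalar >= the number of abundant clonotypes.
#' @examples
#' aceRichness(c(a = 1, b = 1, c = 2, d = 3))  # ~5.787
#' @export
aceRichness <- function(cv, rareThreshold = 10) {
  .checkCountVector(cv)
  rare <- cv[cv <= rareThreshold]
  s_abund <- sum(cv > rareThreshold)
  if (length(rare) == 0) return(s_abund)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1Richness(cv))
  i <- seq_len(rareThreshold)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1,
        0)
  } else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Repertoire diversity table
#'
#' All four diversity estimators per sample (or per group when counts were
#' pooled by group): Shannon (nats), inverse Simpson, bias-corrected Chao1
#' and ACE, plus the observed richness and library size.
#'
#' @param x A [RepertoireSet-class] or a named list of count vectors.
#' @param callBy Clonotype key used when `x` is a `RepertoireSet`.
#' @param scope `"per_sample"` or `"per_group"`.
#' @param rareThreshold ACE rare-class ceiling, see [aceRichness()].
#' @param ... Unused.
#' @return `data.frame` with columns `sample`, `cells`, `richness`,
#'   `shannon`, `inv_simpson`, `chao1`, `ace`.
#' @examples
#' sim <- simulateRepertoire(nCells = 200, seed = 3, sampleName = "S1")
#' rep <- combineReceptors(list(sim$contigs), samples = "S1")
#' clonalDiversity(rep)
#' @export
setGeneric("clonalDiversity",
           function(x, callBy = "aa", scope = "per_sample",
                    rareThreshold = 10, ...)
             standardGeneric("clonalDiversity"))

#' @rdname clonalDiversity
#' @export
setMethod("clonalDiversity", "ANY",
  function(x, callBy = "aa", scope = "per_sample", rareThreshold = 10, ...) {
    cvs <- .asCountList(x, callBy, scope)
    out <- do.call(rbind, lapply(names(cvs), function(s) {
      cv <- cvs[[s]]
      data.frame(sample = s, cells = sum(cv), richness = length(cv),
                 shannon = shannonIndex(cv),
                 inv_simpson = inverseSimpson(cv),
                 chao1 = chao1Richness(cv),
                 ace = aceRichness(cv, rareThreshold),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
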