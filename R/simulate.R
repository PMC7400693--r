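# Seeded synthetic-repertoire generator with planted clonal ground truth.
# Strings are schema-valid, not biologically recombined: CDR3 nucleotide
# sequences are random in-frame sense-codon strings and amino-acid fields
# are their standard-genetic-code translation, so parser, pairing and
# recovery logic are testable without any real V(D)J junction model.

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

# Random in-frame CDR3s: nt length 24-60 in steps of 3 (aa length 8-20,
# peaked near 14, the range observed in real repertoires).
.randomCdr3 <- function(n) {
  len_aa <- sample(8:20, n, replace = TRUE,
                   prob = stats::dnorm(8:20, mean = 14, sd = 2.5))
  codons <- sample(.SENSE_CODONS, sum(len_aa), replace = TRUE)
  grp <- rep(seq_len(n), times = len_aa)
  vapply(split(codons, grp), paste, character(1), collapse = "")
}

.translateNT <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

.drawCloneSizes <- function(nCells, model, exponent, meanlog, sdlog) {
  sizes <- integer(0)
  while (sum(sizes) < nCells) {
    draw <- switch(model,
      power_law = {
        u <- stats::runif(256)
        pmax(1L, as.integer(floor(u^(-1 / (exponent - 1)))))
      },
      lognormal = pmax(1L, as.integer(floor(stats::rlnorm(256, meanlog,
                                                          sdlog)))),
      uniform = sample.int(10L, 256, replace = TRUE))
    sizes <- c(sizes, draw)
  }
  cs <- cumsum(sizes)
  k <- which(cs >= nCells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cs[k] - nCells)
  sizes[sizes > 0]
}

.randomBarcodes <- function(n) {
  repeat {
    mat <- matrix(sample(c("A", "C", "G", "T"), 16 * n, replace = TRUE),
                  nrow = n)
    bc <- paste0(apply(mat, 1, paste, collapse = ""), "-1")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate a single-cell TCR repertoire with planted ground truth
#'
#' Generates one sample's contig annotation table (canonical schema,
#' writable in either dialect with [writeContigs()]) together with the
#' planted truth per cell. Clone sizes are drawn from the chosen model and
#' trimmed to exactly `nCells` cells. Every clone has one beta chain; with
#' probability `dualAlphaRate` a clone carries two alpha chains (the
#' dual-alpha T-cell phenotype, a clone-level property shared by all its
#' cells). Per cell, each locus's contigs are dropped independently with
#' probability `chainDropoutRate`, and with probability `multiContigRate` a
#' dual-alpha cell emits a third, strictly lowest-UMI alpha contig (the
#' more-than-two-contigs artifact trimmed by [combineReceptors()]). UMI
#' counts are at least 2 for genuine contigs (artifact contigs get 1) so
#' default filters keep everything. Fully reproducible from `seed`.
#'
#' @param nCells Positive number of cells.
#' @param cloneSizeModel `"power_law"`, `"lognormal"` or `"uniform"`.
#' @param exponent Power-law exponent (> 1; default 2.5).
#' @param meanlog,sdlog Lognormal parameters.
#' @param dualAlphaRate Probability a clone carries two alpha chains.
#' @param chainDropoutRate Per-locus, per-cell dropout probability.
#' @param multiContigRate Probability of the extra-contig artifact.
#' @param cloneSizes Optional explicit integer clone sizes (must sum to
#'   `nCells`); overrides the model.
#' @param seed Integer seed; all randomness derives from it.
#' @param sampleName Sample label stored in the returned list.
#' @return List with `contigs` (canonical contig table), `truth`
#'   (`data.frame`: `barcode`, `clone_id`, `clone_size`, `n_alpha`,
#'   `CTaa`, `CTnt` — the planted per-cell clonotype strings before any
#'   dropout) and `sample` (the sample name).
#' @examples
#' sim <- simulateRepertoire(nCells = 60, cloneSizes = c(30, 20, 10),
#'                           seed = 42, sampleName = "S1")
#' table(sim$truth$clone_id)
#' @export
simulateRepertoire <- function(nCells,
                               cloneSizeModel = c("power_law", "lognormal",
                                                  "uniform"),
                               exponent = 2.5, meanlog = 0.5, sdlog = 1,
                               dualAlphaRate = 0.1,
                               chainDropoutRate = 0.05,
                               multiContigRate = 0.02,
                               cloneSizes = NULL,
                               seed = 1, sampleName = "sample1") {
  cloneSizeModel <- match.arg(cloneSizeModel)
  if (length(nCells) != 1 || nCells < 1) {
    stop("nCells must be a positive integer", call. = FALSE)
  }
  for (p in c(dualAlphaRate, chainDropoutRate, multiContigRate)) {
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (cloneSizeModel == "power_law" && exponent <= 1) {
    stop("power-law exponent must exceed 1", call. = FALSE)
  }
  nCells <- as.integer(nCells)
  set.seed(seed)
  sizes <- if (is.null(cloneSizes)) {
    .drawCloneSizes(nCells, cloneSizeModel, exponent, meanlog, sdlog)
  } else {
    cloneSizes <- as.integer(cloneSizes)
    if (sum(cloneSizes) != nCells || any(cloneSizes < 1)) {
      stop("cloneSizes must be positive and sum to nCells", call. = FALSE)
    }
    cloneSizes
  }
  nClones <- length(sizes)

  trav <- paste0("TRAV", 1:40)
  traj <- paste0("TRAJ", 1:50)

  # clone-level receptor definitions, dual alphas in canonical
  # lexicographic CDR3-nt order
  dual <- stats::runif(nClones) < dualAlphaRate
  n_alpha <- ifelse(dual, 2L, 1L)
  a1_nt <- .randomCdr3(nClones)
  a2_nt <- .randomCdr3(nClones)
  while (any(dual & a1_nt == a2_nt)) {
    redo <- dual & a1_nt == a2_nt
    a2_nt[redo] <- .randomCdr3(sum(redo))
  }
  swap <- dual & a2_nt < a1_nt
  tmp <- a1_nt[swap]; a1_nt[swap] <- a2_nt[swap]; a2_nt[swap] <- tmp
  beta_nt <- .randomCdr3(nClones)
  a1_aa <- .translateNT(a1_nt)
  a2_aa <- .translateNT(a2_nt)
  beta_aa <- .translateNT(beta_nt)
  a1_v <- sample(trav, nClones, replace = TRUE)
  a1_j <- sample(traj, nClones, replace = TRUE)
  a2_v <- sample(trav, nClones, replace = TRUE)
  a2_j <- sample(traj, nClones, replace = TRUE)
  beta_v <- sample(paste0("TRBV", 1:30), nClones, replace = TRUE)
  beta_d <- sample(paste0("TRBD", 1:2), nClones, replace = TRUE)
  beta_j <- sample(paste0("TRBJ", 1:13), nClones, replace = TRUE)
  beta_c <- sample(paste0("TRBC", 1:2), nClones, replace = TRUE)

  barcodes <- .randomBarcodes(nCells)
  cc <- rep(seq_len(nClones), times = sizes)  # clone index per cell

  keep_beta <- stats::runif(nCells) >= chainDropoutRate
  keep_alpha <- stats::runif(nCells) >= chainDropoutRate
  junk <- keep_alpha & dual[cc] & stats::runif(nCells) < multiContigRate
  junk_nt <- .randomCdr3(max(sum(junk), 1))[seq_len(sum(junk))]
  junk_aa <- if (sum(junk)) .translateNT(junk_nt) else character(0)

  # assemble contig rows: within-cell order beta, alpha(s), artifact
  ib <- which(keep_beta)
  ia1 <- which(keep_alpha)
  ia2 <- which(keep_alpha & dual[cc])
  ij <- which(junk)
  cell <- c(ib, ia1, ia2, ij)
  rank <- c(rep(1L, length(ib)), rep(2L, length(ia1)),
            rep(3L, length(ia2)), rep(4L, length(ij)))
  chain <- c(rep("TRB", length(ib)), rep("TRA", length(ia1) +
                                           length(ia2) + length(ij)))
  v <- c(beta_v[cc[ib]], a1_v[cc[ia1]], a2_v[cc[ia2]],
         sample(trav, length(ij), replace = TRUE))
  d <- c(beta_d[cc[ib]], rep(NA_character_, length(ia1) + length(ia2) +
                               length(ij)))
  j <- c(beta_j[cc[ib]], a1_j[cc[ia1]], a2_j[cc[ia2]],
         sample(traj, length(ij), replace = TRUE))
  c_ <- c(beta_c[cc[ib]], rep("TRAC", length(ia1) + length(ia2) +
                                length(ij)))
  nt <- c(beta_nt[cc[ib]], a1_nt[cc[ia1]], a2_nt[cc[ia2]],
          junk_nt[seq_len(length(ij))])
  aa <- c(beta_aa[cc[ib]], a1_aa[cc[ia1]], a2_aa[cc[ia2]], junk_aa)
  nReal <- length(ib) + length(ia1) + length(ia2)
  umis <- c(sample(2:30, nReal, replace = TRUE), rep(1L, length(ij)))
  reads <- as.integer(umis * sample(8:40, length(umis), replace = TRUE))

  o <- order(cell, rank)
  cell <- cell[o]
  per_cell_ix <- stats::ave(cell, cell, FUN = seq_along)
  contigs <- data.frame(
    barcode = barcodes[cell],
    contig_id = sprintf("%s_contig_%d", barcodes[cell], per_cell_ix),
    chain = chain[o], v_gene = v[o], d_gene = d[o], j_gene = j[o],
    c_gene = c_[o], cdr3_nt = nt[o], cdr3_aa = aa[o],
    reads = reads[o], umis = as.integer(umis[o]),
    is_cell = TRUE, high_confidence = TRUE, productive = TRUE,
    full_length = TRUE, stringsAsFactors = FALSE)
  if (nrow(contigs) == 0) contigs <- .emptyContigs()

  alpha_aa_str <- ifelse(dual, paste(a1_aa, a2_aa, sep = ";"), a1_aa)
  alpha_nt_str <- ifelse(dual, paste(a1_nt, a2_nt, sep = ";"), a1_nt)
  truth <- data.frame(
    barcode = barcodes,
    clone_id = sprintf("clone%05d", cc),
    clone_size = sizes[cc],
    n_alpha = n_alpha[cc],
    CTaa = paste(alpha_aa_str[cc], beta_aa[cc], sep = "_"),
    CTnt = paste(alpha_nt_str[cc], beta_nt[cc], sep = "_"),
    stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth, sample = sampleName)
}

#' Simulate per-cell expression metadata
#'
#' Random cluster labels and a 2-D Gaussian-mixture embedding for a set of
#' cell barcodes, emulating the metadata exported from an expression
#' workflow (cluster assignment plus UMAP-like coordinates). Purely
#' synthetic: cluster labels carry no relation to clonotypes.
#'
#' @param barcodes Character vector of (already prefixed) cell barcodes.
#' @param nClusters Number of clusters.
#' @param seed Integer seed.
#' @param sampleType Optional per-cell categorical label (recycled), e.g.
#'   peripheral vs tumor.
#' @return `data.frame` with columns `barcode`, `cluster`, `sample_type`,
#'   `dim1`, `dim2`.
#' @export
simulateCellMeta <- function(barcodes, nClusters = 6, seed = 1,
                             sampleType = "sample") {
  set.seed(seed)
  n <- length(barcodes)
  centers <- matrix(stats::rnorm(2 * nClusters, sd = 6), ncol = 2)
  cl <- sample.int(nClusters, n, replace = TRUE)
  data.frame(
    barcode = barcodes,
    cluster = sprintf("C%d", cl),
    sample_type = rep_len(sampleType, n),
    dim1 = centers[cl, 1] + stats::rnorm(n),
    dim2 = centers[cl, 2] + stats::rnorm(n),
    stringsAsFactors = FALSE)
}
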