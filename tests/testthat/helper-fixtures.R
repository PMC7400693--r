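# Fixture builders shared across test files. Everything is generated in
# code; no binary or stored data.

# One canonical contig row with sensible defaults.
contigRow <- function(barcode, chain, cdr3_nt = "TGTGCTGCT",
                      cdr3_aa = "CAA", v = "V1", d = NA_character_,
                      j = "J1", c_gene = "C1", reads = 100L, umis = 5L,
                      contig_id = NULL, is_cell = TRUE,
                      high_confidence = TRUE, productive = TRUE,
                      full_length = TRUE) {
  data.frame(barcode = barcode,
             contig_id = if (is.null(contig_id))
               paste0(barcode, "_", chain, "_", umis) else contig_id,
             chain = chain, v_gene = v, d_gene = d, j_gene = j,
             c_gene = c_gene, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             reads = as.integer(reads), umis = as.integer(umis),
             is_cell = is_cell, high_confidence = high_confidence,
             productive = productive, full_length = full_length,
             stringsAsFactors = FALSE)
}

contigTable <- function(...) do.call(rbind, list(...))

# A 10x-style CSV file written from raw text lines.
writeTenxCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

tenxHeader <- paste("barcode,is_cell,contig_id,high_confidence,chain",
                    "v_gene,d_gene,j_gene,c_gene,full_length,productive",
                    "cdr3,cdr3_nt,reads,umis", sep = ",")

# Empty clonotype-call container (no cells at all).
emptyRepertoire <- function(sample = "s1") {
  f <- writeTenxCsv(tenxHeader)
  combineReceptors(list(readContigs(f, "tenx_csv")), samples = sample)
}

# Random positive count vector with named keys.
randomCountVector <- function(maxClones = 40, maxCount = 50) {
  k <- sample.int(maxClones, 1)
  stats::setNames(sample.int(maxCount, k, replace = TRUE),
                  paste0("ct", sample.int(10 * maxClones, k)))
}

# Number of well-separated modes in a length distribution: peaks of a
# kernel-density estimate at >= 20% of the maximum, at least 5 units
# apart, separated by a trough dipping below 60% of the smaller peak.
nModes <- function(len, bw = 2.5) {
  d <- stats::density(len, bw = bw)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= 0.2 * max(y)]
  if (length(pk) < 2) return(1L)
  pk <- sort(pk[order(-y[pk])][1:2])
  tr <- min(y[pk[1]:pk[2]])
  if (abs(d$x[pk[2]] - d$x[pk[1]]) >= 5 && tr <= 0.6 * min(y[pk])) 2L
  else 1L
}

# Metadata fixture with the 8/2/2/8 cluster-by-group layout.
compositionMeta <- function() {
  data.frame(
    barcode = paste0("bc", 1:20),
    cluster = rep(c("c1", "c2"), each = 10),
    group = c(rep("g1", 8), rep("g2", 2), rep("g1", 2), rep("g2", 8)),
    stringsAsFactors = FALSE)
}
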