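#' Read V(D)J contig annotations
#'
#' Parses a per-cell contig annotation table into the package's canonical
#' contig schema. Two dialects are supported and selected explicitly (never
#' sniffed): `"tenx_csv"`, the 10x Genomics Cell Ranger
#' `filtered_contig_annotations.csv`, and `"airr_tsv"`, the AIRR
#' Rearrangement tab-separated format.
#'
#' Boolean columns accept `"True"/"False"`, `"true"/"false"`,
#' `"TRUE"/"FALSE"`; Cell Ranger's tri-state `"None"` maps to `FALSE`.
#' Missing genes encoded as `"None"`, `""` or `"NA"` become `NA`. Contigs on
#' unrecognised loci parse to chain `"None"` and are retained: removing them
#' is the job of [filterContigs()], so the dropped rows stay auditable.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return A `data.frame` with one row per contig and columns
#'   `barcode`, `contig_id`, `chain`, `v_gene`, `d_gene`, `j_gene`, `c_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `reads`, `umis`, `is_cell`, `high_confidence`,
#'   `productive`, `full_length`. An empty file (header only) yields an
#'   empty table.
#' @seealso [filterContigs()], [writeContigs()], [combineReceptors()]
#' @examples
#' sim <- simulateRepertoire(nCells = 50, seed = 1, sampleName = "S1")
#' f <- tempfile(fileext = ".csv")
#' writeContigs(sim$contigs, f, dialect = "tenx_csv")
#' contigs <- readContigs(f, dialect = "tenx_csv")
#' head(contigs)
#' @export
readContigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    needed <- c("barcode", "chain", "v_gene", "j_gene", "c_gene",
                "cdr3", "cdr3_nt", "reads", "umis", "productive")
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop("tenx_csv schema error: missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (nrow(raw) == 0) return(.emptyContigs())
    out <- data.frame(
      barcode = as.character(raw$barcode),
      contig_id = if ("contig_id" %in% names(raw)) as.character(raw$contig_id)
                  else paste0(raw$barcode, "_contig_", seq_len(nrow(raw))),
      chain = .parseChain(raw$chain),
      v_gene = .parseMissing(raw$v_gene),
      d_gene = if ("d_gene" %in% names(raw)) .parseMissing(raw$d_gene)
               else NA_character_,
      j_gene = .parseMissing(raw$j_gene),
      c_gene = .parseMissing(raw$c_gene),
      cdr3_nt = .parseMissing(raw$cdr3_nt),
      cdr3_aa = .parseMissing(raw$cdr3),
      reads = as.integer(raw$reads),
      umis = as.integer(raw$umis),
      is_cell = .parseLogical(raw$is_cell, default = TRUE),
      high_confidence = .parseLogical(raw$high_confidence, default = TRUE),
      productive = .parseLogical(raw$productive, default = FALSE),
      full_length = .parseLogical(raw$full_length, default = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    needed <- c("cell_id", "locus", "v_call", "j_call",
                "junction", "junction_aa", "duplicate_count")
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stop("airr_tsv schema error: missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (nrow(raw) == 0) return(.emptyContigs())
    grab <- function(col) if (col %in% names(raw)) raw[[col]] else NULL
    out <- data.frame(
      barcode = as.character(raw$cell_id),
      contig_id = if ("sequence_id" %in% names(raw))
                    as.character(raw$sequence_id)
                  else paste0(raw$cell_id, "_contig_", seq_len(nrow(raw))),
      chain = .parseChain(raw$locus),
      v_gene = .parseMissing(raw$v_call),
      d_gene = if ("d_call" %in% names(raw)) .parseMissing(raw$d_call)
               else NA_character_,
      j_gene = .parseMissing(raw$j_call),
      c_gene = if ("c_call" %in% names(raw)) .parseMissing(raw$c_call)
               else NA_character_,
      cdr3_nt = .parseMissing(raw$junction),
      cdr3_aa = .parseMissing(raw$junction_aa),
      reads = if ("consensus_count" %in% names(raw))
                as.integer(raw$consensus_count)
              else as.integer(raw$duplicate_count),
      umis = as.integer(raw$duplicate_count),
      is_cell = .parseLogical(grab("is_cell"), default = TRUE),
      high_confidence = .parseLogical(grab("high_confidence"), default = TRUE),
      productive = .parseLogical(grab("productive"), default = TRUE),
      full_length = .parseLogical(grab("full_length"), default = TRUE),
      stringsAsFactors = FALSE
    )
    if (length(out$is_cell) == 1) out$is_cell <- rep(out$is_cell, nrow(out))
    if (length(out$high_confidence) == 1)
      out$high_confidence <- rep(out$high_confidence, nrow(out))
    if (length(out$productive) == 1)
      out$productive <- rep(out$productive, nrow(out))
    if (length(out$full_length) == 1)
      out$full_length <- rep(out$full_length, nrow(out))
  }
  out$cdr3_nt <- .sanitizeSeq(out$cdr3_nt, .NT_CHARS, "cdr3_nt")
  out$cdr3_aa <- .sanitizeSeq(out$cdr3_aa, .AA_CHARS, "cdr3_aa")
  rownames(out) <- NULL
  out
}

.emptyContigs <- function() {
  data.frame(barcode = character(0), contig_id = character(0),
             chain = character(0), v_gene = character(0),
             d_gene = character(0), j_gene = character(0),
             c_gene = character(0), cdr3_nt = character(0),
             cdr3_aa = character(0), reads = integer(0), umis = integer(0),
             is_cell = logical(0), high_confidence = logical(0),
             productive = logical(0), full_length = logical(0),
             stringsAsFactors = FALSE)
}

#' Write contig annotations
#'
#' Serialises a canonical contig table back to disk. The `tenx_csv` dialect
#' uses a fixed column order with `"True"/"False"` booleans and `"None"`
#' missing values, matching the Cell Ranger file layout; `airr_tsv` writes
#' AIRR field names plus the QC flags as extension columns so a round trip
#' through [readContigs()] reproduces the table field-for-field.
#'
#' @param contigs Contig table from [readContigs()] or
#'   [simulateRepertoire()].
#' @param path Output file path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return `path`, invisibly.
#' @export
writeContigs <- function(contigs, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  fmtBool <- function(x, style) {
    if (style == "tenx") ifelse(x, "True", "False")
    else ifelse(x, "true", "false")
  }
  fmtMiss <- function(x, miss) ifelse(is.na(x), miss, x)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = contigs$barcode,
      is_cell = fmtBool(contigs$is_cell, "tenx"),
      contig_id = contigs$contig_id,
      high_confidence = fmtBool(contigs$high_confidence, "tenx"),
      chain = contigs$chain,
      v_gene = fmtMiss(contigs$v_gene, "None"),
      d_gene = fmtMiss(contigs$d_gene, "None"),
      j_gene = fmtMiss(contigs$j_gene, "None"),
      c_gene = fmtMiss(contigs$c_gene, "None"),
      full_length = fmtBool(contigs$full_length, "tenx"),
      productive = fmtBool(contigs$productive, "tenx"),
      cdr3 = fmtMiss(contigs$cdr3_aa, "None"),
      cdr3_nt = fmtMiss(contigs$cdr3_nt, "None"),
      reads = contigs$reads,
      umis = contigs$umis,
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(
      cell_id = contigs$barcode,
      sequence_id = contigs$contig_id,
      locus = contigs$chain,
      v_call = fmtMiss(contigs$v_gene, ""),
      d_call = fmtMiss(contigs$d_gene, ""),
      j_call = fmtMiss(contigs$j_gene, ""),
      c_call = fmtMiss(contigs$c_gene, ""),
      junction = fmtMiss(contigs$cdr3_nt, ""),
      junction_aa = fmtMiss(contigs$cdr3_aa, ""),
      productive = fmtBool(contigs$productive, "airr"),
      consensus_count = contigs$reads,
      duplicate_count = contigs$umis,
      is_cell = fmtBool(contigs$is_cell, "airr"),
      high_confidence = fmtBool(contigs$high_confidence, "airr"),
      full_length = fmtBool(contigs$full_length, "airr"),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       sep = "\t")
  }
  invisible(path)
}

#' Contig quality filter
#'
#' Constructs a `ContigFilter`, the predicate set applied by
#' [filterContigs()]. The defaults reproduce the conventional single-cell
#' V(D)J cleanup: called cells only, high-confidence, productive
#' rearrangements with at least one UMI, restricted to the alpha/beta loci
#' (`TCR` mode) or the immunoglobulin loci (`BCR` mode).
#'
#' @param mode `"TCR"` (chains TRA/TRB) or `"BCR"` (IGH/IGK/IGL); sets the
#'   default `chains`.
#' @param productive Require productive rearrangements.
#' @param highConfidence Require the high-confidence flag.
#' @param isCell Require the called-cell flag.
#' @param minUMIs Minimum UMI count (deduplicated molecules) per contig.
#' @param chains Character vector of loci to keep; overrides `mode`.
#' @return A `ContigFilter` object.
#' @examples
#' contigFilter("TCR")
#' contigFilter(chains = c("TRG", "TRD"), minUMIs = 2)
#' @export
contigFilter <- function(mode = c("TCR", "BCR"), productive = TRUE,
                         highConfidence = TRUE, isCell = TRUE, minUMIs = 1,
                         chains = NULL) {
  mode <- match.arg(mode)
  if (is.null(chains)) {
    chains <- if (mode == "TCR") c("TRA", "TRB") else c("IGH", "IGK", "IGL")
  }
  new("ContigFilter", productive = productive,
      highConfidence = highConfidence, isCell = isCell,
      minUMIs = as.numeric(minUMIs), chains = chains)
}

#' Filter contig annotations
#'
#' Keeps exactly the rows satisfying every enabled predicate of a
#' [contigFilter()]. Row order is preserved; the input is not modified; an
#' empty result is legal. Filtering is idempotent, and an all-permissive
#' filter is the identity on the row set.
#'
#' @param contigs Contig table from [readContigs()].
#' @param filter A `ContigFilter`; defaults to `contigFilter("TCR")`.
#' @return The filtered contig table.
#' @export
filterContigs <- function(contigs, filter = contigFilter("TCR")) {
  stopifnot(is(filter, "ContigFilter"))
  if (nrow(contigs) == 0) return(contigs)
  keep <- rep(TRUE, nrow(contigs))
  if (filter@productive) keep <- keep & contigs$productive
  if (filter@highConfidence) keep <- keep & contigs$high_confidence
  if (filter@isCell) keep <- keep & contigs$is_cell
  keep <- keep & contigs$umis >= filter@minUMIs
  keep <- keep & contigs$chain %in% filter@chains
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
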