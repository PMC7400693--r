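# End-to-end pipeline: combine -> metrics -> diversity/overlap -> join,
# driven by a single declarative config so multi-sample runs are
# reproducible from one file. The pipeline adds no computation of its own:
# every output table is the result of the corresponding exported function.

.defaultConfig <- function() {
  list(mode = "TCR", call_by = "aa", dialect = "tenx_csv",
       filter = list(productive = TRUE, high_confidence = TRUE,
                     is_cell = TRUE, min_umis = 1),
       remove_na = FALSE, remove_multi = FALSE,
       jsd_bins = 30, seed = 1,
       metadata_path = NULL)
}

.validateConfig <- function(config) {
  defaults <- .defaultConfig()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$samples)) {
    stop("config must list samples (sample, group, contig_path)",
         call. = FALSE)
  }
  ss <- config$samples
  if (!is.data.frame(ss)) ss <- do.call(rbind, lapply(ss, as.data.frame))
  if (!all(c("sample", "contig_path") %in% names(ss))) {
    stop("sample sheet needs columns sample and contig_path", call. = FALSE)
  }
  if (!"group" %in% names(ss)) ss$group <- NA_character_
  missing <- ss$contig_path[!file.exists(as.character(ss$contig_path))]
  if (length(missing)) {
    stop("contig file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$metadata_path) &&
      !file.exists(config$metadata_path)) {
    stop("metadata file not found: ", config$metadata_path, call. = FALSE)
  }
  config$samples <- ss
  config
}

#' Run the full repertoire pipeline
#'
#' Reads and filters each sample's contigs, calls clonotypes, and writes
#' the complete set of result tables to `outdir`: per-sample clonotype
#' TSVs, unique-clonotype quantification, abundance, CDR3 length,
#' homeostasis and clonal-proportion tables, the diversity table, overlap
#' and Jensen-Shannon matrices with the Newick dendrogram, and (when a
#' metadata table is supplied) the joined per-cell metadata. A `MANIFEST`
#' file records the package version, the config hash and the seed.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Mandatory field `samples`: a table with columns `sample`, `group`
#'   (optional) and `contig_path`. Optional fields with defaults: `mode`
#'   ("TCR"), `call_by` ("aa"), `dialect` ("tenx_csv"), `filter`
#'   (productive/high_confidence/is_cell/min_umis), `remove_na`,
#'   `remove_multi`, `jsd_bins` (30), `metadata_path`, `seed`.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the `RepertoireSet`, the result tables
#'   and the output paths.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$samples)) {
      config$samples <- do.call(rbind,
        lapply(config$samples, function(s) as.data.frame(s,
                                                stringsAsFactors = FALSE)))
    }
  }
  config <- .validateConfig(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ss <- config$samples
  filt <- contigFilter(mode = config$mode,
                       productive = isTRUE(config$filter$productive),
                       highConfidence = isTRUE(config$filter$high_confidence),
                       isCell = isTRUE(config$filter$is_cell),
                       minUMIs = config$filter$min_umis)
  contigs <- lapply(as.character(ss$contig_path), function(p) {
    filterContigs(readContigs(p, dialect = config$dialect), filt)
  })
  groups <- if (all(is.na(ss$group))) NULL else as.character(ss$group)
  rep <- combineReceptors(contigs, samples = as.character(ss$sample),
                          groups = groups, mode = config$mode,
                          removeNA = isTRUE(config$remove_na),
                          removeMulti = isTRUE(config$remove_multi))
  callBy <- config$call_by

  writeClonotypes(rep, file.path(outdir, "clonotypes"))
  results <- list(
    quant = clonalQuant(rep, callBy, scaled = TRUE),
    abundance = clonalAbundance(rep, callBy),
    lengths = cdr3Lengths(rep, callBy = if (callBy %in% c("nt", "aa"))
                                          callBy else "aa"),
    homeostasis = clonalHomeostasis(rep, callBy = callBy),
    proportion = clonalProportion(rep, callBy = callBy),
    diversity = clonalDiversity(rep, callBy = callBy)
  )
  for (nm in names(results)) {
    exportTable(results[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  if (length(rep) >= 2) {
    results$overlap_morisita <- clonalOverlap(rep, "morisita", callBy)
    results$overlap_coefficient <-
      clonalOverlap(rep, "overlap_coefficient", callBy)
    csd <- cloneSizeDistribution(rep, nBins = config$jsd_bins,
                                 callBy = callBy)
    results$jsd <- csd$jsd
    exportTable(results$overlap_morisita,
                file.path(outdir, "overlap_morisita.tsv"))
    exportTable(results$overlap_coefficient,
                file.path(outdir, "overlap_coefficient.tsv"))
    exportTable(csd$jsd, file.path(outdir, "jsd_matrix.tsv"))
    exportDendrogram(csd$dendrogram,
                     file.path(outdir, "jsd_dendrogram.nwk"))
  }
  if (!is.null(config$metadata_path)) {
    meta <- utils::read.delim(config$metadata_path,
                              stringsAsFactors = FALSE)
    joined <- joinExpression(meta, rep, callBy = callBy)
    results$metadata <- joined
    exportTable(joined, file.path(outdir, "joined_metadata.tsv"))
  }

  cfg_file <- file.path(outdir, "config.yaml")
  cfg <- config
  cfg$samples <- as.list(as.data.frame(cfg$samples))
  yaml::write_yaml(cfg, cfg_file)
  manifest <- data.frame(
    package = "ClonalKit",
    version = as.character(utils::packageVersion("ClonalKit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    n_samples = length(rep),
    stringsAsFactors = FALSE)
  write.dcf(manifest, file.path(outdir, "MANIFEST"))
  invisible(list(repertoire = rep, results = results, outdir = outdir))
}
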