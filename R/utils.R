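# Internal helpers shared across modules.

# Recognised V(D)J loci. Anything else parses to "None" (kept by the reader,
# removed only by filters so users can audit what was dropped).
.LOCI <- c("TRA", "TRB", "TRG", "TRD", "IGH", "IGK", "IGL", "Multi", "None")

# Loci carrying a D segment: gene strings are V.D.J.C, others V.J.C.
.D_LOCI <- c("TRB", "TRD", "IGH")

.CALL_BY <- c("gene", "nt", "aa", "strict")

.parseChain <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !(x %in% .LOCI)] <- "None"
  x
}

# Cell Ranger's tri-state booleans: "True"/"False"/"None" in any case.
# "None" (and empty) map to FALSE; absent columns take `default`.
.parseLogical <- function(x, default = TRUE) {
  if (is.null(x)) return(default)
  if (is.logical(x)) {
    x[is.na(x)] <- FALSE
    return(x)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- lx == "true" | lx == "t"
  out[is.na(lx)] <- FALSE
  out
}

# Uniform missing-value encoding for gene/sequence fields.
.parseMissing <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "None" | x == "NA")] <- NA_character_
  x
}

.NT_CHARS <- "ACGTURYSWKMBDHVN"
.AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"

.validSeq <- function(x, alphabet) {
  ok <- grepl(sprintf("^[%s]+$", alphabet), toupper(x))
  ok | is.na(x)
}

# Sequences violating the alphabet become missing, with a single warning.
.sanitizeSeq <- function(x, alphabet, what) {
  bad <- !.validSeq(x, alphabet)
  if (any(bad)) {
    warning(sum(bad), " ", what, " value(s) contain characters outside [",
            alphabet, "] and were set to missing", call. = FALSE)
    x[bad] <- NA_character_
  }
  x
}

# "NA"-literal join used for all CT strings ("_" between loci).
.naJoin <- function(a, b, sep = "_") {
  a[is.na(a)] <- "NA"
  b[is.na(b)] <- "NA"
  paste(a, b, sep = sep)
}

.checkCountVector <- function(cv, allow_empty = FALSE) {
  if (!is.numeric(cv)) stop("count vector must be numeric", call. = FALSE)
  if (length(cv) == 0) {
    if (allow_empty) return(invisible(cv))
    stop("count vector is empty: the quantity is undefined", call. = FALSE)
  }
  if (any(!is.finite(cv)) || any(cv <= 0)) {
    stop("count vector entries must be positive and finite", call. = FALSE)
  }
  if (is.null(names(cv)) && length(cv) > 0) {
    names(cv) <- paste0("clone", seq_along(cv))
  }
  invisible(cv)
}

# Coerce the first argument of the analysis verbs to a named list of
# clonotype count vectors: RepertoireSet -> countClonotypes(); a named list
# of numeric vectors passes through.
.asCountList <- function(x, callBy = "aa", scope = "per_sample") {
  if (is(x, "RepertoireSet")) {
    return(countClonotypes(x, callBy = callBy, scope = scope))
  }
  if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) {
    if (is.null(names(x))) names(x) <- paste0("sample", seq_along(x))
    return(x)
  }
  stop("expected a RepertoireSet or a named list of count vectors",
       call. = FALSE)
}
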