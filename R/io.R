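#' @name io
#' @title Readers and writers for the pipeline's on-disk formats
#'
#' @description Count matrices are TSV with a \code{feature_id} first column
#' and sample ids in the header (an optional \code{length} column carries
#' feature lengths). circRNA calls are BED-like TSV (chrom, start, end, name,
#' bsj_reads, strand, caller) with the coordinate dialect recorded in a
#' \code{# dialect=} header comment. Sequences are FASTA. Transcript
#' annotation is a minimal TSV (transcript_id, chrom, strand, start, end;
#' 0-based half-open), with a GTF import shim mapping gene lines to spans.
#' All loaders check the object invariants and report the offending file and
#' line on malformed input.
NULL

#' @rdname io
#' @param x object to write (ExpressionMatrix, design data.frame, GRanges...).
#' @param path file path.
#' @export
writeCountMatrix <- function(x, path) {
  .assert(is(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  df <- data.frame(feature_id = rownames(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  len <- featureLengths(x)
  if (!is.null(len)) df$length <- as.numeric(len)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param layer layer tag of the values on disk.
#' @export
readCountMatrix <- function(path, layer = "counts") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert("feature_id" %in% colnames(df),
          "%s: missing feature_id column", path)
  dup <- df$feature_id[duplicated(df$feature_id)]
  .assert(length(dup) == 0L, "%s: duplicate feature ids (%s)", path,
          paste(utils::head(dup, 3), collapse = ", "))
  lengths <- NULL
  if ("length" %in% colnames(df)) {
    lengths <- setNames(df$length, df$feature_id)
    df$length <- NULL
  }
  m <- as.matrix(df[, setdiff(colnames(df), "feature_id"), drop = FALSE])
  .assert(is.numeric(m), "%s: non-numeric values", path)
  rownames(m) <- df$feature_id
  if (layer == "counts") storage.mode(m) <- "integer"
  ExpressionMatrix(m, layer = layer, feature_lengths = lengths)
}

#' @rdname io
#' @export
writeSampleDesign <- function(x, path) {
  validateSampleDesign(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSampleDesign <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validateSampleDesign(df)
  df
}

#' @rdname io
#' @param gr canonical junction GRanges.
#' @param dialect coordinate dialect to write.
#' @export
writeJunctionCalls <- function(gr, path, dialect = "bed0-half-open") {
  df <- if (is.data.frame(gr)) gr else junctionsToDialect(gr, dialect)
  dl <- attr(df, "dialect")
  .assert(!is.null(dl) && dl %in% .DIALECTS, "unknown dialect")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dialect=%s", dl), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readJunctionCalls <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*dialect=(\\S+)", first))[[1L]]
  .assert(length(m) == 2L, "%s: line 1: missing '# dialect=' header", path)
  dialect <- m[2L]
  .assert(dialect %in% .DIALECTS, "%s: line 1: unknown dialect '%s'",
          path, dialect)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "bsj_reads", "strand", "caller"))
  for (i in seq_len(nrow(df))) {
    s1 <- if (dialect == "bed0-half-open") df$start[i] + 1L else df$start[i]
    if (!df$strand[i] %in% c("+", "-")) {
      .stopf("%s: line %d: invalid strand '%s'", path, i + 1L, df$strand[i])
    }
    if (df$end[i] < s1) {
      .stopf("%s: line %d: end <= start", path, i + 1L)
    }
  }
  attr(df, "dialect") <- dialect
  canonicalizeJunctions(df, dialect)
}

#' @rdname io
#' @export
writeTranscriptAnnotation <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readTranscriptAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  .assert(all(need %in% colnames(df)), "%s: needs columns %s", path,
          paste(need, collapse = ", "))
  bad <- which(df$end <= df$start)
  .assert(length(bad) == 0L, "%s: line %d: end <= start", path,
          if (length(bad)) bad[1L] + 1L else 0L)
  df
}

#' @rdname io
#' @details \code{importGtfSpans} maps GTF gene lines (or transcript lines if
#'   no gene lines exist) to the minimal span annotation.
#' @export
importGtfSpans <- function(path) {
  .assert(requireNamespace("rtracklayer", quietly = TRUE),
          "importGtfSpans requires the rtracklayer package")
  g <- rtracklayer::import(path)
  type <- as.character(g$type)
  g <- if (any(type == "gene")) g[type == "gene"] else g[type == "transcript"]
  id <- if (!is.null(g$gene_id)) g$gene_id else g$transcript_id
  data.frame(transcript_id = as.character(id),
             chrom = as.character(seqnames(g)),
             strand = as.character(strand(g)),
             start = start(g) - 1L, end = end(g),
             stringsAsFactors = FALSE)
}

#' @rdname io
#' @param alphabet \code{"DNA"} (targets) or \code{"RNA"} (miRNAs).
#' @export
readSequencesFasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seqs <- if (alphabet == "RNA") Biostrings::readRNAStringSet(path)
          else readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  .assert(length(dup) == 0L, "%s: duplicate FASTA header(s): %s", path,
          paste(utils::head(dup, 3), collapse = ", "))
  names(seqs) <- nm
  seqs
}

#' @rdname io
#' @param truth a SyntheticTruth.
#' @export
writeTruthLedger <- function(truth, path) {
  .assert(is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  obj <- list(
    seed = truth@seed,
    planted_triplets = as.data.frame(truth@planted_triplets),
    de_assignments = as.data.frame(truth@de_assignments),
    mre_map = as.data.frame(truth@mre_map),
    nb_params = as.data.frame(truth@nb_params),
    junctions = junctionsToDialect(truth@junctions, "bed0-half-open"),
    hosts = as.data.frame(truth@hosts),
    transcripts = as.data.frame(truth@transcripts),
    caller_profiles = as.data.frame(truth@caller_profiles),
    corr_pairs = as.data.frame(truth@corr_pairs))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load all pipeline inputs from disk
#'
#' @param paths named list: \code{design}, \code{counts_mirna},
#'   \code{counts_mrna}, \code{counts_circ}, \code{calls} (vector of
#'   junction files), \code{mirna_fasta}, \code{target_fasta},
#'   \code{annotation}. Elements may be omitted if a downstream stage is not
#'   run.
#' @return named list of typed objects (\code{design}, \code{counts} list,
#'   \code{call_sets} list keyed by caller, \code{mirna} / \code{targets}
#'   sequence sets, \code{kinds}, \code{transcripts}). Target ids beginning
#'   with \code{"circ|"} are treated as circular.
#' @export
loadInputs <- function(paths) {
  out <- list()
  if (!is.null(paths$design)) out$design <- readSampleDesign(paths$design)
  cnt <- list()
  if (!is.null(paths$counts_mirna)) cnt$mirna <- readCountMatrix(paths$counts_mirna)
  if (!is.null(paths$counts_mrna)) cnt$mrna <- readCountMatrix(paths$counts_mrna)
  if (!is.null(paths$counts_circ)) cnt$circ <- readCountMatrix(paths$counts_circ)
  if (length(cnt)) out$counts <- cnt
  if (!is.null(paths$calls)) {
    sets <- lapply(paths$calls, readJunctionCalls)
    names(sets) <- vapply(sets, function(gr) {
      cl <- unique(mcols(gr)$caller)
      .assert(length(cl) == 1L, "each call file must hold a single caller")
      as.character(cl)
    }, character(1))
    out$call_sets <- sets
  }
  if (!is.null(paths$mirna_fasta)) {
    out$mirna <- readSequencesFasta(paths$mirna_fasta, alphabet = "RNA")
  }
  if (!is.null(paths$target_fasta)) {
    out$targets <- readSequencesFasta(paths$target_fasta)
    out$kinds <- setNames(
      ifelse(startsWith(names(out$targets), "circ|"), "circular", "linear"),
      names(out$targets))
  }
  if (!is.null(paths$annotation)) {
    out$transcripts <- readTranscriptAnnotation(paths$annotation)
  }
  out
}
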