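#' @include utils.R
NULL

# canonical junction key on 0-based half-open coordinates
.junctionKey <- function(gr) {
  if (!length(gr)) return(character(0))
  paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
        as.character(strand(gr)), sep = "|")
}

#' Stable circRNA identifier
#'
#' \code{"circ|chrom|start|end|strand"} on canonical 0-based half-open
#' coordinates; stable and sortable.
#'
#' @param gr GRanges of canonical junctions.
#' @return character vector of ids.
#' @export
circId <- function(gr) {
  if (!length(gr)) return(character(0))
  paste0("circ|", .junctionKey(gr))
}

#' Canonicalize back-splice junction calls
#'
#' Converts caller output in a supported coordinate dialect to the canonical
#' representation: a \link[GenomicRanges]{GRanges} (whose 0-based half-open
#' coordinates are \code{start(gr)-1} and \code{end(gr)}). Conversion is
#' idempotent: canonical coordinates written back as \code{bed0-half-open}
#' and re-read are unchanged.
#'
#' @param calls data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} and optionally \code{caller},
#'   \code{bsj_reads}, \code{name}; or an already-canonical GRanges
#'   (returned after validation). If \code{dialect} is missing, a
#'   \code{"dialect"} attribute on \code{calls} is used.
#' @param dialect \code{"bed0-half-open"} (start 0-based, end exclusive) or
#'   \code{"one-based-inclusive"} (start and end 1-based inclusive).
#' @return GRanges with any \code{caller}/\code{bsj_reads}/\code{name}
#'   columns carried through and a \code{circ_id} column added.
#' @examples
#' df <- data.frame(chrom = "chr1", start = 100, end = 200, strand = "+")
#' gr <- canonicalizeJunctions(df, "one-based-inclusive")
#' start(gr) - 1  # 99: 0-based half-open start
#' @export
canonicalizeJunctions <- function(calls, dialect = attr(calls, "dialect")) {
  if (is(calls, "GRanges")) {
    .assert(all(end(calls) >= start(calls)), "end must exceed start")
    if (is.null(mcols(calls)$circ_id)) mcols(calls)$circ_id <- circId(calls)
    return(calls)
  }
  .assert(!is.null(dialect), "a coordinate dialect is required")
  .assert(dialect %in% .DIALECTS, "unknown dialect '%s' (supported: %s)",
          dialect, paste(.DIALECTS, collapse = ", "))
  need <- c("chrom", "start", "end", "strand")
  .assert(is.data.frame(calls) && all(need %in% colnames(calls)),
          "calls must have columns %s", paste(need, collapse = ", "))
  .assert(all(calls$strand %in% c("+", "-")), "strand must be + or -")
  start1 <- if (dialect == "bed0-half-open") calls$start + 1L else calls$start
  end1 <- calls$end
  .assert(all(calls$start >= 0), "start must be >= 0")
  .assert(all(end1 >= start1),
          "end <= start after conversion to canonical coordinates")
  gr <- GRanges(calls$chrom, IRanges(as.integer(start1), as.integer(end1)),
                strand = calls$strand)
  for (col in c("name", "bsj_reads", "caller")) {
    if (col %in% colnames(calls)) mcols(gr)[[col]] <- calls[[col]]
  }
  mcols(gr)$circ_id <- circId(gr)
  gr
}

#' Write canonical junctions in a coordinate dialect
#'
#' Inverse of \code{\link{canonicalizeJunctions}}: renders a canonical
#' GRanges as a BED-like data.frame in the requested dialect.
#'
#' @param gr canonical junction GRanges.
#' @param dialect target dialect.
#' @param caller optional caller label stored in the \code{caller} column.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{bsj_reads}, \code{strand}, \code{caller}, carrying a
#'   \code{"dialect"} attribute.
#' @export
junctionsToDialect <- function(gr, dialect, caller = NA_character_) {
  .assert(dialect %in% .DIALECTS, "unknown dialect '%s'", dialect)
  start0 <- start(gr) - 1L
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = if (dialect == "bed0-half-open") start0 else start0 + 1L,
    end = end(gr),
    name = if (!is.null(mcols(gr)$circ_id)) mcols(gr)$circ_id else circId(gr),
    bsj_reads = if (!is.null(mcols(gr)$bsj_reads)) mcols(gr)$bsj_reads else 0L,
    strand = as.character(strand(gr)),
    caller = if (!is.null(mcols(gr)$caller) && is.na(caller))
      mcols(gr)$caller else caller,
    stringsAsFactors = FALSE)
  attr(df, "dialect") <- dialect
  df
}

#' Consensus circRNAs across callers
#'
#' A junction key (chrom, start, end, strand) enters the consensus iff it is
#' present in at least \code{min_callers} call sets; with \code{min_callers}
#' equal to the number of callers this is the exact set intersection the
#' study design prescribes. Matching is exact on canonical coordinates by
#' default; a coordinate tolerance merges junctions whose starts and ends
#' both lie within \code{tolerance} of a cluster representative (first
#' member in sorted order), whose coordinates become the consensus ones.
#'
#' @param call_sets named list (caller -> canonical GRanges or data.frame
#'   with a dialect attribute).
#' @param min_callers minimum supporting callers (default: all of them).
#' @param tolerance +/- nucleotides for coordinate matching (default 0).
#' @return GRanges of consensus junctions, sorted by circ_id, with mcols
#'   \code{circ_id}, \code{n_callers} and \code{supporting_callers}
#'   (CharacterList).
#' @export
intersectCallers <- function(call_sets, min_callers = length(call_sets),
                             tolerance = 0L) {
  .assert(is.list(call_sets) && length(call_sets) >= 1L &&
            !is.null(names(call_sets)),
          "call_sets must be a non-empty named list")
  .assert(min_callers >= 1L, "min_callers must be >= 1")
  sets <- lapply(call_sets, canonicalizeJunctions)
  callers <- .csort(names(sets))
  df <- do.call(rbind, lapply(callers, function(cl) {
    gr <- sets[[cl]]
    data.frame(caller = rep(cl, length(gr)),
               chrom = as.character(seqnames(gr)),
               start = start(gr), end = end(gr),
               strand = as.character(strand(gr)),
               stringsAsFactors = FALSE)
  }))
  # per caller a junction counts once
  df <- df[!duplicated(paste(df$caller, df$chrom, df$start, df$end,
                             df$strand)), , drop = FALSE]
  if (tolerance == 0L) {
    df$cluster <- paste(df$chrom, df$start, df$end, df$strand)
  } else {
    ord <- .corder(df$chrom, df$strand, df$start, df$end)
    df <- df[ord, , drop = FALSE]
    cl_id <- integer(nrow(df))
    rep_s <- rep_e <- NA_integer_
    cur <- 0L
    for (i in seq_len(nrow(df))) {
      new_cl <- i == 1L ||
        df$chrom[i] != df$chrom[i - 1L] || df$strand[i] != df$strand[i - 1L] ||
        abs(df$start[i] - rep_s) > tolerance || abs(df$end[i] - rep_e) > tolerance
      if (new_cl) {
        cur <- cur + 1L
        rep_s <- df$start[i]; rep_e <- df$end[i]
      }
      cl_id[i] <- cur
    }
    df$cluster <- as.character(cl_id)
  }
  sup <- split(df$caller, df$cluster)
  sup <- lapply(sup, unique)
  keep <- names(sup)[lengths(sup) >= min_callers]
  if (!length(keep)) {
    gr <- GRanges()
    mcols(gr)$circ_id <- character(0)
    mcols(gr)$n_callers <- integer(0)
    mcols(gr)$supporting_callers <- CharacterList()
    return(gr)
  }
  first <- df[!duplicated(df$cluster), , drop = FALSE]
  rownames(first) <- first$cluster
  first <- first[keep, , drop = FALSE]
  gr <- GRanges(first$chrom, IRanges(first$start, first$end),
                strand = first$strand)
  mcols(gr)$circ_id <- circId(gr)
  mcols(gr)$n_callers <- lengths(sup[keep])
  mcols(gr)$supporting_callers <- CharacterList(lapply(sup[keep], .csort))
  gr[.corder(mcols(gr)$circ_id)]
}

#' Assign consensus circRNAs to host transcripts
#'
#' The host is the transcript on the same chromosome and strand whose span
#' contains the full back-splice interval; ties go to the smallest containing
#' span, then the lexicographically smallest transcript id. circRNAs
#' contained in no span keep an NA host. The number of hosts producing more
#' than one circRNA is stored in \code{metadata(result)$multi_circ_hosts}.
#'
#' @param consensus consensus GRanges (from \code{\link{intersectCallers}}).
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{chrom}, \code{strand}, \code{start} (0-based), \code{end}
#'   (half-open exclusive).
#' @return the consensus GRanges with a \code{host_transcript} column added.
#' @export
mapToHost <- function(consensus, transcripts) {
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  .assert(is.data.frame(transcripts) && all(need %in% colnames(transcripts)),
          "transcripts must have columns %s", paste(need, collapse = ", "))
  host <- rep(NA_character_, length(consensus))
  if (nrow(transcripts) && length(consensus)) {
    txg <- GRanges(transcripts$chrom,
                   IRanges(transcripts$start + 1L, transcripts$end),
                   strand = transcripts$strand)
    hits <- findOverlaps(consensus, txg, type = "within")
    if (length(hits)) {
      h <- data.frame(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits))
      h$w <- width(txg)[h$s]
      h$id <- transcripts$transcript_id[h$s]
      h <- h[.corder(h$q, h$w, h$id), , drop = FALSE]
      h <- h[!duplicated(h$q), , drop = FALSE]
      host[h$q] <- h$id
    }
  }
  mcols(consensus)$host_transcript <- host
  tab <- table(host[!is.na(host)])
  metadata(consensus)$multi_circ_hosts <- sum(tab > 1L)
  consensus
}

#' Attach per-sample BSJ read counts to a consensus set
#'
#' Fills \code{bsj_counts} (a matrix column, samples in columns) from a
#' circRNA count matrix, matching rows by circ_id. Consensus junctions absent
#' from the matrix (e.g. false calls never quantified) get zero counts.
#'
#' @param consensus consensus GRanges.
#' @param circ_counts \linkS4class{ExpressionMatrix} (counts layer) or
#'   integer matrix with circ_id rownames.
#' @return the consensus GRanges with a \code{bsj_counts} mcols matrix.
#' @export
setBsjCounts <- function(consensus, circ_counts) {
  m <- if (is(circ_counts, "ExpressionMatrix")) {
    .assert(identical(exprLayer(circ_counts), "counts"),
            "circ_counts must be on the counts layer")
    exprValues(circ_counts)
  } else circ_counts
  .assert(is.matrix(m) && !is.null(rownames(m)) && !is.null(colnames(m)),
          "circ_counts must be a matrix with dimnames")
  out <- matrix(0L, nrow = length(consensus), ncol = ncol(m),
                dimnames = list(mcols(consensus)$circ_id, colnames(m)))
  hit <- intersect(mcols(consensus)$circ_id, rownames(m))
  out[hit, ] <- m[hit, , drop = FALSE]
  mcols(consensus)$bsj_counts <- out
  consensus
}

#' Back-splice-junction quantification
#'
#' Builds the circRNA abundance matrix from the per-sample BSJ read counts of
#' a consensus set, normalized per million BSJ reads per sample (BSJ-CPM).
#' Samples whose BSJ total is zero get zeros. With \code{normalize = FALSE}
#' the raw BSJ counts are returned (the input to the DE test).
#'
#' @param consensus consensus GRanges carrying \code{bsj_counts} (see
#'   \code{\link{setBsjCounts}}).
#' @param design sample design table; every count column must be a design
#'   sample and vice versa.
#' @param normalize return BSJ-CPM (default) or raw counts.
#' @return an \linkS4class{ExpressionMatrix} (layer \code{BSJ-CPM} or
#'   \code{counts}), samples in design order.
#' @export
quantifyBSJ <- function(consensus, design, normalize = TRUE) {
  validateSampleDesign(design)
  m <- mcols(consensus)$bsj_counts
  .assert(!is.null(m), "consensus carries no bsj_counts; see setBsjCounts()")
  .assert(setequal(colnames(m), design$sample_id),
          "BSJ count samples do not match the design")
  m <- m[, design$sample_id, drop = FALSE]
  rownames(m) <- mcols(consensus)$circ_id
  if (!normalize) return(ExpressionMatrix(m, layer = "counts"))
  tot <- colSums(m)
  cpm <- sweep(m, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  cpm[, tot == 0] <- 0
  ExpressionMatrix(cpm, layer = "BSJ-CPM")
}
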