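#' Canonical miRNA seed-site prediction
#'
#' Scans a target sequence for canonical seed matches to a miRNA. The seed
#' match is anchored on the 6mer core (target = reverse complement of miRNA
#' positions 2-7, both written 5' to 3'); each core occurrence is classified
#' by its extensions: a target base complementary to miRNA position 8
#' immediately 5' of the core upgrades it to 7mer-m8, a target A immediately
#' 3' of the core (opposite miRNA position 1) upgrades it to 7mer-A1, and
#' both upgrades give an 8mer. Exactly one site - the strongest type - is
#' reported per core position. Circular targets are scanned on the sequence
#' concatenated with its own first 7 nucleotides (the longest site minus
#' one), so sites straddling the back-splice junction are found; their
#' positions are reported modulo the original length with
#' \code{junction_spanning = TRUE}.
#'
#' @param mirna_seq miRNA sequence, 18-25 nt, RNA or DNA alphabet, 5' to 3'.
#' @param target_seq target sequence (DNA or RNA; T and U equivalent).
#' @param target_kind \code{"linear"} or \code{"circular"}.
#' @param mirna_id,target_id optional ids recorded in the output.
#' @return data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_kind}, \code{site_type}, \code{position} (0-based start of
#'   the match on the target), \code{junction_spanning}; zero rows if the
#'   target is shorter than 6 nt or carries no site.
#' @examples
#' # let-7 style miRNA: seed complement CTACCTC, 8mer adds the 3' A
#' findSeedSites("UGAGGUAGUAGGUUGUAUAGUU", "AAACTACCTCAAA")
#' @export
findSeedSites <- function(mirna_seq, target_seq,
                          target_kind = c("linear", "circular"),
                          mirna_id = NA_character_,
                          target_id = NA_character_) {
  target_kind <- match.arg(target_kind)
  mir <- .toDNA(mirna_seq, "miRNA sequence")
  .assert(nchar(mir) >= 18L && nchar(mir) <= 25L,
          "miRNA must be 18-25 nt (got %d)", nchar(mir))
  tgt <- .toDNA(target_seq, "target sequence")
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), site_type = character(0),
                      position = integer(0), junction_spanning = logical(0),
                      stringsAsFactors = FALSE)
  L <- nchar(tgt)
  if (L < 6L) return(empty)

  circular <- target_kind == "circular"
  scan <- if (circular) paste0(tgt, substr(tgt, 1L, min(7L, L))) else tgt
  hits <- .seedScan(.revcompDNA(substr(mir, 2L, 7L)),
                    .compBase(substr(mir, 8L, 8L)),
                    scan, strsplit(scan, "", fixed = TRUE)[[1L]],
                    L, circular)
  if (is.null(hits)) return(empty)
  out <- data.frame(mirna_id = mirna_id, target_id = target_id,
                    target_kind = target_kind, site_type = hits$site_type,
                    position = hits$position,
                    junction_spanning = hits$junction_spanning,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# core of the seed scan, shared by findSeedSites and the generator's scrub:
# classify every 6mer-core occurrence by its m8/A1 extensions and keep the
# strongest type per reported position. scan = (possibly junction-extended)
# target string, tchars its characters, L the original target length.
.seedScan <- function(core6, m8c, scan, tchars, L, circular) {
  q <- .findAllFixed(core6, scan)            # 0-based core starts
  if (circular) q <- q[q < L]                # wrapped duplicates
  if (!length(q)) return(NULL)
  left <- if (circular) tchars[((q - 1L) %% L) + 1L] else {
    ifelse(q > 0L, tchars[pmax(q, 1L)], NA_character_)
  }
  right <- if (circular) tchars[((q + 6L) %% L) + 1L] else {
    ifelse(q + 6L < L, tchars[pmin(q + 7L, L)], NA_character_)
  }
  m8 <- !is.na(left) & left == m8c
  a1 <- !is.na(right) & right == "A"
  type <- ifelse(m8 & a1, "8mer",
                 ifelse(m8, "7mer-m8", ifelse(a1, "7mer-A1", "6mer")))
  pos <- ifelse(m8, q - 1L, q)
  len <- ifelse(m8 & a1, 8L, ifelse(m8 | a1, 7L, 6L))
  spanning <- if (circular) (pos < 0L | pos + len > L) else rep(FALSE, length(q))
  pos <- pos %% L
  out <- data.frame(site_type = type, position = as.integer(pos),
                    junction_spanning = spanning, stringsAsFactors = FALSE)
  # strongest type per reported position (periodic seeds can stack types)
  out <- out[.corder(out$position, -.SITE_RANK[out$site_type]), , drop = FALSE]
  out <- out[!duplicated(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate seed sites over all miRNA/target pairs
#'
#' @param mirnas named character vector or
#'   \link[Biostrings]{RNAStringSet}/\code{DNAStringSet} of miRNA sequences.
#' @param targets named character vector or \code{DNAStringSet} of target
#'   sequences.
#' @param kinds named character vector mapping each target id to
#'   \code{"linear"} or \code{"circular"}; targets missing from \code{kinds}
#'   default to linear.
#' @return a \linkS4class{TargetMap} with deterministic row ordering.
#' @export
buildTargetMap <- function(mirnas, targets, kinds = NULL) {
  mirnas <- .asNamedSeqs(mirnas, "miRNA")
  targets <- .asNamedSeqs(targets, "target")
  .assert(!anyDuplicated(names(mirnas)), "duplicate miRNA ids")
  .assert(!anyDuplicated(names(targets)), "duplicate target ids")
  if (is.null(kinds)) kinds <- setNames(rep("linear", length(targets)),
                                        names(targets))
  mids <- .csort(names(mirnas))
  mirdna <- vapply(mids, function(m) .toDNA(mirnas[[m]], "miRNA sequence"),
                   character(1))
  .assert(all(nchar(mirdna) >= 18L & nchar(mirdna) <= 25L),
          "miRNAs must be 18-25 nt")
  core6 <- .revcompDNA(substr(mirdna, 2L, 7L))
  m8c <- .compBase(substr(mirdna, 8L, 8L))
  res <- list()
  for (t in .csort(names(targets))) {
    kind <- if (!is.na(kinds[t])) kinds[[t]] else "linear"
    tgt <- .toDNA(targets[[t]], "target sequence")
    L <- nchar(tgt)
    if (L < 6L) next
    circular <- kind == "circular"
    scan <- if (circular) paste0(tgt, substr(tgt, 1L, min(7L, L))) else tgt
    tchars <- strsplit(scan, "", fixed = TRUE)[[1L]]
    for (k in seq_along(mids)) {
      s <- .seedScan(core6[k], m8c[k], scan, tchars, L, circular)
      if (!is.null(s)) {
        res[[length(res) + 1L]] <- data.frame(
          mirna_id = mids[k], target_id = t, target_kind = kind,
          site_type = s$site_type, position = s$position,
          junction_spanning = s$junction_spanning, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(res)) do.call(rbind, res) else {
    data.frame(mirna_id = character(0), target_id = character(0),
               target_kind = character(0), site_type = character(0),
               position = integer(0), junction_spanning = logical(0),
               stringsAsFactors = FALSE)
  }
  sites <- sites[.corder(sites$mirna_id, sites$target_id, sites$position), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  new("TargetMap", sites = DataFrame(sites))
}

.asNamedSeqs <- function(x, what) {
  if (is(x, "XStringSet")) x <- as.character(x)
  .assert(is.character(x), "%s sequences must be a character vector or XStringSet",
          what)
  if (length(x)) {
    .assert(!is.null(names(x)) && all(nzchar(names(x))),
            "%s sequences must be named", what)
  }
  x
}

#' miRNAs shared between a circRNA and an mRNA
#'
#' The sponge criterion: miRNAs with at least one seed site (of at least
#' \code{min_site_type} strength) on both the circRNA and the mRNA. Absent
#' ids contribute nothing.
#'
#' @param target_map a \linkS4class{TargetMap}.
#' @param circ_id,mrna_id target ids.
#' @param min_site_type weakest site type counted (default \code{"6mer"},
#'   i.e. all canonical sites).
#' @return data.frame with columns \code{mirna_id}, \code{sites_on_circ},
#'   \code{sites_on_mrna}, sorted by miRNA id; zero rows if none shared.
#' @export
sharedMiRNAs <- function(target_map, circ_id, mrna_id,
                         min_site_type = "6mer") {
  .assert(min_site_type %in% .SITE_TYPES, "unknown site type '%s'",
          min_site_type)
  s <- as.data.frame(mreSites(target_map))
  s <- s[.SITE_RANK[s$site_type] >= .SITE_RANK[min_site_type], , drop = FALSE]
  on_c <- s[s$target_id == circ_id, , drop = FALSE]
  on_m <- s[s$target_id == mrna_id, , drop = FALSE]
  shared <- .csort(intersect(unique(on_c$mirna_id), unique(on_m$mirna_id)))
  data.frame(
    mirna_id = shared,
    sites_on_circ = vapply(shared, function(m) sum(on_c$mirna_id == m),
                           integer(1), USE.NAMES = FALSE),
    sites_on_mrna = vapply(shared, function(m) sum(on_m$mirna_id == m),
                           integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
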