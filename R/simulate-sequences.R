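#' Simulate miRNA and target sequences carrying the planted MRE map
#'
#' Emits a random RNA sequence per miRNA and a random DNA sequence per target
#' (mRNAs linear, circRNAs circular) such that every planted site in the
#' truth's MRE map is present as the exact seed-complement motif of its type
#' at its position, and the background contains no unplanned canonical site
#' for any truth miRNA (accidental sites are removed by local re-draws, a
#' rejection-sampling scrub). miRNA seeds are drawn mutually collision-free
#' so the scrub can never destroy a planted site. Junction-spanning circRNA
#' sites are written across the back-splice, so they exist only on the
#' circularized sequence.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param lengths named lengths per layer (\code{mirna}, \code{mrna},
#'   \code{circ}); defaults to the truth's configuration. Targets must be >=
#'   30 nt and miRNAs 18-25 nt; a planted position exceeding a target length
#'   is a sizing error.
#' @return list with \code{mirna} (\link[Biostrings]{RNAStringSet}),
#'   \code{targets} (\link[Biostrings]{DNAStringSet} over mRNAs and
#'   circRNAs) and \code{kinds} (named vector, \code{"linear"} or
#'   \code{"circular"} per target).
#' @export
simulateSequences <- function(truth, lengths = NULL) {
  .assert(is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  cfg <- truth@config
  if (is.null(lengths)) {
    lengths <- c(mirna = as.numeric(cfg@mirna_length),
                 mrna = cfg@target_lengths[["mrna"]],
                 circ = cfg@target_lengths[["circ"]])
  }
  .assert(all(c("mirna", "mrna", "circ") %in% names(lengths)),
          "lengths must name mirna, mrna and circ")
  .assert(lengths[["mirna"]] >= 18 && lengths[["mirna"]] <= 25,
          "miRNA length must be 18-25 nt")
  .assert(all(lengths[c("mrna", "circ")] >= 30),
          "target lengths must be >= 30 nt")

  np <- truth@nb_params
  mirna_ids <- .csort(np$feature_id[np$layer == "mirna"])
  mrna_ids <- .csort(np$feature_id[np$layer == "mrna"])
  circ_ids <- .csort(np$feature_id[np$layer == "circ"])
  mm <- as.data.frame(truth@mre_map)

  # sizing check: every planted site must fit its target
  if (nrow(mm)) {
    len_of <- function(kind) ifelse(kind == "circular", lengths[["circ"]],
                                    lengths[["mrna"]])
    site_len <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
    Ls <- len_of(mm$target_kind)
    over <- ifelse(mm$target_kind == "circular",
                   mm$position >= Ls,
                   mm$position + site_len[mm$site_type] > Ls)
    .assert(!any(over), "planted site position exceeds its target length")
  }

  mirseqs <- .simulateMirnas(mirna_ids, as.integer(lengths[["mirna"]]),
                             truth@seed)
  kinds <- c(setNames(rep("linear", length(mrna_ids)), mrna_ids),
             setNames(rep("circular", length(circ_ids)), circ_ids))
  targets <- character(0)
  for (tid in c(mrna_ids, circ_ids)) {
    L <- as.integer(if (kinds[[tid]] == "circular") lengths[["circ"]]
                    else lengths[["mrna"]])
    planted <- mm[mm$target_id == tid, , drop = FALSE]
    targets[tid] <- withSubSeed(truth@seed, paste0("seq:target:", tid),
                                .buildTarget(L, kinds[[tid]], planted,
                                             mirseqs, tid))
  }
  list(mirna = RNAStringSet(chartr("T", "U", mirseqs)),
       targets = DNAStringSet(targets),
       kinds = kinds)
}

# draw miRNAs whose seed motifs cannot collide: no miRNA's 6mer core occurs
# inside another miRNA's 8mer motif, and no core is self-overlapping
.simulateMirnas <- function(ids, len, seed) {
  seqs <- character(0)
  motifs8 <- character(0)
  cores6 <- character(0)
  for (id in ids) {
    s <- withSubSeed(seed, paste0("seq:mirna:", id), {
      repeat {
        cand <- .randomDNA(len)
        core6 <- .revcompDNA(substr(cand, 2L, 7L))
        motif8 <- paste0(.revcompDNA(substr(cand, 2L, 8L)), "A")
        ok <- length(.findAllFixed(core6, motif8)) == 1L &&
          length(.findAllFixed(core6, paste0(core6, core6))) == 2L &&
          !any(vapply(motifs8, function(m) {
            length(.findAllFixed(core6, m)) > 0L
          }, logical(1))) &&
          !any(vapply(cores6, function(c6) {
            length(.findAllFixed(c6, motif8)) > 0L
          }, logical(1)))
        if (ok) break
      }
      cand
    })
    seqs[id] <- s
    motifs8 <- c(motifs8, paste0(.revcompDNA(substr(s, 2L, 8L)), "A"))
    cores6 <- c(cores6, .revcompDNA(substr(s, 2L, 7L)))
  }
  seqs
}

# assemble one target: random background, planted motifs + guard bases,
# then scrub accidental sites by local re-draws
.buildTarget <- function(L, kind, planted, mirseqs, tid) {
  circular <- kind == "circular"
  chars <- sample(.DNA_BASES, L, replace = TRUE)
  hard <- logical(L)                  # motif bases, never mutable
  guard_allowed <- vector("list", L)  # guard bases, mutable within a set
  idx <- function(i) {                # 0-based -> 1-based, wrapping if circular
    if (circular) (i %% L) + 1L else i + 1L
  }
  valid <- function(i) circular || (i >= 0L && i < L)
  setGuard <- function(i, allowed) {
    if (!valid(i)) return(invisible())
    j <- idx(i)
    if (hard[j]) return(invisible())  # adjacent motif base already fixed
    guard_allowed[[j]] <<- allowed
    chars[j] <<- sample(allowed, 1L)
    invisible()
  }
  writeMotif <- function(motif, s0) {
    mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
    for (k in seq_along(mchars)) {
      j <- idx(s0 + k - 1L)
      chars[j] <<- mchars[k]
      hard[j] <<- TRUE
      guard_allowed[j] <<- list(NULL)
    }
  }
  for (r in seq_len(nrow(planted))) {
    mir <- mirseqs[[planted$mirna_id[r]]]
    core6 <- .revcompDNA(substr(mir, 2L, 7L))
    core7 <- .revcompDNA(substr(mir, 2L, 8L))
    m8c <- .compBase(substr(mir, 8L, 8L))
    p <- planted$position[r]
    switch(planted$site_type[r],
      "8mer" = writeMotif(paste0(core7, "A"), p),
      "7mer-m8" = {
        writeMotif(core7, p)
        setGuard(p + 7L, setdiff(.DNA_BASES, "A"))
      },
      "7mer-A1" = {
        writeMotif(paste0(core6, "A"), p)
        setGuard(p - 1L, setdiff(.DNA_BASES, m8c))
      },
      "6mer" = {
        writeMotif(core6, p)
        setGuard(p - 1L, setdiff(.DNA_BASES, m8c))
        setGuard(p + 6L, setdiff(.DNA_BASES, "A"))
      },
      .stopf("unknown site type '%s'", planted$site_type[r]))
  }
  planted_keys <- if (nrow(planted)) {
    paste(planted$mirna_id, planted$site_type, planted$position)
  } else character(0)

  mids <- names(mirseqs)
  mcore6 <- .revcompDNA(substr(mirseqs, 2L, 7L))
  mm8c <- .compBase(substr(mirseqs, 8L, 8L))
  scanAll <- function() {
    s <- paste(chars, collapse = "")
    scan <- if (circular) paste0(s, substr(s, 1L, min(7L, L))) else s
    tchars <- strsplit(scan, "", fixed = TRUE)[[1L]]
    hits <- lapply(seq_along(mids), function(k) {
      h <- .seedScan(mcore6[k], mm8c[k], scan, tchars, L, circular)
      if (!is.null(h)) h$mirna_id <- mids[k]
      h
    })
    do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  }
  for (iter in seq_len(200L)) {
    found <- scanAll()
    if (is.null(found)) found <- data.frame(site_type = character(0),
                                            position = integer(0),
                                            junction_spanning = logical(0),
                                            mirna_id = character(0))
    keys <- if (nrow(found)) {
      paste(found$mirna_id, found$site_type, found$position)
    } else character(0)
    bad <- found[!keys %in% planted_keys, , drop = FALSE]
    if (!nrow(bad)) {
      .assert(setequal(keys, planted_keys),
              "planted site lost while scrubbing target %s", tid)
      return(paste(chars, collapse = ""))
    }
    for (r in seq_len(nrow(bad))) {
      q <- bad$position[r]
      if (bad$site_type[r] %in% c("8mer", "7mer-m8")) q <- (q + 1L) %% max(L, 1L)
      win <- if (circular) ((q + 0:5) %% L) + 1L else (q + 0:5) + 1L
      win <- win[win >= 1L & win <= L]
      free <- win[!hard[win] &
                    vapply(win, function(j) is.null(guard_allowed[[j]]),
                           logical(1))]
      if (length(free)) {
        j <- if (length(free) == 1L) free else sample(free, 1L)
        chars[j] <- sample(setdiff(.DNA_BASES, chars[j]), 1L)
      } else {
        gpos <- win[vapply(win, function(j) !is.null(guard_allowed[[j]]),
                           logical(1))]
        .assert(length(gpos) > 0L,
                "accidental site on %s cannot be scrubbed", tid)
        j <- gpos[1L]
        alt <- setdiff(guard_allowed[[j]], chars[j])
        .assert(length(alt) > 0L,
                "accidental site on %s cannot be scrubbed", tid)
        chars[j] <- if (length(alt) == 1L) alt else sample(alt, 1L)
      }
    }
  }
  .stopf("scrubbing of target %s did not converge", tid)
}
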