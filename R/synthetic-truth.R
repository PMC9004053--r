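#' @include AllClasses.R utils.R
NULL

# random unique back-splice junctions avoiding a set of existing keys
.randomJunctions <- function(n, existing_keys = character(0)) {
  chrom <- character(0); start0 <- integer(0); end <- integer(0)
  strand <- character(0)
  keys <- existing_keys
  guard <- 0L
  while (length(chrom) < n) {
    guard <- guard + 1L
    .assert(guard < 100L, "failed to draw %d unique junctions", n)
    m <- max(2L * (n - length(chrom)), 8L)
    ch <- sample(paste0("chr", 1:18), m, replace = TRUE)
    st <- sample.int(2000000L, m, replace = TRUE) * 50L
    en <- st + sample(200:2000, m, replace = TRUE)
    sd <- sample(c("+", "-"), m, replace = TRUE)
    key <- paste(ch, st, en, sd, sep = "|")
    keep <- !duplicated(key) & !key %in% keys
    ch <- ch[keep]; st <- st[keep]; en <- en[keep]; sd <- sd[keep]
    key <- key[keep]
    take <- seq_len(min(length(ch), n - length(chrom)))
    chrom <- c(chrom, ch[take]); start0 <- c(start0, st[take])
    end <- c(end, en[take]); strand <- c(strand, sd[take])
    keys <- c(keys, key[take])
  }
  gr <- GRanges(factor(chrom, levels = paste0("chr", 1:18)),
                IRanges(start0 + 1L, end), strand = strand)
  mcols(gr)$circ_id <- circId(gr)
  gr
}

# grid of non-overlapping candidate site positions on a target of length len
.sitePositionGrid <- function(len) {
  if (len < 40L) return(integer(0))
  seq(12L, len - 20L, by = 14L)
}

#' Generate the ground truth of a synthetic scenario
#'
#' Draws the planted structure that every downstream stage is validated
#' against: K sponge triplets (circRNA, miRNA, mRNA) with direction patterns,
#' DE assignments, an MRE map placing seed sites of each triplet's miRNA on
#' its circRNA and mRNA, NB count parameters per feature, true back-splice
#' junctions with host transcript spans, caller noise profiles, and the
#' co-expression pairs that receive a shared per-sample factor. Decoy
#' features are planted at the configured fractions: DE features without
#' shared MREs, MRE-sharing trios that are not DE, and DE trios whose miRNA
#' moves in the pattern-breaking direction.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a \linkS4class{SyntheticTruth}; identical for identical config
#'   (including seed).
#' @examples
#' truth <- generateTruth(generatorConfig(n_triplets = 5, seed = 7))
#' truth
#' @export
generateTruth <- function(config) {
  .assert(is(config, "GeneratorConfig"), "config must be a GeneratorConfig")
  validObject(config)
  set.seed(config@seed)
  K <- config@n_triplets
  lfc <- config@log2fc
  mirna_ids <- if (config@n_mirna) sprintf("miR-%03d", seq_len(config@n_mirna)) else character(0)
  mrna_ids <- if (config@n_mrna) sprintf("gene-%04d", seq_len(config@n_mrna)) else character(0)
  junctions <- .randomJunctions(config@n_circ)
  circ_ids <- if (config@n_circ) mcols(junctions)$circ_id else character(0)

  nd1 <- round(config@decoy_de_no_mre * K)
  nd2 <- round(config@decoy_mre_no_de * K)
  nd3 <- round(config@decoy_wrong_direction * K)

  take <- function(pool, n, from) {
    .assert(from + n - 1L <= length(pool),
            "not enough features in a layer for the requested triplets/decoys")
    pool[seq(from, length.out = n)]
  }
  circ_pool <- sample(circ_ids)
  mirna_pool <- sample(mirna_ids)
  mrna_pool <- sample(mrna_ids)

  # planted triplets
  patterns <- if (K) sample(.PATTERNS, K, replace = TRUE) else character(0)
  tri <- DataFrame(circ_id = take(circ_pool, K, 1L),
                   mirna_id = take(mirna_pool, K, 1L),
                   mrna_id = take(mrna_pool, K, 1L),
                   pattern = patterns)
  # wrong-direction decoy trios: DE + shared MRE + co-expression factor, but
  # the miRNA moves with (not against) the circ/mRNA
  wrong <- DataFrame(circ_id = take(circ_pool, nd3, K + 1L),
                     mirna_id = take(mirna_pool, nd3, K + 1L),
                     mrna_id = take(mrna_pool, nd3, K + 1L),
                     sign = if (nd3) sample(c(1, -1), nd3, replace = TRUE) else numeric(0))
  # shared-MRE-but-not-DE decoy trios
  silent <- DataFrame(circ_id = take(circ_pool, nd2, K + nd3 + 1L),
                      mirna_id = take(mirna_pool, nd2, K + nd3 + 1L),
                      mrna_id = take(mrna_pool, nd2, K + nd3 + 1L))
  # DE-but-no-MRE decoys, one per layer
  de_only <- DataFrame(circ_id = take(circ_pool, nd1, K + nd3 + nd2 + 1L),
                       mirna_id = take(mirna_pool, nd1, K + nd3 + nd2 + 1L),
                       mrna_id = take(mrna_pool, nd1, K + nd3 + nd2 + 1L),
                       sign = if (nd1) sample(c(1, -1), nd1, replace = TRUE) else numeric(0))

  # DE assignments (log2fc is B over A)
  de <- list()
  addDE <- function(feature_id, layer, val) {
    de[[length(de) + 1L]] <<- DataFrame(feature_id = feature_id,
                                        layer = layer, log2fc = val)
  }
  if (K) {
    s <- ifelse(tri$pattern == "up-down-up", 1, -1)
    addDE(tri$circ_id, "circ", s * lfc)
    addDE(tri$mrna_id, "mrna", s * lfc)
    addDE(tri$mirna_id, "mirna", -s * lfc)
  }
  if (nd3) {
    addDE(wrong$circ_id, "circ", wrong$sign * lfc)
    addDE(wrong$mrna_id, "mrna", wrong$sign * lfc)
    addDE(wrong$mirna_id, "mirna", wrong$sign * lfc)
  }
  if (nd1) {
    addDE(de_only$circ_id, "circ", de_only$sign * lfc)
    addDE(de_only$mrna_id, "mrna", de_only$sign * lfc)
    addDE(de_only$mirna_id, "mirna", de_only$sign * lfc)
  }
  de_assignments <- if (length(de)) do.call(rbind, de) else {
    DataFrame(feature_id = character(0), layer = character(0),
              log2fc = numeric(0))
  }

  # MRE map: sites of each trio's miRNA on its circ and mRNA
  circ_len <- as.integer(config@target_lengths[["circ"]])
  mrna_len <- as.integer(config@target_lengths[["mrna"]])
  mm <- list()
  plantSites <- function(mirna, target, kind, len, n_sites) {
    grid <- .sitePositionGrid(len)
    .assert(length(grid) >= n_sites, "target too short for planted sites")
    pos <- sort(sample(grid, n_sites))
    DataFrame(mirna_id = mirna, target_id = target, target_kind = kind,
              site_type = sample(c("7mer-m8", "8mer"), n_sites, replace = TRUE),
              position = as.integer(pos),
              junction_spanning = rep(FALSE, n_sites))
  }
  trios <- rbind(tri[, c("circ_id", "mirna_id", "mrna_id")],
                 wrong[, c("circ_id", "mirna_id", "mrna_id")],
                 silent[, c("circ_id", "mirna_id", "mrna_id")])
  for (i in seq_len(nrow(trios))) {
    mm[[length(mm) + 1L]] <- plantSites(trios$mirna_id[i], trios$circ_id[i],
                                        "circular", circ_len,
                                        sample(1:2, 1))
    mm[[length(mm) + 1L]] <- plantSites(trios$mirna_id[i], trios$mrna_id[i],
                                        "linear", mrna_len,
                                        sample(1:2, 1))
  }
  if (nrow(tri)) {
    # one site of the first planted triplet straddles the back-splice
    mm[[length(mm) + 1L]] <- DataFrame(
      mirna_id = tri$mirna_id[1L], target_id = tri$circ_id[1L],
      target_kind = "circular", site_type = "8mer",
      position = circ_len - 4L, junction_spanning = TRUE)
  }
  mre_map <- if (length(mm)) do.call(rbind, mm) else {
    DataFrame(mirna_id = character(0), target_id = character(0),
              target_kind = character(0), site_type = character(0),
              position = integer(0), junction_spanning = logical(0))
  }

  # NB parameters: planted/DE features get the planted-mean range
  lfc_by <- setNames(de_assignments$log2fc,
                     paste(de_assignments$layer, de_assignments$feature_id))
  in_trio <- paste(c(rep("circ", nrow(trios)), rep("mrna", nrow(trios)),
                     rep("mirna", nrow(trios))),
                   c(trios$circ_id, trios$mrna_id, trios$mirna_id))
  layerParams <- function(ids, layer) {
    if (!length(ids)) {
      return(DataFrame(feature_id = character(0), layer = character(0),
                       mean_a = numeric(0), mean_b = numeric(0),
                       dispersion = numeric(0)))
    }
    key <- paste(layer, ids)
    f <- ifelse(is.na(lfc_by[key]), 0, lfc_by[key])
    planted <- key %in% names(lfc_by) | key %in% in_trio
    rng <- ifelse(planted, 1, 0)
    lo <- ifelse(rng == 1, config@planted_mean_range[1L],
                 config@background_mean_range[1L])
    hi <- ifelse(rng == 1, config@planted_mean_range[2L],
                 config@background_mean_range[2L])
    base <- exp(runif(length(ids), log(lo), log(hi)))
    DataFrame(feature_id = ids, layer = layer,
              mean_a = base * 2^(-f / 2), mean_b = base * 2^(f / 2),
              dispersion = rep(config@dispersion, length(ids)))
  }
  nb_params <- rbind(layerParams(mirna_ids, "mirna"),
                     layerParams(mrna_ids, "mrna"),
                     layerParams(circ_ids, "circ"))

  # host assignment: walk junctions sorted by position; a circ reuses the
  # previous host (multi-circ host) with prob 0.25 when on the same
  # chrom/strand
  hosts <- DataFrame(circ_id = character(0), host_transcript = character(0))
  transcripts <- DataFrame(transcript_id = character(0), chrom = character(0),
                           strand = character(0), start = integer(0),
                           end = integer(0))
  if (length(junctions) && length(mrna_ids)) {
    ord <- .corder(as.character(seqnames(junctions)),
                   as.character(strand(junctions)), start(junctions))
    js <- junctions[ord]
    host_pool <- sample(mrna_ids)
    host_of <- character(length(js))
    pool_i <- 0L
    for (i in seq_along(js)) {
      reuse <- i > 1L &&
        as.character(seqnames(js[i])) == as.character(seqnames(js[i - 1L])) &&
        as.character(strand(js[i])) == as.character(strand(js[i - 1L])) &&
        runif(1) < 0.25
      if (reuse) {
        host_of[i] <- host_of[i - 1L]
      } else {
        pool_i <- pool_i + 1L
        .assert(pool_i <= length(host_pool), "not enough mRNAs to host circRNAs")
        host_of[i] <- host_pool[pool_i]
      }
    }
    hosts <- DataFrame(circ_id = mcols(js)$circ_id, host_transcript = host_of)
    tx <- lapply(.csort(unique(host_of)), function(h) {
      sub <- js[host_of == h]
      DataFrame(transcript_id = h,
                chrom = as.character(seqnames(sub))[1L],
                strand = as.character(strand(sub))[1L],
                start = max(0L, min(start(sub)) - 1L -
                              sample(100:2000, 1)),
                end = max(end(sub)) + sample(100:2000, 1))
    })
    transcripts <- do.call(rbind, tx)
  }

  # co-expression pairs sharing a per-sample log-normal factor
  cp <- list()
  addPair <- function(a, la, b, lb) {
    cp[[length(cp) + 1L]] <<- DataFrame(
      id_a = a, layer_a = la, id_b = b, layer_b = lb,
      sdlog = rep(config@shared_factor_sdlog, length(a)))
  }
  if (K) addPair(tri$circ_id, "circ", tri$mrna_id, "mrna")
  if (nd3) addPair(wrong$circ_id, "circ", wrong$mrna_id, "mrna")
  nch <- min(config@n_corr_hosts, nrow(hosts))
  if (nch > 0L) {
    addPair(hosts$circ_id[seq_len(nch)], "circ",
            hosts$host_transcript[seq_len(nch)], "mrna")
  }
  corr_pairs <- if (length(cp)) do.call(rbind, cp) else {
    DataFrame(id_a = character(0), layer_a = character(0),
              id_b = character(0), layer_b = character(0), sdlog = numeric(0))
  }

  callers <- .csort(names(config@caller_sensitivity))
  caller_profiles <- DataFrame(
    caller = callers,
    sensitivity = as.numeric(config@caller_sensitivity[callers]),
    false_rate = as.numeric(config@caller_false_rate[callers]),
    dialect = rep(.DIALECTS, length.out = length(callers)))

  out <- new("SyntheticTruth", config = config,
             planted_triplets = tri, de_assignments = de_assignments,
             mre_map = mre_map, nb_params = nb_params, junctions = junctions,
             hosts = hosts, transcripts = transcripts,
             caller_profiles = caller_profiles, corr_pairs = corr_pairs,
             seed = config@seed)
  validObject(out)
  out
}

#' @describeIn generateTruth the planted triplet table.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @export
plantedTriplets <- function(truth) truth@planted_triplets

#' @describeIn generateTruth the DE assignment table (feature, layer, log2fc).
#' @export
deAssignments <- function(truth) truth@de_assignments

#' @describeIn generateTruth the planted MRE site table.
#' @export
plantedSites <- function(truth) truth@mre_map

#' @describeIn generateTruth the true back-splice junctions (GRanges).
#' @export
trueJunctions <- function(truth) truth@junctions
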