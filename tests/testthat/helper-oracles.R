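# Independent brute-force oracles. These re-implement the documented rules
# with plain string/loop arithmetic and must stay independent of the package
# code paths they check.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

oracle_seed_scan <- function(mirna_seq, target_seq, kind = "linear") {
  norm <- function(s) chartr("U", "T", toupper(s))
  comp <- function(s) chartr("ACGT", "TGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  mir <- norm(mirna_seq)
  tgt <- norm(target_seq)
  L <- nchar(tgt)
  empty <- data.frame(site_type = character(0), position = integer(0),
                      junction_spanning = logical(0), stringsAsFactors = FALSE)
  if (L < 6) return(empty)
  seed6 <- rc(substr(mir, 2, 7))
  m8 <- comp(substr(mir, 8, 8))
  ext <- if (kind == "circular") paste0(tgt, substr(tgt, 1, 7)) else tgt
  res <- list()
  for (q in 0:(nchar(ext) - 6)) {
    if (substr(ext, q + 1, q + 6) != seed6) next
    if (kind == "circular" && q >= L) next
    if (kind == "circular") {
      li <- ((q - 1) %% L) + 1
      lb <- substr(tgt, li, li)
      ri <- ((q + 6) %% L) + 1
      rb <- substr(tgt, ri, ri)
    } else {
      lb <- if (q >= 1) substr(ext, q, q) else ""
      rb <- if (q + 6 < L) substr(ext, q + 7, q + 7) else ""
    }
    hasm8 <- lb == m8
    hasa1 <- rb == "A"
    if (hasm8 && hasa1) { ty <- "8mer"; p <- q - 1; ln <- 8 }
    else if (hasm8) { ty <- "7mer-m8"; p <- q - 1; ln <- 7 }
    else if (hasa1) { ty <- "7mer-A1"; p <- q; ln <- 7 }
    else { ty <- "6mer"; p <- q; ln <- 6 }
    js <- kind == "circular" && (p < 0 || p + ln > L)
    res[[length(res) + 1]] <- data.frame(site_type = ty, position = p %% L,
                                         junction_spanning = js,
                                         stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  out <- out[order(out$position, -rank[out$site_type]), , drop = FALSE]
  out <- out[!duplicated(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_keys <- function(df) {
  sort(paste(df$site_type, df$position, df$junction_spanning))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(list(r = 0, p = 1))
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# plain triple loop over every (circ, miRNA, mRNA) combination re-checking
# the three emission criteria
oracle_triplets <- function(de_circ, de_mirna, de_mrna, sites, circ_mat,
                            mrna_mat, th, comparison = "A_vs_B") {
  rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  sites <- sites[rank[sites$site_type] >= rank[th@min_site_type], ,
                 drop = FALSE]
  lc <- log2(circ_mat + th@pseudocount)
  lm <- log2(mrna_mat + th@pseudocount)
  dirs <- function(de) setNames(de$direction, de$feature_id)
  dc <- dirs(de_circ); dmi <- dirs(de_mirna); dmr <- dirs(de_mrna)
  rows <- list()
  for (ci in de_circ$feature_id) {
    for (mi in de_mirna$feature_id) {
      for (mr in de_mrna$feature_id) {
        pat <- if (dc[ci] == "up" && dmi[mi] == "down" && dmr[mr] == "up") {
          "up-down-up"
        } else if (dc[ci] == "down" && dmi[mi] == "up" && dmr[mr] == "down") {
          "down-up-down"
        } else NA
        if (is.na(pat)) next
        n_c <- sum(sites$mirna_id == mi & sites$target_id == ci)
        n_m <- sum(sites$mirna_id == mi & sites$target_id == mr)
        if (n_c < 1 || n_m < 1) next
        on_ci <- unique(sites$mirna_id[sites$target_id == ci])
        on_mr <- unique(sites$mirna_id[sites$target_id == mr])
        if (length(intersect(on_ci, on_mr)) < th@min_shared_mirnas) next
        if (!(ci %in% rownames(lc)) || !(mr %in% rownames(lm))) next
        pe <- oracle_pearson(lc[ci, ], lm[mr, colnames(lc)])
        if (th@corr_sign == "positive" && pe$r <= 0) next
        if (pe$p >= th@corr_p_threshold) next
        rows[[length(rows) + 1]] <- data.frame(
          comparison = comparison, circ_id = ci, mirna_id = mi, mrna_id = mr,
          pattern = pat, pearson_r = pe$r, pearson_p = pe$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(comparison = character(0), circ_id = character(0),
                      mirna_id = character(0), mrna_id = character(0),
                      pattern = character(0), pearson_r = numeric(0),
                      pearson_p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$comparison, out$circ_id, out$mirna_id, out$mrna_id), ,
      drop = FALSE]
}

triplet_keys <- function(df) {
  sort(paste(df$comparison, df$circ_id, df$mirna_id, df$mrna_id, df$pattern))
}

random_junction_df <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    start = sample.int(100000, n, replace = TRUE) * 10,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  df$end <- df$start + sample(100:2000, n, replace = TRUE)
  df <- df[!duplicated(paste(df$chrom, df$start, df$end, df$strand)), ]
  df[, c("chrom", "start", "end", "strand")]
}

random_rna <- function(n_nt) {
  paste(sample(c("A", "C", "G", "U"), n_nt, replace = TRUE), collapse = "")
}

random_dna <- function(n_nt) {
  paste(sample(c("A", "C", "G", "T"), n_nt, replace = TRUE), collapse = "")
}

# a compact scenario used by the oracle-equivalence tests: small enough that
# the brute-force triple loop stays under 1e4 candidate combinations
small_scenario <- function(seed) {
  cfg <- generatorConfig(n_mirna = 10L, n_mrna = 25L, n_circ = 15L,
                         n_triplets = 6L, seed = seed)
  truth <- generateTruth(cfg)
  design <- makeSampleDesign()
  counts <- simulateCounts(truth, design)
  seqs <- simulateSequences(truth)
  libs <- setNames(design$library_size, design$sample_id)
  de <- list(
    mirna = testTwoGroup(counts$mirna, design, library_sizes = libs),
    mrna = testTwoGroup(counts$mrna, design, library_sizes = libs),
    circ = testTwoGroup(counts$circ, design, library_sizes = libs))
  tm <- buildTargetMap(seqs$mirna, seqs$targets, seqs$kinds)
  circ_cpm <- normalizeCounts(counts$circ, "CPM", library_sizes = libs)
  mrna_fpkm <- normalizeCounts(counts$mrna, "FPKM", library_sizes = libs)
  list(truth = truth, design = design, counts = counts, de = de,
       target_map = tm, circ_expr = circ_cpm, mrna_expr = mrna_fpkm)
}
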