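test_that("the Pearson filter matches closed forms and stats::cor.test", {
  expect_equal(pearsonFilter(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearsonFilter(c(1, 2, 3), c(2, 4, 6))$p, 0)
  expect_equal(pearsonFilter(c(1, 2, 3), c(3, 2, 1))$r, -1)
  cst <- pearsonFilter(rep(2, 5), rnorm(5))
  expect_equal(cst$r, 0)
  expect_equal(cst$p, 1)
  expect_true(cst$flagged)
  expect_error(pearsonFilter(1:4, 1:5), "equal length")
  expect_error(pearsonFilter(1:2, 1:2), "n >= 3")
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    pf <- pearsonFilter(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(pf$r, orc$r, tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y))
    expect_equal(pf$p, unname(ct$p.value), tolerance = 1e-10)
  }
  # the t-transform p agrees with a permutation null within Monte-Carlo error
  set.seed(62)
  x <- rnorm(8); y <- x + rnorm(8, sd = 1.5)
  pf <- pearsonFilter(x, y)
  perm <- replicate(4000, abs(cor(x, sample(y))) >= abs(pf$r) - 1e-12)
  expect_lt(abs(mean(perm) - pf$p), 3 * sqrt(pf$p * (1 - pf$p) / 4000) + 0.01)
})

test_that("the pattern rule covers the full direction table", {
  dirs <- c("up", "down", "ns")
  for (a in dirs) for (b in dirs) for (c in dirs) {
    got <- classifyPattern(a, b, c)
    if (a == "up" && b == "down" && c == "up") {
      expect_identical(got, "up-down-up")
    } else if (a == "down" && b == "up" && c == "down") {
      expect_identical(got, "down-up-down")
    } else {
      expect_true(is.na(got))
    }
  }
  expect_error(classifyPattern("up", "sideways", "up"), "up, down or ns")
})

# a hand-built miniature: one planted triplet plus distractors
tiny_network <- function() {
  design <- makeSampleDesign()
  th <- thresholdConfig()
  de <- function(ids, lfc, fdr) S4Vectors::DataFrame(
    feature_id = ids, log2fc = lfc, p_value = fdr, fdr = fdr,
    direction = ifelse(fdr < 0.05, ifelse(lfc > 0, "up", "down"), "ns"),
    mean_abundance = 10, flagged = FALSE)
  de_circ <- de(c("circA", "circB"), c(2.5, -1), c(0.001, 0.5))
  de_mirna <- de(c("miR-1", "miR-2"), c(-2.2, 1.0), c(0.002, 0.01))
  de_mrna <- de(c("geneX", "geneY"), c(2.1, 2.0), c(0.004, 0.01))
  sites <- data.frame(
    mirna_id = c("miR-1", "miR-1", "miR-2"),
    target_id = c("circA", "geneX", "geneY"),
    target_kind = c("circular", "linear", "linear"),
    site_type = c("8mer", "7mer-m8", "8mer"),
    position = c(10L, 20L, 30L), junction_spanning = FALSE,
    stringsAsFactors = FALSE)
  tm <- new("TargetMap", sites = S4Vectors::DataFrame(sites))
  base <- c(10, 12, 11, 80, 85, 82)  # strong shared group shift
  cm <- rbind(circA = base * c(1, 1.1, 0.9, 1.05, 1, 0.95),
              circB = rep(20, 6))
  mm <- rbind(geneX = base * c(0.95, 1, 1.1, 1, 1.05, 0.9),
              geneY = rev(base))
  colnames(cm) <- colnames(mm) <- design$sample_id
  list(de_circ = de_circ, de_mirna = de_mirna, de_mrna = de_mrna, tm = tm,
       circ_expr = ExpressionMatrix(cm, layer = "BSJ-CPM"),
       mrna_expr = ExpressionMatrix(mm, layer = "FPKM"), th = th)
}

test_that("triplet assembly emits exactly the qualifying triplets", {
  nw <- tiny_network()
  out <- assembleTriplets(nw$de_circ, nw$de_mirna, nw$de_mrna, nw$tm,
                          nw$circ_expr, nw$mrna_expr, nw$th)
  expect_equal(nrow(out), 1L)
  expect_identical(out$circ_id, "circA")
  expect_identical(out$mirna_id, "miR-1")
  expect_identical(out$mrna_id, "geneX")
  expect_identical(out$pattern, "up-down-up")
  expect_gte(out$sites_on_circ, 1L)
  expect_identical(
    S4Vectors::metadata(out)$mirna_interactions, c(`miR-1` = 1L))

  # criterion necessity: removing the shared miRNA site kills the triplet
  sites2 <- as.data.frame(mreSites(nw$tm))
  sites2 <- sites2[sites2$target_id != "circA", ]
  tm2 <- new("TargetMap", sites = S4Vectors::DataFrame(sites2))
  out2 <- assembleTriplets(nw$de_circ, nw$de_mirna, nw$de_mrna, tm2,
                           nw$circ_expr, nw$mrna_expr, nw$th)
  expect_equal(nrow(out2), 0L)
})

test_that("assembly output is invariant to input row order", {
  nw <- tiny_network()
  ref <- assembleTriplets(nw$de_circ, nw$de_mirna, nw$de_mrna, nw$tm,
                          nw$circ_expr, nw$mrna_expr, nw$th)
  shuf <- assembleTriplets(nw$de_circ[2:1, ], nw$de_mirna[2:1, ],
                           nw$de_mrna[2:1, ], nw$tm,
                           nw$circ_expr, nw$mrna_expr, nw$th)
  expect_identical(as.data.frame(ref), as.data.frame(shuf))
})

test_that("assembly equals the brute-force triple loop on a synthetic scenario", {
  sc <- small_scenario(seed = 41)
  th <- thresholdConfig()
  got <- assembleTriplets(sc$de$circ, sc$de$mirna, sc$de$mrna, sc$target_map,
                          sc$circ_expr, sc$mrna_expr, th)
  want <- oracle_triplets(sc$de$circ, sc$de$mirna, sc$de$mrna,
                          as.data.frame(mreSites(sc$target_map)),
                          exprValues(sc$circ_expr), exprValues(sc$mrna_expr),
                          th)
  expect_identical(triplet_keys(as.data.frame(got)), triplet_keys(want))
  if (nrow(got)) {
    ord <- order(got$circ_id, got$mirna_id, got$mrna_id)
    expect_equal(got$pearson_r[ord], want$pearson_r, tolerance = 1e-12)
    expect_equal(got$pearson_p[ord], want$pearson_p, tolerance = 1e-12)
  }
})

test_that("tightening any threshold never adds triplets", {
  sc <- small_scenario(seed = 43)
  base <- thresholdConfig()
  ref <- assembleTriplets(sc$de$circ, sc$de$mirna, sc$de$mrna, sc$target_map,
                          sc$circ_expr, sc$mrna_expr, base)
  refk <- triplet_keys(as.data.frame(ref))
  tighter <- list(
    thresholdConfig(corr_p_threshold = 0.01),
    thresholdConfig(min_shared_mirnas = 2L),
    thresholdConfig(min_site_type = "8mer"))
  for (th in tighter) {
    out <- assembleTriplets(sc$de$circ, sc$de$mirna, sc$de$mrna,
                            sc$target_map, sc$circ_expr, sc$mrna_expr, th)
    expect_true(all(triplet_keys(as.data.frame(out)) %in% refk))
  }
  # a stricter FDR relabels directions upstream
  th_fdr <- thresholdConfig(fdr_threshold = 0.001)
  de2 <- lapply(sc$de, classifyDirection, thresholds = th_fdr)
  out <- assembleTriplets(de2$circ, de2$mirna, de2$mrna, sc$target_map,
                          sc$circ_expr, sc$mrna_expr, th_fdr)
  expect_true(all(triplet_keys(as.data.frame(out)) %in% refk))
})

test_that("host correlation flags positive significant pairs", {
  design <- makeSampleDesign()
  cons <- canonicalizeJunctions(data.frame(
    chrom = c("chr1", "chr2"), start = c(0, 10), end = c(100, 300),
    strand = "+"), "bed0-half-open")
  S4Vectors::mcols(cons)$host_transcript <- c("geneH", NA)
  ids <- circId(cons)
  cm <- matrix(c(1, 2, 3, 4, 5, 6, rep(7, 6)), 2, 6, byrow = TRUE,
               dimnames = list(ids, design$sample_id))
  mm <- matrix(c(2, 4, 6, 8, 10, 12), 1, 6,
               dimnames = list("geneH", design$sample_id))
  de0 <- S4Vectors::DataFrame(feature_id = c(ids, "geneH"),
                              direction = "ns")
  hc <- hostCorrelation(cons, ExpressionMatrix(cm, layer = "BSJ-CPM"),
                        ExpressionMatrix(mm, layer = "FPKM"),
                        de0, de0)
  expect_equal(nrow(hc), 1L)   # hostless circRNA omitted
  expect_gt(hc$r, 0.99)
  expect_true(hc$positive_corr)
  expect_false(hc$both_de)

  # brute-force recomputation of the flag set on random pairs
  set.seed(47)
  n <- 50
  jx <- random_junction_df(n, seed = 53)
  consr <- canonicalizeJunctions(jx, "one-based-inclusive")
  hosts <- sprintf("g%02d", seq_len(n))
  S4Vectors::mcols(consr)$host_transcript <- hosts
  cmr <- matrix(rpois(n * 6, 50), n, 6,
                dimnames = list(circId(consr), design$sample_id))
  mmr <- matrix(rpois(n * 6, 50), n, 6,
                dimnames = list(hosts, design$sample_id))
  der <- S4Vectors::DataFrame(feature_id = c(rownames(cmr), hosts),
                              direction = "ns")
  th <- thresholdConfig()
  hcr <- hostCorrelation(consr, ExpressionMatrix(cmr, layer = "BSJ-CPM"),
                         ExpressionMatrix(mmr, layer = "FPKM"), der, der, th)
  for (i in seq_len(nrow(hcr))) {
    o <- oracle_pearson(log2(cmr[hcr$circ_id[i], ] + 0.5),
                        log2(mmr[hcr$host_transcript[i], ] + 0.5))
    expect_equal(hcr$r[i], o$r, tolerance = 1e-12)
    expect_identical(hcr$positive_corr[i], o$r > 0 && o$p < 0.05)
  }
})
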