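test_that("coordinate dialects canonicalize as specified", {
  one <- data.frame(chrom = "chr1", start = 100, end = 200, strand = "+")
  gr <- canonicalizeJunctions(one, "one-based-inclusive")
  expect_equal(start(gr) - 1L, 99L)   # 0-based half-open start
  expect_equal(end(gr), 200L)
  bed <- data.frame(chrom = "chr1", start = 99, end = 200, strand = "+")
  gr2 <- canonicalizeJunctions(bed, "bed0-half-open")
  expect_equal(circId(gr2), circId(gr))
  # idempotence: canonical -> bed dialect -> canonical is the identity
  rt <- canonicalizeJunctions(junctionsToDialect(gr2, "bed0-half-open"))
  expect_equal(circId(rt), circId(gr2))

  expect_error(canonicalizeJunctions(bed, "zero-half"), "unknown dialect")
  bad <- data.frame(chrom = "chr1", start = 200, end = 100, strand = "+")
  expect_error(canonicalizeJunctions(bad, "bed0-half-open"), "end")
})

test_that("dialect round trips are the identity on random junctions", {
  df <- random_junction_df(1000, seed = 17)
  for (dialect in c("bed0-half-open", "one-based-inclusive")) {
    df0 <- df
    if (dialect == "bed0-half-open") df0$start <- df0$start - 1L
    gr <- canonicalizeJunctions(df0, dialect)
    back <- junctionsToDialect(gr, dialect)
    expect_equal(back$chrom, df0$chrom)
    expect_equal(back$start, df0$start)
    expect_equal(back$end, df0$end)
    expect_equal(back$strand, df0$strand)
  }
})

test_that("caller intersection equals brute-force set intersection and is monotone", {
  df <- random_junction_df(1000, seed = 23)
  all_ids <- circId(canonicalizeJunctions(df, "one-based-inclusive"))
  set.seed(29)
  callers <- paste0("caller", 1:5)
  picks <- lapply(callers, function(cl) sample(nrow(df), 700))
  sets <- setNames(lapply(picks, function(ix) {
    canonicalizeJunctions(df[ix, ], "one-based-inclusive")
  }), callers)
  counted <- table(unlist(lapply(picks, function(ix) all_ids[ix])))
  prev <- NULL
  for (mc in 5:1) {
    cons <- intersectCallers(sets, min_callers = mc)
    want <- names(counted)[counted >= mc]
    expect_setequal(S4Vectors::mcols(cons)$circ_id, want)
    if (!is.null(prev)) {
      expect_true(all(prev %in% S4Vectors::mcols(cons)$circ_id))
    }
    prev <- S4Vectors::mcols(cons)$circ_id
  }
  # consensus at min_callers = 5 is contained in every caller's set
  cons5 <- intersectCallers(sets, min_callers = 5)
  for (s in sets) {
    expect_true(all(S4Vectors::mcols(cons5)$circ_id %in%
                      S4Vectors::mcols(s)$circ_id))
  }
  expect_error(intersectCallers(list()), "non-empty")
})

test_that("membership thresholds behave at the boundary", {
  base <- data.frame(chrom = "chr2", start = 10, end = 500, strand = "-")
  sets <- lapply(1:5, function(i) canonicalizeJunctions(base, "bed0-half-open"))
  names(sets) <- paste0("c", 1:5)
  expect_equal(length(intersectCallers(sets, 5)), 1L)
  sets4 <- sets
  sets4[[5]] <- canonicalizeJunctions(
    data.frame(chrom = "chr3", start = 10, end = 500, strand = "-"),
    "bed0-half-open")
  expect_equal(length(intersectCallers(sets4, 5)), 0L)
  expect_equal(length(intersectCallers(sets4, 4)), 1L)
})

test_that("host mapping picks the smallest containing transcript on the same strand", {
  tx <- data.frame(
    transcript_id = sprintf("t%02d", 1:10),
    chrom = c(rep("chr1", 6), rep("chr2", 4)),
    strand = c(rep("+", 5), "-", rep("+", 4)),
    start = c(100, 100, 50, 1000, 2000, 100, 0, 500, 900, 5000),
    end = c(500, 450, 600, 1500, 2500, 500, 400, 800, 1200, 6000))
  cons <- canonicalizeJunctions(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(150, 160, 1100, 9000, 950),
    end = c(400, 420, 1400, 9500, 1100),
    strand = c("+", "+", "+", "+", "+")), "bed0-half-open")
  mapped <- mapToHost(cons, tx)
  host <- S4Vectors::mcols(mapped)$host_transcript
  # smallest containing span wins: t02 (width 350) over t01/t03
  expect_identical(host[1:2], c("t02", "t02"))
  expect_identical(host[3], "t04")
  expect_true(is.na(host[4]))
  expect_identical(host[5], "t09")
  # exhaustive recount of multi-circRNA hosts
  tab <- table(host[!is.na(host)])
  expect_equal(S4Vectors::metadata(mapped)$multi_circ_hosts,
               sum(tab > 1L))
  expect_equal(S4Vectors::metadata(mapped)$multi_circ_hosts, 1L)
})

test_that("BSJ quantification normalizes per million junction reads", {
  design <- makeSampleDesign()
  cons <- canonicalizeJunctions(data.frame(
    chrom = c("chr1", "chr1"), start = c(0, 100), end = c(50, 400),
    strand = c("+", "+")), "bed0-half-open")
  m <- matrix(c(10L, 90L, rep(25L, 10)), nrow = 2, ncol = 6,
              dimnames = list(circId(cons), design$sample_id))
  cons <- setBsjCounts(cons, ExpressionMatrix(m))
  bsj <- quantifyBSJ(cons, design)
  expect_identical(exprLayer(bsj), "BSJ-CPM")
  expect_equal(unname(exprValues(bsj)[1, 1]), 10 / 100 * 1e6)
  expect_equal(unname(colSums(exprValues(bsj))), rep(1e6, 6))
  # all-zero counts give an all-zero matrix
  cons0 <- setBsjCounts(cons, ExpressionMatrix(m * 0L))
  expect_true(all(exprValues(quantifyBSJ(cons0, design)) == 0))
  # samples must match the design
  m2 <- m; colnames(m2)[1] <- "ghost"
  cons2 <- setBsjCounts(cons, ExpressionMatrix(m2))
  expect_error(quantifyBSJ(cons2, design), "design")
})

test_that("a coordinate tolerance merges near-identical junctions", {
  a <- canonicalizeJunctions(data.frame(
    chrom = "chr1", start = 100, end = 500, strand = "+"), "bed0-half-open")
  b <- canonicalizeJunctions(data.frame(
    chrom = "chr1", start = 101, end = 499, strand = "+"), "bed0-half-open")
  sets <- list(x = a, y = b)
  expect_equal(length(intersectCallers(sets, 2, tolerance = 0L)), 0L)
  expect_equal(length(intersectCallers(sets, 2, tolerance = 2L)), 1L)
})
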