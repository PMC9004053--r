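test_that("canonical seed sites are classified by their extensions", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"  # seed complement CTACCTC
  s <- findSeedSites(let7, "AAACTACCTCAAA")
  expect_equal(nrow(s), 1L)
  expect_identical(s$site_type, "8mer")
  expect_equal(s$position, 3L)
  # the four types from the same core, driven by flanks
  expect_identical(findSeedSites(let7, "GGTTACCTCAGG")$site_type, "7mer-A1")
  expect_identical(findSeedSites(let7, "GGCTACCTCGGG")$site_type, "7mer-m8")
  expect_identical(findSeedSites(let7, "GGGTACCTCGGG")$site_type, "6mer")
  # no complement possible on a homopolymer
  expect_equal(nrow(findSeedSites(let7, strrep("G", 50))), 0L)
  # short target yields an empty result
  expect_equal(nrow(findSeedSites(let7, "ACGUA")), 0L)
  expect_error(findSeedSites(let7, "ACGTNNNAC"), "A,C,G,U/T")
  expect_error(findSeedSites("ACGU", "ACGTACGT"), "18-25")
})

test_that("junction-spanning sites appear only on the circularized scan", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  # place the 8mer motif CTACCTCA across the end/start boundary
  L <- 60
  motif <- "CTACCTCA"
  body <- strrep("G", L - 8)
  tgt <- paste0(substr(motif, 5, 8), body, substr(motif, 1, 4))
  lin <- findSeedSites(let7, tgt, "linear")
  circ <- findSeedSites(let7, tgt, "circular")
  expect_equal(nrow(lin), 0L)
  expect_equal(nrow(circ), 1L)
  expect_identical(circ$site_type, "8mer")
  expect_true(circ$junction_spanning)
  expect_equal(circ$position, L - 4L)
  # linear sites are a subset of circular sites for the same sequence
  set.seed(5)
  for (i in 1:50) {
    tg <- random_dna(80)
    mi <- random_rna(22)
    linr <- findSeedSites(mi, tg, "linear")
    circ2 <- findSeedSites(mi, tg, "circular")
    expect_true(all(paste(linr$site_type, linr$position) %in%
                      paste(circ2$site_type, circ2$position)))
  }
})

test_that("the scanner matches the exhaustive all-offsets oracle on random pairs", {
  set.seed(71)
  for (i in 1:500) {
    mi <- random_rna(sample(18:25, 1))
    kind <- if (i %% 2 == 0) "circular" else "linear"
    tg <- random_dna(sample(30:120, 1))
    got <- findSeedSites(mi, tg, kind)
    want <- oracle_seed_scan(mi, tg, kind)
    expect_identical(site_keys(got), site_keys(want))
  }
})

test_that("the target map aggregates deterministically and validates ids", {
  mir <- c(m1 = "UGAGGUAGUAGGUUGUAUAGUU")
  tg <- c(t1 = strrep("G", 40),
          t2 = paste0(strrep("G", 10), "CTACCTCA", strrep("G", 22)),
          t3 = strrep("A", 40))
  tm <- buildTargetMap(mir, tg)
  s <- as.data.frame(mreSites(tm))
  expect_equal(nrow(s), 1L)
  expect_identical(s$target_id, "t2")
  expect_identical(s$site_type, "8mer")
  expect_equal(nrow(mreSites(buildTargetMap(character(0), tg))), 0L)
  expect_error(buildTargetMap(c(a = "A", a = "C"), tg), "named|duplicate")
  tg_dup <- c(t1 = "ACGT", t1 = "ACGT")
  expect_error(buildTargetMap(mir, tg_dup), "duplicate")
})

test_that("shared miRNAs equal the brute-force key intersection", {
  mk <- function(mirna, target, n) {
    data.frame(mirna_id = rep(mirna, n), target_id = rep(target, n),
               target_kind = "linear", site_type = "7mer-m8",
               position = seq(0, by = 10, length.out = n),
               junction_spanning = FALSE, stringsAsFactors = FALSE)
  }
  sites <- rbind(mk("miR-a", "circX", 2), mk("miR-b", "circX", 1),
                 mk("miR-b", "geneY", 3), mk("miR-c", "geneY", 1))
  tm <- new("TargetMap", sites = S4Vectors::DataFrame(sites))
  sh <- sharedMiRNAs(tm, "circX", "geneY")
  expect_identical(sh$mirna_id, "miR-b")
  expect_equal(sh$sites_on_circ, 1L)
  expect_equal(sh$sites_on_mrna, 3L)
  expect_equal(nrow(sharedMiRNAs(tm, "circX", "nowhere")), 0L)

  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    sites <- data.frame(
      mirna_id = sample(paste0("m", 1:6), n, TRUE),
      target_id = sample(c("c1", "c2", "g1", "g2"), n, TRUE),
      target_kind = "linear",
      site_type = sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), n, TRUE),
      position = sample.int(500, n),
      junction_spanning = FALSE, stringsAsFactors = FALSE)
    sites <- sites[!duplicated(paste(sites$mirna_id, sites$target_id,
                                     sites$position)), ]
    tm <- new("TargetMap", sites = S4Vectors::DataFrame(sites))
    got <- sharedMiRNAs(tm, "c1", "g1")$mirna_id
    want <- intersect(sites$mirna_id[sites$target_id == "c1"],
                      sites$mirna_id[sites$target_id == "g1"])
    expect_setequal(got, want)
  }
})

test_that("site-type filtering respects the strength ordering", {
  sites <- data.frame(
    mirna_id = c("m1", "m1"), target_id = c("c1", "g1"),
    target_kind = "linear", site_type = c("6mer", "8mer"),
    position = c(0L, 0L), junction_spanning = FALSE,
    stringsAsFactors = FALSE)
  tm <- new("TargetMap", sites = S4Vectors::DataFrame(sites))
  expect_equal(nrow(sharedMiRNAs(tm, "c1", "g1", min_site_type = "6mer")), 1L)
  expect_equal(nrow(sharedMiRNAs(tm, "c1", "g1", min_site_type = "7mer-m8")), 0L)
})
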