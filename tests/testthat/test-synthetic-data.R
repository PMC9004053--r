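test_that("generated truth plants direction-consistent triplets and is deterministic", {
  cfg <- generatorConfig(n_triplets = 20L, seed = 7L)
  truth <- generateTruth(cfg)
  tp <- as.data.frame(plantedTriplets(truth))
  expect_equal(nrow(tp), 20L)
  da <- as.data.frame(deAssignments(truth))
  lfc <- setNames(da$log2fc, paste(da$layer, da$feature_id))
  mm <- as.data.frame(plantedSites(truth))
  for (i in seq_len(nrow(tp))) {
    s <- if (tp$pattern[i] == "up-down-up") 1 else -1
    expect_equal(sign(lfc[paste("circ", tp$circ_id[i])]), s,
                 ignore_attr = TRUE)
    expect_equal(sign(lfc[paste("mrna", tp$mrna_id[i])]), s,
                 ignore_attr = TRUE)
    expect_equal(sign(lfc[paste("mirna", tp$mirna_id[i])]), -s,
                 ignore_attr = TRUE)
    expect_gt(sum(mm$mirna_id == tp$mirna_id[i] &
                    mm$target_id == tp$circ_id[i]), 0)
    expect_gt(sum(mm$mirna_id == tp$mirna_id[i] &
                    mm$target_id == tp$mrna_id[i]), 0)
  }
  truth2 <- generateTruth(cfg)
  expect_identical(as.data.frame(plantedTriplets(truth2)), tp)
  expect_identical(as.data.frame(truth2@nb_params),
                   as.data.frame(truth@nb_params))
  expect_identical(as.data.frame(truth2@mre_map), mm)
})

test_that("decoy fractions are honoured exactly (enumerated from the emitted maps)", {
  cfg <- generatorConfig(n_triplets = 20L, decoy_mre_no_de = 0.2, seed = 11L)
  truth <- generateTruth(cfg)
  mm <- as.data.frame(plantedSites(truth))
  da <- as.data.frame(deAssignments(truth))
  de_ids <- paste(da$layer, da$feature_id)
  # enumerate all circRNA-mRNA pairs sharing >= 1 miRNA in the MRE map
  circ_t <- unique(mm$target_id[mm$target_kind == "circular"])
  mrna_t <- unique(mm$target_id[mm$target_kind == "linear"])
  shared_non_de <- 0L
  for (ci in circ_t) {
    for (mr in mrna_t) {
      sh <- intersect(mm$mirna_id[mm$target_id == ci],
                      mm$mirna_id[mm$target_id == mr])
      if (!length(sh)) next
      any_de <- paste("circ", ci) %in% de_ids ||
        paste("mrna", mr) %in% de_ids ||
        any(paste("mirna", sh) %in% de_ids)
      if (!any_de) shared_non_de <- shared_non_de + 1L
    }
  }
  expect_equal(shared_non_de, round(0.2 * 20))
})

test_that("simulated counts match their NB parameterization", {
  # phi = 0 degenerates to Poisson: mean over 1000 samples near mu
  cfg <- generatorConfig(n_mirna = 2L, n_mrna = 2L, n_circ = 2L,
                         n_triplets = 0L, decoy_de_no_mre = 0,
                         decoy_mre_no_de = 0, decoy_wrong_direction = 0,
                         dispersion = 0, seed = 5L)
  truth <- generateTruth(cfg)
  np <- truth@nb_params
  np$mean_a <- rep(100, nrow(np)); np$mean_b <- rep(100, nrow(np))
  truth@nb_params <- np
  design <- makeSampleDesign(replicates = 500L)
  mats <- simulateCounts(truth, design)
  x <- exprValues(mats$mirna)[1L, ]
  expect_lt(abs(mean(x) - 100), 3 * sqrt(100 / 1000))

  # planted log2FC = 2 from mu_A = 50: B/A mean ratio near 4
  truth2 <- truth
  np2 <- truth2@nb_params
  np2$mean_a <- rep(50, nrow(np2)); np2$mean_b <- rep(200, nrow(np2))
  np2$dispersion <- rep(0.1, nrow(np2))
  truth2@nb_params <- np2
  mats2 <- simulateCounts(truth2, makeSampleDesign(replicates = 500L))
  y <- exprValues(mats2$mrna)[1L, ]
  grp <- rep(c("A", "B"), each = 500)
  ratio <- mean(y[grp == "B"]) / mean(y[grp == "A"])
  se <- ratio * sqrt((200 + 0.1 * 200^2) / 200^2 / 500 +
                       (50 + 0.1 * 50^2) / 50^2 / 500)
  expect_lt(abs(ratio - 4), 3 * se)
})

test_that("an empty feature universe yields empty matrices with sample columns", {
  cfg <- generatorConfig(n_mirna = 0L, n_mrna = 0L, n_circ = 0L,
                         n_triplets = 0L, decoy_de_no_mre = 0,
                         decoy_mre_no_de = 0, decoy_wrong_direction = 0,
                         seed = 1L)
  truth <- generateTruth(cfg)
  mats <- simulateCounts(truth, makeSampleDesign())
  for (m in mats) {
    expect_equal(nrow(m), 0L)
    expect_equal(ncol(m), 6L)
  }
})

test_that("simulated sequences carry exactly the planted sites", {
  cfg <- generatorConfig(seed = 13L)
  truth <- generateTruth(cfg)
  seqs <- simulateSequences(truth)
  mm <- as.data.frame(plantedSites(truth))
  mir <- as.character(seqs$mirna)
  tgt <- as.character(seqs$targets)
  # oracle scan of every (miRNA, target) pair recovers the planted map and
  # nothing else
  found <- list()
  for (t in names(tgt)) {
    for (m in names(mir)) {
      s <- oracle_seed_scan(mir[[m]], tgt[[t]], seqs$kinds[[t]])
      if (nrow(s)) {
        s$mirna_id <- m; s$target_id <- t
        found[[length(found) + 1]] <- s
      }
    }
  }
  found <- do.call(rbind, found)
  expect_setequal(
    paste(found$mirna_id, found$target_id, found$site_type, found$position,
          found$junction_spanning),
    paste(mm$mirna_id, mm$target_id, mm$site_type, mm$position,
          mm$junction_spanning))

  # planted motif arithmetic: an 8mer site is the reverse complement of
  # miRNA positions 2-8 followed by A
  e8 <- mm[mm$site_type == "8mer" & !mm$junction_spanning, ][1, ]
  ms <- chartr("U", "T", mir[[e8$mirna_id]])
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                       "")[[1]]), collapse = "")
  expect_identical(substr(tgt[[e8$target_id]], e8$position + 1,
                          e8$position + 8),
                   paste0(rc(substr(ms, 2, 8)), "A"))

  # the junction-spanning site exists only on the circularized sequence
  js <- mm[mm$junction_spanning, ][1, ]
  lin <- findSeedSites(mir[[js$mirna_id]], tgt[[js$target_id]], "linear")
  circ <- findSeedSites(mir[[js$mirna_id]], tgt[[js$target_id]], "circular")
  expect_false(any(lin$position == js$position &
                     lin$site_type == js$site_type))
  expect_true(any(circ$position == js$position & circ$junction_spanning))
})

test_that("an empty MRE map yields site-free sequences", {
  cfg <- generatorConfig(n_mirna = 6L, n_mrna = 8L, n_circ = 4L,
                         n_triplets = 0L, decoy_de_no_mre = 0,
                         decoy_mre_no_de = 0, decoy_wrong_direction = 0,
                         seed = 3L)
  truth <- generateTruth(cfg)
  expect_equal(nrow(plantedSites(truth)), 0L)
  seqs <- simulateSequences(truth)
  tm <- buildTargetMap(seqs$mirna, seqs$targets, seqs$kinds)
  expect_equal(nrow(mreSites(tm)), 0L)
})

test_that("caller outputs follow their noise profiles", {
  cfg <- generatorConfig(seed = 2L)
  truth <- generateTruth(cfg)
  # noiseless profile reproduces the true set exactly, and the five-way
  # intersection of noiseless callers equals the truth
  perfect <- truth@caller_profiles
  perfect$sensitivity <- rep(1, nrow(perfect))
  perfect$false_rate <- rep(0, nrow(perfect))
  truth@caller_profiles <- perfect
  outs <- simulateCallerOutputs(truth)
  sets <- lapply(outs, canonicalizeJunctions)
  truth_ids <- S4Vectors::mcols(trueJunctions(truth))$circ_id
  for (s in sets) {
    expect_setequal(S4Vectors::mcols(s)$circ_id, truth_ids)
  }
  cons <- intersectCallers(sets, min_callers = 5L)
  expect_setequal(S4Vectors::mcols(cons)$circ_id, truth_ids)

  # binomial recovery: sensitivity 0.8 over 100 junctions, 200 seeds
  cfg2 <- generatorConfig(
    n_circ = 100L, n_triplets = 0L, decoy_de_no_mre = 0,
    decoy_mre_no_de = 0, decoy_wrong_direction = 0,
    caller_sensitivity = c(only = 0.8), caller_false_rate = c(only = 0),
    seed = 9L)
  truth2 <- generateTruth(cfg2)
  rec <- vapply(1:200, function(s) {
    truth2@seed <- as.integer(s)
    nrow(simulateCallerOutputs(truth2)$only)
  }, numeric(1))
  se <- sqrt(100 * 0.8 * 0.2)
  expect_lt(abs(mean(rec) - 80), 3 * se / sqrt(200))
})

test_that("generator rejects impossible sizing", {
  expect_error(generatorConfig(n_mirna = 5L, n_triplets = 20L), "exceed")
  expect_error(generatorConfig(log2fc = -1), "positive")
})
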