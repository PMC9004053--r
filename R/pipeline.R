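#' Run the ceRNA inference pipeline end to end
#'
#' In synthetic mode (the default) the pipeline generates a ground-truthed
#' scenario from \code{config} and pushes it through every stage: caller-set
#' canonicalization and consensus intersection, host-transcript mapping, BSJ
#' quantification, per-layer differential expression, seed-site target
#' mapping, direction/MRE/correlation-filtered triplet assembly, and
#' circRNA-host correlation, finishing with a truth-vs-called evaluation.
#' With \code{inputs} (see \code{\link{loadInputs}}) the same stages run on
#' data read from disk and no evaluation is produced. Outputs are written to
#' \code{out_dir} when given; identical (config, seed) yield byte-identical
#' result tables.
#'
#' @param config a \code{\link{generatorConfig}} (synthetic mode).
#' @param thresholds a \code{\link{thresholdConfig}}.
#' @param inputs optional list of typed inputs (file mode).
#' @param out_dir optional output directory.
#' @param comparison label for the two-group comparison; default
#'   \code{"<groupA>_vs_<groupB>"}.
#' @return list with \code{consensus} (GRanges), \code{de} (list of DE tables
#'   per layer), \code{triplets}, \code{host_correlation},
#'   \code{evaluation} (synthetic mode), \code{truth} (synthetic mode),
#'   \code{design}, \code{counts}, \code{target_map} and \code{run_record}.
#' @examples
#' \donttest{
#' res <- runPipeline(generatorConfig(seed = 1))
#' res$evaluation
#' }
#' @export
runPipeline <- function(config = generatorConfig(),
                        thresholds = thresholdConfig(),
                        inputs = NULL, out_dir = NULL, comparison = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  synthetic <- is.null(inputs)
  if (synthetic) {
    truth <- stage("generate_truth", generateTruth(config))
    design <- stage("design", makeSampleDesign(
      config@groups, config@replicates, config@library_size))
    counts <- stage("simulate_counts", simulateCounts(truth, design))
    seqs <- stage("simulate_sequences", simulateSequences(truth))
    call_dfs <- stage("simulate_callers", simulateCallerOutputs(truth))
    call_sets <- lapply(call_dfs, canonicalizeJunctions)
    transcripts <- as.data.frame(truth@transcripts)
  } else {
    for (nm in c("design", "counts", "mirna", "targets", "call_sets")) {
      .assert(!is.null(inputs[[nm]]), "inputs lack '%s'", nm)
    }
    truth <- NULL
    call_dfs <- NULL
    design <- inputs$design
    counts <- inputs$counts
    seqs <- list(mirna = inputs$mirna, targets = inputs$targets,
                 kinds = inputs$kinds)
    call_sets <- lapply(inputs$call_sets, canonicalizeJunctions)
    transcripts <- inputs$transcripts
    if (is.null(transcripts)) {
      transcripts <- data.frame(transcript_id = character(0),
                                chrom = character(0), strand = character(0),
                                start = integer(0), end = integer(0))
    }
  }
  groups <- unique(design$group)
  ga <- groups[1L]; gb <- groups[2L]
  if (is.null(comparison)) comparison <- paste0(ga, "_vs_", gb)

  consensus <- stage("consensus", intersectCallers(
    call_sets, min_callers = thresholds@min_callers,
    tolerance = thresholds@junction_tolerance))
  consensus <- stage("map_to_host", mapToHost(consensus, transcripts))
  consensus <- stage("quantify_bsj", setBsjCounts(consensus, counts$circ))
  bsj_counts <- quantifyBSJ(consensus, design, normalize = FALSE)
  bsj_cpm <- quantifyBSJ(consensus, design, normalize = TRUE)

  # library sizes from the design (total mapped reads): immune to the
  # compositional bias column sums pick up when many features are DE
  libs <- setNames(design$library_size, design$sample_id)
  de <- stage("de_analysis", list(
    mirna = testTwoGroup(counts$mirna, design, ga, gb, thresholds,
                         library_sizes = libs),
    mrna = testTwoGroup(counts$mrna, design, ga, gb, thresholds,
                        library_sizes = libs),
    circ = testTwoGroup(bsj_counts, design, ga, gb, thresholds,
                        library_sizes = libs)))

  mrna_expr <- stage("normalize", {
    if (!is.null(featureLengths(counts$mrna))) {
      normalizeCounts(counts$mrna, "FPKM", library_sizes = libs)
    } else {
      normalizeCounts(counts$mrna, "CPM", library_sizes = libs)
    }
  })

  target_ids <- intersect(names(seqs$targets),
                          c(rownames(counts$mrna), mcols(consensus)$circ_id))
  target_map <- stage("mre_prediction", buildTargetMap(
    seqs$mirna, seqs$targets[target_ids], seqs$kinds[target_ids]))

  triplets <- stage("cerna_network", assembleTriplets(
    de$circ, de$mirna, de$mrna, target_map, bsj_cpm, mrna_expr,
    thresholds, comparison))
  hostcor <- stage("host_correlation", hostCorrelation(
    consensus, bsj_cpm, mrna_expr, de$circ, de$mrna, thresholds))

  evaluation <- if (synthetic) {
    evaluatePipeline(truth, consensus, de, triplets)
  } else NULL

  stages <- data.frame(
    stage = c("consensus", "de_mirna", "de_mrna", "de_circ",
              "mre_prediction", "cerna_network", "host_correlation"),
    n_in = c(sum(lengths(call_sets)), nrow(counts$mirna),
             nrow(counts$mrna), nrow(bsj_counts),
             length(seqs$mirna) * length(target_ids),
             nrow(de$circ) + nrow(de$mirna) + nrow(de$mrna),
             length(consensus)),
    n_out = c(length(consensus), nrow(de$mirna), nrow(de$mrna),
              nrow(de$circ), nrow(mreSites(target_map)), nrow(triplets),
              nrow(hostcor)),
    stringsAsFactors = FALSE)
  run_record <- list(
    package = "circSponge",
    version = as.character(packageVersion("circSponge")),
    seed = if (synthetic) config@seed else NA_integer_,
    mode = if (synthetic) "synthetic" else "files",
    comparison = comparison,
    thresholds = .thresholdsAsList(thresholds),
    config = if (synthetic) .configAsList(config) else NULL,
    stages = stages,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- list(consensus = consensus, de = de, triplets = triplets,
                 host_correlation = hostcor, evaluation = evaluation,
                 truth = truth, design = design, counts = counts,
                 sequences = seqs, caller_outputs = call_dfs,
                 bsj_cpm = bsj_cpm, mrna_expr = mrna_expr,
                 target_map = target_map, run_record = run_record)
  if (!is.null(out_dir)) writePipelineOutputs(result, out_dir)
  result
}

.thresholdsAsList <- function(th) {
  list(fdr_threshold = th@fdr_threshold,
       corr_p_threshold = th@corr_p_threshold, corr_sign = th@corr_sign,
       min_shared_mirnas = th@min_shared_mirnas,
       min_callers = th@min_callers, pseudocount = th@pseudocount,
       min_site_type = th@min_site_type,
       junction_tolerance = th@junction_tolerance)
}

.configAsList <- function(cf) {
  nm <- slotNames(cf)
  out <- lapply(nm, function(s) slot(cf, s))
  names(out) <- nm
  out
}

#' Compare pipeline output against the planted truth
#'
#' Per-stage sensitivity and precision: consensus junctions against the true
#' junction set; per-layer DE calls against the planted DE assignments
#' (sensitivity over planted features the stage actually tested); emitted
#' triplets against the planted triplets (matching ids and pattern), both
#' end-to-end (over all planted triplets) and conditional on the triplet's
#' circRNA having survived consensus - the assembly-stage metric.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param consensus consensus GRanges.
#' @param de named list of DE tables (\code{mirna}, \code{mrna},
#'   \code{circ}).
#' @param triplets triplet table from \code{\link{assembleTriplets}}.
#' @return data.frame with columns \code{stage}, \code{sensitivity},
#'   \code{precision}, \code{n_true}, \code{n_called}.
#' @export
evaluatePipeline <- function(truth, consensus, de, triplets) {
  rows <- list()
  add <- function(stage, tp, n_true, n_called) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage,
      sensitivity = if (n_true > 0) tp / n_true else NA_real_,
      precision = if (n_called > 0) tp / n_called else NA_real_,
      n_true = n_true, n_called = n_called, stringsAsFactors = FALSE)
  }
  true_ids <- mcols(truth@junctions)$circ_id
  called_ids <- mcols(consensus)$circ_id
  add("consensus", length(intersect(true_ids, called_ids)),
      length(true_ids), length(called_ids))

  da <- as.data.frame(truth@de_assignments)
  for (layer in c("mirna", "mrna", "circ")) {
    tab <- de[[layer]]
    planted <- da$feature_id[da$layer == layer]
    planted_tested <- intersect(planted, tab$feature_id)
    called <- tab$feature_id[tab$direction != "ns"]
    add(paste0("de_", layer), length(intersect(planted_tested, called)),
        length(planted_tested), length(called))
  }

  tp_tab <- as.data.frame(truth@planted_triplets)
  truth_key <- paste(tp_tab$circ_id, tp_tab$mirna_id, tp_tab$mrna_id,
                     tp_tab$pattern)
  out_key <- paste(triplets$circ_id, triplets$mirna_id, triplets$mrna_id,
                   triplets$pattern)
  tp <- length(intersect(truth_key, out_key))
  add("triplets", tp, nrow(tp_tab), nrow(triplets))
  reachable <- sum(tp_tab$circ_id %in% called_ids)
  add("triplets_conditional", tp, reachable, nrow(triplets))
  do.call(rbind, rows)
}

#' Write all pipeline outputs
#'
#' Design, count matrices, sequences, per-caller call sets, the consensus
#' table, DE tables, the triplet edge list with a node-attribute table
#' (mean abundance and -log2 FDR per node, for graph tools), the host
#' correlation table, the evaluation (synthetic mode), the truth ledger
#' (synthetic mode) and the run record.
#'
#' @param result list returned by \code{\link{runPipeline}}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
writePipelineOutputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  writeSampleDesign(result$design, fp("design.tsv"))
  for (layer in names(result$counts)) {
    writeCountMatrix(result$counts[[layer]],
                     fp(sprintf("counts_%s.tsv", layer)))
  }
  if (!is.null(result$sequences$mirna)) {
    writeXStringSet(result$sequences$mirna, fp("mirna.fa"))
    writeXStringSet(result$sequences$targets, fp("targets.fa"))
  }
  if (!is.null(result$caller_outputs)) {
    for (cl in names(result$caller_outputs)) {
      writeJunctionCalls(result$caller_outputs[[cl]],
                         fp(sprintf("calls_%s.tsv", cl)))
    }
  }
  cons <- result$consensus
  cons_df <- data.frame(
    circ_id = mcols(cons)$circ_id,
    chrom = as.character(seqnames(cons)),
    start = start(cons) - 1L, end = end(cons),
    strand = as.character(strand(cons)),
    n_callers = mcols(cons)$n_callers,
    supporting_callers = vapply(mcols(cons)$supporting_callers,
                                paste, character(1), collapse = ","),
    host_transcript = mcols(cons)$host_transcript,
    stringsAsFactors = FALSE)
  write.table(cons_df, fp("consensus.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (layer in names(result$de)) {
    write.table(as.data.frame(result$de[[layer]]),
                fp(sprintf("de_%s.tsv", layer)), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(as.data.frame(result$triplets), fp("triplets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(.nodeAttributes(result), fp("triplet_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$host_correlation),
              fp("host_correlation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(result$evaluation)) {
    write.table(result$evaluation, fp("evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$truth)) {
    writeTruthLedger(result$truth, fp("truth.json"))
  }
  jsonlite::write_json(result$run_record, fp("run_record.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(out_dir)
}

# node metadata mirroring the network rendering: mean abundance and
# -log2(FDR) per triplet member
.nodeAttributes <- function(result) {
  tr <- result$triplets
  if (!nrow(tr)) {
    return(data.frame(node = character(0), kind = character(0),
                      mean_abundance = numeric(0), neg_log2_fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pick <- function(ids, layer) {
    tab <- as.data.frame(result$de[[layer]])
    i <- match(ids, tab$feature_id)
    data.frame(node = ids, kind = layer,
               mean_abundance = tab$mean_abundance[i],
               neg_log2_fdr = -log2(pmax(tab$fdr[i], 1e-300)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(unique(tr$circ_id), "circ"),
               pick(unique(tr$mirna_id), "mirna"),
               pick(unique(tr$mrna_id), "mrna"))
  out[.corder(out$kind, out$node), , drop = FALSE]
}
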