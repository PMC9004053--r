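#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#'   findOverlaps
#' @importFrom Biostrings DNAStringSet RNAStringSet readDNAStringSet
#'   writeXStringSet
NULL

.EXPR_LAYERS <- c("counts", "CPM", "FPKM", "BSJ-CPM")
.SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
.SITE_RANK <- setNames(1:4, .SITE_TYPES)
.PATTERNS <- c("up-down-up", "down-up-down")
.DIALECTS <- c("bed0-half-open", "one-based-inclusive")

#' ExpressionMatrix: a features-by-samples abundance table
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' carrying a single assay plus a \code{layer} tag recording what the values
#' are: raw \code{counts}, \code{CPM}, \code{FPKM} or \code{BSJ-CPM}
#' (back-splice-junction reads per million). Optional per-feature lengths
#' (nucleotides), required for FPKM, live in \code{rowData()$length}.
#'
#' @slot layer character scalar, one of \code{counts}, \code{CPM},
#'   \code{FPKM}, \code{BSJ-CPM}.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(layer = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character(0)
  if (length(object@layer) != 1L || !object@layer %in% .EXPR_LAYERS) {
    msg <- c(msg, sprintf("layer must be one of %s",
                          paste(.EXPR_LAYERS, collapse = ", ")))
  }
  v <- assay(object)
  if (length(v)) {
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
    else if (any(v < 0)) msg <- c(msg, "values must be non-negative")
    else if (identical(object@layer, "counts") &&
             any(abs(v - round(v)) > 1e-8)) {
      msg <- c(msg, "counts layer must contain integers")
    }
  }
  if (nrow(object) > 0L) {
    if (is.null(rownames(object))) msg <- c(msg, "feature ids required")
    else if (anyDuplicated(rownames(object))) {
      msg <- c(msg, "feature ids must be unique")
    }
  }
  if (ncol(object) > 0L) {
    if (is.null(colnames(object))) msg <- c(msg, "sample ids required")
    else if (anyDuplicated(colnames(object))) {
      msg <- c(msg, "sample ids must be unique")
    }
  }
  len <- rowData(object)$length
  if (!is.null(len) && length(len) &&
      any(!is.na(len) & (!is.finite(len) | len <= 0))) {
    msg <- c(msg, "feature lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param layer one of \code{"counts"}, \code{"CPM"}, \code{"FPKM"},
#'   \code{"BSJ-CPM"}.
#' @param feature_lengths optional named numeric vector of feature lengths in
#'   nucleotides; names must cover the rownames of \code{values}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m)
#' exprLayer(em)
#' @export
ExpressionMatrix <- function(values, layer = "counts",
                             feature_lengths = NULL) {
  .assert(is.matrix(values), "values must be a matrix")
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(feature_lengths) && nrow(values) > 0L) {
    .assert(!is.null(names(feature_lengths)) &&
              all(rownames(values) %in% names(feature_lengths)),
            "feature_lengths must be named and cover all feature ids")
    rd$length <- as.numeric(feature_lengths[rownames(values)])
  }
  se <- SummarizedExperiment(assays = list(values = values), rowData = rd)
  new("ExpressionMatrix", se, layer = layer)
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              object@layer, nrow(object), ncol(object)))
  if (!is.null(rowData(object)$length)) cat("  with feature lengths\n")
})

#' Analysis thresholds
#'
#' Bundles the cutoffs used across the pipeline: the FDR below which a
#' feature is called differentially expressed, the Pearson p-value and sign
#' required of a circRNA-mRNA co-expression pair, the minimum number of
#' shared miRNAs per circRNA-mRNA pair, the minimum number of callers that
#' must support a back-splice junction, the pseudocount added to group-mean
#' CPM before the log2 fold change, the weakest seed-site type that counts as
#' a miRNA response element, and the coordinate tolerance for matching
#' junctions across callers.
#'
#' @export
setClass("ThresholdConfig", representation(
  fdr_threshold = "numeric",
  corr_p_threshold = "numeric",
  corr_sign = "character",
  min_shared_mirnas = "integer",
  min_callers = "integer",
  pseudocount = "numeric",
  min_site_type = "character",
  junction_tolerance = "integer"))

setValidity("ThresholdConfig", function(object) {
  msg <- character(0)
  chk01 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
      sprintf("%s must be in (0,1)", nm)
    } else character(0)
  }
  msg <- c(msg, chk01(object@fdr_threshold, "fdr_threshold"))
  msg <- c(msg, chk01(object@corr_p_threshold, "corr_p_threshold"))
  if (!object@corr_sign %in% c("positive", "any")) {
    msg <- c(msg, "corr_sign must be 'positive' or 'any'")
  }
  if (object@min_shared_mirnas < 1L) msg <- c(msg, "min_shared_mirnas >= 1")
  if (object@min_callers < 1L) msg <- c(msg, "min_callers >= 1")
  if (!is.finite(object@pseudocount) || object@pseudocount <= 0) {
    msg <- c(msg, "pseudocount must be > 0")
  }
  if (!object@min_site_type %in% .SITE_TYPES) {
    msg <- c(msg, "min_site_type must be a canonical site type")
  }
  if (object@junction_tolerance < 0L) msg <- c(msg, "junction_tolerance >= 0")
  if (length(msg)) msg else TRUE
})

#' @param fdr_threshold FDR below which a feature is differentially
#'   expressed (default 0.05).
#' @param corr_p_threshold two-sided Pearson p-value cutoff for the
#'   co-expression filter (default 0.05).
#' @param corr_sign \code{"positive"} (default; ceRNA logic implies positive
#'   circRNA-mRNA coupling) or \code{"any"}.
#' @param min_shared_mirnas minimum shared miRNAs per circRNA-mRNA pair
#'   (default 1).
#' @param min_callers minimum supporting callers for a consensus junction
#'   (default 5, the five-way intersection).
#' @param pseudocount added to group-mean CPM before log2 fold change
#'   (default 0.5).
#' @param min_site_type weakest seed-site type counted as an MRE
#'   (default \code{"7mer-m8"}, i.e. 7mer-m8 or 8mer).
#' @param junction_tolerance +/- nucleotides allowed when matching junctions
#'   across callers (default 0, exact matching).
#' @return a \linkS4class{ThresholdConfig}.
#' @rdname ThresholdConfig-class
#' @export
thresholdConfig <- function(fdr_threshold = 0.05, corr_p_threshold = 0.05,
                            corr_sign = c("positive", "any"),
                            min_shared_mirnas = 1L, min_callers = 5L,
                            pseudocount = 0.5, min_site_type = "7mer-m8",
                            junction_tolerance = 0L) {
  new("ThresholdConfig",
      fdr_threshold = fdr_threshold,
      corr_p_threshold = corr_p_threshold,
      corr_sign = match.arg(corr_sign),
      min_shared_mirnas = as.integer(min_shared_mirnas),
      min_callers = as.integer(min_callers),
      pseudocount = pseudocount,
      min_site_type = min_site_type,
      junction_tolerance = as.integer(junction_tolerance))
}

setMethod("show", "ThresholdConfig", function(object) {
  cat("ThresholdConfig:\n")
  cat(sprintf("  FDR < %g; corr p < %g (%s); >= %d shared miRNA(s); >= %d caller(s)\n",
              object@fdr_threshold, object@corr_p_threshold, object@corr_sign,
              object@min_shared_mirnas, object@min_callers))
  cat(sprintf("  pseudocount %g; min site type %s; junction tolerance +/-%d\n",
              object@pseudocount, object@min_site_type,
              object@junction_tolerance))
})

#' Synthetic-scenario configuration
#'
#' Parameters of the ground-truthed generator: feature counts per RNA layer,
#' number of planted sponge triplets, planted effect size, negative-binomial
#' dispersion, decoy fractions, caller noise profiles, sequence lengths, the
#' two-group triplicate design, and the seed. Defaults define the package's
#' standard validation scenario (see the methods vignette).
#'
#' @export
setClass("GeneratorConfig", representation(
  n_mirna = "integer", n_mrna = "integer", n_circ = "integer",
  n_triplets = "integer",
  log2fc = "numeric", dispersion = "numeric",
  decoy_de_no_mre = "numeric", decoy_mre_no_de = "numeric",
  decoy_wrong_direction = "numeric",
  planted_mean_range = "numeric", background_mean_range = "numeric",
  shared_factor_sdlog = "numeric",
  groups = "character", replicates = "integer", library_size = "numeric",
  mirna_length = "integer", target_lengths = "numeric",
  caller_sensitivity = "numeric", caller_false_rate = "numeric",
  n_corr_hosts = "integer",
  seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  if (object@n_triplets < 0L) msg <- c(msg, "n_triplets must be >= 0")
  if (object@log2fc <= 0) msg <- c(msg, "log2fc magnitude must be positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  for (nm in c("decoy_de_no_mre", "decoy_mre_no_de", "decoy_wrong_direction")) {
    if (slot(object, nm) < 0) msg <- c(msg, paste(nm, "must be >= 0"))
  }
  if (length(object@groups) < 2L || anyDuplicated(object@groups)) {
    msg <- c(msg, "at least two distinct groups required")
  }
  if (object@replicates < 2L) msg <- c(msg, "need >= 2 replicates per group")
  if (any(object@library_size <= 0)) msg <- c(msg, "library_size must be > 0")
  if (object@mirna_length < 18L || object@mirna_length > 25L) {
    msg <- c(msg, "mirna_length must be 18-25 nt")
  }
  if (!all(c("mrna", "circ") %in% names(object@target_lengths)) ||
      any(object@target_lengths < 30)) {
    msg <- c(msg, "target_lengths must name mrna and circ, each >= 30 nt")
  }
  if (length(object@caller_sensitivity) < 1L ||
      is.null(names(object@caller_sensitivity)) ||
      any(object@caller_sensitivity <= 0 | object@caller_sensitivity > 1)) {
    msg <- c(msg, "caller sensitivities must be named and in (0,1]")
  }
  if (!identical(sort(names(object@caller_false_rate)),
                 sort(names(object@caller_sensitivity))) ||
      any(object@caller_false_rate < 0)) {
    msg <- c(msg, "caller_false_rate must be >= 0 for the same callers")
  }
  # sizing: planted + decoys must fit into each layer
  K <- object@n_triplets
  nd2 <- round(object@decoy_mre_no_de * K)
  nd3 <- round(object@decoy_wrong_direction * K)
  nd1 <- round(object@decoy_de_no_mre * K)
  need <- K + nd1 + nd2 + nd3
  if (need > object@n_mirna || need > object@n_mrna || need > object@n_circ) {
    msg <- c(msg, sprintf(
      "planted triplets plus decoys (%d features/layer) exceed layer sizes",
      need))
  }
  if (length(msg)) msg else TRUE
})

#' @param n_mirna,n_mrna,n_circ features per RNA layer.
#' @param n_triplets number K of planted sponge triplets.
#' @param log2fc magnitude of planted log2 fold changes (> 0).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param decoy_de_no_mre,decoy_mre_no_de,decoy_wrong_direction decoy
#'   fractions of K: DE features without shared MREs; circRNA-miRNA-mRNA
#'   trios sharing MREs but not DE; trios that are DE and correlated but with
#'   the miRNA moving in the same (pattern-breaking) direction.
#' @param planted_mean_range,background_mean_range log-uniform base-mean
#'   ranges for planted/DE and background features.
#' @param shared_factor_sdlog sdlog of the per-sample log-normal factor shared
#'   by a planted circRNA-mRNA pair, inducing their positive co-expression.
#' @param groups,replicates,library_size the two-group design: group labels,
#'   replicates per group, expected library size per sample.
#' @param mirna_length miRNA length in nt (18-25).
#' @param target_lengths named lengths (nt) for \code{mrna} and \code{circ}
#'   target sequences.
#' @param caller_sensitivity,caller_false_rate named per-caller recall in
#'   (0,1] and Poisson false-call rate.
#' @param n_corr_hosts number of circRNA/host pairs given a shared
#'   co-expression factor (emulating circRNAs coupled to their linear host).
#' @param seed integer seed controlling every draw.
#' @return a \linkS4class{GeneratorConfig}.
#' @rdname GeneratorConfig-class
#' @export
generatorConfig <- function(n_mirna = 40L, n_mrna = 150L, n_circ = 60L,
                            n_triplets = 20L, log2fc = 3, dispersion = 0.1,
                            decoy_de_no_mre = 0.2, decoy_mre_no_de = 0.2,
                            decoy_wrong_direction = 0.2,
                            planted_mean_range = c(100, 400),
                            background_mean_range = c(5, 300),
                            shared_factor_sdlog = 0.2,
                            groups = c("A", "B"), replicates = 3L,
                            library_size = 1e6,
                            mirna_length = 22L,
                            target_lengths = c(mrna = 300, circ = 250),
                            caller_sensitivity = c(
                              find_circ = 1.0, circRNA_Finder = 0.95,
                              CIRCexplorer2 = 0.9, CIRI = 0.85,
                              MapSplice = 0.8),
                            caller_false_rate = c(
                              find_circ = 40, circRNA_Finder = 30,
                              CIRCexplorer2 = 20, CIRI = 15, MapSplice = 5),
                            n_corr_hosts = 1L, seed = 1L) {
  new("GeneratorConfig",
      n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
      n_circ = as.integer(n_circ), n_triplets = as.integer(n_triplets),
      log2fc = log2fc, dispersion = dispersion,
      decoy_de_no_mre = decoy_de_no_mre, decoy_mre_no_de = decoy_mre_no_de,
      decoy_wrong_direction = decoy_wrong_direction,
      planted_mean_range = planted_mean_range,
      background_mean_range = background_mean_range,
      shared_factor_sdlog = shared_factor_sdlog,
      groups = groups, replicates = as.integer(replicates),
      library_size = library_size,
      mirna_length = as.integer(mirna_length),
      target_lengths = target_lengths,
      caller_sensitivity = caller_sensitivity,
      caller_false_rate = caller_false_rate,
      n_corr_hosts = as.integer(n_corr_hosts),
      seed = as.integer(seed))
}

#' Ground truth of a synthetic scenario
#'
#' Everything the generator planted: the sponge triplets with their direction
#' patterns, per-feature DE assignments (log2 fold change, B over A), the
#' miRNA response-element map, NB parameters per feature, true back-splice
#' junctions, circRNA host assignments with transcript spans, caller noise
#' profiles, and the co-expression pairs receiving a shared per-sample
#' factor.
#'
#' @export
setClass("SyntheticTruth", representation(
  config = "GeneratorConfig",
  planted_triplets = "DataFrame",
  de_assignments = "DataFrame",
  mre_map = "DataFrame",
  nb_params = "DataFrame",
  junctions = "GRanges",
  hosts = "DataFrame",
  transcripts = "DataFrame",
  caller_profiles = "DataFrame",
  corr_pairs = "DataFrame",
  seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  tp <- object@planted_triplets
  if (nrow(tp)) {
    if (!all(tp$pattern %in% .PATTERNS)) {
      msg <- c(msg, "triplet patterns must be up-down-up or down-up-down")
    }
    de <- object@de_assignments
    lfc <- setNames(de$log2fc, paste(de$layer, de$feature_id))
    mm <- object@mre_map
    for (i in seq_len(nrow(tp))) {
      s <- if (tp$pattern[i] == "up-down-up") 1 else -1
      ok <- isTRUE(sign(lfc[paste("circ", tp$circ_id[i])]) == s) &&
        isTRUE(sign(lfc[paste("mrna", tp$mrna_id[i])]) == s) &&
        isTRUE(sign(lfc[paste("mirna", tp$mirna_id[i])]) == -s)
      if (!ok) {
        msg <- c(msg, sprintf("triplet %d directions inconsistent", i))
      }
      has <- function(tid) any(mm$mirna_id == tp$mirna_id[i] &
                                 mm$target_id == tid)
      if (!(has(tp$circ_id[i]) && has(tp$mrna_id[i]))) {
        msg <- c(msg, sprintf("triplet %d lacks shared MRE sites", i))
      }
    }
  }
  if (nrow(object@nb_params) && any(object@nb_params$dispersion < 0)) {
    msg <- c(msg, "dispersions must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d planted triplet(s), %d DE assignment(s), %d MRE site(s)\n",
    nrow(object@planted_triplets), nrow(object@de_assignments),
    nrow(object@mre_map)))
  cat(sprintf("  %d true junction(s), %d caller profile(s), seed %d\n",
              length(object@junctions), nrow(object@caller_profiles),
              object@seed))
})

#' Map of predicted miRNA response elements
#'
#' Aggregated seed-match sites over all (miRNA, target) pairs. One row per
#' site: miRNA id, target id, target kind (linear/circular), site type,
#' 0-based position on the target, and whether the site spans a back-splice
#' junction.
#'
#' @export
setClass("TargetMap", representation(sites = "DataFrame"))

setValidity("TargetMap", function(object) {
  s <- object@sites
  need <- c("mirna_id", "target_id", "target_kind", "site_type", "position",
            "junction_spanning")
  if (!all(need %in% colnames(s))) {
    return(sprintf("sites must have columns %s", paste(need, collapse = ", ")))
  }
  msg <- character(0)
  if (nrow(s)) {
    if (!all(s$site_type %in% .SITE_TYPES)) msg <- c(msg, "bad site_type")
    if (anyDuplicated(paste(s$mirna_id, s$target_id, s$position,
                            s$site_type))) {
      msg <- c(msg, "duplicate (mirna, target, position, site_type) sites")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TargetMap", function(object) {
  s <- object@sites
  cat(sprintf("TargetMap: %d site(s), %d miRNA(s), %d target(s)\n",
              nrow(s), length(unique(s$mirna_id)),
              length(unique(s$target_id))))
})
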