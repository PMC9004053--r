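#' Build a sample design table
#'
#' A design table has one row per sample with its group label, replicate
#' index and library size (total mapped reads; used as a relative depth
#' factor by the simulator and as an optional library-size override in
#' normalization).
#'
#' @param groups character vector of group labels (>= 2 distinct).
#' @param replicates replicates per group (>= 2).
#' @param library_size expected library size per sample; scalar or one value
#'   per sample.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{replicate}, \code{library_size}.
#' @examples
#' makeSampleDesign(c("A", "B"), replicates = 3)
#' @export
makeSampleDesign <- function(groups = c("A", "B"), replicates = 3L,
                             library_size = 1e6) {
  .assert(length(groups) >= 2L && !anyDuplicated(groups),
          "need >= 2 distinct groups")
  .assert(replicates >= 2L, "need >= 2 replicates per group")
  n <- length(groups) * replicates
  design <- data.frame(
    sample_id = paste0(rep(groups, each = replicates), "_r",
                       rep(seq_len(replicates), length(groups))),
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), length(groups)),
    library_size = rep_len(library_size, n),
    stringsAsFactors = FALSE)
  validateSampleDesign(design)
  design
}

#' Validate a sample design table
#'
#' Checks the invariants: unique sample ids, >= 2 groups, >= 2 replicates per
#' group, positive library sizes.
#'
#' @param design a data.frame as produced by \code{\link{makeSampleDesign}}.
#' @return the design, invisibly, if valid; otherwise an error.
#' @export
validateSampleDesign <- function(design) {
  need <- c("sample_id", "group", "replicate", "library_size")
  .assert(is.data.frame(design) && all(need %in% colnames(design)),
          "design must have columns %s", paste(need, collapse = ", "))
  .assert(!anyDuplicated(design$sample_id), "sample ids must be unique")
  .assert(length(unique(design$group)) >= 2L, "need >= 2 groups")
  .assert(all(table(design$group) >= 2L), "need >= 2 replicates per group")
  .assert(all(design$replicate >= 1L), "replicate indices must be positive")
  .assert(all(is.finite(design$library_size) & design$library_size > 0),
          "library sizes must be positive")
  invisible(design)
}
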