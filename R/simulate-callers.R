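#' Simulate noisy per-caller circRNA call sets
#'
#' Each caller reports every true back-splice junction independently with
#' probability equal to its sensitivity, plus Poisson-distributed false
#' junctions at its false-call rate. Coordinates are emitted in the caller's
#' dialect (alternating 0-based half-open and 1-based inclusive across
#' callers), exercising the canonicalization step.
#'
#' @param truth a \linkS4class{SyntheticTruth} (supplies caller profiles and
#'   the seed).
#' @param true_junctions GRanges of true junctions; defaults to the truth's.
#' @return named list (one element per caller) of BED-like data.frames with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{name},
#'   \code{bsj_reads}, \code{strand}, \code{caller}, each carrying a
#'   \code{"dialect"} attribute.
#' @export
simulateCallerOutputs <- function(truth, true_junctions = trueJunctions(truth)) {
  .assert(is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  prof <- truth@caller_profiles
  .assert(nrow(prof) > 0L, "caller profiles must be non-empty")
  .assert(all(prof$sensitivity > 0 & prof$sensitivity <= 1),
          "caller sensitivities must be in (0,1]")
  true_keys <- .junctionKey(true_junctions)
  out <- list()
  for (i in seq_len(nrow(prof))) {
    caller <- prof$caller[i]
    calls <- withSubSeed(truth@seed, paste0("caller:", caller), {
      keep <- runif(length(true_junctions)) <= prof$sensitivity[i]
      gr <- true_junctions[keep]
      n_false <- rpois(1L, prof$false_rate[i])
      if (n_false > 0L) {
        gr <- c(gr, .randomJunctions(n_false, existing_keys = true_keys))
      }
      mcols(gr)$bsj_reads <- rpois(length(gr), 20) + 1L
      gr
    })
    df <- junctionsToDialect(calls, prof$dialect[i], caller = caller)
    out[[caller]] <- df
  }
  out
}
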