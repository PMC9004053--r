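#' Relative expression by the 2^-ddCt method
#'
#' Delta Ct = Ct(target) - Ct(reference) within each condition; delta-delta
#' Ct = dCt(treatment) - dCt(control); relative expression = 2^(-ddCt).
#' Replicate Ct values are averaged before dCt.
#'
#' @param treatment,control lists or one-row-per-replicate data.frames with
#'   fields \code{gene}, \code{ct_target}, \code{ct_reference} (finite,
#'   positive Ct values).
#' @return relative expression of the treatment over the control (> 0).
#' @examples
#' ddct(list(gene = "MyoD1", ct_target = 20, ct_reference = 18),
#'      list(gene = "MyoD1", ct_target = 22, ct_reference = 18))  # 4
#' @export
ddct <- function(treatment, control) {
  dct <- function(m, what) {
    .assert(all(c("gene", "ct_target", "ct_reference") %in% names(m)),
            "%s needs fields gene, ct_target, ct_reference", what)
    ct_t <- as.numeric(m$ct_target); ct_r <- as.numeric(m$ct_reference)
    .assert(all(is.finite(ct_t) & ct_t > 0) && all(is.finite(ct_r) & ct_r > 0),
            "Ct values must be finite and positive")
    mean(ct_t) - mean(ct_r)
  }
  .assert(identical(unique(as.character(treatment$gene)),
                    unique(as.character(control$gene))),
          "treatment and control measure different genes")
  2^(-(dct(treatment, "treatment") - dct(control, "control")))
}

#' Muscle fiber-type proportions from MyHC isoform expression
#'
#' Normalizes relative expression levels of the myosin heavy chain isoforms
#' (I, IIa, IIx, IIb) to proportions summing to 1.
#'
#' @param relative_levels named non-negative numeric vector over the isoforms
#'   (at least one nonzero).
#' @return named proportions in the same order.
#' @examples
#' myhcProportions(c(I = 2, IIa = 1, IIx = 1, IIb = 4))
#' @export
myhcProportions <- function(relative_levels) {
  .assert(is.numeric(relative_levels) && !is.null(names(relative_levels)),
          "relative_levels must be a named numeric vector")
  .assert(all(is.finite(relative_levels) & relative_levels >= 0),
          "levels must be finite and non-negative")
  tot <- sum(relative_levels)
  .assert(tot > 0, "all-zero isoform levels")
  relative_levels / tot
}
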