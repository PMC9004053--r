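#' Simulate negative-binomial count matrices for the three RNA layers
#'
#' Draws per-sample counts for every feature in the truth from an NB model
#' with variance mu + phi mu^2 (Poisson when phi = 0). Group means follow the
#' planted fold changes; per-sample library sizes in the design act as
#' multiplicative depth factors (relative to their mean); planted
#' co-expression pairs share a per-sample log-normal factor. Each feature
#' draws from its own RNG substream keyed by its id, so the counts of a
#' feature do not depend on which other features exist.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param design a sample design table whose groups are the truth's two
#'   parameterized groups.
#' @return named list of \linkS4class{ExpressionMatrix} objects
#'   (\code{mirna}, \code{mrna}, \code{circ}), all on the \code{counts}
#'   layer; mRNA and circRNA matrices carry feature lengths.
#' @examples
#' truth <- generateTruth(generatorConfig(n_triplets = 2, seed = 1))
#' mats <- simulateCounts(truth, makeSampleDesign())
#' mats$mirna
#' @export
simulateCounts <- function(truth, design) {
  .assert(is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  validateSampleDesign(design)
  groups <- truth@config@groups
  .assert(all(design$group %in% groups),
          "design groups must match the truth's group parameterization (%s)",
          paste(groups, collapse = ", "))
  n_samp <- nrow(design)
  sf <- design$library_size / mean(design$library_size)
  is_b <- design$group == groups[2L]

  # shared per-sample factors for co-expression pairs (mean 1)
  cp <- truth@corr_pairs
  pair_factor <- matrix(1, nrow = nrow(cp), ncol = n_samp)
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      pair_factor[i, ] <- withSubSeed(
        truth@seed, paste0("pair:", cp$id_a[i], ":", cp$id_b[i]),
        rlnorm(n_samp, meanlog = -cp$sdlog[i]^2 / 2, sdlog = cp$sdlog[i]))
    }
  }
  factorFor <- function(layer, id) {
    f <- rep(1, n_samp)
    if (!nrow(cp)) return(f)
    hit <- which((cp$layer_a == layer & cp$id_a == id) |
                   (cp$layer_b == layer & cp$id_b == id))
    for (i in hit) f <- f * pair_factor[i, ]
    f
  }

  np <- truth@nb_params
  oneLayer <- function(layer) {
    sub <- np[np$layer == layer, , drop = FALSE]
    ids <- .csort(sub$feature_id)
    sub <- sub[match(ids, sub$feature_id), , drop = FALSE]
    m <- matrix(0L, nrow = length(ids), ncol = n_samp,
                dimnames = list(ids, design$sample_id))
    for (i in seq_along(ids)) {
      mu <- ifelse(is_b, sub$mean_b[i], sub$mean_a[i]) * sf *
        factorFor(layer, ids[i])
      phi <- sub$dispersion[i]
      m[i, ] <- withSubSeed(truth@seed, paste0("count:", layer, ":", ids[i]), {
        if (phi == 0) rpois(n_samp, mu) else rnbinom(n_samp, mu = mu, size = 1 / phi)
      })
    }
    m
  }
  lens <- truth@config@target_lengths
  mrna_m <- oneLayer("mrna")
  circ_m <- oneLayer("circ")
  list(
    mirna = ExpressionMatrix(oneLayer("mirna"), layer = "counts"),
    mrna = ExpressionMatrix(mrna_m, layer = "counts",
      feature_lengths = setNames(rep(lens[["mrna"]], nrow(mrna_m)),
                                 rownames(mrna_m))),
    circ = ExpressionMatrix(circ_m, layer = "counts",
      feature_lengths = setNames(rep(lens[["circ"]], nrow(circ_m)),
                                 rownames(circ_m))))
}
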