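#' Library-size normalization of a count matrix
#'
#' Converts a raw-count \linkS4class{ExpressionMatrix} to CPM
#' (count / library size x 10^6), FPKM (count / (library size / 10^6) /
#' (length / 10^3)) or BSJ-CPM (CPM applied to back-splice-junction read
#' counts). Library sizes default to the per-sample column sums of the raw
#' counts; a named override (e.g. total mapped reads from a design table) may
#' be supplied.
#'
#' @param x an \linkS4class{ExpressionMatrix} on the \code{counts} layer.
#' @param method \code{"CPM"}, \code{"FPKM"} or \code{"BSJ-CPM"}.
#' @param library_sizes optional named numeric vector of per-sample library
#'   sizes covering all samples; must be positive.
#' @return an \linkS4class{ExpressionMatrix} on the requested layer.
#' @examples
#' m <- matrix(c(10L, 90L), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' cpm <- normalizeCounts(ExpressionMatrix(m),
#'                        library_sizes = c(s1 = 100, s2 = 100))
#' exprValues(cpm)  # 1e5 and 9e5
#' @export
normalizeCounts <- function(x, method = c("CPM", "FPKM", "BSJ-CPM"),
                            library_sizes = NULL) {
  method <- match.arg(method)
  .assert(is(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  .assert(identical(exprLayer(x), "counts"),
          "normalization starts from the counts layer (got %s)", exprLayer(x))
  v <- exprValues(x)
  libs <- .resolveLibSizes(v, library_sizes)
  out <- sweep(v, 2L, libs, "/") * 1e6
  if (method == "FPKM") {
    len <- featureLengths(x)
    .assert(!is.null(len) && !any(is.na(len)),
            "FPKM requires feature lengths for every feature")
    out <- out / (len / 1e3)
  }
  ExpressionMatrix(out, layer = method, feature_lengths = featureLengths(x))
}

.resolveLibSizes <- function(v, library_sizes) {
  if (is.null(library_sizes)) {
    libs <- colSums(v)
  } else {
    .assert(!is.null(names(library_sizes)) &&
              all(colnames(v) %in% names(library_sizes)),
            "library_sizes must be named and cover all samples")
    libs <- library_sizes[colnames(v)]
  }
  .assert(all(is.finite(libs) & libs > 0),
          "library sizes must be positive for all samples")
  libs
}
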