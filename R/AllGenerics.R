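#' Accessors
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprLayer", function(x) standardGeneric("exprLayer"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' @rdname accessors
#' @export
setGeneric("mreSites", function(x) standardGeneric("mreSites"))

#' @describeIn ExpressionMatrix-class the layer tag.
#' @param x an ExpressionMatrix.
#' @export
setMethod("exprLayer", "ExpressionMatrix", function(x) x@layer)

#' @describeIn ExpressionMatrix-class the values matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x))

#' @describeIn ExpressionMatrix-class named vector of feature lengths, or
#'   NULL if absent.
#' @export
setMethod("featureLengths", "ExpressionMatrix", function(x) {
  len <- rowData(x)$length
  if (is.null(len)) NULL else setNames(as.numeric(len), rownames(x))
})

#' @describeIn TargetMap-class the site table (one row per site).
#' @param x a TargetMap.
#' @export
setMethod("mreSites", "TargetMap", function(x) x@sites)
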