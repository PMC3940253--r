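#' Accessors for ExpressionExperiment and friends
#'
#' @param x an \linkS4class{ExpressionExperiment}, \linkS4class{GeneSetCollection}
#'   or \linkS4class{EnrichmentNull}.
#' @name accessors
NULL

#' @describeIn accessors the genes x samples expression matrix.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn accessors the scale flag, \code{"linear"} or \code{"log2"}.
#' @export
exprScale <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn accessors per-sample tissue factor (blood/cerebellum).
#' @export
tissueFactor <- function(x) SummarizedExperiment::colData(x)$tissue

#' @describeIn accessors per-sample genotype factor (wildtype/transgenic).
#' @export
genotypeFactor <- function(x) SummarizedExperiment::colData(x)$genotype

#' @describeIn accessors record of normalization steps applied so far.
#' @export
normProvenance <- function(x) S4Vectors::metadata(x)$normalization

#' @describeIn accessors named list of gene-set memberships.
#' @export
geneSets <- function(x) x@sets

#' @describeIn accessors per-set descriptions.
#' @export
setDescriptions <- function(x) x@descriptions

#' @describeIn accessors integer vector of set sizes.
#' @export
setSizes <- function(x) lengths(x@sets)

#' @describeIn accessors the vector of permutation-null enrichment scores.
#' @export
nullES <- function(x) x@nullEs

#' Number and names of sets in a collection
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname length-GeneSetCollection-method
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Subset a GeneSetCollection by name or index
#' @param x a GeneSetCollection.
#' @param i character or integer index.
#' @param j,drop,... unused.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  GeneSetCollection(x@sets[i], x@descriptions[i])
})

#' Convert an ExpressionExperiment to log2 scale
#'
#' Linear-scale values must be strictly positive. A no-op when already log2.
#'
#' @param x an ExpressionExperiment.
#' @return an ExpressionExperiment on the log2 scale.
#' @export
log2Transform <- function(x) {
  if (identical(exprScale(x), "log2")) return(x)
  v <- exprValues(x)
  if (any(v <= 0))
    stop("cannot log2-transform: non-positive values present", call. = FALSE)
  SummarizedExperiment::assay(x, "exprs") <- log2(v)
  S4Vectors::metadata(x)$scale <- "log2"
  S4Vectors::metadata(x)$normalization <-
    c(S4Vectors::metadata(x)$normalization, "log2")
  validObject(x)
  x
}

#' Convert an ExpressionExperiment to linear scale
#' @param x an ExpressionExperiment.
#' @return an ExpressionExperiment on the linear scale.
#' @export
linearScale <- function(x) {
  if (identical(exprScale(x), "linear")) return(x)
  SummarizedExperiment::assay(x, "exprs") <- 2^exprValues(x)
  S4Vectors::metadata(x)$scale <- "linear"
  validObject(x)
  x
}
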