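#' Quantile normalization across samples
#'
#' Replaces each column's values by the mean-across-columns of the order
#' statistics at each rank, so that after normalization every column has an
#' identical sorted value vector. Tied values receive the mean of the
#' reference values at their tied ranks. Idempotent.
#'
#' Input must be on the log2 scale; log-transform linear intensities first
#' (\code{\link{log2Transform}}).
#'
#' @param x numeric matrix (genes x samples) or an ExpressionExperiment.
#' @param ... unused.
#' @return same shape as the input, normalized; for an ExpressionExperiment
#'   the normalization provenance is extended.
#' @export
setGeneric("quantileNormalize", function(x, ...) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (ncol(x) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ExpressionExperiment", function(x, ...) {
  if (!identical(exprScale(x), "log2"))
    stop("quantileNormalize expects log2-scale values; call log2Transform() first",
         call. = FALSE)
  SummarizedExperiment::assay(x, "exprs") <-
    quantileNormalize(exprValues(x))
  S4Vectors::metadata(x)$normalization <-
    c(S4Vectors::metadata(x)$normalization, "quantile")
  x
})

#' Row standardization
#'
#' Centers and scales each row to mean 0 and sample sd 1 (n - 1 denominator),
#' as used for heatmap display and correlation-based clustering. Constant
#' rows map to all zeros with a warning.
#'
#' @param x numeric matrix (genes x samples) or an ExpressionExperiment.
#' @param ... unused.
#' @return matrix of standardized rows (dimnames preserved).
#' @export
setGeneric("standardizeRows", function(x, ...) standardGeneric("standardizeRows"))

#' @rdname standardizeRows
#' @export
setMethod("standardizeRows", "matrix", function(x, ...) {
  if (ncol(x) < 2L) stop("row standardization needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  centered <- x - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
  flat <- sds < 1e-12
  if (any(flat)) {
    warning(sum(flat), " constant row(s) standardized to all zeros", call. = FALSE)
    sds[flat] <- Inf
  }
  out <- centered / sds
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname standardizeRows
#' @export
setMethod("standardizeRows", "ExpressionExperiment", function(x, ...) {
  standardizeRows(exprValues(x))
})
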