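#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.TISSUE_LEVELS <- c("blood", "cerebellum")
.GENOTYPE_LEVELS <- c("wildtype", "transgenic")

#' Expression experiment container
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{exprs} assay
#' (genes in rows, samples in columns), per-sample \code{tissue} and
#' \code{genotype} factors in \code{colData}, and a \code{scale} flag
#' (\code{"linear"} or \code{"log2"}) plus a normalization provenance record
#' in \code{metadata}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate sample ids")
  if (anyNA(v)) msg <- c(msg, "missing values in expression matrix")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("tissue", "genotype") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'tissue' and 'genotype'")
  else {
    if (!all(as.character(cd$tissue) %in% .TISSUE_LEVELS))
      msg <- c(msg, sprintf("tissue values must be in {%s}",
                            paste(.TISSUE_LEVELS, collapse = ", ")))
    if (!all(as.character(cd$genotype) %in% .GENOTYPE_LEVELS))
      msg <- c(msg, sprintf("genotype values must be in {%s}",
                            paste(.GENOTYPE_LEVELS, collapse = ", ")))
  }
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msg <- c(msg, "metadata$scale must be 'linear' or 'log2'")
  else if (identical(sc, "linear") && !anyNA(v) && any(v < 0))
    msg <- c(msg, "linear-scale values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param design data.frame with columns \code{sample}, \code{tissue}
#'   (\code{blood}/\code{cerebellum}) and \code{genotype}
#'   (\code{wildtype}/\code{transgenic}); sample set must match the matrix
#'   columns exactly.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return An \linkS4class{ExpressionExperiment}.
#' @export
ExpressionExperiment <- function(values, design, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names", call. = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "genotype")
  if (!all(need %in% colnames(design)))
    stop("'design' needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$sample))
    stop("duplicate sample ids in design", call. = FALSE)
  if (!setequal(design$sample, colnames(values)))
    stop("design samples do not match matrix sample ids", call. = FALSE)
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    tissue = factor(design$tissue, levels = .TISSUE_LEVELS),
    genotype = factor(design$genotype, levels = .GENOTYPE_LEVELS),
    row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(scale = scale, normalization = character()))
  new("ExpressionExperiment", se)
}

#' Named gene-set collection
#'
#' Holds uniquely named gene sets (character vectors of member ids, unique
#' within each set) and one description string per set, mirroring the GMT
#' format used for KEGG-like pathway collections.
#'
#' @slot sets named list of character vectors.
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets) &&
      (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    msg <- c(msg, "set names must be unique and non-empty")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "members must be unique within each set")
  if (length(object@sets) && !identical(names(object@descriptions), nm))
    msg <- c(msg, "descriptions must be named parallel to sets")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' Size-matched permutation null for the enrichment score
#'
#' Enrichment scores of \code{nDraws} random gene sets of a fixed size drawn
#' without replacement from a fixed ranked gene universe.
#'
#' @slot setSize integer, size of the permuted sets.
#' @slot nDraws integer, number of random draws.
#' @slot nullEs numeric vector of length \code{nDraws}.
#' @slot seed integer seed used for the draws.
#' @exportClass EnrichmentNull
setClass("EnrichmentNull",
         representation(setSize = "integer", nDraws = "integer",
                        nullEs = "numeric", seed = "integer"))

setValidity("EnrichmentNull", function(object) {
  if (length(object@nullEs) != object@nDraws)
    "length(nullEs) must equal nDraws"
  else TRUE
})

#' Synthetic-experiment configuration
#'
#' Parameters of the two-tissue by two-genotype expression simulator. All
#' effects are on the log2 scale; the exported matrix is linear
#' (\code{2^x}), mirroring absolute array intensities.
#'
#' @slot nGenes number of gene rows.
#' @slot nPerCell replicates per tissue x genotype cell.
#' @slot tissueEffectSd sd (log2) of per-gene tissue effects.
#' @slot fracTissueAffected fraction of genes given a tissue effect.
#' @slot nDeGenes number of individually genotype-responsive genes.
#' @slot deEffectLog2 absolute log2 shift of the DE genes.
#' @slot plantedSets list of lists with fields \code{name}, \code{size},
#'   \code{meanShift} (log2) and \code{direction} ("up"/"down").
#' @slot nBackgroundSets number of random background gene sets.
#' @slot setSizeRange integer length-2, background set size bounds.
#' @slot noiseSd residual sd (log2).
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nGenes = "integer", nPerCell = "integer",
                        tissueEffectSd = "numeric", fracTissueAffected = "numeric",
                        nDeGenes = "integer", deEffectLog2 = "numeric",
                        plantedSets = "list", nBackgroundSets = "integer",
                        setSizeRange = "integer", noiseSd = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nPerCell < 1L) msg <- c(msg, "nPerCell must be >= 1")
  if (object@nDeGenes < 0L || object@nDeGenes > object@nGenes)
    msg <- c(msg, "nDeGenes must satisfy 0 <= nDeGenes <= nGenes")
  if (object@fracTissueAffected < 0 || object@fracTissueAffected > 1)
    msg <- c(msg, "fracTissueAffected must be in [0, 1]")
  if (object@tissueEffectSd < 0) msg <- c(msg, "tissueEffectSd must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nBackgroundSets < 0L) msg <- c(msg, "nBackgroundSets must be >= 0")
  if (length(object@setSizeRange) != 2L ||
      object@setSizeRange[1L] < 1L ||
      object@setSizeRange[2L] < object@setSizeRange[1L])
    msg <- c(msg, "setSizeRange must be (min, max) with 1 <= min <= max")
  else if (object@setSizeRange[2L] > object@nGenes)
    msg <- c(msg, "setSizeRange max must be <= nGenes")
  for (ps in object@plantedSets) {
    ok <- is.list(ps) && all(c("name", "size", "meanShift", "direction") %in% names(ps))
    if (!ok) { msg <- c(msg, "each planted set needs name, size, meanShift, direction"); next }
    if (ps$size > object@nGenes)
      msg <- c(msg, sprintf("planted set '%s' size exceeds nGenes", ps$name))
    if (!ps$direction %in% c("up", "down"))
      msg <- c(msg, sprintf("planted set '%s' direction must be 'up' or 'down'", ps$name))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the profiled study design: five replicates per tissue x
#' genotype cell, strong tissue effects on a majority of genes, a small
#' fraction of genotype-responsive genes, and KEGG-like background sets of
#' size 15-500.
#'
#' @param nGenes,nPerCell,tissueEffectSd,fracTissueAffected,nDeGenes
#'   see the class documentation.
#' @param deEffectLog2,plantedSets,nBackgroundSets,setSizeRange,noiseSd,seed
#'   see the class documentation.
#' @return A \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nGenes = 10000L, nPerCell = 5L,
                             tissueEffectSd = 1.0, fracTissueAffected = 0.6,
                             nDeGenes = 100L, deEffectLog2 = 1.0,
                             plantedSets = list(), nBackgroundSets = 50L,
                             setSizeRange = c(15L, 500L), noiseSd = 0.5,
                             seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nPerCell = as.integer(nPerCell), tissueEffectSd = tissueEffectSd,
      fracTissueAffected = fracTissueAffected, nDeGenes = as.integer(nDeGenes),
      deEffectLog2 = deEffectLog2, plantedSets = plantedSets,
      nBackgroundSets = as.integer(nBackgroundSets),
      setSizeRange = as.integer(setSizeRange), noiseSd = noiseSd,
      seed = as.integer(seed))
}

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection with", length(object@sets), "sets",
      if (length(sz)) sprintf("(sizes %d-%d)", min(sz), max(sz)) else "", "\n")
})

setMethod("show", "EnrichmentNull", function(object) {
  cat(sprintf("EnrichmentNull: %d draws at set size %d (seed %d)\n",
              object@nDraws, object@setSize, object@seed))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d genes x 4*%d samples; ",
                     "%d DE genes (|log2| = %.2f), %d planted sets, ",
                     "%d background sets, noise sd %.2f, seed %d\n"),
              object@nGenes, object@nPerCell, object@nDeGenes,
              object@deEffectLog2, length(object@plantedSets),
              object@nBackgroundSets, object@noiseSd, object@seed))
})
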