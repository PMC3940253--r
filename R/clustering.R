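#' Two-way hierarchical clustering of significant genes
#'
#' Standardizes the rows (genes), then clusters genes and samples by
#' agglomerative hierarchical clustering with average linkage on
#' 1 - Pearson correlation distance, the standard pairing for expression
#' heatmaps. Rows constant before standardization, and columns constant
#' after it, are excluded with a warning.
#'
#' @param x numeric matrix (significant genes x samples, log2 scale) or an
#'   ExpressionExperiment restricted to the significant genes.
#' @param distance \code{"correlation"} (default) or \code{"euclidean"}.
#' @param linkage linkage method for \code{\link[stats]{hclust}}
#'   (default \code{"average"}).
#' @return list: \code{gene_hclust}, \code{sample_hclust} (both
#'   \code{hclust} objects), and \code{ordered} - the standardized matrix
#'   permuted to the dendrogram leaf orders (heatmap-ready).
#' @export
clusterBimodal <- function(x, distance = c("correlation", "euclidean"),
                           linkage = "average") {
  distance <- match.arg(distance)
  if (is(x, "ExpressionExperiment")) x <- exprValues(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 genes and >= 2 samples", call. = FALSE)
  rsd <- apply(x, 1L, stats::sd)
  if (any(rsd < 1e-12)) {
    warning(sum(rsd < 1e-12), " constant gene row(s) excluded", call. = FALSE)
    x <- x[rsd >= 1e-12, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("fewer than 2 non-constant genes remain", call. = FALSE)
  z <- standardizeRows(x)
  csd <- apply(z, 2L, stats::sd)
  if (any(csd < 1e-12)) {
    warning(sum(csd < 1e-12), " constant sample column(s) excluded", call. = FALSE)
    z <- z[, csd >= 1e-12, drop = FALSE]
  }
  if (ncol(z) < 2L) stop("fewer than 2 usable samples remain", call. = FALSE)
  dfun <- function(m) {
    if (distance == "correlation") stats::as.dist(1 - stats::cor(t(m)))
    else stats::dist(m)
  }
  gh <- stats::hclust(dfun(z), method = linkage)
  sh <- stats::hclust(dfun(t(z)), method = linkage)
  list(gene_hclust = gh, sample_hclust = sh,
       ordered = z[gh$order, sh$order, drop = FALSE])
}

# TRUE iff two labelings induce the same partition of the samples
.samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

#' Does the sample dendrogram separate tissue, then genotype?
#'
#' Cuts the sample tree at 2 and at 4 clusters and checks whether the 2-cut
#' reproduces the tissue partition and the 4-cut the tissue x genotype
#' partition. Designs with a single tissue are trivially separated.
#'
#' @param sampleHclust the \code{sample_hclust} from
#'   \code{\link{clusterBimodal}}.
#' @param design data.frame with sample, tissue, genotype (or an
#'   ExpressionExperiment).
#' @return list: \code{tissue_separated}, \code{cell_separated} (logicals),
#'   \code{tissue_table}, \code{cell_table} (confusion counts).
#' @export
tissueGenotypeSeparation <- function(sampleHclust, design) {
  if (is(design, "ExpressionExperiment")) {
    design <- data.frame(sample = colnames(design),
                         tissue = as.character(tissueFactor(design)),
                         genotype = as.character(genotypeFactor(design)),
                         stringsAsFactors = FALSE)
  }
  idx <- match(sampleHclust$labels, design$sample)
  if (anyNA(idx)) stop("dendrogram labels missing from design", call. = FALSE)
  tissue <- design$tissue[idx]
  cell <- paste(design$tissue, design$genotype, sep = ".")[idx]
  n_tis <- length(unique(tissue)); n_cell <- length(unique(cell))
  cut2 <- stats::cutree(sampleHclust, k = min(2L, length(idx)))
  cut4 <- stats::cutree(sampleHclust, k = min(4L, length(idx)))
  tissue_ok <- if (n_tis < 2L) TRUE else .samePartition(cut2, tissue)
  cell_ok <- if (n_cell < 2L) TRUE
             else .samePartition(stats::cutree(sampleHclust, k = n_cell), cell)
  list(tissue_separated = tissue_ok, cell_separated = cell_ok,
       tissue_table = table(cluster = cut2, tissue = tissue),
       cell_table = table(cluster = cut4, cell = cell))
}

#' Write a dendrogram in Newick format
#' @param hc an \code{hclust} object.
#' @param path output file path.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
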