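#' Hypergeometric overlap test
#'
#' Upper-tail test of whether a differential-expression list shares more
#' genes with a candidate list than expected by chance within a finite
#' measured universe. Both lists are intersected with the universe first;
#' the p-value is the exact tail sum \code{P(X >= overlap)} for
#' \code{X ~ Hypergeometric(universe, candidates, |DE|)}.
#'
#' @param universe character vector of measured gene ids.
#' @param candidates candidate gene ids (e.g. an ASD candidate list,
#'   homolog-translated if needed; see \code{\link{translateIds}}).
#' @param deList differentially expressed gene ids.
#' @return list of class \code{OverlapTest}: \code{universe_size},
#'   \code{candidates_in_universe}, \code{de_in_universe}, \code{overlap},
#'   \code{p_value}.
#' @export
hypergeometricOverlap <- function(universe, candidates, deList) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  cand <- intersect(candidates, universe)
  de <- intersect(deList, universe)
  k <- length(intersect(cand, de))
  N <- length(universe); K <- length(cand); n <- length(de)
  kmax <- min(K, n)
  p <- if (k == 0L) 1 else sum(stats::dhyper(k:kmax, K, N - K, n))
  structure(list(universe_size = N, candidates_in_universe = K,
                 de_in_universe = n, overlap = k, p_value = min(p, 1)),
            class = "OverlapTest")
}

#' Genes significant in two models
#'
#' Intersects the significant gene lists (genotype p < alpha) of two
#' differential-expression results over their common universe, reporting
#' each shared gene's effect direction in both models.
#'
#' @param deA,deB data.frames from \code{\link{fitGeneModels}}.
#' @param alpha significance threshold (default 0.01, uncorrected).
#' @return data.frame: gene, effect_A, direction_A, effect_B, direction_B.
#' @export
crossModelSharedGenes <- function(deA, deB, alpha = 0.01) {
  .assertScalarNumber(alpha, "alpha", lower = 0, upper = 1)
  common <- intersect(deA$gene, deB$gene)
  if (length(common) == 0L)
    stop("the two results share no genes (disjoint universes)", call. = FALSE)
  a <- deA[match(common, deA$gene), ]
  b <- deB[match(common, deB$gene), ]
  keep <- a$p_value < alpha & b$p_value < alpha
  data.frame(gene = common[keep],
             effect_A = a$genotype_effect[keep],
             direction_A = ifelse(a$genotype_effect[keep] >= 0, "up", "down"),
             effect_B = b$genotype_effect[keep],
             direction_B = ifelse(b$genotype_effect[keep] >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}
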