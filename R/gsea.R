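#' Signal-to-noise gene ranking
#'
#' Within one tissue stratum, ranks all genes by
#' \code{(mean_transgenic - mean_wildtype) / (sd_transgenic + sd_wildtype)},
#' descending. Each group sd is floored at
#' \code{max(sd, 0.2 * |group mean|, 1e-8)} so constant genes cannot produce
#' infinite metrics. Ties keep the input gene order (stable sort).
#'
#' @param x an ExpressionExperiment on the log2 scale.
#' @param tissue \code{"blood"} or \code{"cerebellum"}.
#' @return data.frame with columns \code{gene_id}, \code{metric}, ordered
#'   best to worst; attributes \code{tissue} and \code{grouping} record the
#'   contrast.
#' @export
signalToNoise <- function(x, tissue = c("cerebellum", "blood")) {
  tissue <- match.arg(tissue)
  sel <- tissueFactor(x) == tissue
  y <- exprValues(x)[, sel, drop = FALSE]
  gen <- genotypeFactor(x)[sel]
  if (sum(gen == "transgenic") < 2L || sum(gen == "wildtype") < 2L)
    stop("need >= 2 samples per genotype within the tissue", call. = FALSE)
  grp <- function(g) {
    v <- y[, gen == g, drop = FALSE]
    mu <- rowMeans(v)
    sd <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
    list(mu = mu, sd = pmax(sd, 0.2 * abs(mu), 1e-8))
  }
  tg <- grp("transgenic"); wt <- grp("wildtype")
  metric <- (tg$mu - wt$mu) / (tg$sd + wt$sd)
  o <- order(metric, decreasing = TRUE)  # radix: stable, ties by input order
  out <- data.frame(gene_id = rownames(y)[o], metric = unname(metric[o]),
                    stringsAsFactors = FALSE)
  attr(out, "tissue") <- tissue
  attr(out, "grouping") <- "transgenic vs wildtype"
  out
}

#' Running-sum enrichment score
#'
#' Walks the ranked list from the top; the running sum rises by \code{1/Nh}
#' at each set member and falls by \code{1/(N - Nh)} otherwise, ending at 0.
#' The enrichment score is the signed maximum deviation from zero (ties
#' between equal positive and negative deviations resolve positive). For
#' positive ES the leading edge is the members at or before the maximum, in
#' rank order; for negative ES the members at or after the minimum, in
#' reverse rank order.
#'
#' A weighting exponent on |metric| is exposed for completeness
#' (\code{weightExp = 0}, the unweighted walk, is the default and the
#' convention used throughout this package).
#'
#' @param ranked character vector of ranked gene ids (best first), or the
#'   data.frame from \code{\link{signalToNoise}}.
#' @param members character vector of set member ids.
#' @param weightExp nonnegative exponent on |metric| for hit increments
#'   (requires metric values when > 0).
#' @return list: \code{es}, \code{leading_edge}, \code{running_sum}.
#' @export
enrichmentScore <- function(ranked, members, weightExp = 0) {
  metric <- NULL
  if (is.data.frame(ranked)) {
    metric <- ranked$metric
    ranked <- ranked$gene_id
  }
  N <- length(ranked)
  hit <- ranked %in% members
  Nh <- sum(hit)
  if (Nh == 0L) stop("no set members present in the ranked list", call. = FALSE)
  if (Nh == N) stop("set covers the whole ranked list", call. = FALSE)
  if (weightExp > 0) {
    if (is.null(metric))
      stop("weighted scoring needs metric values; pass the signalToNoise table",
           call. = FALSE)
    w <- abs(metric)^weightExp
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - Nh))
  } else {
    inc <- ifelse(hit, 1 / Nh, -1 / (N - Nh))
  }
  rs <- cumsum(inc)
  mx <- max(rs); mn <- min(rs)
  # deviations live on a rational grid far coarser than 1e-9, so this
  # tolerance only absorbs cumsum rounding in exact +/- ties
  if (mx + mn >= -1e-9) {
    pos <- which.max(rs)
    es <- mx
    le <- ranked[hit & seq_len(N) <= pos]
  } else {
    pos <- which.min(rs)
    es <- mn
    le <- rev(ranked[hit & seq_len(N) >= pos])
  }
  list(es = es, leading_edge = le, running_sum = rs)
}

# ES from sorted hit positions only (unweighted walk) -- O(Nh) per draw.
# The walk's local maxima sit right after hits, local minima right before
# hits; the end value 0 is always a candidate on both sides.
.esFromPositions <- function(pos, Nh, N) {
  Nm <- N - Nh
  i <- seq_len(Nh)
  s_hit <- i / Nh - (pos - i) / Nm
  s_pre <- (i - 1) / Nh - (pos - i) / Nm  # value at position pos - 1
  mx <- max(0, s_hit)
  mn <- min(0, s_pre)
  if (mx + mn >= -1e-9) mx else mn
}

#' Size-matched permutation null distribution
#'
#' Draws \code{nDraws} random gene sets of size \code{setSize} uniformly
#' without replacement from the ranked universe and records their
#' (unweighted) enrichment scores.
#'
#' @param ranked ranked ids or signalToNoise table (only the length and
#'   ordering matter).
#' @param setSize size of the random sets, in \code{[1, N - 1]}.
#' @param nDraws number of draws (default 2000).
#' @param seed integer RNG seed.
#' @return an \linkS4class{EnrichmentNull}.
#' @export
sampleNull <- function(ranked, setSize, nDraws = 2000L, seed = 1L) {
  if (is.data.frame(ranked)) ranked <- ranked$gene_id
  N <- length(ranked)
  if (setSize < 1L || setSize >= N)
    stop("setSize must lie in [1, N - 1]", call. = FALSE)
  nullEs <- withSeed(seed, {
    vapply(seq_len(nDraws), function(i) {
      .esFromPositions(sort.int(sample.int(N, setSize)), setSize, N)
    }, numeric(1))
  })
  new("EnrichmentNull", setSize = as.integer(setSize),
      nDraws = as.integer(nDraws), nullEs = nullEs, seed = as.integer(seed))
}

#' Permutation p-value for an enrichment score
#'
#' \code{p = max(#\{|null| >= |es|\}, 1) / nDraws}: the fraction of random
#' same-size gene sets at least as extreme in magnitude as the observed
#' score (the unweighted null is symmetric, so magnitude extremity is the
#' natural two-sided measure). The smallest attainable p at 2,000 draws is
#' 0.0005, and under a null ranking p is uniform on \{1/nDraws, ..., 1\}.
#' An ES of exactly 0 returns p = 1.
#'
#' @param es observed enrichment score.
#' @param null an \linkS4class{EnrichmentNull}.
#' @return permutation p-value.
#' @export
permutationP <- function(es, null) {
  v <- nullES(null)
  if (length(v) == 0L) stop("empty null distribution", call. = FALSE)
  if (es == 0) return(1)
  max(sum(abs(v) >= abs(es)), 1L) / length(v)
}

#' Normalized enrichment score
#'
#' Rescales ES by the mean magnitude of the same-sign null scores, making
#' scores comparable across set sizes: \code{nes = es / mean(|null of same
#' sign|)}; \code{nes = 0} iff \code{es = 0}.
#'
#' @param es observed enrichment score.
#' @param null an \linkS4class{EnrichmentNull}.
#' @return normalized enrichment score.
#' @export
normalizedES <- function(es, null) {
  if (es == 0) return(0)
  v <- nullES(null)
  same <- v[sign(v) == sign(es)]
  if (length(same) == 0L)
    stop("no same-sign null values; NES undefined", call. = FALSE)
  es / mean(abs(same))
}

# normalize every null draw by its own distribution's same-sign mean |ES|
.normalizeNullVector <- function(v) {
  out <- numeric(length(v))
  pos <- v > 0; neg <- v < 0
  if (any(pos)) out[pos] <- v[pos] / mean(v[pos])
  if (any(neg)) out[neg] <- v[neg] / mean(abs(v[neg]))
  out
}

#' Permutation FDR for a batch of enrichment results
#'
#' Pools the per-set null ES draws after normalizing each by its own
#' distribution's same-sign mean magnitude, then for each observed NES
#' computes
#' \code{q = [same-sign pooled-null fraction >= |nes|] / [same-sign observed
#' fraction >= |nes|]}, clipped into [0, 1] and enforced monotone
#' non-increasing in |NES| within each sign.
#'
#' @param nes numeric vector of observed NES values (one per set).
#' @param nulls list of \linkS4class{EnrichmentNull} objects, parallel to
#'   \code{nes} (entries may be shared between sets of equal size).
#' @return numeric vector of FDR q-values.
#' @export
gseaFdr <- function(nes, nulls) {
  if (length(nes) < 1L) stop("need >= 1 set", call. = FALSE)
  pool <- unlist(lapply(unique(nulls), function(nd) .normalizeNullVector(nullES(nd))),
                 use.names = FALSE)
  n_pos <- sum(pool > 0); n_neg <- sum(pool < 0)
  o_pos <- sum(nes > 0); o_neg <- sum(nes < 0)
  q <- vapply(nes, function(s) {
    if (s == 0) return(1)
    if (s > 0) {
      num <- if (n_pos) sum(pool >= s) / n_pos else 0
      den <- sum(nes >= s) / o_pos
    } else {
      num <- if (n_neg) sum(pool <= s) / n_neg else 0
      den <- sum(nes <= s) / o_neg
    }
    min(max(num / den, 0), 1)
  }, numeric(1))
  # monotone: stronger |NES| never gets a larger q than a weaker one (per
  # sign); like BH, each set takes the minimum raw q over itself and all
  # weaker same-sign sets
  for (sgn in c(1, -1)) {
    idx <- which(sign(nes) == sgn)
    if (length(idx) < 2L) next
    ord <- idx[order(abs(nes[idx]), decreasing = TRUE)]
    q[ord] <- rev(cummin(rev(q[ord])))
  }
  q
}

#' Gene set enrichment analysis with a gene-set permutation null
#'
#' Orchestrates the per-tissue GSEA: signal-to-noise ranking of transgenic
#' vs wildtype, unweighted running-sum ES with leading edge per set,
#' size-matched random-gene-set nulls (cached and shared across sets of
#' equal size), permutation p-values, NES and permutation FDR.
#'
#' @param x an ExpressionExperiment on the log2 scale.
#' @param tissue tissue stratum to analyze.
#' @param collection a GeneSetCollection.
#' @param minSize,maxSize measured-size bounds applied before scoring
#'   (defaults 15 and 500).
#' @param nDraws random draws per null distribution (default 2000, giving a
#'   minimum permutation p of 0.0005).
#' @param seed integer seed; per-size null seeds are derived as
#'   \code{seed + setSize} so equal-size nulls are shared and reproducible.
#' @return data.frame, one row per retained set, ordered by decreasing
#'   |NES|: \code{name}, \code{set_size_used}, \code{es}, \code{nes},
#'   \code{perm_p}, \code{fdr_q}, and \code{leading_edge} (list column).
#' @export
runGsea <- function(x, tissue = c("cerebellum", "blood"), collection,
                    minSize = 15L, maxSize = 500L, nDraws = 2000L, seed = 1L) {
  tissue <- match.arg(tissue)
  ranked <- signalToNoise(x, tissue)
  collection <- filterSetsBySize(collection, ranked$gene_id, minSize, maxSize)
  if (length(collection) == 0L)
    stop("no gene sets within the size bounds", call. = FALSE)
  sets <- geneSets(collection)
  sizes <- lengths(sets)
  nullCache <- list()
  for (sz in sort(unique(sizes))) {
    nullCache[[as.character(sz)]] <-
      sampleNull(ranked, sz, nDraws = nDraws, seed = seed + sz)
  }
  scored <- lapply(sets, function(m) enrichmentScore(ranked$gene_id, m))
  es <- vapply(scored, `[[`, numeric(1), "es")
  nulls <- nullCache[as.character(sizes)]
  perm_p <- mapply(permutationP, es, nulls)
  nes <- mapply(normalizedES, es, nulls)
  fdr_q <- gseaFdr(nes, nulls)
  out <- data.frame(name = names(sets), set_size_used = unname(sizes),
                    es = unname(es), nes = unname(nes),
                    perm_p = unname(perm_p), fdr_q = unname(fdr_q),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- unname(lapply(scored, `[[`, "leading_edge"))
  o <- order(abs(out$nes), decreasing = TRUE)
  out[o, , drop = FALSE]
}

#' Leading-edge overlap between two enrichment results
#'
#' The core genes a pathway shares between two analyses (e.g. blood and
#' cerebellum of one model): the intersection of the two leading-edge
#' subsets, ordered by rank in the first result.
#'
#' @param resultA,resultB data.frames from \code{\link{runGsea}}.
#' @param setName name of a set present in both.
#' @return character vector of shared leading-edge genes.
#' @export
leadingEdgeOverlap <- function(resultA, resultB, setName) {
  ia <- match(setName, resultA$name); ib <- match(setName, resultB$name)
  if (is.na(ia) || is.na(ib))
    stop("set '", setName, "' missing from a result table", call. = FALSE)
  lea <- resultA$leading_edge[[ia]]
  leb <- resultB$leading_edge[[ib]]
  lea[lea %in% leb]
}
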