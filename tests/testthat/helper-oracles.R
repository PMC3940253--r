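# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive each quantity from its definition by a
# different route than the package implementation.

# build a small ExpressionExperiment with a balanced 2x2 design
make_ee <- function(values, nPerCell, scale = "log2") {
  n <- 4L * nPerCell
  stopifnot(ncol(values) == n)
  design <- data.frame(
    sample = colnames(values),
    tissue = rep(c("blood", "cerebellum"), each = 2L * nPerCell),
    genotype = rep(rep(c("wildtype", "transgenic"), each = nPerCell), 2L),
    stringsAsFactors = FALSE)
  ExpressionExperiment(values, design, scale = scale)
}

rand_ee <- function(nGenes, nPerCell, sd = 1, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * 4L * nPerCell, 8, sd), nrow = nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(4L * nPerCell))))
  make_ee(v, nPerCell)
}

# explicit step-by-step running-sum recomputation of the enrichment score
brute_es <- function(ids, members) {
  N <- length(ids)
  inside <- ids %in% members
  Nh <- sum(inside)
  s <- 0
  rs <- numeric(N)
  for (k in seq_len(N)) {
    s <- s + (if (inside[k]) 1 / Nh else -1 / (N - Nh))
    rs[k] <- s
  }
  mx <- max(rs); mn <- min(rs)
  # same +/- tie convention as the package: exact ties resolve positive
  list(es = if (mx + mn >= -1e-9) mx else mn, final = rs[N], running_sum = rs)
}

# literal min-over-thresholds Storey q-value definition
brute_storey_q <- function(p, pi0) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), numeric(1)), 1)
  }, numeric(1))
}

# per-gene OLS by explicit normal equations
brute_ols <- function(y, tissue, genotype) {
  X <- cbind(1, tissue, genotype)
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - 3L
  s2 <- sum(res^2) / df
  covb <- s2 * solve(t(X) %*% X)
  tt <- b / sqrt(diag(covb))
  list(b = drop(b), t = drop(tt), p = drop(2 * pt(-abs(tt), df)))
}

# double-loop permutation FDR with within-sign fractions
brute_gsea_fdr <- function(nes, null_list) {
  pool <- unlist(lapply(null_list, function(v) {
    out <- numeric(length(v))
    if (any(v > 0)) out[v > 0] <- v[v > 0] / mean(v[v > 0])
    if (any(v < 0)) out[v < 0] <- v[v < 0] / mean(abs(v[v < 0]))
    out
  }))
  raw <- vapply(nes, function(s) {
    if (s == 0) return(1)
    same_pool <- pool[sign(pool) == sign(s)]
    same_obs <- nes[sign(nes) == sign(s)]
    num <- if (length(same_pool)) mean(abs(same_pool) >= abs(s)) else 0
    den <- mean(abs(same_obs) >= abs(s))
    min(max(num / den, 0), 1)
  }, numeric(1))
  q <- raw
  for (i in seq_along(nes)) {
    if (nes[i] == 0) next
    weaker_or_eq <- which(sign(nes) == sign(nes[i]) & abs(nes) <= abs(nes[i]))
    q[i] <- min(raw[weaker_or_eq])
  }
  q
}

# exhaustive upper-tail hypergeometric by subset enumeration (universe <= 12)
enum_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  cand <- seq_len(K)
  mean(apply(subsets, 2L, function(s) sum(s %in% cand) >= k))
}

# naive average-linkage agglomeration returning sorted merge heights
brute_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
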