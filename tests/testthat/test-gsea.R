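test_that("signal-to-noise metric matches hand evaluation, with sd floor", {
  npc <- 2
  v <- matrix(8, nrow = 3, ncol = 8,
              dimnames = list(c("gA", "gB", "gC"), sprintf("s%d", 1:8)))
  ee <- make_ee(v, npc)
  cere <- tissueFactor(ee) == "cerebellum"
  wt <- cere & genotypeFactor(ee) == "wildtype"
  tg <- cere & genotypeFactor(ee) == "transgenic"
  v["gA", wt] <- c(1, 3); v["gA", tg] <- c(2, 4)
  v["gB", wt] <- c(4, 4); v["gB", tg] <- c(4, 4)
  v["gC", wt] <- c(3, 3); v["gC", tg] <- c(5, 5)   # zero sds -> floors 0.6, 1.0
  SummarizedExperiment::assay(ee, "exprs") <- v
  r <- signalToNoise(ee, "cerebellum")
  metric <- setNames(r$metric, r$gene_id)
  expect_equal(metric[["gA"]], 1 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(metric[["gB"]], 0)
  expect_equal(metric[["gC"]], 2 / 1.6, tolerance = 1e-12)
  expect_identical(r$gene_id, c("gC", "gA", "gB"))  # descending metric

  expect_error(signalToNoise(ee[, -which(tg)[1]], "cerebellum"), ">= 2 samples")
})

test_that("running-sum enrichment score reproduces hand-walked cases", {
  ids <- paste0("g", 1:5)
  r <- enrichmentScore(ids, c("g1", "g2"))
  expect_equal(r$running_sum, c(0.5, 1, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(r$es, 1)
  expect_identical(r$leading_edge, c("g1", "g2"))

  r <- enrichmentScore(ids, c("g4", "g5"))
  expect_equal(r$es, -1)
  expect_identical(r$leading_edge, c("g5", "g4"))

  r <- enrichmentScore(ids, c("g1", "g4"))
  expect_equal(r$es, 0.5)
  expect_identical(r$leading_edge, "g1")

  expect_error(enrichmentScore(ids, "zzz"), "no set members")
  expect_error(enrichmentScore(ids, ids), "whole ranked list")
})

test_that("enrichment score matches brute-force recomputation and conserves mass", {
  set.seed(101)
  for (i in 1:300) {
    N <- sample(3:50, 1)
    ids <- paste0("g", seq_len(N))
    members <- sample(ids, sample(seq_len(N - 1), 1))
    ours <- enrichmentScore(ids, members)
    ref <- brute_es(ids, members)
    expect_lt(abs(ours$es - ref$es), 1e-12)
    expect_lt(abs(ours$running_sum[N]), 1e-12)
  }
})

test_that("ES depends only on the ordering, and reversal negates it", {
  ids <- paste0("g", 1:30)
  members <- c("g2", "g5", "g6", "g20")
  ranked_df <- data.frame(gene_id = ids, metric = sort(rnorm(30), decreasing = TRUE))
  expect_equal(enrichmentScore(ranked_df, members)$es,
               enrichmentScore(ids, members)$es)
  fwd <- enrichmentScore(ids, members)
  rev_ <- enrichmentScore(rev(ids), members)
  expect_equal(rev_$es, -fwd$es, tolerance = 1e-12)
  expect_identical(rev_$leading_edge, fwd$leading_edge)
})

test_that("unweighted ES agrees with the fgsea reference implementation", {
  library(fgsea)
  set.seed(77)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(N))
    sel <- sort(sample.int(N, sample(2:min(20, N - 1), 1)))
    ref <- fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = 0)
    if (ref == 0) next  # fgsea returns 0 on exact +/- ties; we resolve positive
    ours <- enrichmentScore(names(stats), names(stats)[sel])
    expect_equal(ours$es, ref, tolerance = 1e-12)
  }
})

test_that("the fast positions-only ES used for nulls equals the full walk", {
  set.seed(55)
  for (i in 1:200) {
    N <- sample(5:100, 1)
    Nh <- sample(seq_len(N - 1), 1)
    pos <- sort(sample.int(N, Nh))
    ids <- paste0("g", seq_len(N))
    full <- enrichmentScore(ids, ids[pos])$es
    fast <- gsetperm:::.esFromPositions(pos, Nh, N)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("null distributions are seeded, sized and roughly symmetric", {
  ids <- paste0("g", 1:500)
  n1 <- sampleNull(ids, 20, nDraws = 2000, seed = 9)
  n2 <- sampleNull(ids, 20, nDraws = 2000, seed = 9)
  expect_identical(nullES(n1), nullES(n2))
  expect_length(nullES(n1), 2000)
  expect_lt(abs(mean(nullES(n1))), 3 * sd(nullES(n1)) / sqrt(2000))

  nb <- sampleNull(paste0("g", 1:12), 11, nDraws = 500, seed = 1)
  expect_lte(length(unique(nullES(nb))), 12)  # complement-of-one-gene structure
  expect_error(sampleNull(ids, 500, seed = 1), "setSize")
})

test_that("permutation p has the 1/n floor and matches a brute-force count", {
  ids <- paste0("g", 1:300)
  null <- sampleNull(ids, 25, nDraws = 2000, seed = 13)
  expect_equal(permutationP(0.999, null), 0.0005)
  expect_equal(permutationP(0, null), 1)
  for (es in c(0.08, -0.1, 0.2, -0.25)) {
    v <- nullES(null)
    ref <- max(sum(abs(v) >= abs(es)), 1) / length(v)
    expect_equal(permutationP(es, null), ref, tolerance = 1e-15)
  }
  med <- median(nullES(null)[nullES(null) > 0])
  expect_equal(permutationP(med, null), 0.5, tolerance = 0.05)
  # p of ES values drawn from the null itself is close to uniform
  set.seed(3)
  ps <- vapply(sample(nullES(null), 200), permutationP, numeric(1), null = null)
  expect_lt(max(abs(sort(ps) - (1:200) / 200)), 0.12)
})

test_that("NES rescales by same-sign null mean magnitude", {
  null <- new("EnrichmentNull", setSize = 5L, nDraws = 6L,
              nullEs = c(0.4, 0.4, 0.4, -0.2, -0.4, -0.6), seed = 1L)
  expect_equal(normalizedES(0.8, null), 2)
  expect_equal(normalizedES(-0.8, null), -2)
  expect_equal(normalizedES(0, null), 0)
  neg_only <- new("EnrichmentNull", setSize = 2L, nDraws = 2L,
                  nullEs = c(-0.1, -0.2), seed = 1L)
  expect_error(normalizedES(0.5, neg_only), "same-sign")
})

test_that("permutation FDR matches a brute-force double loop and calibrates", {
  set.seed(19)
  ids <- paste0("g", 1:200)
  nulls <- lapply(c(10, 20, 30, 40, 50), function(sz)
    sampleNull(ids, sz, nDraws = 200, seed = sz))
  nes <- c(2.1, -1.4, 0.9, -0.6, 1.1)
  q <- gseaFdr(nes, nulls)
  ref <- brute_gsea_fdr(nes, lapply(nulls, nullES))
  expect_equal(q, ref, tolerance = 1e-12)
  expect_true(all(q >= 0 & q <= 1))

  # a lone set far beyond the pooled null gets q = 0
  expect_equal(gseaFdr(50, nulls[1]), 0)

  # observed NES drawn from the null itself should not look significant
  meds <- replicate(10, {
    obs_es <- vapply(nulls, function(nd) sample(nullES(nd), 1), numeric(1))
    obs_nes <- mapply(normalizedES, obs_es, nulls)
    median(gseaFdr(obs_nes, nulls))
  })
  expect_gt(mean(meds), 0.5)
})

test_that("runGsea is deterministic and recovers a planted set at rank 1", {
  cfg <- SimulationConfig(nGenes = 1200L, nPerCell = 5L, nDeGenes = 0L,
    plantedSets = list(list(name = "PLANTED", size = 50L, meanShift = 1.0,
                            direction = "up")),
    nBackgroundSets = 10L, setSizeRange = c(15L, 100L), noiseSd = 0.5,
    seed = 41L)
  sim <- simulateExperiment(cfg)
  se <- quantileNormalize(log2Transform(sim$experiment))
  r1 <- runGsea(se, "cerebellum", sim$geneSets, nDraws = 500L, seed = 8L)
  r2 <- runGsea(se, "cerebellum", sim$geneSets, nDraws = 500L, seed = 8L)
  expect_identical(r1, r2)
  expect_identical(r1$name[1], "PLANTED")
  expect_equal(r1$perm_p[1], 1 / 500)
  expect_lte(r1$fdr_q[1], 0.05)
  expect_true(all(r1$leading_edge[[1]] %in% geneSets(sim$geneSets)$PLANTED))
  # a down-planted contrast flips the ES sign
  expect_gt(r1$es[1], 0)
})

test_that("leading-edge overlap is rank-ordered intersection", {
  mk <- function(le) data.frame(name = "S", set_size_used = 3L, es = 0.5,
                                nes = 1, perm_p = 0.01, fdr_q = 0.01,
                                leading_edge = I(list(le)))
  a <- mk(c("g1", "g3", "g5")); b <- mk(c("g5", "g2", "g3"))
  expect_identical(leadingEdgeOverlap(a, b, "S"), c("g3", "g5"))
  expect_identical(leadingEdgeOverlap(a, a, "S"), c("g1", "g3", "g5"))
  expect_identical(leadingEdgeOverlap(a, mk(c("g7")), "S"), character(0))
  expect_error(leadingEdgeOverlap(a, b, "T"), "missing")
})
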