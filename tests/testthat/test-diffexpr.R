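test_that("per-gene OLS matches the normal-equations oracle", {
  ee <- rand_ee(40, 2, seed = 11)  # 8 samples, balanced
  de <- suppressWarnings(fitGeneModels(ee))
  tissue <- as.integer(tissueFactor(ee)) - 1L
  genotype <- as.integer(genotypeFactor(ee)) - 1L
  y <- exprValues(ee)
  for (g in c(1, 7, 23, 40)) {
    o <- brute_ols(y[g, ], tissue, genotype)
    expect_equal(de$genotype_effect[g], o$b[[3]], tolerance = 1e-9)
    expect_equal(de$tissue_effect[g], o$b[[2]], tolerance = 1e-9)
    expect_equal(de$t_stat[g], o$t[[3]], tolerance = 1e-9)
    expect_equal(de$p_value[g], o$p[[3]], tolerance = 1e-9)
    expect_equal(de$tissue_p[g], o$p[[2]], tolerance = 1e-9)
  }
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(abs(de$signed_fold_change) >= 1))
  # q monotone non-decreasing in p
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-15))
})

test_that("model fit is invariant to joint sample/design permutation", {
  ee <- rand_ee(25, 2, seed = 5)
  set.seed(9)
  perm <- sample(ncol(ee))
  de1 <- suppressWarnings(fitGeneModels(ee))
  de2 <- suppressWarnings(fitGeneModels(ee[, perm]))
  expect_equal(de1, de2, tolerance = 1e-12)
})

test_that("exact-fit genes get the degenerate-variance p-value rule", {
  ee <- rand_ee(3, 2, seed = 2)
  v <- exprValues(ee)
  v[1, ] <- 5 + (as.integer(tissueFactor(ee)) - 1L)  # y == tissue indicator
  SummarizedExperiment::assay(ee, "exprs") <- v
  de <- NULL
  warns <- capture_warnings(de <- fitGeneModels(ee))
  expect_true(any(grepl("residual variance", warns)))
  expect_equal(de$genotype_effect[1], 0, tolerance = 1e-10)
  expect_equal(de$p_value[1], 1)
  expect_equal(de$tissue_p[1], 0)
})

test_that("degenerate designs are rejected", {
  ee <- rand_ee(5, 2, seed = 3)
  one_tissue <- ee[, tissueFactor(ee) == "blood"]
  expect_error(fitGeneModels(one_tissue), "tissue")
  expect_error(fitGeneModels(ee[, 1:3]), "3 samples")
})

test_that("Welch statistic, df and p match hand evaluation and t.test", {
  w <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  w <- welchTTest(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(w$t, -4 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(w$df, 6)
  expect_equal(w$p, 2 * pt(-4 / sqrt(5 / 6), 6), tolerance = 1e-12)

  # symmetry and agreement with the stats oracle on random draws
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), mean = 0.5)
    w <- welchTTest(a, b)
    ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    ws <- welchTTest(b, a)
    expect_equal(ws$t, -w$t)
    expect_equal(ws$p, w$p)
  }

  expect_warning(w <- welchTTest(c(2, 2), c(3, 3)), "constant")
  expect_equal(w$p, 0)
  expect_error(welchTTest(1, c(1, 2)), ">= 2")
})

test_that("signed fold change follows the down-in-transgenic sign convention", {
  expect_equal(signedFoldChange(4, 2), 2)
  expect_equal(signedFoldChange(2, 4), -2)
  expect_equal(signedFoldChange(3, 3), 1)
  expect_error(signedFoldChange(0, 1), "positive")
  set.seed(4)
  x <- runif(50, 0.1, 10); y <- runif(50, 0.1, 10)
  expect_true(all(abs(signedFoldChange(x, y)) >= 1))
})

test_that("Storey q-values match the min-over-thresholds definition", {
  q <- storeyQvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(q$q_values, rep(0.04, 4))
  expect_equal(q$pi0, 1)

  set.seed(33)
  for (i in 1:5) {
    p <- runif(200)^(sample(1:3, 1))  # mildly enriched near 0
    fit <- storeyQvalues(p)
    expect_true(fit$pi0 > 0 && fit$pi0 <= 1)
    expect_equal(fit$q_values, brute_storey_q(p, fit$pi0), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(fit$q_values[o]) >= -1e-15))
  }

  # with pi0 forced to 1 the result is Benjamini-Hochberg
  p <- runif(150)
  expect_equal(storeyQvalues(p, pi0 = 1)$q_values, p.adjust(p, "BH"),
               tolerance = 1e-12)

  q1 <- storeyQvalues(rep(1, 500))
  expect_equal(unique(q1$q_values), q1$pi0)
  expect_warning(storeyQvalues(runif(10)), "pi0 = 1")
  expect_error(storeyQvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("tissue-nonspecific fraction counts significant-but-tissue-flat genes", {
  # planted truth: 20 strong DE genes, 5 of them with no tissue effect
  set.seed(61)
  nG <- 200; npc <- 5
  base <- matrix(rnorm(nG * 4 * npc, 8, 0.1), nrow = nG,
                 dimnames = list(sprintf("g%03d", 1:nG),
                                 sprintf("s%02d", 1:(4 * npc))))
  ee <- make_ee(base, npc)
  tis <- as.integer(tissueFactor(ee)) - 1L
  gen <- as.integer(genotypeFactor(ee)) - 1L
  v <- exprValues(ee)
  v[1:20, ] <- v[1:20, ] + 4 * rep(gen, each = 20)          # DE genes
  v[6:200, ] <- v[6:200, ] + 5 * rep(tis, each = 195)       # tissue effect except genes 1-5
  SummarizedExperiment::assay(ee, "exprs") <- v
  de <- suppressWarnings(fitGeneModels(ee))
  out <- tissueNonspecificFraction(de, alphaGenotype = 1e-4, alphaTissue = 0.05)
  expect_lt(abs(out$fraction - 0.25), 0.05)

  none <- de; none$p_value <- rep(0.9, nG)
  expect_identical(tissueNonspecificFraction(none),
                   list(count_significant = 0L, count_tissue_flat = 0L,
                        fraction = 0))
  all_in <- tissueNonspecificFraction(de, alphaGenotype = 1.0)
  expect_equal(all_in$count_significant, nG)
})
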