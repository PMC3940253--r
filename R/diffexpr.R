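#' Per-gene two-factor linear model
#'
#' Fits, by ordinary least squares, \code{y = b0 + b1 * tissue + b2 * genotype}
#' to every gene, with tissue coded blood = 0 / cerebellum = 1 and genotype
#' coded wildtype = 0 / transgenic = 1, so a positive genotype effect means
#' up-regulation in transgenic animals. Two-sided p-values come from the t
#' distribution with \code{n_samples - 3} degrees of freedom. Genotype
#' p-values are converted to Storey-Tibshirani q-values, and a signed linear
#' fold change (transgenic vs wildtype group means) is attached.
#'
#' Exact-fit genes (residual variance below 1e-12) get p = 1 when the
#' coefficient is also ~0 and p = 0 otherwise, with a warning.
#'
#' @param x an \linkS4class{ExpressionExperiment} on the log2 scale
#'   (normalize first).
#' @return data.frame with columns \code{gene}, \code{genotype_effect},
#'   \code{t_stat}, \code{p_value}, \code{q_value}, \code{signed_fold_change},
#'   \code{tissue_effect}, \code{tissue_t}, \code{tissue_p}.
#' @export
fitGeneModels <- function(x) {
  if (!identical(exprScale(x), "log2"))
    stop("fitGeneModels expects log2-scale values", call. = FALSE)
  y <- exprValues(x)
  tissue <- as.integer(tissueFactor(x)) - 1L    # blood=0, cerebellum=1
  genotype <- as.integer(genotypeFactor(x)) - 1L # wildtype=0, transgenic=1
  n <- ncol(y)
  if (n <= 3L) stop("need more than 3 samples (zero residual df)", call. = FALSE)
  if (length(unique(tissue)) < 2L)
    stop("tissue factor has a single level", call. = FALSE)
  if (length(unique(genotype)) < 2L)
    stop("genotype factor has a single level", call. = FALSE)

  X <- cbind(intercept = 1, tissue = tissue, genotype = genotype)
  fit <- stats::lm.fit(X, t(y))
  B <- t(fit$coefficients)           # genes x 3
  res <- t(fit$residuals)            # genes x n
  df <- n - 3L
  sigma2 <- rowSums(res^2) / df
  xtxinv <- solve(crossprod(X))

  tp <- function(j) {
    b <- B[, j]
    se <- sqrt(sigma2 * xtxinv[j, j])
    tt <- b / se
    p <- 2 * stats::pt(-abs(tt), df)
    exact <- sigma2 < 1e-12
    if (any(exact)) {
      warning(sum(exact), " gene(s) with ~zero residual variance; ",
              "p set to 0/1 by coefficient magnitude", call. = FALSE)
      tt[exact] <- 0
      p[exact] <- ifelse(abs(b[exact]) < 1e-12, 1, 0)
    }
    list(b = b, t = tt, p = p)
  }
  gt <- tp(3L)
  ts <- tp(2L)

  lin <- 2^y
  m_tg <- rowMeans(lin[, genotype == 1L, drop = FALSE])
  m_wt <- rowMeans(lin[, genotype == 0L, drop = FALSE])
  sfc <- signedFoldChange(m_tg, m_wt)

  qfit <- storeyQvalues(gt$p)

  data.frame(gene = rownames(y),
             genotype_effect = unname(gt$b), t_stat = unname(gt$t),
             p_value = unname(gt$p), q_value = unname(qfit$q_values),
             signed_fold_change = unname(sfc),
             tissue_effect = unname(ts$b), tissue_t = unname(ts$t),
             tissue_p = unname(ts$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Welch's two-sample t-test
#'
#' \code{t = (mean(a) - mean(b)) / sqrt(var(a)/nA + var(b)/nB)} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When both
#' groups have (numerically) zero variance: equal means give t = 0, p = 1;
#' different means give p = 0 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with elements \code{t}, \code{df}, \code{p}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va < 1e-24 && vb < 1e-24) {
    if (abs(dm) < 1e-12) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    warning("both groups constant with different means; p = 0", call. = FALSE)
    return(list(t = sign(dm) * Inf, df = length(a) + length(b) - 2, p = 0))
  }
  sa <- va / length(a); sb <- vb / length(b)
  tt <- dm / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1L) + sb^2 / (length(b) - 1L))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Per-tissue post-hoc Welch tests for one gene
#'
#' Runs \code{\link{welchTTest}} of transgenic vs wildtype within each
#' tissue stratum, the post-hoc follow-up used for individual genes of
#' interest.
#'
#' @param x an ExpressionExperiment (log2 scale).
#' @param gene a gene id present in \code{x}.
#' @return data.frame with one row per tissue: tissue, t, df, p,
#'   mean_transgenic, mean_wildtype.
#' @export
welchByTissue <- function(x, gene) {
  if (!gene %in% rownames(x)) stop("unknown gene: ", gene, call. = FALSE)
  v <- exprValues(x)[gene, ]
  tis <- tissueFactor(x); gen <- genotypeFactor(x)
  do.call(rbind, lapply(levels(droplevels(tis)), function(tl) {
    sel <- tis == tl
    a <- v[sel & gen == "transgenic"]; b <- v[sel & gen == "wildtype"]
    w <- welchTTest(a, b)
    data.frame(tissue = tl, t = w$t, df = w$df, p = w$p,
               mean_transgenic = mean(a), mean_wildtype = mean(b),
               stringsAsFactors = FALSE)
  }))
}

#' Signed fold change
#'
#' Ratio of linear-scale group means with the sign convention that negative
#' values mean down-regulation in transgenic animals: returns
#' \code{tg/wt} when \code{tg >= wt} and \code{-(wt/tg)} otherwise, so
#' \code{|value| >= 1} always.
#'
#' @param transgenicMean,wildtypeMean positive linear-scale means
#'   (vectorized).
#' @return signed ratio(s).
#' @export
signedFoldChange <- function(transgenicMean, wildtypeMean) {
  if (any(transgenicMean <= 0) || any(wildtypeMean <= 0))
    stop("group means must be positive (linear scale)", call. = FALSE)
  ifelse(transgenicMean >= wildtypeMean,
         transgenicMean / wildtypeMean,
         -(wildtypeMean / transgenicMean))
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the grid lambda = 0, 0.05, ..., 0.90
#' from \code{pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))} via a cubic
#' smoothing spline evaluated at lambda = 0.90, clipped into (0, 1]; then
#' \code{q_i = min over t >= p_(i) of pi0 * m * t / #\{p <= t\}}, enforced
#' monotone in p. With pi0 forced to 1 this reduces to Benjamini-Hochberg.
#' Fewer than 100 p-values fall back to pi0 = 1 with a warning (the smoother
#' is unstable at small m).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 optional: force a null-proportion value instead of estimating.
#' @return list of class \code{QValueFit}: \code{pi0}, \code{lambda_grid},
#'   \code{q_values} (in input order).
#' @export
storeyQvalues <- function(p, pi0 = NULL) {
  if (length(p) < 1L || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  m <- length(p)
  lambda <- seq(0, 0.90, by = 0.05)
  if (is.null(pi0)) {
    if (m < 100L) {
      warning("fewer than 100 p-values: falling back to pi0 = 1", call. = FALSE)
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = 0.90)$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  } else {
    .assertScalarNumber(pi0, "pi0", lower = 1e-12, upper = 1)
  }
  o <- order(p)
  ps <- p[o]
  qs <- pi0 * m * ps / seq_len(m)
  qs <- rev(cummin(rev(qs)))     # min over thresholds t >= p_(i)
  qs <- pmin(qs, 1)
  q <- numeric(m)
  q[o] <- qs
  structure(list(pi0 = pi0, lambda_grid = lambda, q_values = q),
            class = "QValueFit")
}

#' Tissue-nonspecific fraction of significant genes
#'
#' Among genes with genotype p-value below \code{alphaGenotype}, counts those
#' whose tissue term is not significant (\code{tissue_p >= alphaTissue}),
#' i.e. genes whose expression does not differ between blood and brain.
#'
#' @param de data.frame from \code{\link{fitGeneModels}}.
#' @param alphaGenotype significance threshold on the genotype p-value
#'   (default 0.01, the uncorrected cutoff used for the significant lists).
#' @param alphaTissue threshold on the tissue p-value (default 0.05).
#' @return list: \code{count_significant}, \code{count_tissue_flat},
#'   \code{fraction} (0 when nothing is significant).
#' @export
tissueNonspecificFraction <- function(de, alphaGenotype = 0.01,
                                      alphaTissue = 0.05) {
  .assertScalarNumber(alphaGenotype, "alphaGenotype", lower = 1e-300, upper = 1)
  .assertScalarNumber(alphaTissue, "alphaTissue", lower = 1e-300, upper = 1)
  sig <- de$p_value < alphaGenotype
  flat <- sig & de$tissue_p >= alphaTissue
  n_sig <- sum(sig); n_flat <- sum(flat)
  list(count_significant = n_sig, count_tissue_flat = n_flat,
       fraction = if (n_sig == 0L) 0 else n_flat / n_sig)
}
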