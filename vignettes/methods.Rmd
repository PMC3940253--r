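---
title: "Models and design choices in gsetperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gsetperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsetperm)
```

gsetperm analyzes two-genotype × two-tissue expression studies: paired
blood and cerebellum profiles from transgenic and wild-type animals, with
3–5 replicates per cell. This vignette records the statistical models, the
parameters that matter, and the choices made where conventions genuinely
diverge. Nothing here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The per-gene model

Expression (log2 scale, quantile-normalized) is modeled per gene as

$$y = \beta_0 + \beta_1\,\text{tissue} + \beta_2\,\text{genotype} + \varepsilon$$

by ordinary least squares, with tissue coded blood = 0 / cerebellum = 1 and
genotype wildtype = 0 / transgenic = 1, so $\beta_2 > 0$ means up-regulation
in transgenic animals. No interaction term is fitted: with 3–5 replicates
per cell the additive model is the power-sensible choice, and per-tissue
questions are answered downstream by Welch tests on the tissue strata
(`welchByTissue`). Two-sided p-values use the $t$ distribution with
$n - 3$ degrees of freedom. Genes fitted exactly (residual variance below
$10^{-12}$) cannot carry distributional p-values; they get p = 1 when the
coefficient is also ~0 and p = 0 otherwise, with a warning — a rule chosen
so that degenerate rows never silently dominate a ranking.

Fold changes are reported on the linear scale with the convention that
negative values mean down-regulation in transgenic samples:
$\mathrm{tg}/\mathrm{wt}$ when the transgenic mean is larger, otherwise
$-(\mathrm{wt}/\mathrm{tg})$, so magnitudes are always ≥ 1.

### Storey–Tibshirani q-values

$\hat\pi_0$ is estimated from $\pi_0(\lambda) = \#\{p > \lambda\} /
(m(1-\lambda))$ on $\lambda = 0, 0.05, \ldots, 0.90$, smoothed with a cubic
spline (df = 3) and read off at $\lambda = 0.90$. The estimate is clamped
into $[10^{-8}, 1]$: the spec of the estimator requires $\pi_0 \in (0, 1]$,
and a smoother extrapolation can dip below zero on sparse grids. Below 100
tests the smoother is unstable, so the code falls back to $\pi_0 = 1$
(Benjamini–Hochberg) with a warning. Q-values are the running minimum of
$\hat\pi_0\, m\, p_{(i)} / i$ from the largest p downward, which realizes
the min-over-thresholds definition and guarantees monotonicity in p.

## Gene set enrichment with a gene-set permutation null

Within one tissue, genes are ranked by the signal-to-noise ratio
$(\bar{x}_{tg} - \bar{x}_{wt}) / (s_{tg} + s_{wt})$. Each group sd is
floored at $\max(s,\ 0.2\,|\bar{x}|,\ 10^{-8})$ — the conventional guard
that keeps near-constant genes from producing unbounded metrics; on
quantile-normalized log2 data the floor rarely binds.

The running sum is **unweighted**: +1/Nh at members, −1/(N−Nh) elsewhere,
so it always terminates at zero. The ES is the *signed maximum deviation*
from zero — not the literal largest value, which could never be negative,
while down-regulated pathways (negative NES) are an expected outcome. A
weighting exponent on |metric| is exposed (`weightExp`) but defaults to 0,
which is the convention used throughout. Ties between equal positive and
negative deviations resolve positive, compared with a $10^{-9}$ tolerance:
attainable deviations live on a rational grid with spacing far above
$10^{-9}$, so the tolerance only absorbs floating-point accumulation and
can never misclassify a true difference.

Because replication is too small for phenotype-label permutation, the null
is **gene-set permutation**: 2,000 random same-size subsets of the ranked
universe, scored identically. Null generation uses a positions-only
evaluation of the walk (local maxima sit just after hits, minima just
before), which the tests verify against the full prefix-sum walk.

* **Permutation p** = $\max(\#\{|ES_{null}| \ge |ES|\}, 1)/n_{draws}$, so
  the floor at 2,000 draws is exactly 0.0005, and under a null ranking p is
  uniform on $\{1/n_{draws}, \ldots, 1\}$. The magnitude-based two-sided
  count is the convention under which the permutation test is calibrated
  (type-I ≈ nominal at the 0.05 threshold used for significance); the null
  of the unweighted walk is symmetric, so no per-sign normalization of the
  denominator is needed.
* **NES** = ES divided by the mean |ES| of same-sign null draws; NES = 0
  iff ES = 0, and the sign is preserved.
* **FDR q** pools every null draw after normalizing it by its own
  distribution's same-sign mean, then compares within-sign tail fractions
  of the pooled null and the observed NES values, clips into [0, 1], and
  enforces that a stronger |NES| never receives a larger q than a weaker
  same-sign one (each set takes the minimum over itself and all weaker
  sets, as in Benjamini–Hochberg). Within-sign fractions (rather than
  fractions of the whole pool) are used in both numerator and denominator;
  with a symmetric null and balanced observed signs the two conventions
  agree in expectation, and the within-sign form is the one used by the
  standard multiple-hypothesis procedure for permutation GSEA.

The **leading edge** is the set members at or before the running-sum
maximum (in rank order) for positive ES, or at or after the minimum (in
reverse rank order) for negative ES; `leadingEdgeOverlap` intersects two
results' leading edges in the first result's rank order, which is how
shared core genes of a pathway across tissues are extracted.

Null distributions are cached per set size within a run; per-size seeds are
derived as `seed + size`, so equal-size sets share one null and every run
is reproducible from a single integer.

## Overlap testing and clustering

Candidate-list overlap uses the exact hypergeometric upper tail computed as
a direct tail sum of `dhyper` terms. The universe is the set of measured
genes after filtering — not the genome — matching standard enrichment
practice; candidate lists in another species' symbols are translated
through an explicit two-column homolog map (one-to-many mappings expand,
unmapped ids are dropped with a count).

Clustering of significant genes standardizes rows (mean 0, sd 1, $n-1$
denominator, consistent with the Welch statistics) and applies
average-linkage agglomeration on 1 − Pearson correlation for both genes and
samples — the standard pairing for expression heatmaps; Euclidean/complete
are exposed as options. Constant rows or columns carry no correlation
information and are excluded with a warning. Cutting the sample tree at 2
and at the number of tissue×genotype cells reports whether samples separate
by tissue first and then by genotype.

Gene sets are filtered to measured size 15–500 **after** intersection with
the measured genes: enrichment statistics only see measured genes, so the
size that matters is the measured size (this also makes the filter
idempotent).

## The synthetic-data generator

`simulateExperiment` builds log2 expression as baseline
$\mathcal{N}(8, 2)$ + tissue effect + genotype effect + i.i.d.
$\mathcal{N}(0, \sigma)$ noise, and exports linear-scale intensities
($2^x$) so the pipeline exercises its own re-logging and normalization.
Defaults are the study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| `nGenes` | 10,000 | lower end of a genome-wide array's probe-set count |
| `nPerCell` | 5 | the larger model's 5 vs 5 design |
| `tissueEffectSd` | 1.0 log2 | stand-in for a strong tissue main effect |
| `fracTissueAffected` | 0.6 | "majority of genes" tissue-dependent |
| `nDeGenes`, `deEffectLog2` | 100, 1.0 | a small genotype-responsive fraction |
| `noiseSd` | 0.5 log2 | typical residual sd for array replicates |
| background sets | 50 of size 15–500 | KEGG-like collection |

Planted pathway members all receive the stated shift (so the mean member
shift equals it exactly) and are drawn disjoint from the individual DE
genes and from other planted sets, keeping the recorded truth
single-valued per gene; background sets may overlap anything, as real
pathway collections do. The generator emulates the *statistical* structure
only: no probe-level model, no batch or array effects, no count noise,
no correlated gene blocks beyond the planted sets. Passing tests therefore
demonstrate correctness of the statistics under the assumed model, not
robustness to every artifact of real array data.

The demo (`runDemo`) uses a tissue-dominant variant (tissue sd 3.0, DE
effect 1.5 log2, 2,000 genes, 1,000 draws) so that the sample dendrogram
displays the tissue-first, genotype-second separation characteristic of
paired-tissue designs, at a size that runs in seconds.

## Problem sizes used in validation

The test-suite and acceptance-script simulations use sizes chosen as the
smallest at which each property is sharp: null calibration at 5,000 genes
with 50 background sets and 2,000 draws (KS tolerance 0.05; binomial 99%
band for the 0.05-threshold fraction); power at 4,000 genes over 20
replicates of a planted size-50, +1 log2 pathway at noise sd 0.5 with 5 vs
5 replicates; oracle equivalence over 1,000 random instances at N ≤ 50.
Determinism is checked byte-for-byte on rerun demo outputs.

## Known limitations

* Probe-level summarization (e.g. PLIER from CEL files) is out of scope;
  the pipeline consumes a gene-level (or probe-set-level) matrix, and
  several probe sets per gene are retained as distinct rows.
* The additive model has no interaction term; tissue-specific genotype
  effects surface only through the post-hoc per-tissue Welch tests.
* Gene-set permutation preserves the ranking while permuting membership,
  so inter-gene correlation within real pathways is not reflected in the
  null; q-values for strongly co-expressed sets are anti-conservative in
  that respect (a known property of this null, accepted for small-n
  designs).
* Homolog translation is a static table; no live database lookups.
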