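#' Simulate a two-tissue by two-genotype expression experiment
#'
#' Generates, on the log2 scale, per-gene values
#' \code{baseline + tissue effect + genotype effect + Gaussian noise} for a
#' balanced design of \code{4 * nPerCell} samples (blood/cerebellum x
#' wildtype/transgenic), then exports linear-scale intensities (\code{2^x})
#' to mirror absolute array measurements. A configurable fraction of genes
#' carries a per-gene tissue effect (cerebellum relative to blood); a small
#' set of DE genes carries an individual genotype shift (random sign); each
#' planted gene set shifts all of its members by a common subtle amount in
#' the transgenic samples - the regime in which pathway-level enrichment is
#' detectable while no single member reaches per-gene significance. Random
#' background sets are drawn without replacement per set (overlap across
#' sets allowed, as in KEGG). Identical configs give byte-identical outputs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list: \code{experiment} (linear-scale
#'   \linkS4class{ExpressionExperiment}), \code{geneSets}
#'   (\linkS4class{GeneSetCollection}: planted sets first, then background),
#'   and \code{truth} - a list of class \code{SimulationTruth} with
#'   \code{de_gene_ids}, \code{planted_set_names} and
#'   \code{per_gene_true_effect} (named log2 shifts).
#' @export
simulateExperiment <- function(config) {
  validObject(config)
  ng <- config@nGenes; npc <- config@nPerCell
  genes <- sprintf("G%06d", seq_len(ng))
  cells <- expand.grid(rep = seq_len(npc),
                       genotype = .GENOTYPE_LEVELS, tissue = .TISSUE_LEVELS,
                       stringsAsFactors = FALSE)
  samples <- sprintf("%s_%s_%d", cells$tissue, cells$genotype, cells$rep)
  tisInd <- as.numeric(cells$tissue == "cerebellum")
  genInd <- as.numeric(cells$genotype == "transgenic")

  out <- withSeed(config@seed, {
    baseline <- stats::rnorm(ng, mean = 8, sd = 2)
    tissue_eff <- numeric(ng)
    n_aff <- round(config@fracTissueAffected * ng)
    if (n_aff > 0L) {
      aff <- sample.int(ng, n_aff)
      tissue_eff[aff] <- stats::rnorm(n_aff, 0, config@tissueEffectSd)
    }
    geno_eff <- numeric(ng)
    de_idx <- integer(0)
    if (config@nDeGenes > 0L) {
      de_idx <- sort(sample.int(ng, config@nDeGenes))
      geno_eff[de_idx] <- sample(c(-1, 1), config@nDeGenes, replace = TRUE) *
        config@deEffectLog2
    }
    # planted sets: members disjoint from DE genes and from each other, so
    # the recorded true effect is single-valued per gene
    sets <- list(); descs <- character()
    avail <- setdiff(seq_len(ng), de_idx)
    for (ps in config@plantedSets) {
      if (length(avail) < ps$size)
        stop("not enough genes left to plant set '", ps$name, "'", call. = FALSE)
      pick <- sample(avail, ps$size)
      avail <- setdiff(avail, pick)
      shift <- if (ps$direction == "up") ps$meanShift else -ps$meanShift
      geno_eff[pick] <- geno_eff[pick] + shift
      sets[[ps$name]] <- genes[sort(pick)]
      descs[ps$name] <- sprintf("planted %s set (%.2f log2)", ps$direction, shift)
    }
    planted_names <- names(sets)
    sz <- config@setSizeRange
    for (b in seq_len(config@nBackgroundSets)) {
      nm <- sprintf("BG%03d", b)
      size <- if (sz[1L] == sz[2L]) sz[1L] else sample(sz[1L]:sz[2L], 1L)
      sets[[nm]] <- genes[sort(sample.int(ng, size))]
      descs[nm] <- "random background set"
    }
    log2mat <- outer(baseline, rep(1, length(samples))) +
      outer(tissue_eff, tisInd) + outer(geno_eff, genInd) +
      matrix(stats::rnorm(ng * length(samples), 0, config@noiseSd),
             nrow = ng)
    dimnames(log2mat) <- list(genes, samples)
    affected <- which(geno_eff != 0)
    list(log2mat = log2mat, sets = sets, descs = descs,
         de_ids = genes[de_idx], planted_names = planted_names,
         effects = stats::setNames(geno_eff[affected], genes[affected]))
  })

  design <- data.frame(sample = samples, tissue = cells$tissue,
                       genotype = cells$genotype, stringsAsFactors = FALSE)
  se <- ExpressionExperiment(2^out$log2mat, design, scale = "linear")
  truth <- structure(list(de_gene_ids = out$de_ids,
                          planted_set_names = out$planted_names,
                          per_gene_true_effect = out$effects),
                     class = "SimulationTruth")
  list(experiment = se,
       geneSets = GeneSetCollection(out$sets, out$descs),
       truth = truth)
}

#' Write a simulated experiment to disk
#'
#' Writes \code{expression.tsv} (linear scale), \code{design.tsv},
#' \code{sets.gmt} and \code{truth.tsv} under \code{dir}.
#'
#' @param sim result of \code{\link{simulateExperiment}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "design.tsv", "sets.gmt", "truth.tsv"))
  writeExpression(sim$experiment, paths[1L])
  writeDesign(sim$experiment, paths[2L])
  writeGmt(sim$geneSets, paths[3L])
  eff <- sim$truth$per_gene_true_effect
  .writeTsv(data.frame(gene = names(eff), true_log2_effect = unname(eff),
                       is_de_gene = names(eff) %in% sim$truth$de_gene_ids,
                       stringsAsFactors = FALSE), paths[4L])
  invisible(paths)
}
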