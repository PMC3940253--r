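#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form \code{key = value}; \code{#} comments and blank lines
#' ignored. Recognized keys: \code{matrix}, \code{design}, \code{gmt},
#' \code{candidates}, \code{homolog_map}, \code{scale}, \code{alpha},
#' \code{n_draws}, \code{seed}, \code{min_size}, \code{max_size},
#' \code{tissues} (comma-separated).
#'
#' @param path configuration file path.
#' @return named list of configuration values (numerics parsed).
#' @export
readPipelineConfig <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  cfg <- stats::setNames(
    lapply(kv, function(f) trimws(paste(f[-1L], collapse = "="))),
    trimws(vapply(kv, `[[`, character(1), 1L)))
  for (k in c("alpha", "n_draws", "seed", "min_size", "max_size"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$tissues))
    cfg$tissues <- trimws(strsplit(cfg$tissues, ",", fixed = TRUE)[[1L]])
  cfg
}

.defaultPipelineParams <- function(cfg) {
  defaults <- list(scale = "linear", alpha = 0.01, n_draws = 2000,
                   seed = 1, min_size = 15, max_size = 500,
                   tissues = c("cerebellum", "blood"))
  defaults[names(cfg)] <- cfg
  if (defaults$n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  if (defaults$min_size < 1 || defaults$max_size < defaults$min_size)
    stop("invalid set size bounds", call. = FALSE)
  defaults
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Reads an expression matrix, design and gene sets; quantile-normalizes on
#' the log2 scale; fits the per-gene tissue + genotype model with
#' Storey-Tibshirani q-values; runs per-tissue gene-set-permutation GSEA;
#' optionally tests candidate-gene overlap (with homolog translation); and
#' clusters the significant genes. Results and a JSON run manifest are
#' written under \code{outDir}. Fully deterministic given the config: the
#' single seed fans out to fixed per-stage child seeds so each stage is
#' independently reproducible.
#'
#' @param config a named list (see \code{\link{readPipelineConfig}}) or a
#'   path to a flat key=value config file. Required keys: \code{matrix},
#'   \code{design}, \code{gmt}.
#' @param outDir output directory.
#' @return invisibly, the manifest list.
#' @export
runFullPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  p <- .defaultPipelineParams(config)
  for (k in c("matrix", "design", "gmt")) {
    if (is.null(p[[k]])) stop("config is missing required key '", k, "'", call. = FALSE)
    if (!file.exists(p[[k]]))
      stop("stage input: file not found for '", k, "': ", p[[k]], call. = FALSE)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "gsetperm",
                   version = as.character(utils::packageVersion("gsetperm")),
                   parameters = p[c("alpha", "n_draws", "seed", "min_size",
                                    "max_size", "tissues", "scale")],
                   seed_fanout = list(gsea = "seed + 202 + tissue index"),
                   outputs = character(), status = "incomplete")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      .writeManifest(manifest, outDir)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  se <- stage("load", {
    mat <- readExpression(p$matrix, scale = p$scale)
    design <- readDesign(p$design)
    ExpressionExperiment(mat, design, scale = attr(mat, "scale"))
  })
  norm <- stage("normalize", quantileNormalize(log2Transform(se)))
  stage("normalize", writeExpression(norm, file.path(outDir, "normalized.tsv")))
  manifest$outputs <- c(manifest$outputs, "normalized.tsv")

  de <- stage("diffexpr", fitGeneModels(norm))
  stage("diffexpr", writeDeTable(de, file.path(outDir, "de.tsv")))
  manifest$outputs <- c(manifest$outputs, "de.tsv")
  manifest$n_significant <- sum(de$p_value < p$alpha)
  manifest$tissue_nonspecific <-
    tissueNonspecificFraction(de, alphaGenotype = p$alpha)

  sets <- stage("gsea", readGmt(p$gmt))
  tissues_present <- intersect(p$tissues, as.character(unique(tissueFactor(norm))))
  gsea_results <- list()
  for (i in seq_along(tissues_present)) {
    ti <- tissues_present[[i]]
    res <- stage("gsea", runGsea(norm, ti, sets, minSize = p$min_size,
                                 maxSize = p$max_size, nDraws = p$n_draws,
                                 seed = p$seed + 202 + i))
    fn <- sprintf("gsea_%s.tsv", ti)
    stage("gsea", writeGseaTable(res, file.path(outDir, fn)))
    manifest$outputs <- c(manifest$outputs, fn)
    gsea_results[[ti]] <- res
  }

  if (!is.null(p$candidates)) {
    ov <- stage("overlap", {
      cand <- readGeneList(p$candidates)
      universe <- de$gene
      if (!is.null(p$homolog_map)) {
        map <- readHomologMap(p$homolog_map)
        universe <- translateIds(universe, map)
        de_ids <- translateIds(de$gene[de$p_value < p$alpha], map)
      } else {
        de_ids <- de$gene[de$p_value < p$alpha]
      }
      hypergeometricOverlap(universe, cand, de_ids)
    })
    stage("overlap", .writeTsv(as.data.frame(unclass(ov)),
                               file.path(outDir, "overlap.tsv")))
    manifest$outputs <- c(manifest$outputs, "overlap.tsv")
  }

  sig <- de$gene[de$p_value < p$alpha]
  if (length(sig) >= 2L) {
    cl <- stage("cluster", clusterBimodal(exprValues(norm)[sig, , drop = FALSE]))
    stage("cluster", {
      writeExpression(cl$ordered, file.path(outDir, "cluster_matrix.tsv"))
      writeDendrogram(cl$gene_hclust, file.path(outDir, "cluster_genes.nwk"))
      writeDendrogram(cl$sample_hclust, file.path(outDir, "cluster_samples.nwk"))
    })
    sep <- stage("cluster", tissueGenotypeSeparation(cl$sample_hclust, se))
    manifest$outputs <- c(manifest$outputs,
                          c("cluster_matrix.tsv", "cluster_genes.nwk",
                            "cluster_samples.nwk"))
    manifest$sample_separation <- sep[c("tissue_separated", "cell_separated")]
  }

  manifest$status <- "complete"
  .writeManifest(manifest, outDir)
  invisible(manifest)
}

.writeManifest <- function(manifest, outDir) {
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' One-command demonstration on synthetic data
#'
#' Simulates an experiment with one planted up-regulated pathway (size 50,
#' +1 log2 member shift) plus background sets, writes the inputs, and runs
#' the full pipeline on them. Deterministic given the seed.
#'
#' @param outDir output directory; inputs go to \code{outDir/inputs}.
#' @param seed integer seed (default 17).
#' @param nGenes number of simulated genes (default 2000: demo-sized).
#' @param nDraws permutation draws per null (default 1000).
#' @return invisibly, the pipeline manifest.
#' @export
runDemo <- function(outDir, seed = 17L, nGenes = 2000L, nDraws = 1000L) {
  cfg <- SimulationConfig(
    nGenes = nGenes, nPerCell = 5L, tissueEffectSd = 3.0,
    fracTissueAffected = 0.6, nDeGenes = 20L, deEffectLog2 = 1.5,
    plantedSets = list(list(name = "PLANTED_UP", size = 50L,
                            meanShift = 1.0, direction = "up")),
    nBackgroundSets = 20L, setSizeRange = c(15L, 100L), noiseSd = 0.5,
    seed = seed + 101L)
  sim <- simulateExperiment(cfg)
  inputs <- file.path(outDir, "inputs")
  writeSimulation(sim, inputs)
  runFullPipeline(list(matrix = file.path(inputs, "expression.tsv"),
                       design = file.path(inputs, "design.tsv"),
                       gmt = file.path(inputs, "sets.gmt"),
                       scale = "linear", n_draws = nDraws, seed = seed),
                  outDir)
}
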