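#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds gene ids.
#'
#' @param path file path.
#' @param scale scale of the stored values, \code{"linear"} or \code{"log2"}.
#' @return numeric matrix with gene row names, sample column names and a
#'   \code{"scale"} attribute.
#' @export
readExpression <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >= 1 sample", call. = FALSE)
  gene_ids <- trimws(df[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  sample_ids <- colnames(df)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !nzchar(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (scale == "linear" && any(num < 0))
    stop("linear-scale matrix contains negative values", call. = FALSE)
  attr(num, "scale") <- scale
  num
}

#' Write an expression matrix (or ExpressionExperiment) as TSV
#'
#' @param x numeric matrix with dimnames, or an ExpressionExperiment.
#' @param path output file path.
#' @param id_column header of the gene-id column.
#' @export
writeExpression <- function(x, path, id_column = "gene") {
  if (is(x, "ExpressionExperiment")) x <- exprValues(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  .writeTsv(df, path)
}

#' Read a sample design table
#'
#' @param path TSV with header columns \code{sample}, \code{tissue},
#'   \code{genotype}.
#' @return data.frame with those columns.
#' @export
readDesign <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("sample", "tissue", "genotype")
  if (!all(need %in% colnames(df)))
    stop("design TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  df$sample <- trimws(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in design", call. = FALSE)
  bad <- setdiff(unique(df$tissue), .TISSUE_LEVELS)
  if (length(bad)) stop("unknown tissue values: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$genotype), .GENOTYPE_LEVELS)
  if (length(bad)) stop("unknown genotype values: ", paste(bad, collapse = ", "), call. = FALSE)
  df[need]
}

#' Write a sample design table
#' @param design data.frame with sample, tissue, genotype columns, or an
#'   ExpressionExperiment (its colData is written).
#' @param path output file path.
#' @export
writeDesign <- function(design, path) {
  if (is(design, "ExpressionExperiment")) {
    design <- data.frame(sample = colnames(design),
                         tissue = as.character(tissueFactor(design)),
                         genotype = as.character(genotypeFactor(design)),
                         stringsAsFactors = FALSE)
  }
  .writeTsv(design[c("sample", "tissue", "genotype")], path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member ids, tab-separated.
#' Duplicate members within a line are dropped with a warning; duplicate set
#' names are an error.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                   i, length(f)), call. = FALSE)
    nm <- trimws(f[1L])
    if (nm %in% names(sets))
      stop("duplicate set name: ", nm, call. = FALSE)
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members dropped", nm), call. = FALSE)
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- f[2L]
  }
  GeneSetCollection(sets, descs)
}

#' Write a GeneSetCollection as GMT
#' @param collection a GeneSetCollection.
#' @param path output file path.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection@descriptions[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one id per line)
#' @param path file path.
#' @return character vector of unique, trimmed ids.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a two-column homolog mapping table
#'
#' @param path TSV with header; column 1 = source id (e.g. mouse symbol),
#'   column 2 = target id (e.g. human homolog).
#' @return data.frame with columns \code{from}, \code{to}.
#' @export
readHomologMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("homolog map needs two columns", call. = FALSE)
  out <- data.frame(from = trimws(df[[1L]]), to = trimws(df[[2L]]),
                    stringsAsFactors = FALSE)
  out[nzchar(out$from) & nzchar(out$to), ]
}

#' Translate gene ids through a homolog map
#'
#' One-to-many mappings expand to all targets; the result is de-duplicated in
#' first-seen order. Unmapped ids are dropped and their count reported.
#'
#' @param ids character vector of source ids.
#' @param map data.frame with \code{from}/\code{to} columns
#'   (see \code{\link{readHomologMap}}).
#' @return character vector of translated ids.
#' @export
translateIds <- function(ids, map) {
  hit <- map$from %in% ids
  n_unmapped <- sum(!ids %in% map$from)
  if (n_unmapped > 0L)
    message(n_unmapped, " id(s) had no homolog mapping and were dropped")
  unique(map$to[hit])
}

#' Filter gene sets by measured size
#'
#' Each set's membership is first intersected with \code{measuredGenes}; sets
#' are retained iff the intersection size lies in \code{[minSize, maxSize]},
#' and memberships are replaced by the intersections. Idempotent.
#'
#' @param collection a GeneSetCollection.
#' @param measuredGenes character vector of measured gene ids.
#' @param minSize,maxSize inclusive size bounds (defaults 15 and 500, the
#'   conventional pathway-analysis window).
#' @return filtered GeneSetCollection.
#' @export
filterSetsBySize <- function(collection, measuredGenes, minSize = 15L,
                             maxSize = 500L) {
  if (length(measuredGenes) == 0L)
    stop("'measuredGenes' must be non-empty", call. = FALSE)
  if (minSize < 1L || maxSize < minSize)
    stop("need 1 <= minSize <= maxSize", call. = FALSE)
  sets <- lapply(collection@sets, function(m) m[m %in% measuredGenes])
  keep <- lengths(sets) >= minSize & lengths(sets) <= maxSize
  GeneSetCollection(sets[keep], collection@descriptions[keep])
}

#' Read a differential-expression result table written by writeDeTable
#' @param path TSV path.
#' @return data.frame of per-gene statistics.
#' @export
readDeTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Write a differential-expression result table
#' @param de data.frame as returned by \code{\link{fitGeneModels}}.
#' @param path output TSV path.
#' @export
writeDeTable <- function(de, path) .writeTsv(de, path)

#' Write a GSEA result table
#'
#' Columns mirror published enrichment tables (NAME, SIZE, ES, NES,
#' NOM p-val, FDR q-val) plus the leading edge as comma-joined ids.
#'
#' @param res data.frame as returned by \code{\link{runGsea}}.
#' @param path output TSV path.
#' @export
writeGseaTable <- function(res, path) {
  out <- data.frame(
    NAME = res$name, SIZE = res$set_size_used, ES = res$es, NES = res$nes,
    `NOM p-val` = res$perm_p, `FDR q-val` = res$fdr_q,
    LEADING_EDGE = vapply(res$leading_edge, paste, character(1), collapse = ","),
    check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(out, path)
}
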