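#' Read and write tab-separated fixtures
#'
#' Matrices travel as TSV with a leading ID column and sample columns;
#' gene sets as GMT (name, description, then member genes, tab-separated);
#' motif count matrices as 4-row TSV with rows A, C, G, T; gene lists as
#' one symbol per line; promoters as FASTA with headers
#' \code{gene|window:-450..+50}.
#'
#' @param m numeric matrix with row and column names
#' @param path file path
#' @param idColumn header of the ID column (default \code{"id"})
#' @name fixture-io
NULL

#' @rdname fixture-io
#' @export
writeMatrixTSV <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname fixture-io
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname fixture-io
#' @param sets named list of character vectors (gene sets)
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' @rdname fixture-io
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname fixture-io
#' @param counts 4 x width numeric matrix, rows A, C, G, T
#' @export
writeMotifCounts <- function(counts, path) {
  utils::write.table(data.frame(base = rownames(counts), counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname fixture-io
#' @export
readMotifCounts <- function(path) {
  df <- utils::read.delim(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  m
}

#' @rdname fixture-io
#' @param genes character vector of gene symbols
#' @export
writeGeneList <- function(genes, path) writeLines(genes, path)

#' @rdname fixture-io
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname fixture-io
#' @param promoters named character vector of promoter sequences
#' @param window window label written into headers (default
#'   \code{"-450..+50"})
#' @importFrom Biostrings DNAStringSet writeXStringSet readDNAStringSet
#' @export
writePromoters <- function(promoters, path, window = "-450..+50") {
  x <- Biostrings::DNAStringSet(promoters)
  names(x) <- paste0(names(promoters), "|window:", window)
  Biostrings::writeXStringSet(x, path)
}

#' @rdname fixture-io
#' @export
readPromoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\|window:.*$", "", names(x))
  out
}

#' @rdname fixture-io
#' @param annotation probe annotation data.frame
#' @export
writeAnnotationTSV <- function(annotation, path) {
  utils::write.table(annotation[, c("chrom", "pos", "probe_id", "gene_id",
                                    "tss_distance", "island", "snp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname fixture-io
#' @export
readAnnotationTSV <- function(path) utils::read.delim(path)
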