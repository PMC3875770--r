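#' Treated-versus-mock expression log ratios
#'
#' Computes the expression M value log2(treated / mock) cellwise from two
#' linear-scale matrices with matched features and samples. Cells where
#' either side is non-positive or masked are masked.
#'
#' @param treated,mock linear-scale [ExprMatrix] objects with identical
#'   feature and sample indexing
#' @return an [ExprMatrix] on the log_ratio scale at the same feature level
#' @export
treatmentLogRatio <- function(treated, mock) {
  stopifnot(is(treated, "ExprMatrix"), is(mock, "ExprMatrix"))
  if (scaleTag(treated) != "linear" || scaleTag(mock) != "linear")
    stop("treatmentLogRatio requires linear-scale matrices")
  a <- as.matrix(treated)
  b <- as.matrix(mock)
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)))
    stop("feature/sample indexing differs between treated and mock")
  bad <- (!is.na(a) & a <= 0) | (!is.na(b) & b <= 0)
  r <- log2(a / b)
  r[bad] <- NA_real_
  ExprMatrix(r, featureLevel(treated), "log_ratio")
}

#' Collapse probe-level expression to gene level by the median
#'
#' For each gene and sample, takes the median over that gene's unmasked
#' probe values (the midpoint of the two central values for an even count).
#' A gene is masked in a sample where all its probes are masked. Probes
#' without a gene mapping are dropped, with the count reported via a
#' message.
#'
#' @param probeMatrix a probe-level [ExprMatrix]
#' @param mapping data.frame with columns \code{probe_id}, \code{gene_id};
#'   each probe maps to at most one gene
#' @return a gene-level [ExprMatrix] on the same scale
#' @export
aggregateProbesToGenes <- function(probeMatrix, mapping) {
  stopifnot(is(probeMatrix, "ExprMatrix"))
  v <- as.matrix(probeMatrix)
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(mapping)))
  if (anyDuplicated(mapping$probe_id))
    stop("each probe must map to at most one gene")
  idx <- match(rownames(v), mapping$probe_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0)
    message(unmapped, " unmapped probe(s) dropped")
  keep <- !is.na(idx)
  v <- v[keep, , drop = FALSE]
  gene <- mapping$gene_id[idx[keep]]
  genes <- unique(gene)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  rows <- split(seq_len(nrow(v)), gene)
  for (g in names(rows)) {
    sub <- v[rows[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  ExprMatrix(out, "gene", scaleTag(probeMatrix))
}

#' Genes up-regulated by at least a given fold change
#'
#' Selects genes whose log2 treated/mock ratio in the named sample reaches
#' log2(thresholdFold) or more (boundary inclusive: "4-fold or more" keeps
#' a gene at exactly 2 on the log2 scale), sorted by decreasing ratio.
#'
#' @param geneMatrix a gene-level [ExprMatrix] on the log_ratio scale
#' @param sample column name of the sample/timepoint to filter on
#' @param thresholdFold linear fold-change cutoff (default 4)
#' @return a [GeneSignature] ordered by decreasing log ratio, with the
#'   ratio recorded in provenance
#' @export
foldChangeSignature <- function(geneMatrix, sample, thresholdFold = 4) {
  stopifnot(is(geneMatrix, "ExprMatrix"))
  if (scaleTag(geneMatrix) != "log_ratio")
    stop("foldChangeSignature requires a log_ratio matrix")
  v <- as.matrix(geneMatrix)
  if (!sample %in% colnames(v))
    stop("unknown sample: ", sample)
  x <- v[, sample]
  cutoff <- log2(thresholdFold)
  keep <- !is.na(x) & x >= cutoff
  x <- sort(x[keep], decreasing = TRUE)
  GeneSignature(names(x),
                data.frame(gene_id = names(x), log2_ratio = unname(x),
                           sample = rep(sample, length(x))))
}

#' Preprocess cohort RPKM expression
#'
#' Applies the cohort expression conventions: RPKM values of 0 (no reads
#' observed) are set to \code{NA}, remaining values are log2 transformed,
#' and genes on the X and Y chromosomes are removed. Genes lacking a
#' chromosome annotation are dropped with a message.
#'
#' @param rpkm a linear-scale gene-level [ExprMatrix] of RPKM values
#' @param annotation data.frame with columns \code{gene_id}, \code{chrom}
#'   (one row per gene suffices; extra rows are tolerated)
#' @return a gene-level [ExprMatrix] on the log_rpkm scale
#' @export
preprocessCohortRpkm <- function(rpkm, annotation) {
  stopifnot(is(rpkm, "ExprMatrix"))
  if (scaleTag(rpkm) != "linear")
    stop("preprocessCohortRpkm requires a linear-scale matrix")
  v <- as.matrix(rpkm)
  stopifnot(all(c("gene_id", "chrom") %in% colnames(annotation)))
  chrom <- annotation$chrom[match(rownames(v), annotation$gene_id)]
  noAnn <- is.na(chrom)
  if (any(noAnn))
    message(sum(noAnn), " gene(s) without chromosome annotation dropped")
  sex <- !noAnn & sub("^chr", "", chrom) %in% c("X", "Y")
  v <- v[!noAnn & !sex, , drop = FALSE]
  v[!is.na(v) & v == 0] <- NA_real_
  ExprMatrix(log2(v), "gene", "log_rpkm")
}
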