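.asValues <- function(x) {
  if (is(x, "MethMatrix") || is(x, "ExprMatrix")) as.matrix(x) else as.matrix(x)
}

#' Center and scale matrix rows
#'
#' Standardizes each row to mean 0 and SD 1 (n - 1 denominator) over its
#' unmasked entries — the row-direction scaling used for heat-map display
#' and (by default) for clustering. Rows with fewer than 2 unmasked values
#' or zero variance are dropped with a message.
#'
#' @param m numeric matrix (or [ExprMatrix]/[MethMatrix])
#' @return standardized numeric matrix (possibly fewer rows)
#' @export
rowStandardize <- function(m) {
  v <- .asValues(m)
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  n <- rowSums(!is.na(v))
  bad <- n < 2 | is.na(sdv) | sdv == 0
  if (any(bad))
    message(sum(bad), " constant or near-empty row(s) dropped")
  (v[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
}

#' Hierarchical ordering of rows or columns
#'
#' Euclidean distance and complete-linkage hierarchical clustering (the
#' default distance/clustering pairing of standard heat-map functions),
#' with dendrogram leaves reordered by subtree mean value (ties broken by
#' input order). Missing values are handled pairwise-complete with
#' rescaling by the fraction of complete coordinates, as \code{stats::dist}
#' does.
#'
#' @param m numeric matrix
#' @param axis \code{"row"} or \code{"col"}
#' @return list with \code{order} (permutation of the axis indices),
#'   \code{labels} (axis names in dendrogram order), \code{linkage}
#'   (the \code{hclust} object)
#' @export
hierarchicalOrder <- function(m, axis = c("row", "col")) {
  axis <- match.arg(axis)
  v <- .asValues(m)
  if (axis == "col") v <- t(v)
  if (nrow(v) < 2L) stop("need at least 2 items to cluster")
  d <- stats::dist(v)
  if (any(is.na(d))) {
    dm <- as.matrix(d)
    bad <- which(is.na(dm), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("no overlapping values between items: ",
         paste(apply(bad, 1, function(i)
           paste(rownames(dm)[i], collapse = " / ")), collapse = "; "))
  }
  hc <- stats::hclust(d, method = "complete")
  dend <- stats::reorder(stats::as.dendrogram(hc),
                         wts = rowMeans(v, na.rm = TRUE),
                         agglo.FUN = mean)
  ord <- stats::order.dendrogram(dend)
  list(order = ord, labels = rownames(v)[ord], linkage = hc)
}

#' A clustered heat-map view of a matrix
#'
#' Row-standardizes (optionally) and hierarchically orders both axes of a
#' matrix, producing the permutations that linked heat maps share.
#'
#' @param m numeric matrix (genes x samples)
#' @param clusterOn \code{"scaled"} (cluster the row-standardized matrix,
#'   the default) or \code{"raw"}
#' @return list of class \code{ClusteredView}: \code{matrix} (the
#'   standardized matrix), \code{rowOrder}, \code{colOrder},
#'   \code{rowLinkage}, \code{colLinkage}
#' @export
clusteredView <- function(m, clusterOn = c("scaled", "raw")) {
  clusterOn <- match.arg(clusterOn)
  v <- .asValues(m)
  z <- rowStandardize(v)
  basis <- if (clusterOn == "scaled") z else v[rownames(z), , drop = FALSE]
  ro <- hierarchicalOrder(basis, "row")
  co <- hierarchicalOrder(basis, "col")
  structure(list(matrix = z, rowOrder = ro$order, colOrder = co$order,
                 rowLinkage = ro$linkage, colLinkage = co$linkage),
            class = "ClusteredView")
}

#' Propagate a view's sample order to linked matrices
#'
#' Reorders the columns of every supplied matrix to the sample order of a
#' clustered view, so stacked heat maps stay aligned. Methylation matrices
#' accompanied by probe annotation are additionally row-ordered by
#' ascending signed distance to the TSS.
#'
#' @param view a \code{ClusteredView} from [clusteredView()]
#' @param matrices named list of matrices (or Meth/ExprMatrix) sharing the
#'   view's sample IDs
#' @param annotation optional probe annotation with \code{probe_id},
#'   \code{tss_distance}; applied to matrices whose rownames are probe ids
#' @return named list of reordered plain matrices
#' @export
propagateOrder <- function(view, matrices, annotation = NULL) {
  stopifnot(inherits(view, "ClusteredView"))
  samples <- colnames(view$matrix)[view$colOrder]
  lapply(matrices, function(m) {
    v <- .asValues(m)
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("matrix lacks sample(s): ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
    if (!is.null(annotation) &&
        all(rownames(v) %in% annotation$probe_id)) {
      d <- annotation$tss_distance[match(rownames(v), annotation$probe_id)]
      v <- v[order(d), , drop = FALSE]
    }
    v
  })
}

#' Equal-frequency quantile track
#'
#' Assigns each sample a bin label 1..k by the rank of the gene's value
#' (1 = lowest fifth for k = 5), for display as an expression spectrum
#' under a heat map. Average ranks make tied values share a label; a
#' constant vector collapses to a single label with a warning. Masked
#' values keep NA labels.
#'
#' @param values numeric vector (one gene across samples)
#' @param k number of intervals (default 5)
#' @return integer vector of labels in 1..k, NA where masked
#' @export
quantileTrack <- function(values, k = 5) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < k) {
    warning("fewer than k unmasked values; no track")
    return(rep(NA_integer_, length(values)))
  }
  lab <- rep(NA_integer_, length(values))
  r <- rank(values[ok], ties.method = "average")
  lab[ok] <- as.integer(ceiling(r * k / n))
  if (length(unique(lab[ok])) == 1L && n > 1L)
    warning("constant values; ties collapse to a single interval")
  lab
}

#' PCA batch assessment of methylation M values
#'
#' Principal component analysis of samples over M values after removing
#' X/Y-chromosome probes, SNP-associated probes, and probes with any
#' masked value. Returns the first two principal-component coordinates
#' per sample and their explained-variance fractions, for batch-effect
#' inspection.
#'
#' @param mvalues an mvalue-scale [MethMatrix]
#' @param annotation probe annotation with \code{probe_id}, \code{chrom},
#'   \code{snp}
#' @return list with \code{coordinates} (data.frame sample/PC1/PC2) and
#'   \code{varianceExplained} (length-2 numeric)
#' @export
pcaBatchCheck <- function(mvalues, annotation) {
  stopifnot(is(mvalues, "MethMatrix"))
  v <- as.matrix(mvalues)
  if (ncol(v) < 3L) stop("need at least 3 samples")
  ann <- annotation[match(rownames(v), annotation$probe_id), ]
  drop <- sub("^chr", "", ann$chrom) %in% c("X", "Y") |
    as.logical(ann$snp) | is.na(ann$chrom)
  v <- v[!drop, , drop = FALSE]
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("fewer than 3 complete autosomal non-SNP probes")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = data.frame(sample = colnames(v),
                                PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                                row.names = NULL),
       varianceExplained = ve[1:2])
}

# complete-linkage sample partition on a gene subset (rows standardized)
.samplePartition <- function(v, genes, nClusters) {
  z <- suppressMessages(rowStandardize(v[genes, , drop = FALSE]))
  hc <- stats::hclust(stats::dist(t(z)), method = "complete")
  stats::cutree(hc, k = nClusters)
}

#' Random-gene-set control for signature-based stratification
#'
#' Clusters cohort samples on the signature genes (complete linkage on
#' row-standardized values, cut at \code{nClusters}), then repeats the
#' clustering on random gene sets of size k and measures agreement with
#' the signature partition by the adjusted Rand index. A signature whose
#' stratification reflects real structure rather than chance yields random
#' ARIs near 0.
#'
#' @param expr gene-level [ExprMatrix] (log scale) or matrix
#' @param signatureGenes character vector (or [GeneSignature]) defining
#'   the stratifying signature
#' @param k random-set size (default 25)
#' @param nDraws number of random sets (default 100)
#' @param seed RNG seed (local to this call)
#' @param nClusters partition size (default 2)
#' @return list with \code{signaturePartition} (named integer vector),
#'   \code{ari} (per-draw), \code{ariMean}
#' @importFrom mclust adjustedRandIndex
#' @export
randomSignatureControl <- function(expr, signatureGenes, k = 25,
                                   nDraws = 100, seed = 1L, nClusters = 2) {
  v <- .asValues(expr)
  if (is(signatureGenes, "GeneSignature"))
    signatureGenes <- geneIds(signatureGenes)
  signatureGenes <- intersect(signatureGenes, rownames(v))
  if (length(signatureGenes) < 2L) stop("signature too small to cluster")
  if (nrow(v) < k) stop("fewer than k genes available")
  base <- .samplePartition(v, signatureGenes, nClusters)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(seed)
  pool <- rownames(v)
  ari <- vapply(seq_len(nDraws), function(i) {
    g <- sample(pool, k)
    mclust::adjustedRandIndex(base, .samplePartition(v, g, nClusters))
  }, numeric(1))
  list(signaturePartition = base, ari = ari, ariMean = mean(ari))
}
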