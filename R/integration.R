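#' Spearman rank correlation with average-rank ties
#'
#' Rank correlation over jointly unmasked pairs. With fewer than 3 complete
#' pairs the coefficient is undefined and \code{NA} is returned with a
#' warning.
#'
#' @param x,y numeric vectors of equal length (NA allowed)
#' @return correlation in [-1, 1], or NA
#' @export
spearmanRho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 jointly unmasked pairs; rho undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "spearman")
}

# rho and its t-approximation p-value for one probe/gene pair;
# p is one value per probe, two-sided is not wanted here: the screen is
# directional only through the rho < 0 requirement, so the p tests
# rho != 0 (as the original coefficient test does).
.spearmanTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(c(rho = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok], method = "spearman")
  if (is.na(r) || abs(r) >= 1)
    return(c(rho = r, p = if (is.na(r)) NA_real_ else 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed)
#' @return q-values, same length and order
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Informative probes: cohort methylation-expression correlation
#'
#' For every probe with a gene in the cohort expression matrix, computes
#' the Spearman correlation between the probe's beta values and the gene's
#' expression across samples with data on both platforms. A probe is
#' informative when its coefficient is negative and its BH-adjusted p-value
#' (FDR) is below \code{informativeFdrMax} (default 0.01). Informative
#' probes carry their signed distance to the TSS.
#'
#' @param cohortBeta beta-scale [MethMatrix], probe x sample
#' @param cohortExpr gene-level [ExprMatrix] (log_rpkm), gene x sample;
#'   columns are matched to \code{cohortBeta} by sample name
#' @param annotation probe annotation data.frame with columns
#'   \code{probe_id}, \code{gene_id}, \code{tss_distance}
#' @param thresholds a [FilterThresholds]
#' @return data.frame with one row per tested probe: \code{probe_id},
#'   \code{gene_id}, \code{tss_distance}, \code{rho}, \code{p}, \code{q},
#'   \code{n}, \code{informative}
#' @export
informativeProbes <- function(cohortBeta, cohortExpr, annotation,
                              thresholds = filterThresholds()) {
  stopifnot(is(cohortBeta, "MethMatrix"), is(cohortExpr, "ExprMatrix"),
            is(thresholds, "FilterThresholds"))
  if (scaleTag(cohortBeta) != "beta")
    stop("cohortBeta must be on the beta scale")
  bv <- as.matrix(cohortBeta)
  ev <- as.matrix(cohortExpr)
  common <- intersect(colnames(bv), colnames(ev))
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between platforms")
  bv <- bv[, common, drop = FALSE]
  ev <- ev[, common, drop = FALSE]
  ann <- annotation[annotation$probe_id %in% rownames(bv) &
                    annotation$gene_id %in% rownames(ev), , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(probe_id = character(), gene_id = character(),
                      tss_distance = numeric(), rho = numeric(),
                      p = numeric(), q = numeric(), n = integer(),
                      informative = logical()))
  res <- t(vapply(seq_len(nrow(ann)), function(i) {
    suppressWarnings(.spearmanTest(bv[ann$probe_id[i], ],
                                   ev[ann$gene_id[i], ]))
  }, c(rho = 0, p = 0, n = 0)))
  q <- bhAdjust(res[, "p"])
  data.frame(probe_id = ann$probe_id, gene_id = ann$gene_id,
             tss_distance = ann$tss_distance,
             rho = res[, "rho"], p = res[, "p"], q = q,
             n = as.integer(res[, "n"]),
             informative = !is.na(res[, "rho"]) & res[, "rho"] < 0 &
               !is.na(q) & q < thresholds@informativeFdrMax,
             row.names = NULL)
}

#' Re-expression and promoter-demethylation filter
#'
#' The cell-line arm of the integrative cascade. A gene is kept when both
#' hold:
#' \itemize{
#'   \item re-expression: its median expression log-ratio (treated/mock)
#'     is strictly greater than \code{exprMMin} at day 3 OR day 10;
#'   \item demethylation: at least one of its probes is on a CpG island
#'     (when \code{requireIsland}), lies within \code{tssWindow} bp up- or
#'     downstream of the TSS, has mock beta strictly above
#'     \code{betaMockMin}, and loses at least \code{deltaBetaMin} beta
#'     under treatment (mock - treated, evaluated per timepoint and
#'     OR-combined, with the passing timepoint recorded).
#' }
#' Masked values never satisfy a cutoff.
#'
#' @param exprRatio gene-level [ExprMatrix] on the log_ratio scale with
#'   one column per timepoint
#' @param betaMock,betaTreated beta-scale [MethMatrix] objects, probe x
#'   timepoint, with the same column names as \code{exprRatio}
#' @param annotation probe annotation data.frame with columns
#'   \code{probe_id}, \code{gene_id}, \code{tss_distance}, \code{island}
#' @param thresholds a [FilterThresholds]
#' @param timepoints columns to evaluate (default the columns of
#'   \code{exprRatio})
#' @return a [GeneSignature] ordered by decreasing maximal expression
#'   ratio, with per-probe, per-timepoint provenance
#' @export
reexpressionFilter <- function(exprRatio, betaMock, betaTreated, annotation,
                               thresholds = filterThresholds(),
                               timepoints = colnames(as.matrix(exprRatio))) {
  stopifnot(is(exprRatio, "ExprMatrix"), is(betaMock, "MethMatrix"),
            is(betaTreated, "MethMatrix"), is(thresholds, "FilterThresholds"))
  if (!nrow(annotation)) stop("empty probe annotation")
  if (scaleTag(exprRatio) != "log_ratio")
    stop("exprRatio must be on the log_ratio scale")
  ev <- as.matrix(exprRatio)
  bm <- as.matrix(betaMock)
  bt <- as.matrix(betaTreated)
  stopifnot(all(timepoints %in% colnames(ev)),
            all(timepoints %in% colnames(bm)),
            all(timepoints %in% colnames(bt)),
            identical(rownames(bm), rownames(bt)))

  th <- thresholds
  ann <- annotation
  promoter <- abs(ann$tss_distance) <= th@tssWindow &
    (!th@requireIsland | as.logical(ann$island))
  ann <- ann[promoter & ann$probe_id %in% rownames(bm), , drop = FALSE]

  prov <- list()
  for (tp in timepoints) {
    mock <- bm[ann$probe_id, tp]
    delta <- mock - bt[ann$probe_id, tp]
    pass <- !is.na(mock) & mock > th@betaMockMin &
      !is.na(delta) & delta >= th@deltaBetaMin
    if (any(pass))
      prov[[tp]] <- data.frame(gene_id = ann$gene_id[pass],
                               probe_id = ann$probe_id[pass],
                               timepoint = tp,
                               beta_mock = unname(mock[pass]),
                               delta_beta = unname(delta[pass]))
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene_id = character(), probe_id = character(),
               timepoint = character(), beta_mock = numeric(),
               delta_beta = numeric())

  exprPass <- rep(FALSE, nrow(ev))
  exprMax <- rep(-Inf, nrow(ev))
  for (tp in timepoints) {
    x <- ev[, tp]
    exprPass <- exprPass | (!is.na(x) & x > th@exprMMin)
    exprMax <- pmax(exprMax, ifelse(is.na(x), -Inf, x))
  }
  reexpressed <- rownames(ev)[exprPass]

  genes <- intersect(reexpressed, unique(prov$gene_id))
  genes <- genes[order(-exprMax[match(genes, rownames(ev))])]
  prov <- prov[prov$gene_id %in% genes, , drop = FALSE]
  prov$expr_m_max <- exprMax[match(prov$gene_id, rownames(ev))]
  rownames(prov) <- NULL
  GeneSignature(genes, prov)
}

#' Validate candidate genes against the cohort
#'
#' A candidate gene is retained when at least one of its passing promoter
#' probes is informative in the cohort (negative rho at the informative
#' FDR) with a methylation-expression correlation strictly below
#' \code{cohortRhoMax} and an FDR below \code{cohortFdrMax}. Probes absent
#' from the cohort are treated as non-informative.
#'
#' @param candidates a [GeneSignature] from [reexpressionFilter()]
#' @param informative probe table from [informativeProbes()]
#' @param thresholds a [FilterThresholds]
#' @return a [GeneSignature] in candidate order with rho/q added to the
#'   provenance of retained probes
#' @export
cohortValidation <- function(candidates, informative,
                             thresholds = filterThresholds()) {
  stopifnot(is(candidates, "GeneSignature"), is(thresholds, "FilterThresholds"))
  prov <- provenance(candidates)
  if (!nrow(prov)) return(GeneSignature(character(0)))
  keep <- informative[informative$informative &
                      !is.na(informative$rho) &
                      informative$rho < thresholds@cohortRhoMax &
                      !is.na(informative$q) &
                      informative$q < thresholds@cohortFdrMax, , drop = FALSE]
  idx <- match(prov$probe_id, keep$probe_id)
  prov$rho <- keep$rho[idx]
  prov$q <- keep$q[idx]
  validated <- prov[!is.na(idx), , drop = FALSE]
  genes <- geneIds(candidates)[geneIds(candidates) %in% validated$gene_id]
  rownames(validated) <- NULL
  GeneSignature(genes, validated)
}

.normalizeSymbols <- function(x) unique(toupper(trimws(unlist(x))))

#' Transcription-factor content of a signature
#'
#' Matches a gene signature against one or more transcription-factor lists
#' (combined, deduplicated, case-insensitively). Returns the matching
#' sub-signature and the fraction of signature genes that are
#' transcription factors.
#'
#' @param signature a [GeneSignature]
#' @param tfLists character vector or list of character vectors of TF gene
#'   symbols
#' @return list with \code{signature} (the TF subset, original order) and
#'   \code{fraction} (NA for an empty input signature)
#' @export
annotateTranscriptionFactors <- function(signature, tfLists) {
  stopifnot(is(signature, "GeneSignature"))
  tf <- .normalizeSymbols(tfLists)
  ids <- geneIds(signature)
  if (!length(ids)) {
    warning("empty signature; TF fraction undefined")
    return(list(signature = GeneSignature(character(0)), fraction = NA_real_))
  }
  hit <- ids[toupper(ids) %in% tf]
  prov <- provenance(signature)
  if (nrow(prov)) prov <- prov[prov$gene_id %in% hit, , drop = FALSE]
  list(signature = GeneSignature(hit, prov),
       fraction = length(hit) / length(ids))
}

#' Fraction of a signature found in a reference gene list
#'
#' @param signature a [GeneSignature]
#' @param referenceList character vector of gene symbols (case-insensitive)
#' @return |signature intersect reference| / |signature|; NA for an empty
#'   signature
#' @export
overlapFraction <- function(signature, referenceList) {
  stopifnot(is(signature, "GeneSignature"))
  ids <- geneIds(signature)
  if (!length(ids)) {
    warning("empty signature; overlap fraction undefined")
    return(NA_real_)
  }
  sum(toupper(ids) %in% .normalizeSymbols(referenceList)) / length(ids)
}
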