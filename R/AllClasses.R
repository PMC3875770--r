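#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata SimpleList DataFrame
NULL

#' Container for probe-level bead intensities
#'
#' An \code{IntensitySet} extends \code{SummarizedExperiment} with two
#' assays, \code{Meth} and \code{Unmeth} (probe x sample mean bead
#' intensities of the methylated and unmethylated bead types), plus a
#' negative-control intensity matrix (control probe x sample) stored in
#' \code{metadata(x)$negctrl}. Negative controls carry the background signal
#' distribution used for detection p-values.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure
#' @export
setClass("IntensitySet", contains = "SummarizedExperiment")

setValidity("IntensitySet", function(object) {
  msg <- NULL
  an <- names(assays(object))
  if (!all(c("Meth", "Unmeth") %in% an))
    msg <- c(msg, "assays must include 'Meth' and 'Unmeth'")
  else {
    if (any(assay(object, "Meth") < 0, na.rm = TRUE) ||
        any(assay(object, "Unmeth") < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
  }
  nc <- metadata(object)$negctrl
  if (is.null(nc) || !is.matrix(nc))
    msg <- c(msg, "metadata(object)$negctrl must be a control x sample matrix")
  else {
    if (ncol(nc) != ncol(object))
      msg <- c(msg, "negative-control matrix must have one column per sample")
    if (any(nc < 0, na.rm = TRUE))
      msg <- c(msg, "negative-control intensities must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an IntensitySet
#'
#' @param methylated,unmethylated probe x sample numeric matrices with
#'   identical dimnames; mean intensities of the methylated (M) and
#'   unmethylated (U) bead types.
#' @param negctrl control x sample numeric matrix of negative-control
#'   intensities; columns must match the sample columns.
#' @param rowData optional per-probe annotation (\code{DataFrame} or
#'   data.frame).
#' @return an \code{IntensitySet}
#' @examples
#' m <- matrix(c(300, 100), 1, 2, dimnames = list("cg1", c("s1", "s2")))
#' u <- matrix(c(100, 300), 1, 2, dimnames = list("cg1", c("s1", "s2")))
#' nc <- matrix(50, 4, 2, dimnames = list(NULL, c("s1", "s2")))
#' ints <- IntensitySet(m, u, nc)
#' @export
IntensitySet <- function(methylated, unmethylated, negctrl, rowData = NULL) {
  methylated <- as.matrix(methylated)
  unmethylated <- as.matrix(unmethylated)
  negctrl <- as.matrix(negctrl)
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("methylated and unmethylated matrices must have identical dimensions")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  args <- list(assays = SimpleList(Meth = methylated, Unmeth = unmethylated),
               metadata = list(negctrl = negctrl))
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment, args)
  new("IntensitySet", se)
}

#' Matrix of methylation values with a scale tag
#'
#' Holds probe x sample methylation values on either the beta scale
#' (proportions in [0, 1]) or the M-value scale (log2 of the
#' methylated/unmethylated intensity ratio, unbounded). Masked cells are
#' \code{NA}; all package arithmetic propagates \code{NA}, never substitutes
#' zero.
#'
#' @slot values numeric matrix, probe x sample
#' @slot scaleTag \code{"beta"} or \code{"mvalue"}
#' @export
setClass("MethMatrix",
         representation(values = "matrix", scaleTag = "character"))

setValidity("MethMatrix", function(object) {
  msg <- NULL
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("beta", "mvalue"))
    msg <- c(msg, "scaleTag must be 'beta' or 'mvalue'")
  else if (object@scaleTag == "beta") {
    v <- object@values
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "beta-scale values must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname MethMatrix-class
#' @param values numeric matrix (probe x sample)
#' @param scaleTag \code{"beta"} or \code{"mvalue"}
#' @export
MethMatrix <- function(values, scaleTag = c("beta", "mvalue")) {
  scaleTag <- match.arg(scaleTag)
  new("MethMatrix", values = as.matrix(values), scaleTag = scaleTag)
}

#' Matrix of expression values with feature level and scale tags
#'
#' Holds feature x sample expression values at the probe or gene level, on
#' a declared scale: \code{"linear"} (non-negative intensities or RPKM),
#' \code{"log_ratio"} (log2 treated/mock), or \code{"log_rpkm"}. Masked
#' cells are \code{NA}.
#'
#' @slot values numeric matrix, feature x sample
#' @slot featureLevel \code{"probe"} or \code{"gene"}
#' @slot scaleTag \code{"linear"}, \code{"log_ratio"} or \code{"log_rpkm"}
#' @export
setClass("ExprMatrix",
         representation(values = "matrix", featureLevel = "character",
                        scaleTag = "character"))

setValidity("ExprMatrix", function(object) {
  msg <- NULL
  if (!object@featureLevel %in% c("probe", "gene"))
    msg <- c(msg, "featureLevel must be 'probe' or 'gene'")
  if (!object@scaleTag %in% c("linear", "log_ratio", "log_rpkm"))
    msg <- c(msg, "scaleTag must be 'linear', 'log_ratio' or 'log_rpkm'")
  rn <- rownames(object@values)
  if (!is.null(rn) && anyDuplicated(rn))
    msg <- c(msg, "feature IDs must be unique")
  if (identical(object@scaleTag, "linear") &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "linear-scale values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ExprMatrix-class
#' @param values numeric matrix (feature x sample)
#' @param featureLevel \code{"probe"} or \code{"gene"}
#' @param scaleTag \code{"linear"}, \code{"log_ratio"} or \code{"log_rpkm"}
#' @export
ExprMatrix <- function(values, featureLevel = c("gene", "probe"),
                       scaleTag = c("linear", "log_ratio", "log_rpkm")) {
  new("ExprMatrix", values = as.matrix(values),
      featureLevel = match.arg(featureLevel), scaleTag = match.arg(scaleTag))
}

#' An ordered gene signature with per-gene filter provenance
#'
#' Ordered list of gene identifiers together with a provenance table
#' recording, per gene, which probes and timepoints passed each filter and
#' (after cohort validation) the supporting Spearman correlation and
#' q-value.
#'
#' @slot geneIds character vector, unique, in signature order
#' @slot provenance data.frame with one row per (gene, passing probe) pair
#' @export
setClass("GeneSignature",
         representation(geneIds = "character", provenance = "data.frame"))

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "geneIds must be unique")
  if (nrow(object@provenance) > 0L) {
    if (!"gene_id" %in% colnames(object@provenance))
      msg <- c(msg, "provenance must have a gene_id column")
    else if (!all(object@geneIds %in% object@provenance$gene_id))
      msg <- c(msg, "every gene must have at least one provenance record")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSignature-class
#' @param geneIds character vector of gene identifiers (ordered)
#' @param provenance data.frame of per-gene filter records; must contain a
#'   \code{gene_id} column when non-empty
#' @export
GeneSignature <- function(geneIds, provenance = data.frame()) {
  new("GeneSignature", geneIds = as.character(geneIds),
      provenance = provenance)
}

#' Threshold set for the re-expression/demethylation filter cascade
#'
#' All cutoffs of the integrative filter in one object. Defaults follow the
#' published cascade: a gene is re-expressed when its median expression
#' log-ratio exceeds \code{exprMMin} (strict) at either timepoint; a probe
#' is demethylated when mock beta exceeds \code{betaMockMin} (strict) and
#' mock - treated beta is at least \code{deltaBetaMin} (inclusive); probes
#' must lie within \code{tssWindow} bp of the TSS and (if
#' \code{requireIsland}) on a CpG island; cohort validation retains genes
#' with a probe showing rho < \code{cohortRhoMax} (strict) at
#' q < \code{cohortFdrMax}; informative probes require rho < 0 at
#' q < \code{informativeFdrMax}.
#'
#' @slot exprMMin numeric, log2 units (default 0.5)
#' @slot betaMockMin numeric, beta units (default 0.5)
#' @slot deltaBetaMin numeric, beta units (default 0.25)
#' @slot tssWindow numeric, base pairs (default 1000)
#' @slot requireIsland logical (default TRUE)
#' @slot cohortRhoMax numeric, correlation (default -0.25)
#' @slot cohortFdrMax numeric, proportion (default 0.05)
#' @slot informativeFdrMax numeric, proportion (default 0.01)
#' @export
setClass("FilterThresholds",
         representation(exprMMin = "numeric", betaMockMin = "numeric",
                        deltaBetaMin = "numeric", tssWindow = "numeric",
                        requireIsland = "logical", cohortRhoMax = "numeric",
                        cohortFdrMax = "numeric",
                        informativeFdrMax = "numeric"))

setValidity("FilterThresholds", function(object) {
  msg <- NULL
  if (object@betaMockMin < 0 || object@betaMockMin > 1)
    msg <- c(msg, "betaMockMin must lie in [0, 1]")
  if (object@deltaBetaMin < 0 || object@deltaBetaMin > 1)
    msg <- c(msg, "deltaBetaMin must lie in [0, 1]")
  if (object@tssWindow < 0)
    msg <- c(msg, "tssWindow must be non-negative")
  if (object@cohortRhoMax < -1 || object@cohortRhoMax > 1)
    msg <- c(msg, "cohortRhoMax must lie in [-1, 1]")
  if (object@cohortFdrMax <= 0 || object@cohortFdrMax > 1)
    msg <- c(msg, "cohortFdrMax must lie in (0, 1]")
  if (object@informativeFdrMax <= 0 || object@informativeFdrMax > 1)
    msg <- c(msg, "informativeFdrMax must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @rdname FilterThresholds-class
#' @param exprMMin,betaMockMin,deltaBetaMin,tssWindow,requireIsland
#'   cell-line filter cutoffs; see slot documentation
#' @param cohortRhoMax,cohortFdrMax,informativeFdrMax cohort-validation
#'   cutoffs; see slot documentation
#' @export
filterThresholds <- function(exprMMin = 0.5, betaMockMin = 0.5,
                             deltaBetaMin = 0.25, tssWindow = 1000,
                             requireIsland = TRUE, cohortRhoMax = -0.25,
                             cohortFdrMax = 0.05, informativeFdrMax = 0.01) {
  new("FilterThresholds", exprMMin = exprMMin, betaMockMin = betaMockMin,
      deltaBetaMin = deltaBetaMin, tssWindow = tssWindow,
      requireIsland = requireIsland, cohortRhoMax = cohortRhoMax,
      cohortFdrMax = cohortFdrMax, informativeFdrMax = informativeFdrMax)
}
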