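#' Accessors for package classes
#'
#' \code{scaleTag} returns the value scale of a \code{MethMatrix} or
#' \code{ExprMatrix}; \code{featureLevel} the probe/gene level of an
#' \code{ExprMatrix}; \code{geneIds} and \code{provenance} the ordered gene
#' list and filter records of a \code{GeneSignature};
#' \code{methylated}, \code{unmethylated} and \code{negativeControls} the
#' intensity channels of an \code{IntensitySet}. \code{as.matrix} on a
#' \code{MethMatrix} or \code{ExprMatrix} returns the value matrix.
#'
#' @param x an object of the documented class
#' @param ... unused
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname accessors
#' @export
setGeneric("featureLevel", function(x) standardGeneric("featureLevel"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("methylated", function(x) standardGeneric("methylated"))

#' @rdname accessors
#' @export
setGeneric("unmethylated", function(x) standardGeneric("unmethylated"))

#' @rdname accessors
#' @export
setGeneric("negativeControls", function(x) standardGeneric("negativeControls"))

#' @rdname accessors
setMethod("scaleTag", "MethMatrix", function(x) x@scaleTag)

#' @rdname accessors
setMethod("scaleTag", "ExprMatrix", function(x) x@scaleTag)

#' @rdname accessors
setMethod("featureLevel", "ExprMatrix", function(x) x@featureLevel)

#' @rdname accessors
setMethod("geneIds", "GeneSignature", function(x) x@geneIds)

#' @rdname accessors
setMethod("provenance", "GeneSignature", function(x) x@provenance)

#' @rdname accessors
setMethod("methylated", "IntensitySet",
          function(x) SummarizedExperiment::assay(x, "Meth"))

#' @rdname accessors
setMethod("unmethylated", "IntensitySet",
          function(x) SummarizedExperiment::assay(x, "Unmeth"))

#' @rdname accessors
setMethod("negativeControls", "IntensitySet",
          function(x) S4Vectors::metadata(x)$negctrl)

#' @rdname accessors
#' @export
setMethod("as.matrix", "MethMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "ExprMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("length", "GeneSignature", function(x) length(x@geneIds))

setMethod("show", "MethMatrix", function(object) {
  v <- object@values
  cat(sprintf("MethMatrix (%s): %d probes x %d samples, %.1f%% masked\n",
              object@scaleTag, nrow(v), ncol(v),
              100 * mean(is.na(v))))
})

setMethod("show", "ExprMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExprMatrix (%s, %s-level): %d features x %d samples\n",
              object@scaleTag, object@featureLevel, nrow(v), ncol(v)))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature: %d genes\n", length(object@geneIds)))
  if (length(object@geneIds))
    cat("  ", paste(utils::head(object@geneIds, 6), collapse = ", "),
        if (length(object@geneIds) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds:\n",
      sprintf("  expression median M > %g (either timepoint)\n", object@exprMMin),
      sprintf("  mock beta > %g, mock - treated delta beta >= %g\n",
              object@betaMockMin, object@deltaBetaMin),
      sprintf("  promoter window +/-%g bp of TSS, CpG island required: %s\n",
              object@tssWindow, object@requireIsland),
      sprintf("  cohort: rho < %g at FDR < %g; informative FDR < %g\n",
              object@cohortRhoMax, object@cohortFdrMax,
              object@informativeFdrMax), sep = "")
})
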