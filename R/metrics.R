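#' Flow-cytometry log2 change in surface expression
#'
#' Change between treated and mock cells from mean fluorescence
#' intensities (MFI), with isotype-control background subtraction on each
#' side: log2((MFI_antibody,treated - MFI_isotype,treated) /
#' (MFI_antibody,mock - MFI_isotype,mock)). A non-positive
#' background-subtracted difference (possible in noisy cytometry) yields a
#' flagged NA rather than an error, so batch runs survive bad wells.
#'
#' All arguments are vectorized.
#'
#' @param antibodyTreated,isotypeTreated,antibodyMock,isotypeMock MFI
#'   values (arbitrary units, >= 0)
#' @return numeric vector of log2 ratios, with attribute
#'   \code{"flagged"} marking entries where a difference was non-positive
#' @examples
#' facsLog2Change(120, 20, 70, 20)   # log2(100/50) = 1
#' @export
facsLog2Change <- function(antibodyTreated, isotypeTreated,
                           antibodyMock, isotypeMock) {
  dT <- antibodyTreated - isotypeTreated
  dM <- antibodyMock - isotypeMock
  bad <- !is.na(dT) & !is.na(dM) & (dT <= 0 | dM <= 0)
  out <- rep(NA_real_, length(bad))
  out[!bad] <- log2(dT[!bad] / dM[!bad])
  attr(out, "flagged") <- bad
  out
}

#' RECIST percent change in target-lesion burden
#'
#' Percentage change of the summed target-lesion diameters at each
#' evaluation relative to baseline:
#' ((sum_timepoint / sum_baseline) - 1) * 100. Negative values indicate
#' shrinkage.
#'
#' @param baselineSum summed target-lesion diameters at baseline (mm, > 0)
#' @param timepointSums numeric vector of summed diameters per evaluation
#' @return numeric vector of percent changes, one per timepoint
#' @examples
#' recistPercentChange(100, c(70, 100, 120))   # -30, 0, +20
#' @export
recistPercentChange <- function(baselineSum, timepointSums) {
  if (!is.numeric(baselineSum) || length(baselineSum) != 1L ||
      is.na(baselineSum) || baselineSum <= 0)
    stop("baselineSum must be a single positive number")
  (timepointSums / baselineSum - 1) * 100
}
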