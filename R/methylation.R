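#' Beta values from bead intensities
#'
#' Computes the methylation proportion beta = M / (U + M) per probe and
#' sample, where M and U are the mean intensities of the methylated and
#' unmethylated bead types. No offset constant is added to the denominator.
#' Cells with U + M = 0 are masked as \code{NA}.
#'
#' @param intensities an [IntensitySet]
#' @return a [MethMatrix] on the beta scale
#' @seealso [computeMValue()] for the log-ratio transform;
#'   [detectionPValues()] and [maskLowConfidence()] for background masking
#' @examples
#' m <- matrix(300, 1, 1, dimnames = list("cg1", "s1"))
#' u <- matrix(100, 1, 1, dimnames = list("cg1", "s1"))
#' ints <- IntensitySet(m, u, matrix(50, 4, 1))
#' as.matrix(computeBeta(ints))   # 0.75
#' @export
computeBeta <- function(intensities) {
  stopifnot(is(intensities, "IntensitySet"))
  m <- methylated(intensities)
  u <- unmethylated(intensities)
  tot <- m + u
  beta <- m / tot
  beta[!is.na(tot) & tot == 0] <- NA_real_
  MethMatrix(beta, "beta")
}

#' M values from bead intensities
#'
#' Computes the M value log2(M / U) per probe and sample. Cells where
#' either channel is zero are masked as \code{NA} (the log-ratio is
#' undefined there).
#'
#' @inheritParams computeBeta
#' @return a [MethMatrix] on the mvalue scale
#' @export
computeMValue <- function(intensities) {
  stopifnot(is(intensities, "IntensitySet"))
  m <- methylated(intensities)
  u <- unmethylated(intensities)
  bad <- (!is.na(m) & m == 0) | (!is.na(u) & u == 0)
  mv <- log2(m / u)
  mv[bad] <- NA_real_
  MethMatrix(mv, "mvalue")
}

#' Detection p-values against negative-control background
#'
#' One-sided p-value that a probe's total signal (M + U) exceeds the
#' background, under a normal model with the per-sample mean and standard
#' deviation of the negative-control intensities. A signal equal to the
#' control mean gives p = 0.5; large signals give vanishing p.
#'
#' Requires at least two negative-control probes per sample. A zero control
#' standard deviation is floored at a small positive value with a warning.
#'
#' @inheritParams computeBeta
#' @return numeric matrix of p-values, probe x sample
#' @export
detectionPValues <- function(intensities) {
  stopifnot(is(intensities, "IntensitySet"))
  nc <- negativeControls(intensities)
  if (nrow(nc) < 2L)
    stop("need at least 2 negative-control probes per sample")
  mu <- colMeans(nc)
  sdv <- apply(nc, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("zero negative-control variance in ", sum(sdv == 0),
            " sample(s); flooring SD")
    sdv <- pmax(sdv, 1e-8)
  }
  signal <- methylated(intensities) + unmethylated(intensities)
  p <- stats::pnorm(sweep(sweep(signal, 2, mu, "-"), 2, sdv, "/"),
                    lower.tail = FALSE)
  dimnames(p) <- dimnames(signal)
  p
}

#' Mask methylation values that fail background detection
#'
#' Cells with detection p-value strictly greater than \code{alpha} are not
#' significantly different from background and are masked as \code{NA};
#' cells at exactly \code{alpha} are retained. All other cells pass through
#' unchanged.
#'
#' @param values a [MethMatrix]
#' @param pvals detection p-value matrix matching \code{values} in shape
#' @param alpha masking threshold (default 0.05)
#' @return a [MethMatrix] on the same scale with failing cells masked
#' @export
maskLowConfidence <- function(values, pvals, alpha = 0.05) {
  stopifnot(is(values, "MethMatrix"))
  v <- as.matrix(values)
  if (!identical(dim(v), dim(pvals)))
    stop("values and pvals must have identical dimensions")
  v[!is.na(pvals) & pvals > alpha] <- NA_real_
  MethMatrix(v, scaleTag(values))
}

#' Delta beta between treated and mock conditions
#'
#' Cellwise difference treated - mock on the beta scale. A cell masked on
#' either side is masked in the result (NA propagates; it never becomes
#' zero). Pass mock as \code{treated} and treated as \code{mock} to obtain
#' the demethylation-oriented mock - treated difference.
#'
#' @param treated,mock beta-scale [MethMatrix] objects with identical
#'   probe/sample indexing
#' @return numeric matrix of differences, probe x sample (in [-1, 1])
#' @export
deltaBeta <- function(treated, mock) {
  stopifnot(is(treated, "MethMatrix"), is(mock, "MethMatrix"))
  if (scaleTag(treated) != "beta" || scaleTag(mock) != "beta")
    stop("deltaBeta requires beta-scale matrices")
  a <- as.matrix(treated)
  b <- as.matrix(mock)
  if (!identical(dim(a), dim(b)))
    stop("matrices must have identical dimensions")
  if (!is.null(rownames(a)) && !identical(rownames(a), rownames(b)))
    stop("probe indexing differs between matrices")
  a - b
}

#' Per-sample summary of demethylation
#'
#' Five-number summary (minimum, quartiles, maximum) plus the count of
#' unmasked probes of the delta-beta distribution in each sample, as used
#' to compare degrees of demethylation across cell lines.
#'
#' @param deltas numeric matrix of delta-beta values, probe x sample
#' @return data.frame with one row per sample: \code{sample}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max}, \code{n}; samples with
#'   no unmasked values get NA summaries with a warning
#' @export
demethylationSummary <- function(deltas) {
  deltas <- as.matrix(deltas)
  sm <- vapply(seq_len(ncol(deltas)), function(j) {
    x <- deltas[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(rep(NA_real_, 5), 0))
    c(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE), length(x))
  }, numeric(6))
  if (any(sm[6, ] == 0))
    warning("sample(s) with no unmasked delta-beta values: ",
            paste(colnames(deltas)[sm[6, ] == 0], collapse = ", "))
  data.frame(sample = colnames(deltas) %||% as.character(seq_len(ncol(deltas))),
             min = sm[1, ], q1 = sm[2, ], median = sm[3, ], q3 = sm[4, ],
             max = sm[5, ], n = as.integer(sm[6, ]),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
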