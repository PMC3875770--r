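#' Position weight matrix with log-odds weights
#'
#' A motif model: a 4 x width matrix of finite per-position log2-odds
#' weights (rows A, C, G, T) against a background base distribution that
#' sums to 1.
#'
#' @slot weights 4 x width numeric matrix, rows named A, C, G, T
#' @slot background named numeric vector of base frequencies
#' @export
setClass("PWM", representation(weights = "matrix", background = "numeric"))

setValidity("PWM", function(object) {
  msg <- NULL
  if (!identical(rownames(object@weights), c("A", "C", "G", "T")))
    msg <- c(msg, "weight rows must be named A, C, G, T")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background frequencies must sum to 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PWM", function(object) {
  cons <- paste(rownames(object@weights)[apply(object@weights, 2,
                                               which.max)], collapse = "")
  cat(sprintf("PWM: width %d, consensus %s\n", ncol(object@weights), cons))
})

#' @rdname PWM-class
#' @param weights 4 x width log2-odds matrix with rows A, C, G, T
#' @param background base frequencies (default uniform)
#' @export
pwm <- function(weights, background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  new("PWM", weights = weights, background = background)
}

#' Build a PWM from a base-count matrix
#'
#' Converts per-position base counts to log2-odds weights against the
#' background, with a pseudocount to keep the weights finite.
#'
#' @param counts 4 x width count matrix, rows named A, C, G, T
#' @param background base frequencies (default uniform)
#' @param pseudocount added to every count (default 0.5)
#' @return a [PWM]
#' @export
pwmFromCounts <- function(counts, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                          pseudocount = 0.5) {
  stopifnot(identical(rownames(counts), c("A", "C", "G", "T")))
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  pwm(log2(sweep(freq, 1, background, "/")), background)
}

.baseIndex <- function(sequence) {
  match(strsplit(toupper(as.character(sequence)), "")[[1]],
        c("A", "C", "G", "T"))
}

.scanStrand <- function(idx, w) {
  width <- ncol(w)
  n <- length(idx) - width + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (j in seq_len(width))
    acc <- acc + w[cbind(idx[seq_len(n) + j - 1L], j)]
  acc
}

#' Best motif hit score in a promoter sequence
#'
#' Maximum log-odds score of the PWM over every position of the sequence
#' on both strands. Windows containing non-ACGT characters score NA and
#' are skipped. A sequence shorter than the motif yields NA with a
#' warning.
#'
#' @param sequence a character string or \code{DNAString} (the promoter
#'   window, e.g. -450..+50 around the TSS)
#' @param motif a [PWM]
#' @return the best-hit score (numeric scalar, NA if no scorable window)
#' @export
pwmBestScore <- function(sequence, motif) {
  stopifnot(is(motif, "PWM"))
  w <- motif@weights
  idx <- .baseIndex(sequence)
  if (length(idx) < ncol(w)) {
    warning("sequence shorter than motif width")
    return(NA_real_)
  }
  fwd <- .scanStrand(idx, w)
  rev <- .scanStrand(rev(5L - idx), w)   # reverse complement
  best <- suppressWarnings(max(c(fwd, rev), na.rm = TRUE))
  if (is.infinite(best)) NA_real_ else best
}

#' Motif over-representation in a foreground promoter set
#'
#' Compares mean best-hit motif scores between a foreground gene list's
#' promoters and a background promoter universe with a one-sided z-test:
#' z = (mean(fg) - mean(bg)) / (sd(bg) / sqrt(n_fg)), p = P(Z > z).
#' Positive z indicates over-representation of the motif in the
#' foreground promoters.
#'
#' @param foreground named character vector (or \code{DNAStringSet}) of
#'   foreground promoter sequences; at least 5
#' @param background promoter sequences of the background universe
#' @param motif a [PWM]
#' @return list with \code{z}, \code{p}, \code{meanForeground},
#'   \code{meanBackground}, \code{nForeground}
#' @export
motifOverrepresentation <- function(foreground, background, motif) {
  fg <- vapply(as.character(foreground), pwmBestScore, numeric(1),
               motif = motif)
  bg <- vapply(as.character(background), pwmBestScore, numeric(1),
               motif = motif)
  fg <- fg[!is.na(fg)]; bg <- bg[!is.na(bg)]
  if (length(fg) < 5L) stop("need at least 5 scorable foreground promoters")
  sdbg <- stats::sd(bg)
  if (!is.finite(sdbg) || sdbg == 0)
    stop("zero background score variance; z undefined")
  z <- (mean(fg) - mean(bg)) / (sdbg / sqrt(length(fg)))
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
       meanForeground = mean(fg), meanBackground = mean(bg),
       nForeground = length(fg))
}
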