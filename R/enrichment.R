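#' Build a ranked gene list
#'
#' A ranked list is a named numeric vector of per-gene scores sorted in
#' decreasing order (genes sorted by decreasing expression M value, for the
#' treatment experiment). Ties keep their input order (stable sort), so
#' results are reproducible for a given input ordering.
#'
#' @param scores numeric vector named by gene id; duplicates forbidden
#' @return named numeric vector, decreasing
#' @export
rankedList <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  scores <- scores[!is.na(scores)]
  scores[order(-scores)]   # radix order is stable in ties
}

#' Weighted running-sum enrichment score
#'
#' The preranked enrichment statistic: walking down the ranked list, the
#' running sum rises by |score|^weightExponent (normalized by the total
#' hit weight) at each gene-set member and falls by 1/(N - Nh) at each
#' non-member. The enrichment score (ES) is the signed extremum of the
#' running sum.
#'
#' @param ranked named numeric vector from [rankedList()]
#' @param geneSet character vector of member gene ids
#' @param weightExponent weighting of ranking scores (default 1; 0 gives
#'   the classic unweighted Kolmogorov-Smirnov statistic)
#' @return list with \code{es} and the full \code{runningSum} vector
#'   (one entry per ranked gene); \code{es} is NA when the set does not
#'   intersect the list
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% geneSet
  nh <- sum(hit)
  if (nh == 0L) {
    message("gene set does not intersect the ranked list")
    return(list(es = NA_real_, runningSum = rep(NA_real_, N)))
  }
  if (nh == N)
    stop("gene set covers the entire ranked list; ES undefined")
  w <- abs(ranked)^weightExponent
  w[!hit] <- 0
  tot <- sum(w)
  step <- if (tot > 0) w / tot else ifelse(hit, 1 / nh, 0)
  step[!hit] <- -1 / (N - nh)
  rs <- cumsum(step)
  es <- unname(rs[which.max(abs(rs))])
  list(es = es, runningSum = rs)
}

# ES only, evaluated at hit boundaries; same statistic as enrichmentScore
# but O(nh log nh) given precomputed |score|^w, for the permutation null.
.esAtPositions <- function(wAll, N, pos) {
  pos <- sort.int(pos)
  nh <- length(pos)
  wn <- wAll[pos]
  tot <- sum(wn)
  wn <- if (tot > 0) wn / tot else rep(1 / nh, nh)
  cw <- cumsum(wn)
  miss <- (pos - seq_len(nh)) / (N - nh)
  after <- cw - miss                 # just after each hit
  before <- after - wn               # just before each hit
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Permutation-normalized enrichment score
#'
#' Builds a null distribution of ES from random gene sets of the same size
#' drawn from the ranked list (the gene-set permutation null, the one
#' available for preranked input). NES is the observed ES divided by the
#' mean absolute null ES of matching sign; the nominal p is the fraction
#' of same-sign null values at least as extreme. When no null value shares
#' the observed sign, p is reported as 1/(nPerm + 1) and flagged.
#'
#' @param es observed enrichment score
#' @param ranked named numeric vector from [rankedList()]
#' @param setSize number of genes in the set
#' @param weightExponent as in [enrichmentScore()]
#' @param nPerm number of random sets (>= 100)
#' @param nullES optional precomputed null ES vector (bypasses sampling;
#'   used to share one null across same-size sets)
#' @return list with \code{nes}, \code{p}, \code{flagged}
#' @export
permutationNes <- function(es, ranked, setSize, weightExponent = 1,
                           nPerm = 1000, nullES = NULL) {
  if (is.null(nullES)) {
    if (nPerm < 100) stop("nPerm must be at least 100")
    nullES <- nullEnrichmentScores(ranked, setSize, weightExponent, nPerm)
  }
  same <- nullES[sign(nullES) == sign(es)]
  if (!length(same))
    return(list(nes = NA_real_, p = 1 / (length(nullES) + 1), flagged = TRUE))
  list(nes = es / mean(abs(same)),
       p = mean(abs(same) >= abs(es)),
       flagged = FALSE)
}

#' Null enrichment scores for random same-size gene sets
#'
#' @inheritParams permutationNes
#' @return numeric vector of \code{nPerm} null ES values
#' @export
nullEnrichmentScores <- function(ranked, setSize, weightExponent = 1,
                                 nPerm = 1000) {
  N <- length(ranked)
  if (setSize < 1 || setSize >= N)
    stop("setSize must lie in [1, length(ranked) - 1]")
  wAll <- abs(ranked)^weightExponent
  vapply(seq_len(nPerm),
         function(i) .esAtPositions(wAll, N, sample.int(N, setSize)),
         numeric(1))
}

#' Preranked gene-set enrichment over a collection
#'
#' Runs [enrichmentScore()] and [permutationNes()] for every gene set,
#' adjusts the nominal p-values across sets by Benjamini-Hochberg, and
#' flags significance at p < 0.05 and FDR < 0.25. Null distributions are
#' shared across sets of identical effective size. Sets with no genes in
#' the list yield NA rows.
#'
#' @param ranked named numeric vector from [rankedList()]
#' @param geneSets named list of character vectors
#' @param weightExponent,nPerm as in [permutationNes()]
#' @param seed integer seed for the permutation RNG (local to this call)
#' @return data.frame: \code{set_id}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{fdr}, \code{significant}, \code{flagged}
#' @export
gseaPreranked <- function(ranked, geneSets, weightExponent = 1,
                          nPerm = 1000, seed = 1L) {
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  sizes <- vapply(geneSets, function(s) sum(names(ranked) %in% s), 0L)
  res <- data.frame(set_id = names(geneSets), size = sizes,
                    es = NA_real_, nes = NA_real_, p = NA_real_,
                    fdr = NA_real_, significant = FALSE, flagged = FALSE,
                    row.names = NULL)
  nullCache <- list()
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(seed)
  for (i in seq_along(geneSets)) {
    if (sizes[i] == 0L || sizes[i] == length(ranked)) next
    sc <- enrichmentScore(ranked, geneSets[[i]], weightExponent)
    key <- as.character(sizes[i])
    if (is.null(nullCache[[key]]))
      nullCache[[key]] <- nullEnrichmentScores(ranked, sizes[i],
                                               weightExponent, nPerm)
    pn <- permutationNes(sc$es, ranked, sizes[i], weightExponent,
                         nPerm, nullES = nullCache[[key]])
    res$es[i] <- sc$es
    res$nes[i] <- pn$nes
    res$p[i] <- pn$p
    res$flagged[i] <- pn$flagged
  }
  res$fdr <- bhAdjust(res$p)
  res$significant <- !is.na(res$p) & res$p < 0.05 &
    !is.na(res$fdr) & res$fdr < 0.25
  res
}

#' NES matrix across ranked lists with the zero-substitution convention
#'
#' Combines enrichment results from several ranked lists into a gene-set x
#' list matrix of NES values. A gene set appears only if it is significant
#' in at least one list; wherever it is not significant, its NES is
#' replaced by 0.
#'
#' @param results data.frame with columns \code{list_id}, \code{set_id},
#'   \code{nes}, \code{significant} (e.g. row-bound [gseaPreranked()]
#'   outputs with a \code{list_id} column added)
#' @return numeric matrix, selected sets x lists
#' @export
assembleNesMatrix <- function(results) {
  stopifnot(all(c("list_id", "set_id", "nes", "significant") %in%
                colnames(results)))
  keepSets <- unique(results$set_id[results$significant])
  lists <- unique(results$list_id)
  out <- matrix(0, length(keepSets), length(lists),
                dimnames = list(keepSets, lists))
  sub <- results[results$set_id %in% keepSets & results$significant, ,
                 drop = FALSE]
  out[cbind(match(sub$set_id, keepSets), match(sub$list_id, lists))] <-
    ifelse(is.na(sub$nes), 0, sub$nes)
  out
}

.saveSeed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
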