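# Shared fixtures and independent oracles.

tinyIntensitySet <- function(m, u, ncMean = 50, ncSd = 10, nCtrl = 10,
                             seed = 1) {
  set.seed(seed)
  nc <- matrix(abs(rnorm(nCtrl * ncol(m), ncMean, ncSd)), nCtrl,
               dimnames = list(NULL, colnames(m)))
  IntensitySet(m, u, nc)
}

randomIntensitySet <- function(nProbe = 40, nSample = 3, seed = 7) {
  set.seed(seed)
  tot <- matrix(rlnorm(nProbe * nSample, log(1000), 0.4), nProbe,
                dimnames = list(sprintf("cg%03d", 1:nProbe),
                                sprintf("s%d", 1:nSample)))
  beta <- matrix(runif(nProbe * nSample, 0.02, 0.98), nProbe)
  tinyIntensitySet(beta * tot, (1 - beta) * tot, seed = seed)
}

smallCfg <- function(seed = 1, ...) {
  simConfig(nGenes = 300, nPlanted = 15, seed = seed, ...)
}

# independent running-sum enumeration (loop, no vectorization shared with
# the implementation)
bruteES <- function(ranked, set, w = 1) {
  genes <- names(ranked)
  hits <- genes %in% set
  nh <- sum(hits)
  nm <- length(genes) - nh
  norm <- sum(abs(ranked[hits])^w)
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- if (hits[i]) run + abs(ranked[i])^w / norm else run - 1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# independent complete-linkage: returns sorted merge heights
bruteCompleteHeights <- function(m) {
  d <- as.matrix(stats::dist(m))
  groups <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      h <- max(d[groups[[i]], groups[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  sort(heights)
}
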