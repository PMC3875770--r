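test_that("row standardization centers and scales with the n-1 denominator", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 6), const = c(2, 2, 2))
  expect_message(z <- rowStandardize(m), "dropped")
  expect_equal(z["a", ], c(-1, 0, 1))
  expect_false("const" %in% rownames(z))
  expect_equal(unname(rowStandardize(z["a", , drop = FALSE])[1, ]),
               c(-1, 0, 1))   # idempotent on standardized rows
})

test_that("hierarchical ordering is complete-linkage Euclidean with mean reordering", {
  m <- rbind(a = c(0, 0), b = c(10, 10), c = c(0.1, 0), d = c(10, 10))
  ord <- hierarchicalOrder(m, "row")
  # identical items are adjacent at height 0
  labs <- ord$labels
  expect_equal(abs(which(labs == "b") - which(labs == "d")), 1)
  expect_equal(min(ord$linkage$height), 0)
  # linkage heights equal an independent complete-linkage enumeration
  set.seed(2)
  m2 <- matrix(rnorm(24), 6)
  rownames(m2) <- paste0("r", 1:6)
  expect_equal(sort(hierarchicalOrder(m2, "row")$linkage$height),
               bruteCompleteHeights(m2))
  # leaves ordered low-mean to high-mean subtrees
  expect_true(which(labs == "a") < which(labs == "b"))
})

test_that("clustering separates a planted two-block structure", {
  set.seed(5)
  m <- cbind(matrix(rnorm(200, 0), 10), matrix(rnorm(200, 4), 10))
  rownames(m) <- paste0("g", 1:10)
  colnames(m) <- paste0("s", 1:40)
  truth <- rep(1:2, each = 20)
  view <- clusteredView(m)
  part <- stats::cutree(view$colLinkage, k = 2)
  expect_equal(mclust::adjustedRandIndex(part, truth), 1)
})

test_that("order propagation permutes columns and sorts probes by TSS distance", {
  set.seed(9)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  view <- clusteredView(m)
  samples <- colnames(m)[view$colOrder]
  meth <- matrix(runif(30), 3, 10,
                 dimnames = list(c("cgA", "cgB", "cgC"), paste0("s", 1:10)))
  ann <- data.frame(probe_id = c("cgA", "cgB", "cgC"),
                    tss_distance = c(300, -800, -200))
  out <- propagateOrder(view, list(expr = m, meth = meth), ann)
  expect_identical(colnames(out$expr), samples)
  expect_identical(rownames(out$meth), c("cgB", "cgC", "cgA"))
  # pure permutation: value multisets unchanged
  expect_equal(sort(out$meth), sort(meth))
  expect_equal(sort(out$expr), sort(m))
  expect_error(propagateOrder(view, list(bad = m[, 1:3])), "lacks sample")
})

test_that("quantile tracks are equal-frequency and monotone", {
  expect_equal(quantileTrack(1:10, k = 5), rep(1:5, each = 2))
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  lab <- quantileTrack(v, k = 5)
  expect_equal(lab, rep(1:5, each = 2)[rank(v)])   # permutation equivariance
  expect_true(all(diff(lab[order(v)]) >= 0))       # monotone in values
  expect_warning(labc <- quantileTrack(rep(3, 8)), "single interval")
  expect_equal(length(unique(labc)), 1)
  expect_warning(nt <- quantileTrack(c(1, 2, NA), k = 5), "fewer than k")
  expect_true(all(is.na(nt)))
})

test_that("PCA batch check filters probes and exposes a planted shift", {
  set.seed(13)
  n <- 20
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:40),
                    chrom = c(rep("chr1", 30), rep("chrX", 5), rep("chr2", 5)),
                    snp = c(rep(FALSE, 35), rep(TRUE, 5)))
  m <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(ann$probe_id, sprintf("s%02d", 1:n)))
  batch <- rep(c(0, 3), each = n / 2)
  m[1:30, ] <- m[1:30, ] + rep(batch, each = 30)
  res <- pcaBatchCheck(MethMatrix(m, "mvalue"), ann)
  expect_equal(nrow(res$coordinates), n)
  expect_true(sum(res$varianceExplained) <= 1)
  # PC1 separates the two batches cleanly
  pc1 <- res$coordinates$PC1
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
              min(pc1[1:10]) > max(pc1[11:20]))
  # identical samples get identical coordinates
  m2 <- m; m2[, 2] <- m2[, 1]
  res2 <- pcaBatchCheck(MethMatrix(m2, "mvalue"), ann)
  expect_equal(res2$coordinates$PC1[1], res2$coordinates$PC1[2])
})

test_that("random 25-gene controls do not reproduce a planted stratification", {
  cfg <- smallCfg(seed = 6)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  co <- generateCohort(cfg, ann, cl$truth$plantedGenes)
  expr <- preprocessCohortRpkm(co$rpkm, unique(ann[, c("gene_id", "chrom")]))
  ctrl <- randomSignatureControl(expr, cl$truth$plantedGenes, k = 25,
                                 nDraws = 30, seed = 3)
  # the signature partition recovers the planted subgroup...
  expect_equal(mclust::adjustedRandIndex(ctrl$signaturePartition,
                                         co$truth$subgroup), 1)
  # ...random gene sets do not
  expect_lt(ctrl$ariMean, 0.2)
  # self-agreement sanity: a partition always matches itself
  expect_equal(mclust::adjustedRandIndex(ctrl$signaturePartition,
                                         ctrl$signaturePartition), 1)
})
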