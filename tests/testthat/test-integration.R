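test_that("Spearman rho matches rank arithmetic, including ties", {
  expect_equal(spearmanRho(1:10, 10:1), -1)
  expect_equal(spearmanRho(1:10, (1:10)^3), 1)
  # tied instance: brute-force Pearson on average ranks
  x <- c(1, 2, 2, 3, 5); y <- c(9, 7, 7, 7, 1)
  expect_equal(spearmanRho(x, y), cor(rank(x), rank(y)))
  expect_warning(r <- spearmanRho(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
  expect_true(is.na(r))
})

test_that("BH adjustment reproduces step-up arithmetic", {
  expect_equal(bhAdjust(0.02), 0.02)                    # m = 1 identity
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))      # exchangeability
  p <- runif(50)
  expect_false(is.unsorted(bhAdjust(p)[order(p)]))      # monotone in p
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

.tinyCohort <- function() {
  # probe cgA anti-correlated with gene g1; cgB positively correlated with
  # g2; cgC independent noise on g3
  set.seed(42)
  n <- 30
  x <- runif(n, 0.1, 0.9)
  beta <- rbind(cgA = x, cgB = x, cgC = runif(n))
  colnames(beta) <- sprintf("s%02d", 1:n)
  expr <- rbind(g1 = 5 - 3 * x, g2 = 1 + 2 * x, g3 = rnorm(n, 5))
  colnames(expr) <- colnames(beta)
  ann <- data.frame(probe_id = c("cgA", "cgB", "cgC"),
                    gene_id = c("g1", "g2", "g3"),
                    tss_distance = c(-200, 300, -800))
  list(beta = MethMatrix(beta, "beta"),
       expr = ExprMatrix(expr, "gene", "log_rpkm"), ann = ann)
}

test_that("informative probes require negative rho at the FDR cutoff", {
  tc <- .tinyCohort()
  info <- informativeProbes(tc$beta, tc$expr, tc$ann)
  a <- info[info$probe_id == "cgA", ]
  expect_equal(a$rho, -1)
  expect_true(a$informative)
  expect_equal(a$tss_distance, -200)
  b <- info[info$probe_id == "cgB", ]
  expect_equal(b$rho, 1)
  expect_false(b$informative)   # positive rho excluded regardless of q
})

.tinyFilterFixture <- function(betaMockP1 = 0.8, d1 = -500) {
  ann <- data.frame(probe_id = c("p1", "p2"),
                    gene_id = c("g1", "g2"),
                    tss_distance = c(d1, -300),
                    island = c(TRUE, TRUE))
  expr <- ExprMatrix(
    matrix(c(0.1, 0.1, 0.7, 0.2), 2, 2,
           dimnames = list(c("g1", "g2"), c("day3", "day10"))),
    "gene", "log_ratio")
  mock <- MethMatrix(
    matrix(c(betaMockP1, 0.9, betaMockP1, 0.9), 2, 2,
           dimnames = list(c("p1", "p2"), c("day3", "day10"))), "beta")
  aza <- MethMatrix(
    matrix(c(betaMockP1 - 0.3, 0.88, betaMockP1 - 0.3, 0.88), 2, 2,
           dimnames = dimnames(as.matrix(mock))), "beta")
  list(ann = ann, expr = expr, mock = mock, aza = aza)
}

test_that("the re-expression filter applies all three cutoff families", {
  f <- .tinyFilterFixture()
  # g1: expr 0.7 at day10, island probe at -500 with mock 0.8, delta 0.3
  sig <- reexpressionFilter(f$expr, f$mock, f$aza, f$ann)
  expect_identical(geneIds(sig), "g1")
  expect_true(all(provenance(sig)$gene_id == "g1"))
  expect_setequal(unique(provenance(sig)$timepoint), c("day3", "day10"))
  # probe outside the 1000 bp window -> excluded
  f2 <- .tinyFilterFixture(d1 = -1500)
  expect_length(geneIds(reexpressionFilter(f2$expr, f2$mock, f2$aza,
                                           f2$ann)), 0)
  # mock beta at 0.45 fails the strict > 0.5 rule
  f3 <- .tinyFilterFixture(betaMockP1 = 0.45)
  expect_length(geneIds(reexpressionFilter(f3$expr, f3$mock, f3$aza,
                                           f3$ann)), 0)
  # g2 fails only on expression (0.2 <= 0.5): demethylation alone is not
  # enough
  f4 <- .tinyFilterFixture()
  f4$aza@values["p2", ] <- 0.5
  expect_identical(geneIds(reexpressionFilter(f4$expr, f4$mock, f4$aza,
                                              f4$ann)), "g1")
  expect_error(reexpressionFilter(f$expr, f$mock, f$aza,
                                  f$ann[0, ]), "empty")
})

test_that("cohort validation keeps genes whose probes pass rho and FDR cutoffs", {
  cand <- GeneSignature(c("g1", "g2", "g3"),
                        data.frame(gene_id = c("g1", "g2", "g3"),
                                   probe_id = c("p1", "p2", "p3")))
  info <- data.frame(probe_id = c("p1", "p2"),
                     gene_id = c("g1", "g2"),
                     tss_distance = c(-10, 20),
                     rho = c(-0.8, -0.20), p = c(1e-5, 0.2),
                     q = c(0.001, 0.3),
                     informative = c(TRUE, FALSE))
  out <- cohortValidation(cand, info)
  expect_identical(geneIds(out), "g1")       # -0.20 > -0.25 dropped;
                                             # p3 absent from cohort
  expect_equal(provenance(out)$rho, -0.8)
})

test_that("TF and reference-list fractions use case-insensitive set semantics", {
  sig <- GeneSignature(sprintf("g%03d", 1:100),
                       data.frame(gene_id = sprintf("g%03d", 1:100)))
  tfs <- list(toupper(sprintf("g%03d", 1:10)),
              sprintf("g%03d", c(5:19, 19, 19)))   # duplicates collapse
  res <- annotateTranscriptionFactors(sig, tfs)
  expect_equal(res$fraction, 0.19)
  expect_identical(geneIds(res$signature), sprintf("g%03d", 1:19))
  expect_equal(overlapFraction(sig, sprintf("G%03d", 84:100)), 0.17)
  expect_equal(overlapFraction(sig, "absent"), 0)
  empty <- GeneSignature(character(0))
  expect_warning(r0 <- annotateTranscriptionFactors(empty, tfs), "empty")
  expect_true(is.na(r0$fraction))
})

test_that("tightening any threshold never adds a gene to the output", {
  cfg <- smallCfg(seed = 4)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  bv <- as.matrix(maskLowConfidence(computeBeta(cl$intensities),
                                    detectionPValues(cl$intensities)))
  mock <- MethMatrix(`colnames<-`(bv[, c("mock_day3", "mock_day10")],
                                  c("day3", "day10")), "beta")
  aza <- MethMatrix(`colnames<-`(bv[, c("aza_day3", "aza_day10")],
                                 c("day3", "day10")), "beta")
  expr <- aggregateProbesToGenes(cl$exprRatio, cl$exprMapping)
  cohort <- generateCohort(cfg, ann, cl$truth$plantedGenes)
  cex <- preprocessCohortRpkm(cohort$rpkm,
                              unique(ann[, c("gene_id", "chrom")]))

  base <- filterThresholds()
  tighter <- list(
    filterThresholds(exprMMin = 0.9),
    filterThresholds(betaMockMin = 0.65),
    filterThresholds(deltaBetaMin = 0.35),
    filterThresholds(tssWindow = 400),
    filterThresholds(cohortRhoMax = -0.6),
    filterThresholds(cohortFdrMax = 0.005),
    filterThresholds(informativeFdrMax = 0.001))
  run <- function(th) {
    cand <- reexpressionFilter(expr, mock, aza, ann, th)
    info <- informativeProbes(cohort$beta, cex, ann, th)
    geneIds(cohortValidation(cand, info, th))
  }
  ref <- run(base)
  expect_gt(length(ref), 0)
  for (th in tighter)
    expect_true(all(run(th) %in% ref))
})
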