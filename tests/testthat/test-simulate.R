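test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simConfig(probesPerGene = c(0, 3)), "lower bound")
  expect_error(simConfig(nGenes = 10, nPlanted = 20), "nPlanted")
  expect_error(simConfig(subgroupFraction = 1.2), "subgroupFraction")
  expect_error(simConfig(noiseSdBeta = -0.1), "noiseSdBeta")
})

test_that("annotation satisfies its promoter-window postconditions", {
  cfg <- simConfig(nGenes = 100, probesPerGene = c(2, 4), seed = 7)
  ann <- generateAnnotation(cfg)
  byGene <- split(ann, ann$gene_id)
  expect_length(byGene, 100)
  inWindow <- vapply(byGene, function(g)
    any(g$island & abs(g$tss_distance) <= 1000), logical(1))
  outside <- vapply(byGene, function(g)
    any(!g$island | abs(g$tss_distance) > 1000), logical(1))
  expect_true(all(inWindow))
  expect_true(all(outside))
  # independently re-filter the emitted table: the in-window island
  # fraction matches a recount
  frac <- mean(ann$island & abs(ann$tss_distance) <= 1000)
  recount <- nrow(ann[ann$island %in% TRUE &
                      ann$tss_distance >= -1000 &
                      ann$tss_distance <= 1000, ]) / nrow(ann)
  expect_equal(frac, recount)
  expect_true(mean(ann$snp) < 0.15)
  # positions are consistent with signed distances
  expect_true(all(ann$pos - ann$tss_distance > 0))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- smallCfg(seed = 11)
  expect_identical(generateAnnotation(cfg), generateAnnotation(cfg))
  ann <- generateAnnotation(cfg)
  a <- generateCellLineExperiment(cfg, ann)
  b <- generateCellLineExperiment(cfg, ann)
  expect_identical(methylated(a$intensities), methylated(b$intensities))
  expect_identical(as.matrix(a$exprRatio), as.matrix(b$exprRatio))
  expect_identical(generateCohort(cfg, ann, a$truth$plantedGenes),
                   generateCohort(cfg, ann, a$truth$plantedGenes))
  expect_identical(generateAuxiliary(cfg, a$truth),
                   generateAuxiliary(cfg, a$truth))
  # and the generators do not disturb the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(generateAnnotation(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("zero noise reproduces every planted effect exactly", {
  cfg <- smallCfg(seed = 2, noiseSdBeta = 0, noiseSdExpr = 0,
                  dropoutFraction = 0)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  beta <- as.matrix(computeBeta(cl$intensities))
  expect_equal(beta, cl$targetBeta, tolerance = 1e-12)
  promo <- ann$island & abs(ann$tss_distance) <= 1000 &
    ann$gene_id %in% cl$truth$plantedGenes
  d3 <- beta[promo, "mock_day3"] - beta[promo, "aza_day3"]
  expect_equal(unname(d3), rep(cfg$deltaBetaEffect, sum(promo)))
  d10 <- beta[promo, "mock_day10"] - beta[promo, "aza_day10"]
  expect_equal(unname(d10),
               rep(cfg$deltaBetaEffect * cfg$day10Retention, sum(promo)))
  er <- as.matrix(cl$exprRatio)
  plantedProbe <- cl$exprMapping$gene_id %in% cl$truth$plantedGenes
  expect_true(all(er[plantedProbe, "day10"] == cfg$exprEffect))
  expect_true(all(er[!plantedProbe, ] == 0))
})

test_that("betas recomputed from intensities reproduce the emitted betas", {
  cfg <- smallCfg(seed = 8, dropoutFraction = 0)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  m <- methylated(cl$intensities); u <- unmethylated(cl$intensities)
  expect_lt(max(abs(m / (m + u) -
                    as.matrix(computeBeta(cl$intensities)))), 1e-12)
})

test_that("planted demethylation and detection dropout appear at the configured rates", {
  cfg <- simConfig(nGenes = 400, nPlanted = 40, dropoutFraction = 0.05,
                   seed = 14)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  beta <- computeBeta(cl$intensities)
  promo <- ann$island & abs(ann$tss_distance) <= 1000 &
    ann$gene_id %in% cl$truth$plantedGenes
  bv <- as.matrix(beta)
  d <- mean(bv[promo, "mock_day3"] - bv[promo, "aza_day3"])
  se <- sd(bv[promo, "mock_day3"] - bv[promo, "aza_day3"]) / sqrt(sum(promo))
  expect_lt(abs(d - cfg$deltaBetaEffect), 3 * se)
  # ~5% of cells exceed the detection threshold downstream
  masked <- is.na(as.matrix(maskLowConfidence(
    beta, detectionPValues(cl$intensities))))
  expect_gt(mean(masked), 0.03)
  expect_lt(mean(masked), 0.07)
})

test_that("the cohort couples methylation and expression negatively at planted probes", {
  cfg <- smallCfg(seed = 10, noiseSdBeta = 0, noiseSdExpr = 0,
                  zeroFraction = 0)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  co <- generateCohort(cfg, ann, cl$truth$plantedGenes)
  expect_equal(sum(co$truth$subgroup),
               round(cfg$nSamplesCohort * cfg$subgroupFraction))
  bv <- as.matrix(co$beta)
  ev <- log2(as.matrix(co$rpkm))
  probes <- co$truth$plantedProbes
  genes <- ann$gene_id[match(probes, ann$probe_id)]
  rho <- mapply(function(p, g) spearmanRho(bv[p, ], ev[g, ]),
                probes, genes)
  expect_true(all(rho == -1))
  # non-planted probes: no systematic coupling
  cfg2 <- smallCfg(seed = 10)
  co2 <- generateCohort(cfg2, ann, cl$truth$plantedGenes)
  bv2 <- as.matrix(co2$beta); ev2 <- log2(pmax(as.matrix(co2$rpkm), 1e-9))
  other <- setdiff(ann$probe_id, co2$truth$plantedProbes)[1:200]
  g2 <- ann$gene_id[match(other, ann$probe_id)]
  rho2 <- suppressWarnings(
    mapply(function(p, g) spearmanRho(bv2[p, ], ev2[g, ]), other, g2))
  expect_lt(abs(mean(rho2, na.rm = TRUE)), 0.1)
})

test_that("auxiliary fixtures carry their planted ground truth", {
  cfg <- simConfig(nGenes = 300, nPlanted = 40, seed = 12)
  ann <- generateAnnotation(cfg)
  cl <- generateCellLineExperiment(cfg, ann)
  aux <- generateAuxiliary(cfg, cl$truth)
  for (s in aux$enrichedSets)
    expect_gte(mean(aux$geneSets[[s]] %in% cl$truth$plantedGenes), 0.75)
  expect_true(all(cl$truth$plantedTf %in% aux$tfList))
  # every foreground promoter contains the embedded consensus site
  cons <- DemethylSig:::.consensusOf(aux$pwms$motif1)
  embScore <- sum(apply(aux$pwms$motif1@weights, 2, max))
  for (g in aux$motifForeground)
    expect_gte(pwmBestScore(aux$promoters[[g]], aux$pwms$motif1), embScore)
})
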