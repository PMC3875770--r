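#' Run the full integrative analysis on a synthetic study
#'
#' End-to-end orchestration: generates the synthetic fixtures, computes
#' beta/M values with detection masking, derives delta beta, collapses
#' expression probes to gene medians, applies the
#' re-expression/demethylation filter, validates candidates against the
#' cohort through informative probes, annotates transcription-factor and
#' reference-list content, runs preranked gene-set enrichment on the day-3
#' and day-10 rankings and assembles the NES matrix, tests promoter motif
#' over-representation, stratifies the cohort on the validated signature
#' with the random-gene-set control and a PCA batch check, and evaluates
#' the clinical/cytometry formulas on a bundled example. Every stage draws
#' its RNG stream from the configuration seed plus a fixed offset, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config a [simConfig()]
#' @param thresholds a [filterThresholds()]
#' @param outDir optional directory for artifacts (signature TSV, report
#'   JSON); created if missing
#' @param gseaNPerm permutations for the enrichment null (default 1000)
#' @param nRandomDraws draws for the random-signature control (default 50)
#' @return (invisibly) a list with all stage outputs and \code{report},
#'   the JSON-serializable run summary with counts at every cascade stage
#' @export
runPipeline <- function(config = simConfig(),
                        thresholds = filterThresholds(),
                        outDir = NULL, gseaNPerm = 1000,
                        nRandomDraws = 50) {
  stopifnot(inherits(config, "SimConfig"),
            is(thresholds, "FilterThresholds"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ann <- stage("synthetic_data", generateAnnotation(config))
  cl <- stage("synthetic_data", generateCellLineExperiment(config, ann))
  aux <- stage("synthetic_data", generateAuxiliary(config, cl$truth))
  cohort <- stage("synthetic_data",
                  generateCohort(config, ann, cl$truth$plantedGenes))

  beta <- stage("methylation", computeBeta(cl$intensities))
  mval <- stage("methylation", computeMValue(cl$intensities))
  dp <- stage("methylation", detectionPValues(cl$intensities))
  beta <- stage("methylation", maskLowConfidence(beta, dp))
  mval <- stage("methylation", maskLowConfidence(mval, dp))
  bv <- as.matrix(beta)
  betaMock <- MethMatrix(`colnames<-`(bv[, c("mock_day3", "mock_day10")],
                                      c("day3", "day10")), "beta")
  betaAza <- MethMatrix(`colnames<-`(bv[, c("aza_day3", "aza_day10")],
                                     c("day3", "day10")), "beta")
  delta <- stage("methylation", deltaBeta(betaAza, betaMock))
  demeth <- stage("methylation", demethylationSummary(delta))

  exprGene <- stage("expression",
                    aggregateProbesToGenes(cl$exprRatio, cl$exprMapping))
  geneAnn <- unique(ann[, c("gene_id", "chrom")])
  cohortExpr <- stage("expression",
                      preprocessCohortRpkm(cohort$rpkm, geneAnn))

  candidates <- stage("integration",
                      reexpressionFilter(exprGene, betaMock, betaAza, ann,
                                         thresholds))
  info <- stage("integration",
                informativeProbes(cohort$beta, cohortExpr, ann,
                                  thresholds))
  validated <- stage("integration",
                     cohortValidation(candidates, info, thresholds))
  tf <- stage("integration",
              annotateTranscriptionFactors(validated, aux$tfList))
  refOverlap <- stage("integration",
                      overlapFraction(validated, aux$referenceList))

  ev <- as.matrix(exprGene)
  gsea <- stage("enrichment", {
    res <- lapply(c("day3", "day10"), function(tp) {
      r <- gseaPreranked(rankedList(ev[, tp]), aux$geneSets,
                         nPerm = gseaNPerm, seed = config$seed + 500L)
      cbind(list_id = tp, r)
    })
    do.call(rbind, res)
  })
  nesMatrix <- stage("enrichment", assembleNesMatrix(gsea))
  motif <- stage("enrichment", {
    fg <- aux$promoters[aux$motifForeground]
    motifOverrepresentation(fg, aux$promoters, aux$pwms$motif1)
  })

  strat <- stage("cohort", {
    cm <- as.matrix(cohortExpr)
    sigGenes <- intersect(geneIds(validated), rownames(cm))
    view <- clusteredView(cm[sigGenes, , drop = FALSE])
    partition <- stats::cutree(view$colLinkage, k = 2)
    tracks <- lapply(sigGenes[seq_len(min(2, length(sigGenes)))],
                     function(g) quantileTrack(cm[g, ]))
    names(tracks) <- sigGenes[seq_len(min(2, length(sigGenes)))]
    sigProbes <- provenance(validated)$probe_id
    linked <- propagateOrder(view,
                             list(meth = as.matrix(cohort$beta)[
                               unique(sigProbes), , drop = FALSE]),
                             annotation = ann)
    ctrl <- randomSignatureControl(cohortExpr, sigGenes, k = 25,
                                   nDraws = nRandomDraws,
                                   seed = config$seed + 600L)
    ariTruth <- mclust::adjustedRandIndex(partition,
                                          cohort$truth$subgroup)
    list(view = view, partition = partition, tracks = tracks,
         linked = linked, control = ctrl, ariTruth = ariTruth)
  })
  cohortMval <- MethMatrix(log2(pmax(as.matrix(cohort$beta), 1e-6) /
                                pmax(1 - as.matrix(cohort$beta), 1e-6)),
                           "mvalue")
  pca <- stage("cohort", pcaBatchCheck(cohortMval, ann))

  metrics <- stage("metrics", list(
    facsExample = as.numeric(facsLog2Change(120, 20, 70, 20)),
    recistExample = recistPercentChange(100, c(70, 100, 120))))

  planted <- cl$truth$plantedGenes
  report <- list(
    package_version = as.character(utils::packageVersion("DemethylSig")),
    seed = config$seed,
    thresholds = list(exprMMin = thresholds@exprMMin,
                      betaMockMin = thresholds@betaMockMin,
                      deltaBetaMin = thresholds@deltaBetaMin,
                      tssWindow = thresholds@tssWindow,
                      cohortRhoMax = thresholds@cohortRhoMax,
                      cohortFdrMax = thresholds@cohortFdrMax,
                      informativeFdrMax = thresholds@informativeFdrMax),
    counts = list(
      genes = config$nGenes,
      probes = nrow(ann),
      masked_fraction = mean(is.na(bv)),
      candidates = length(candidates),
      validated = length(validated),
      informative_probes = sum(info$informative),
      planted = length(planted),
      recovered = sum(geneIds(validated) %in% planted),
      false_positives = sum(!geneIds(validated) %in% planted)),
    tf_fraction = tf$fraction,
    reference_overlap = refOverlap,
    median_delta_beta = demeth$median,
    gsea_significant = sum(gsea$significant),
    nes_matrix_sets = nrow(nesMatrix),
    motif = list(z = motif$z, p = motif$p),
    stratification = list(ari_truth = strat$ariTruth,
                          random_ari_mean = strat$control$ariMean),
    pca_variance = pca$varianceExplained,
    metrics = metrics)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(provenance(validated),
                       file.path(outDir, "signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 12,
                                pretty = TRUE),
               file.path(outDir, "report.json"))
  }

  invisible(list(config = config, annotation = ann, cellLine = cl,
                 cohort = cohort, aux = aux, beta = beta, mval = mval,
                 delta = delta, exprGene = exprGene,
                 cohortExpr = cohortExpr, candidates = candidates,
                 informative = info, validated = validated, tf = tf,
                 gsea = gsea, nesMatrix = nesMatrix, motif = motif,
                 stratification = strat, pca = pca, report = report))
}
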