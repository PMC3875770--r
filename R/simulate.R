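#' Simulation configuration
#'
#' Parameters of the synthetic study: a cell-line experiment (mock vs.
#' demethylating treatment at day 3, end of treatment, and day 10, one
#' week later) with planted silenced-then-reactivated genes, and a tumor
#' cohort containing a high-methylation/low-expression subgroup over the
#' same planted genes. Identical configurations (same seed) produce
#' bit-identical fixtures; each generator derives its RNG stream from
#' \code{seed} plus a fixed per-stage offset.
#'
#' @param nGenes number of genes (default 2000)
#' @param probesPerGene inclusive range of methylation probes per gene
#'   (default c(2, 4))
#' @param exprProbesPerGene expression-array probes per gene (default 3)
#' @param nPlanted silenced-and-reactivated genes (default 50)
#' @param nSamplesCohort cohort size (default 60)
#' @param subgroupFraction fraction of cohort samples in the planted
#'   subgroup (default 0.3)
#' @param deltaBetaEffect planted promoter demethylation on the beta scale
#'   at day 3 (default 0.4)
#' @param day10Retention fraction of the day-3 demethylation still present
#'   at day 10, after partial remethylation (default 0.75)
#' @param exprEffect planted expression induction, log2 units, at day 10
#'   (default 1.5)
#' @param day3ExprFraction fraction of the induction already visible at
#'   day 3 (default 0.5)
#' @param noiseSdBeta,noiseSdExpr measurement noise SDs on the beta and
#'   log2-expression scales (defaults 0.05)
#' @param snpFraction fraction of probes flagged as SNP-associated
#'   (default 0.05)
#' @param sexFraction fraction of genes placed on X/Y (default 0.02)
#' @param dropoutFraction fraction of probe/sample cells whose intensities
#'   are background-level (detection failures; default 0.01)
#' @param zeroFraction fraction of cohort RPKM cells set to 0 (default
#'   0.02)
#' @param cohortBetaLow,cohortMethEffect baseline promoter beta of planted
#'   genes outside the subgroup and its elevation inside (defaults 0.25,
#'   0.5)
#' @param cohortExprBase,cohortExprCoupling log2 expression of planted
#'   genes at beta 0 and the (negative) slope against promoter
#'   methylation (defaults 8, 6)
#' @param tfFraction fraction of planted genes flagged as transcription
#'   factors (default 0.2)
#' @param seed integer RNG seed (default 1)
#' @return a validated list of class \code{SimConfig}
#' @export
simConfig <- function(nGenes = 2000, probesPerGene = c(2, 4),
                      exprProbesPerGene = 3, nPlanted = 50,
                      nSamplesCohort = 60, subgroupFraction = 0.3,
                      deltaBetaEffect = 0.4, day10Retention = 0.75,
                      exprEffect = 1.5, day3ExprFraction = 0.5,
                      noiseSdBeta = 0.05, noiseSdExpr = 0.05,
                      snpFraction = 0.05, sexFraction = 0.02,
                      dropoutFraction = 0.01, zeroFraction = 0.02,
                      cohortBetaLow = 0.25, cohortMethEffect = 0.5,
                      cohortExprBase = 8, cohortExprCoupling = 6,
                      tfFraction = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$probesPerGene) != 2L || cfg$probesPerGene[1] < 1)
    stop("invalid config: probesPerGene lower bound must be >= 1")
  if (cfg$nPlanted > cfg$nGenes)
    stop("invalid config: nPlanted must not exceed nGenes")
  for (f in c("subgroupFraction", "tfFraction"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("invalid config: ", f, " must lie in (0, 1)")
  for (f in c("snpFraction", "sexFraction", "dropoutFraction",
              "zeroFraction"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop("invalid config: ", f, " must lie in [0, 1)")
  for (f in c("noiseSdBeta", "noiseSdExpr"))
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "SimConfig")
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.sampleUpTo <- function(x, n) sample(x, min(n, length(x)))

#' Generate probe annotation
#'
#' Every gene receives at least one CpG-island probe within 1000 bp of its
#' TSS (the promoter window of the filter cascade) and at least one probe
#' outside that window or off-island. Probes carry a SNP flag at the
#' configured rate; a small fraction of genes is placed on the sex
#' chromosomes (their probes and cohort expression are removed by the
#' standard preprocessing).
#'
#' TSS distances are signed (negative = upstream) and stored directly, so
#' no genome arithmetic is needed downstream; \code{pos} is \code{tss +
#' tss_distance}.
#'
#' @param config a [simConfig()]
#' @return data.frame with columns \code{probe_id}, \code{gene_id},
#'   \code{chrom}, \code{pos}, \code{tss_distance}, \code{island},
#'   \code{snp}
#' @export
generateAnnotation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed + 101L)
  genes <- sprintf("gene%05d", seq_len(config$nGenes))
  sexGene <- stats::runif(config$nGenes) < config$sexFraction
  chrom <- ifelse(sexGene, sample(c("chrX", "chrY"), config$nGenes, TRUE),
                  paste0("chr", sample(1:22, config$nGenes, TRUE)))
  tss <- sample(1e5:1e8, config$nGenes, replace = TRUE)
  nProbes <- sample(config$probesPerGene[1]:config$probesPerGene[2],
                    config$nGenes, replace = TRUE)
  # probe 1 always island + in-window; probe 2 (if present) outside window
  rows <- vector("list", config$nGenes)
  for (g in seq_len(config$nGenes)) {
    np <- nProbes[g]
    d <- integer(np); isl <- logical(np)
    d[1] <- sample(-1000:1000, 1); isl[1] <- TRUE
    if (np >= 2) {
      d[2] <- sample(c(-5000:-1001, 1001:5000), 1)
      isl[2] <- stats::runif(1) < 0.5
    }
    if (np >= 3) {
      d[3:np] <- sample(-5000:5000, np - 2, replace = TRUE)
      isl[3:np] <- stats::runif(np - 2) < 0.5
    }
    rows[[g]] <- data.frame(gene_id = genes[g], chrom = chrom[g],
                            pos = tss[g] + d, tss_distance = d,
                            island = isl)
  }
  ann <- do.call(rbind, rows)
  ann$snp <- stats::runif(nrow(ann)) < config$snpFraction
  ann <- cbind(probe_id = sprintf("cg%07d", seq_len(nrow(ann))), ann)
  rownames(ann) <- NULL
  ann
}

.sampleNames <- c("mock_day3", "aza_day3", "mock_day10", "aza_day10")

#' Generate the paired mock/treatment cell-line experiment
#'
#' Produces bead intensities for four arrays (mock and treated at day 3
#' and day 10) plus probe-level treated/mock expression log ratios, with
#' known ground truth. Planted genes get mock promoter-island beta drawn
#' in (0.7, 0.95), a beta drop of \code{deltaBetaEffect} under treatment
#' at day 3 (\code{day10Retention} of it remaining at day 10), and an
#' expression induction of \code{exprEffect} log2 units at day 10
#' (\code{day3ExprFraction} of it at day 3). Non-planted genes have
#' delta beta and log ratios centered at 0.
#'
#' Intensities are back-computed from the (noisy) target betas by fixing a
#' log-normal total intensity T and setting M = beta * T, U = (1 - beta)
#' * T, so beta recomputes exactly from the emitted intensities. Detection
#' dropout replaces a cell's total intensity with a draw from the
#' negative-control distribution, producing realistic high detection
#' p-values.
#'
#' @param config a [simConfig()]
#' @param annotation output of [generateAnnotation()]
#' @return list with \code{intensities} ([IntensitySet], columns
#'   mock/aza x day3/day10), \code{exprRatio} (probe-level [ExprMatrix],
#'   log_ratio, columns day3/day10), \code{exprMapping} (probe to gene),
#'   \code{targetBeta} (noise-free check matrix), \code{truth} (list:
#'   \code{plantedGenes}, \code{plantedTf}, \code{dropoutCells})
#' @export
generateCellLineExperiment <- function(config, annotation) {
  stopifnot(inherits(config, "SimConfig"))
  if (!all(sprintf("gene%05d", seq_len(config$nGenes)) %in%
           annotation$gene_id))
    stop("annotation does not cover all configured genes")
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed + 202L)

  autosomal <- unique(annotation$gene_id[
    !sub("^chr", "", annotation$chrom) %in% c("X", "Y")])
  planted <- sort(sample(autosomal, config$nPlanted))
  plantedTf <- sort(sample(planted,
                           max(1L, round(config$tfFraction *
                                         config$nPlanted))))

  nprobe <- nrow(annotation)
  promoterProbe <- annotation$island &
    abs(annotation$tss_distance) <= 1000
  plantedProbe <- promoterProbe & annotation$gene_id %in% planted

  base <- ifelse(plantedProbe,
                 stats::runif(nprobe, 0.7, 0.95),
                 stats::runif(nprobe, 0.05, 0.95))
  delta3 <- ifelse(plantedProbe, config$deltaBetaEffect, 0)
  delta10 <- delta3 * config$day10Retention
  target <- cbind(mock_day3 = base, aza_day3 = base - delta3,
                  mock_day10 = base, aza_day10 = base - delta10)
  if (any(target < 0 | target > 1)) {
    warning("delta beta effect pushes target beta outside [0, 1]; clipped")
    target <- .clamp01(target)
  }
  beta <- target
  if (config$noiseSdBeta > 0)
    beta <- .clamp01(target + matrix(stats::rnorm(length(target), 0,
                                                  config$noiseSdBeta),
                                     nrow(target)))
  rownames(beta) <- rownames(target) <- annotation$probe_id

  tot <- matrix(stats::rlnorm(length(beta), log(2000), 0.3), nrow(beta))
  drop <- matrix(stats::runif(length(beta)) < config$dropoutFraction,
                 nrow(beta))
  tot[drop] <- stats::rlnorm(sum(drop), log(60), 0.4)
  mI <- beta * tot
  uI <- (1 - beta) * tot
  dimnames(mI) <- dimnames(uI) <- list(annotation$probe_id, .sampleNames)
  negctrl <- matrix(stats::rlnorm(30 * 4, log(60), 0.4), 30, 4,
                    dimnames = list(NULL, .sampleNames))
  ints <- IntensitySet(mI, uI, negctrl,
                       rowData = annotation[, c("gene_id", "chrom",
                                                "tss_distance", "island",
                                                "snp")])

  genes <- unique(annotation$gene_id)
  eMap <- data.frame(
    probe_id = sprintf("ep%06d",
                       seq_len(length(genes) * config$exprProbesPerGene)),
    gene_id = rep(genes, each = config$exprProbesPerGene))
  eff10 <- ifelse(eMap$gene_id %in% planted, config$exprEffect, 0)
  eff3 <- eff10 * config$day3ExprFraction
  ne <- nrow(eMap)
  noise <- function() if (config$noiseSdExpr > 0)
    stats::rnorm(ne, 0, config$noiseSdExpr) else 0
  ratio <- cbind(day3 = eff3 + noise(), day10 = eff10 + noise())
  rownames(ratio) <- eMap$probe_id
  list(intensities = ints,
       exprRatio = ExprMatrix(ratio, "probe", "log_ratio"),
       exprMapping = eMap,
       targetBeta = target,
       truth = list(plantedGenes = planted, plantedTf = plantedTf,
                    dropoutCells = drop))
}

#' Generate a tumor cohort with a planted subgroup
#'
#' A fraction of samples forms a subgroup with elevated promoter-island
#' methylation and proportionally reduced expression of the planted genes
#' (monotone negative coupling: log2 expression = cohortExprBase -
#' cohortExprCoupling * latent methylation), yielding negative Spearman
#' correlation at planted promoter probes — with all noise at 0 the
#' coupling is perfect and rho = -1. Non-planted probes and genes are
#' mutually independent. Expression is emitted on the linear RPKM-like
#' scale with a configurable fraction of zeros injected uniformly at
#' random.
#'
#' @param config a [simConfig()]
#' @param annotation output of [generateAnnotation()]
#' @param plantedGenes character vector of planted gene ids (from
#'   [generateCellLineExperiment()]); defaults to regenerating the same
#'   planting from the config seed
#' @return list with \code{beta} (probe x sample [MethMatrix]),
#'   \code{rpkm} (gene x sample linear [ExprMatrix]), \code{truth} (list:
#'   \code{subgroup} named 0/1 vector, \code{plantedGenes},
#'   \code{plantedProbes})
#' @export
generateCohort <- function(config, annotation, plantedGenes = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(plantedGenes))
    plantedGenes <- generateCellLineExperiment(config,
                                               annotation)$truth$plantedGenes
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed + 303L)

  n <- config$nSamplesCohort
  samples <- sprintf("TCGA%03d", seq_len(n))
  nsub <- round(n * config$subgroupFraction)
  sub <- rep(0L, n)
  sub[sample(n, nsub)] <- 1L
  names(sub) <- samples

  genes <- unique(annotation$gene_id)
  promoterProbe <- annotation$island & abs(annotation$tss_distance) <= 1000
  plantedProbe <- promoterProbe & annotation$gene_id %in% plantedGenes

  # latent promoter methylation per planted gene x sample
  latent <- matrix(config$cohortBetaLow, length(plantedGenes), n,
                   dimnames = list(plantedGenes, samples))
  latent <- latent + rep(config$cohortMethEffect * sub, each = nrow(latent))
  if (config$noiseSdBeta > 0)
    latent <- latent + matrix(stats::rnorm(length(latent), 0,
                                           config$noiseSdBeta),
                              nrow(latent))

  nprobe <- nrow(annotation)
  beta <- matrix(stats::runif(nprobe, 0.05, 0.95), nprobe, n,
                 dimnames = list(annotation$probe_id, samples))
  if (config$noiseSdBeta > 0)
    beta <- beta + matrix(stats::rnorm(length(beta), 0,
                                       config$noiseSdBeta), nprobe)
  beta[plantedProbe, ] <- latent[annotation$gene_id[plantedProbe], ]
  if (config$noiseSdBeta > 0)
    beta[plantedProbe, ] <- beta[plantedProbe, ] +
      matrix(stats::rnorm(sum(plantedProbe) * n, 0, config$noiseSdBeta),
             sum(plantedProbe))
  beta <- .clamp01(beta)

  lexpr <- matrix(stats::rnorm(length(genes), 5, 1), length(genes), n,
                  dimnames = list(genes, samples))
  lexpr <- lexpr + matrix(stats::rnorm(length(lexpr), 0, 0.7),
                          nrow(lexpr))
  lexpr[plantedGenes, ] <- config$cohortExprBase -
    config$cohortExprCoupling * latent
  if (config$noiseSdExpr > 0)
    lexpr[plantedGenes, ] <- lexpr[plantedGenes, ] +
      matrix(stats::rnorm(length(latent), 0, config$noiseSdExpr),
             nrow(latent))
  rpkm <- 2^lexpr
  if (config$zeroFraction > 0)
    rpkm[matrix(stats::runif(length(rpkm)) < config$zeroFraction,
                nrow(rpkm))] <- 0

  list(beta = MethMatrix(beta, "beta"),
       rpkm = ExprMatrix(rpkm, "gene", "linear"),
       truth = list(subgroup = sub, plantedGenes = plantedGenes,
                    plantedProbes = annotation$probe_id[plantedProbe]))
}

.consensusOf <- function(motif) {
  paste(rownames(motif@weights)[apply(motif@weights, 2, which.max)],
        collapse = "")
}

#' Generate auxiliary fixtures: gene sets, TF/reference lists, motifs,
#' promoters
#'
#' Gene-set collection with known positives (sets drawn 80% from the
#' planted genes) and random decoys; a transcription-factor list
#' containing the planted TFs; a reference (interferome-like) list with a
#' known planted overlap; position weight matrices; and promoter windows
#' (-450..+50 around the TSS, 500 bp) where the foreground genes carry an
#' embedded consensus site of the first motif and background genes are
#' random sequence.
#'
#' @param config a [simConfig()]
#' @param truth ground-truth list from [generateCellLineExperiment()]
#' @param nEnriched,nRandomSets,setSize gene-set collection shape
#'   (defaults 5, 15, 30)
#' @param nForeground,nBackground promoter counts (defaults 20, 200)
#' @return list with \code{geneSets} (named list), \code{enrichedSets}
#'   (character; ground-truth positives), \code{tfList},
#'   \code{referenceList}, \code{pwms} (list of [PWM]), \code{promoters}
#'   (named character vector), \code{motifForeground} (gene ids with
#'   planted sites)
#' @export
generateAuxiliary <- function(config, truth, nEnriched = 5,
                              nRandomSets = 15, setSize = 30,
                              nForeground = 20, nBackground = 200) {
  stopifnot(inherits(config, "SimConfig"))
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(config$seed + 404L)
  genes <- sprintf("gene%05d", seq_len(config$nGenes))
  planted <- truth$plantedGenes
  other <- setdiff(genes, planted)

  nPl <- min(round(0.8 * setSize), length(planted))
  geneSets <- list()
  for (i in seq_len(nEnriched))
    geneSets[[sprintf("set_planted_%02d", i)]] <-
      c(sample(planted, nPl), sample(other, setSize - nPl))
  for (i in seq_len(nRandomSets))
    geneSets[[sprintf("set_random_%02d", i)]] <- sample(genes, setSize)
  enriched <- grep("^set_planted", names(geneSets), value = TRUE)

  tfList <- sort(c(truth$plantedTf, .sampleUpTo(other, 100)))
  nRef <- max(1L, round(0.4 * length(planted)))
  referenceList <- sort(c(sample(planted, nRef), .sampleUpTo(other, 150)))

  makeCounts <- function() {
    width <- 8
    cons <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    counts <- matrix(5, 4, width, dimnames = list(c("A", "C", "G", "T")))
    counts[cbind(match(cons, rownames(counts)), seq_len(width))] <- 85
    counts
  }
  pwmCounts <- list(motif1 = makeCounts(), motif2 = makeCounts())
  pwms <- lapply(pwmCounts, pwmFromCounts)
  cons1 <- .consensusOf(pwms$motif1)

  randomSeq <- function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  fgGenes <- sample(planted, min(nForeground, length(planted)))
  bgGenes <- .sampleUpTo(setdiff(genes, fgGenes), nBackground)
  promoters <- c(
    vapply(fgGenes, function(g) {
      s <- randomSeq(500)
      at <- sample(500 - nchar(cons1) + 1, 1)
      paste0(substr(s, 1, at - 1), cons1,
             substr(s, at + nchar(cons1), 500))
    }, character(1)),
    vapply(bgGenes, function(g) randomSeq(500), character(1)))
  names(promoters) <- c(fgGenes, bgGenes)

  list(geneSets = geneSets, enrichedSets = enriched, tfList = tfList,
       referenceList = referenceList, pwms = pwms, pwmCounts = pwmCounts,
       promoters = promoters, motifForeground = fgGenes)
}
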