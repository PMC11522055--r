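# Replicate simulation studies: calibration and recovery benchmarks run
# against planted truth. The annotation and truth plan are generated once
# per study (one genome, repeated experiments); only the data layers are
# re-simulated per replicate.

.studyBase <- function(cfg) {
  ann <- simulateAnnotation(cfg)
  truth <- planTruth(cfg, ann)
  list(ann = ann, truth = truth,
       geneIndex = deriveRegions(ann$geneModels),
       mirnaIndex = deriveRegions(ann$mirnaModels))
}

#' Null calibration of the differential calls
#'
#' Simulates replicates with no planted effects and measures the
#' fraction of CpG sites called DMS (q < `maxQ`, |difference| >=
#' `minDiff`) and the fraction of genes called differentially expressed
#' (padj < 0.05, |log2FC| >= 1).
#'
#' @param cfg a [simulationConfig()]; its planted fractions are forced
#'   to zero.
#' @param nReps number of replicates.
#' @param seed base seed; replicate r uses `seed + r` for its data.
#' @return data.frame per replicate (`dms_rate`, `de_rate`, `n_sites`,
#'   `n_genes`); pooled rates in the `pooled` attribute.
#' @export
nullCalibration <- function(cfg = simulationConfig(), nReps = 500L,
                            seed = cfg$seed) {
  cfg$dmsFraction <- 0; cfg$deFraction <- 0
  cfg$mirnaDeFraction <- 0
  cfg$nCoupledGenes <- 0L; cfg$nCascades <- 0L
  base <- .studyBase(cfg)
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    meth <- simulateMethylome(cfg, base$truth, seed = seed + 7L * r)
    filt <- filterCoverage(meth)
    dms <- callDMS(filt, cfg$groupLabels[1], cfg$groupLabels[2])
    expr <- simulateExpression(cfg, base$truth, seed = seed + 7L * r + 3L)
    de <- testDE(expr$geneCounts, cfg$groupLabels[1], cfg$groupLabels[2],
                 tierScheme = NULL)
    rows[[r]] <- data.frame(
      dms_rate = sum(dms$direction != "ns") / nrow(dms),
      de_rate = mean(de$is_de),
      n_sites = nrow(dms), n_genes = nrow(de))
  }
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- c(
    dms_rate = sum(out$dms_rate * out$n_sites) / sum(out$n_sites),
    de_rate = sum(out$de_rate * out$n_genes) / sum(out$n_genes))
  out
}

#' Planted-effect recovery of the differential calls
#'
#' Simulates replicates under the default planted conditions and scores
#' DMS and DEG calls against the truth tables: sensitivity (planted
#' effects recovered, with matching direction counted via the site /
#' gene identity) and empirical FDR among calls.
#'
#' @inheritParams nullCalibration
#' @return data.frame per replicate; pooled sensitivity/FDR in the
#'   `pooled` attribute.
#' @export
plantedRecovery <- function(cfg = simulationConfig(), nReps = 200L,
                            seed = cfg$seed) {
  base <- .studyBase(cfg)
  truth <- base$truth
  plantedSites <- truth$sites$site[truth$sites$planted]
  plantedDeg <- truth$genes$gene_id[truth$genes$planted_de |
                                    truth$genes$coupled |
                                    truth$genes$cascade_target]
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    meth <- simulateMethylome(cfg, truth, seed = seed + 7L * r)
    filt <- filterCoverage(meth)
    dms <- callDMS(filt, cfg$groupLabels[1], cfg$groupLabels[2])
    called <- dms$site[dms$direction != "ns"]
    expr <- simulateExpression(cfg, truth, seed = seed + 7L * r + 3L)
    de <- testDE(expr$geneCounts, cfg$groupLabels[1], cfg$groupLabels[2],
                 tierScheme = NULL)
    calledDeg <- de$feature_id[de$is_de]
    rows[[r]] <- data.frame(
      dms_tp = length(intersect(called, plantedSites)),
      dms_called = length(called),
      deg_tp = length(intersect(calledDeg, plantedDeg)),
      deg_called = length(calledDeg))
  }
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- c(
    dms_sensitivity = sum(out$dms_tp) / (nReps * length(plantedSites)),
    dms_fdr = 1 - sum(out$dms_tp) / sum(out$dms_called),
    deg_sensitivity = sum(out$deg_tp) / (nReps * length(plantedDeg)),
    deg_fdr = 1 - sum(out$deg_tp) / sum(out$deg_called))
  out
}

#' Recovery of the methylation-expression integration layer
#'
#' Per replicate, runs the integration stages (site-gene pairing,
#' stratified Spearman table, methylation-dependent gene selection) and
#' scores promoter-class recovery against the planted promoter-coupled
#' genes; also records the gene-body "all genes" stratum correlations,
#' which the generator leaves uncoupled, together with the half-width of
#' their 95% null band (1.96 / sqrt(n - 1)).
#'
#' @inheritParams nullCalibration
#' @return data.frame per replicate; pooled summary in the `pooled`
#'   attribute.
#' @export
integrationRecovery <- function(cfg = simulationConfig(), nReps = 200L,
                                seed = cfg$seed) {
  base <- .studyBase(cfg)
  truth <- base$truth
  coupled <- truth$genes$gene_id[truth$genes$coupled]
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    meth <- simulateMethylome(cfg, truth, seed = seed + 7L * r)
    filt <- filterCoverage(meth)
    dms <- callDMS(filt, cfg$groupLabels[1], cfg$groupLabels[2])
    expr <- simulateExpression(cfg, truth, seed = seed + 7L * r + 3L)
    de <- testDE(expr$geneCounts, cfg$groupLabels[1], cfg$groupLabels[2])
    asg <- assignSites(filt, base$geneIndex)
    pairs <- buildPairs(dms, asg, de, groupA = cfg$groupLabels[1],
                        groupB = cfg$groupLabels[2])
    sel <- selectMethylationDependent(pairs)
    strata <- stratumTable(pairs)
    body <- strata[strata$expr_class == "all" &
                   strata$region == "gene_body", ]
    rows[[r]] <- data.frame(
      prom_tp = length(intersect(sel$promoter$gene_id, coupled)),
      prom_called = nrow(sel$promoter),
      body_rho_hyper = body$spearman_rho[body$direction == "hyper"],
      body_n_hyper = body$n_cpg[body$direction == "hyper"],
      body_rho_hypo = body$spearman_rho[body$direction == "hypo"],
      body_n_hypo = body$n_cpg[body$direction == "hypo"])
  }
  out <- do.call(rbind, rows)
  bodyRho <- c(out$body_rho_hyper, out$body_rho_hypo)
  bodyN <- c(out$body_n_hyper, out$body_n_hypo)
  ok <- !is.na(bodyRho) & bodyN >= 3
  attr(out, "pooled") <- c(
    promoter_sensitivity = sum(out$prom_tp) / (nReps * length(coupled)),
    promoter_fdr = 1 - sum(out$prom_tp) / sum(out$prom_called),
    body_rho_in_null_band =
      mean(abs(bodyRho[ok]) <= 1.96 / sqrt(bodyN[ok] - 1)),
    body_rho_mean = mean(bodyRho[ok]))
  out
}

#' Cascade recovery and false-chain calibration
#'
#' With `null = FALSE`, simulates replicates under the default planted
#' cascade and reports per replicate how many chains are built and how
#' many planted target links each recovered chain carries. With
#' `null = TRUE`, cascades (and any other planted miRNA differential
#' signal) are removed and the number of spurious chains is counted.
#'
#' @inheritParams nullCalibration
#' @param null remove planted cascades first.
#' @return data.frame per replicate (`n_chains`, `n_links`,
#'   `n_strong_links`, `planted_links_recovered`).
#' @export
cascadeStudy <- function(cfg = simulationConfig(), nReps = 1L,
                         seed = cfg$seed, null = FALSE) {
  if (null) {
    cfg$nCascades <- 0L
    cfg$mirnaDeFraction <- 0
  }
  base <- .studyBase(cfg)
  truth <- base$truth
  plantedPairs <- if (!is.null(truth$pairs))
    paste(truth$pairs$mirna_id, truth$pairs$gene_id) else character(0)
  seqs <- simulateSequences(cfg, truth)
  targetMap <- predictTargetsSeed(seqs$mirna, seqs$utr)
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    meth <- simulateMethylome(cfg, truth, seed = seed + 7L * r)
    filt <- filterCoverage(meth)
    dms <- callDMS(filt, cfg$groupLabels[1], cfg$groupLabels[2])
    expr <- simulateExpression(cfg, truth, seed = seed + 7L * r + 3L)
    geneDE <- testDE(expr$geneCounts, cfg$groupLabels[1],
                     cfg$groupLabels[2])
    mirnaDE <- testDE(expr$mirnaCounts, cfg$groupLabels[1],
                      cfg$groupLabels[2], tierScheme = NULL)
    mirPairs <- correlatePairs(targetMap, attr(mirnaDE, "normalized"),
                               attr(geneDE, "normalized"), geneDE)
    promMap <- mirnaPromoterDMS(base$mirnaIndex, dms)
    chains <- buildChains(promMap, mirnaDE, mirPairs, filt,
                          attr(mirnaDE, "normalized"))
    summ <- attr(chains, "chains")
    calledPairs <- paste(chains$mirna_id, chains$gene_id)
    rows[[r]] <- data.frame(
      n_chains = nrow(summ),
      n_links = nrow(chains),
      n_strong_links = if (nrow(chains)) sum(chains$strong) else 0L,
      planted_links_recovered = length(intersect(calledPairs,
                                                 plantedPairs)))
  }
  do.call(rbind, rows)
}
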