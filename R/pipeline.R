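# End-to-end orchestration: one config drives simulation (or file
# loading), per-comparison differential calls, integration, the miRNA
# layer and chain construction, with deterministic TSV outputs and a run
# manifest. Execution is single-process and a pure function of
# (inputs, config, seed).

#' Default pipeline configuration
#'
#' @param seed RNG seed, used for the simulate block.
#' @param outDir output directory (created on run).
#' @param simulate a [simulationConfig()] (set `NULL` when loading files).
#' @param minDiff,maxQ DMS thresholds (25 percentage points, q < 0.01).
#' @param maxPadj,minLfc DE thresholds (padj < 0.05, |log2FC| >= 1).
#' @param targetR miRNA-target retention threshold (r < -0.9).
#' @param minCov,maxPctile coverage-filter settings.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("triomix_run_"),
                           simulate = simulationConfig(seed = seed),
                           minDiff = 25, maxQ = 0.01, maxPadj = 0.05,
                           minLfc = 1, targetR = -0.9, minCov = 10L,
                           maxPctile = 99.9) {
  stopifnot(minDiff >= 0, minDiff <= 101, maxQ > 0, maxQ <= 1,
            maxPadj > 0, maxPadj <= 1, targetR >= -1, targetR <= 1)
  cfg <- list(seed = as.integer(seed), outDir = outDir, simulate = simulate,
              minDiff = minDiff, maxQ = maxQ, maxPadj = maxPadj,
              minLfc = minLfc, targetR = targetR, minCov = minCov,
              maxPctile = maxPctile)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a
#' `simulate:` mapping is passed to [simulationConfig()]. Unknown keys
#' are an error.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$simulate)) {
    simKnown <- names(formals(simulationConfig))
    badSim <- setdiff(names(y$simulate), simKnown)
    if (length(badSim))
      stop("unknown simulate key(s): ", paste(badSim, collapse = ", "))
    if (is.null(y$simulate$seed) && !is.null(y$seed))
      y$simulate$seed <- y$seed
    y$simulate <- do.call(simulationConfig, y$simulate)
  }
  do.call(pipelineConfig, y)
}

#' Run the full integrative pipeline
#'
#' Simulates (or accepts) a tri-omics dataset and runs every stage for
#' the comparison defined by the dataset's two groups: coverage
#' filtering, DMS calling (TSV + BED + feature distribution), gene and
#' miRNA differential expression, site-gene pairing with stratified
#' Spearman summaries, methylation-dependent gene selection, seed-match
#' target prediction, miRNA-target correlation filtering and regulatory
#' chain construction. Stage outputs and a run manifest are written
#' under `config$outDir`; repeated runs with the same config and seed
#' are byte-identical.
#'
#' @param config a [pipelineConfig()] (or YAML path).
#' @param dataset optionally a precomputed [simulateDataset()] result
#'   (bypasses the simulate block; used for file-based runs too).
#' @return invisibly, a list with every stage's in-memory result.
#' @export
runPipeline <- function(config, dataset = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is.null(dataset)) {
    if (is.null(config$simulate))
      stop("no dataset given and no simulate block in the config")
    dataset <- simulateDataset(config$simulate)
  }
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grp <- sampleGroups(dataset$meth)
  labels <- unique(grp)
  if (length(labels) != 2)
    stop("the dataset must define exactly two groups")
  A <- labels[1]; B <- labels[2]
  comparison <- paste0(A, "vs", B)
  counts <- list()

  geneIndex <- deriveRegions(dataset$geneModels)
  mirnaIndex <- deriveRegions(dataset$mirnaModels)

  filtered <- filterCoverage(dataset$meth, minCov = config$minCov,
                             maxPctile = config$maxPctile)
  counts$sites_after_filter <- nrow(filtered)
  counts$sites_removed_by_filter <- attr(filtered, "removed")

  dms <- callDMS(filtered, A, B, minDiff = config$minDiff,
                 maxQ = config$maxQ)
  counts$dms <- sum(dms$direction != "ns")
  writeTsv(dms, file.path(out, paste0("dms_", comparison, ".tsv")))
  writeDMSBed(dms, file.path(out, paste0("dms_", comparison, ".bed")))
  featDist <- featureDistribution(dms, geneIndex)
  writeTsv(featDist, file.path(out, paste0("dms_features_", comparison,
                                           ".tsv")))

  geneDE <- testDE(dataset$geneCounts, A, B, maxPadj = config$maxPadj,
                   minLfc = config$minLfc)
  counts$de_genes <- sum(geneDE$is_de)
  writeTsv(geneDE, file.path(out, paste0("de_genes_", comparison, ".tsv")))
  mirnaDE <- NULL
  if (!is.null(dataset$mirnaCounts)) {
    mirnaDE <- testDE(dataset$mirnaCounts, A, B, maxPadj = config$maxPadj,
                      minLfc = config$minLfc, tierScheme = NULL)
    counts$de_mirnas <- sum(mirnaDE$is_de)
    writeTsv(mirnaDE, file.path(out, paste0("de_mirnas_", comparison,
                                            ".tsv")))
  }

  assignments <- assignSites(filtered, geneIndex)
  pairs <- buildPairs(dms, assignments, geneDE, groupA = A, groupB = B)
  counts$site_gene_pairs <- nrow(pairs)
  writeTsv(pairs, file.path(out, paste0("pairs_", comparison, ".tsv")))
  strata <- stratumTable(pairs)
  writeTsv(strata, file.path(out, paste0("strata_", comparison, ".tsv")))

  methDep <- selectMethylationDependent(pairs, maxPadj = config$maxPadj,
                                        minAbsLfc = config$minLfc)
  counts$promoter_class_genes <- nrow(methDep$promoter)
  counts$body_class_genes <- nrow(methDep$body)
  writeTsv(methDep$promoter,
           file.path(out, paste0("methdep_promoter_", comparison, ".tsv")))
  writeTsv(methDep$body,
           file.path(out, paste0("methdep_body_", comparison, ".tsv")))

  mirPairs <- NULL; chains <- NULL; promoterMap <- NULL
  if (!is.null(mirnaDE)) {
    targetMap <- predictTargetsSeed(dataset$sequences$mirna,
                                    dataset$sequences$utr)
    counts$predicted_target_pairs <- nrow(targetMap)
    writeTsv(targetMap, file.path(out, "target_map.tsv"))
    mirPairs <- correlatePairs(targetMap, attr(mirnaDE, "normalized"),
                               attr(geneDE, "normalized"), geneDE,
                               rCutoff = config$targetR)
    counts$retained_mirna_pairs <- sum(mirPairs$retained)
    writeTsv(mirPairs, file.path(out, paste0("mirna_pairs_", comparison,
                                             ".tsv")))
    promoterMap <- mirnaPromoterDMS(mirnaIndex, dms)
    writeTsv(promoterMap, file.path(out, paste0("mirna_promoter_dms_",
                                                comparison, ".tsv")))
    chains <- buildChains(promoterMap, mirnaDE, mirPairs, filtered,
                          attr(mirnaDE, "normalized"),
                          rCutoff = config$targetR)
    counts$chains <- nrow(attr(chains, "chains"))
    writeTsv(chains, file.path(out, paste0("chains_", comparison, ".tsv")))
    writeTsv(attr(chains, "chains"),
             file.path(out, paste0("chain_summary_", comparison, ".tsv")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("triomix")),
    seed = config$seed, comparison = comparison,
    thresholds = config[c("minDiff", "maxQ", "maxPadj", "minLfc",
                          "targetR", "minCov", "maxPctile")],
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, dataset = dataset,
                 comparison = comparison, filtered = filtered, dms = dms,
                 featureDistribution = featDist, geneDE = geneDE,
                 mirnaDE = mirnaDE, assignments = assignments,
                 pairs = pairs, strata = strata, methDep = methDep,
                 mirPairs = mirPairs, promoterMap = promoterMap,
                 chains = chains, counts = counts))
}

.rate <- function(num, den) if (den > 0) num / den else NA_real_

#' Score a simulated run against its planted truth
#'
#' Per planted-effect class — DMS, DEG (genes), promoter-coupled gene,
#' miRNA-target pair, cascade chain — reports sensitivity (recovered /
#' planted) and empirical FDR (false calls / calls). With nothing
#' planted in a class, sensitivity is NA and the false-positive count is
#' still reported.
#'
#' @param run a [runPipeline()] result from a simulated dataset.
#' @param truth the matching truth tables ([planTruth()] /
#'   `dataset$truth`).
#' @return data.frame with one row per class.
#' @export
evaluateAgainstTruth <- function(run, truth) {
  rows <- list()
  .row <- function(class, planted, called) {
    tp <- length(intersect(planted, called))
    rows[[length(rows) + 1]] <<- data.frame(
      class = class, n_planted = length(planted), n_called = length(called),
      tp = tp,
      sensitivity = .rate(tp, length(planted)),
      fdr = .rate(length(called) - tp, length(called)),
      stringsAsFactors = FALSE)
  }
  plantedSites <- truth$sites$site[truth$sites$planted]
  calledSites <- run$dms$site[run$dms$direction != "ns"]
  .row("dms", plantedSites, calledSites)

  plantedDeg <- truth$genes$gene_id[truth$genes$planted_de |
                                    truth$genes$coupled |
                                    truth$genes$cascade_target]
  calledDeg <- run$geneDE$feature_id[run$geneDE$is_de]
  .row("deg", plantedDeg, calledDeg)

  .row("promoter_coupled", truth$genes$gene_id[truth$genes$coupled],
       run$methDep$promoter$gene_id)

  plantedPairs <- if (!is.null(truth$pairs))
    paste(truth$pairs$mirna_id, truth$pairs$gene_id) else character(0)
  calledPairs <- if (!is.null(run$mirPairs))
    with(run$mirPairs[run$mirPairs$retained, , drop = FALSE],
         paste(mirna_id, gene_id)) else character(0)
  .row("mirna_target_pair", plantedPairs, calledPairs)

  plantedChains <- if (!is.null(truth$cascades)) truth$cascades$mirna_id
                   else character(0)
  calledChains <- if (!is.null(run$chains))
    attr(run$chains, "chains")$mirna_id else character(0)
  .row("cascade_chain", plantedChains, calledChains)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
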