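# Coupled tri-omics simulator with planted truth. The design emulates a
# two-tissue RRBS + RNA-seq + miRNA-seq study on a small number of
# animals (default 4 vs 4 samples): beta-binomial methylation counts over
# NB-distributed coverage, NB expression counts with log-normal gene
# baselines, planted differential sites/genes, promoter-coupled genes
# whose expression responds (oppositely) to their promoter methylation
# shift, and methylation -> miRNA -> mRNA cascades driven by a shared
# per-sample latent factor so that rank correlations, not just group
# means, carry the planted signal.

#' Simulation configuration
#'
#' All knobs of the planted-truth generator. Defaults describe the study
#' conditions every calibration and recovery benchmark runs under: ~2000
#' CpG sites (200 genes x 8 CpGs, 20 miRNA genes x 4 promoter CpGs, 320
#' intergenic sites), 4 vs 4 samples, 30x mean coverage, beta-binomial
#' precision 30, 15% planted DMSs with 40-point shifts, 15% planted DE
#' genes at |log2FC| = 2, 15 promoter-coupled genes and one planted
#' cascade with 6 anti-coupled targets.
#'
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param nGenes,nMirnas numbers of protein-coding and miRNA genes.
#' @param nCpgPromoter,nCpgBody CpGs per gene promoter / gene body.
#' @param nCpgMirnaPromoter CpGs per miRNA promoter.
#' @param nIntergenicCpg intergenic CpGs.
#' @param nPerGroup samples per group, length 2 (a 4 vs 3 design mirrors
#'   a dropped replicate).
#' @param groupLabels the two tissue-group labels; comparisons are
#'   `A minus B`.
#' @param coverageMean,coverageShape NB coverage model (mean, size).
#' @param bbPrecision beta-binomial precision of methylation proportions.
#' @param dmsFraction fraction of CpGs carrying a planted shift.
#' @param dmsShiftPp planted methylation shift, percentage points.
#' @param deFraction fraction of genes with a planted expression change.
#' @param deLog2fc planted |log2 fold change|.
#' @param mirnaDeFraction fraction of miRNAs with a planted expression
#'   change outside cascades (default 0: differential miRNA signal enters
#'   through cascades).
#' @param nCoupledGenes genes whose promoter methylation shift drives an
#'   opposite-sign expression change.
#' @param couplingStrength scales the coupled genes' expression response.
#' @param nCascades planted methylation -> miRNA -> target cascades.
#' @param cascadeTargets target genes per cascade.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 200L, nMirnas = 20L,
                             nCpgPromoter = 3L, nCpgBody = 5L,
                             nCpgMirnaPromoter = 4L, nIntergenicCpg = 320L,
                             nPerGroup = c(4L, 4L),
                             groupLabels = c("A", "B"),
                             coverageMean = 30, coverageShape = 50,
                             bbPrecision = 30,
                             dmsFraction = 0.15, dmsShiftPp = 40,
                             deFraction = 0.15, deLog2fc = 2,
                             mirnaDeFraction = 0,
                             nCoupledGenes = 15L, couplingStrength = 1,
                             nCascades = 1L, cascadeTargets = 6L) {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nMirnas = as.integer(nMirnas),
              nCpgPromoter = as.integer(nCpgPromoter),
              nCpgBody = as.integer(nCpgBody),
              nCpgMirnaPromoter = as.integer(nCpgMirnaPromoter),
              nIntergenicCpg = as.integer(nIntergenicCpg),
              nPerGroup = as.integer(nPerGroup),
              groupLabels = groupLabels,
              coverageMean = coverageMean, coverageShape = coverageShape,
              bbPrecision = bbPrecision,
              dmsFraction = dmsFraction, dmsShiftPp = dmsShiftPp,
              deFraction = deFraction, deLog2fc = deLog2fc,
              mirnaDeFraction = mirnaDeFraction,
              nCoupledGenes = as.integer(nCoupledGenes),
              couplingStrength = couplingStrength,
              nCascades = as.integer(nCascades),
              cascadeTargets = as.integer(cascadeTargets))
  stopifnot(cfg$nGenes >= 1, cfg$nMirnas >= 0,
            length(cfg$nPerGroup) == 2, all(cfg$nPerGroup >= 1),
            length(cfg$groupLabels) == 2,
            cfg$dmsFraction >= 0, cfg$dmsFraction <= 1,
            cfg$deFraction >= 0, cfg$deFraction <= 1,
            cfg$dmsShiftPp > 0, cfg$dmsShiftPp < 100,
            cfg$coverageMean > 0, cfg$bbPrecision > 0)
  if (cfg$nCascades > 0 && cfg$nMirnas == 0)
    stop("cascades requested but nMirnas is 0")
  if (cfg$nCoupledGenes + cfg$nCascades * cfg$cascadeTargets +
      round(cfg$deFraction * cfg$nGenes) > cfg$nGenes)
    stop("more planted genes requested than genes available")
  class(cfg) <- "SimulationConfig"
  cfg
}

# fixed toy-genome layout constants (bp)
.simLayout <- list(
  exonLen = 300L, intronLen = 1500L, utrLen = 150L, buffer = 2000L,
  geneStride = 8500L, interZoneOff = 7500L, interZoneLen = 1000L,
  mirnaLen = 100L, mirnaStride = 4000L, mirnaBuffer = 1800L)

#' Simulate a toy genome annotation
#'
#' Lays non-overlapping three-exon genes (with a 150 bp 5'UTR at the
#' start of the first exon) and short single-exon miRNA genes on one toy
#' chromosome, with random strands. Deterministic under the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `geneModels` and `mirnaModels`
#'   ([GeneModels-class]) and `intergenicZones` (GRanges guaranteed at
#'   least 1500 bp from any gene or promoter).
#' @export
simulateAnnotation <- function(cfg) {
  set.seed(cfg$seed)
  L <- .simLayout
  spanLen <- 3L * L$exonLen + 2L * L$intronLen        # 3900
  ids <- sprintf("gene%03d", seq_len(cfg$nGenes))
  strands <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  s <- (seq_len(cfg$nGenes) - 1L) * L$geneStride + L$buffer
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(s, width = spanLen), strand = strands)
  genes$gene_id <- ids
  exonOff <- c(0L, L$exonLen + L$intronLen, 2L * (L$exonLen + L$intronLen))
  exStart <- rep(s, each = 3L) + rep(exonOff, cfg$nGenes)
  exGr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(exStart, width = L$exonLen),
    strand = rep(strands, each = 3L))
  exons <- GenomicRanges::split(exGr,
    factor(rep(ids, each = 3L), levels = ids))
  utrStart <- ifelse(strands == "+", s, s + spanLen - L$utrLen)
  utrGr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(utrStart, width = L$utrLen), strand = strands)
  utr5 <- GenomicRanges::split(utrGr, factor(ids, levels = ids))
  geneModels <- new("GeneModels", genes = genes, exons = exons, utr5 = utr5)

  zones <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = (seq_len(cfg$nGenes) - 1L) * L$geneStride + L$interZoneOff + 1L,
    width = L$interZoneLen))

  mirBase <- cfg$nGenes * L$geneStride
  mids <- sprintf("mir%03d", seq_len(cfg$nMirnas))
  mStrands <- if (cfg$nMirnas) sample(c("+", "-"), cfg$nMirnas, TRUE)
              else character(0)
  mStart <- mirBase + (seq_len(cfg$nMirnas) - 1L) * L$mirnaStride +
    L$mirnaBuffer
  mGenes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(mStart, width = L$mirnaLen), strand = mStrands)
  mGenes$gene_id <- mids
  mExons <- GenomicRanges::GRangesList(lapply(seq_len(cfg$nMirnas),
    function(i) GenomicRanges::GRanges("chr1",
      IRanges::IRanges(mStart[i], width = L$mirnaLen),
      strand = mStrands[i])))
  mUtr <- GenomicRanges::GRangesList(lapply(seq_len(cfg$nMirnas),
    function(i) GenomicRanges::GRanges()))
  names(mExons) <- names(mUtr) <- mids
  mirnaModels <- new("GeneModels", genes = mGenes, exons = mExons,
                     utr5 = mUtr)
  list(geneModels = geneModels, mirnaModels = mirnaModels,
       intergenicZones = zones)
}

#' Write gene models as GTF text
#' @param models a [GeneModels-class].
#' @param path output path.
#' @param append append instead of overwrite.
#' @export
writeGTF <- function(models, path, append = FALSE) {
  lines <- character(0)
  g <- models@genes
  .row <- function(type, start, end, strand, gid) {
    sprintf("chr1\ttriomix\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            type, start, end, strand, gid, gid)
  }
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    st <- as.character(GenomicRanges::strand(g))[i]
    lines <- c(lines, .row("gene", GenomicRanges::start(g)[i],
                           GenomicRanges::end(g)[i], st, gid))
    ex <- models@exons[[gid]]
    for (j in seq_along(ex))
      lines <- c(lines, .row("exon", GenomicRanges::start(ex)[j],
                             GenomicRanges::end(ex)[j], st, gid))
    ut <- models@utr5[[gid]]
    for (j in seq_along(ut))
      lines <- c(lines, .row("five_prime_utr", GenomicRanges::start(ut)[j],
                             GenomicRanges::end(ut)[j], st, gid))
  }
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

# sample k distinct positions from a set of intervals (GRanges)
.samplePositions <- function(gr, k) {
  pos <- unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
  k <- min(k, length(pos))
  sort(pos[sample.int(length(pos), k)])
}

#' Plan the planted truth of a simulated study
#'
#' Chooses CpG positions (promoter/exon/intron per gene, miRNA promoter,
#' intergenic), planted differential sites (randomly planted sites follow
#' feature-class weights emulating observed DMS distributions: promoter
#' 0.04, exon 0.08, intron 0.44, intergenic 0.44), planted DE genes,
#' promoter-coupled genes (variable shift 30-55 points with a
#' proportional opposite-sign expression response) and cascades.
#'
#' @param cfg a [simulationConfig()].
#' @param ann a [simulateAnnotation()] result.
#' @return list of truth tables: `sites`, `genes`, `mirnas`, `cascades`,
#'   `pairs`.
#' @export
planTruth <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  geneIdx <- deriveRegions(ann$geneModels)
  mirIdx <- deriveRegions(ann$mirnaModels)
  reg <- regionRanges(geneIdx)
  ids <- names(ann$geneModels)
  mids <- names(ann$mirnaModels)

  regDf <- data.frame(gene_id = reg$gene_id,
                      region = reg$region,
                      start = GenomicRanges::start(reg),
                      end = GenomicRanges::end(reg),
                      stringsAsFactors = FALSE)
  bySub <- split(regDf, regDf$gene_id)
  .pickPos <- function(df, k) {
    pos <- unlist(Map(seq, df$start, df$end))
    k <- min(k, length(pos))
    sort(pos[sample.int(length(pos), k)])
  }
  rows <- list()
  for (gid in ids) {
    sub <- bySub[[gid]]
    pPos <- .pickPos(sub[sub$region == "promoter", ], cfg$nCpgPromoter)
    bodyIv <- sub[sub$region %in% c("exon", "intron"), ]
    bPos <- .pickPos(bodyIv, cfg$nCpgBody)
    bClass <- vapply(bPos, function(p)
      bodyIv$region[bodyIv$start <= p & bodyIv$end >= p][1], character(1))
    rows[[gid]] <- data.frame(
      pos = c(pPos, bPos),
      class = c(rep("promoter", length(pPos)), bClass),
      gene_id = gid, stringsAsFactors = FALSE)
  }
  mreg <- regionRanges(mirIdx)
  mregDf <- data.frame(gene_id = mreg$gene_id, region = mreg$region,
                       start = GenomicRanges::start(mreg),
                       end = GenomicRanges::end(mreg),
                       stringsAsFactors = FALSE)
  mBySub <- split(mregDf, mregDf$gene_id)
  for (m in mids) {
    sub <- mBySub[[m]]
    rows[[m]] <- data.frame(
      pos = .pickPos(sub[sub$region == "promoter", ],
                     cfg$nCpgMirnaPromoter),
      class = "mirna_promoter", gene_id = m, stringsAsFactors = FALSE)
  }
  rows[["intergenic"]] <- data.frame(
    pos = .samplePositions(ann$intergenicZones, cfg$nIntergenicCpg),
    class = "intergenic", gene_id = NA_character_, stringsAsFactors = FALSE)
  sites <- do.call(rbind, rows)
  sites <- sites[!duplicated(sites$pos), ]
  sites$chrom <- "chr1"
  sites$strand <- sample(c("+", "-"), nrow(sites), replace = TRUE)
  sites$site <- paste(sites$chrom, sites$pos, sites$strand, sep = ":")
  sites$planted <- FALSE
  sites$direction <- NA_character_
  sites$shift <- 0
  sites$purpose <- NA_character_
  rownames(sites) <- NULL

  genes <- data.frame(gene_id = ids, planted_de = FALSE, log2fc = 0,
                      coupled = FALSE, coupling_label = NA_character_,
                      cascade_target = FALSE, cascade_mirna = NA_character_,
                      stringsAsFactors = FALSE)
  mirnas <- data.frame(mirna_id = mids, cascade = FALSE, log2fc = 0,
                       stringsAsFactors = FALSE)

  # cascades: hypermethylated miRNA promoter, miRNA down, targets up
  cascades <- NULL; pairs <- NULL
  freeGenes <- ids
  if (cfg$nCascades > 0) {
    casMirs <- sample(mids, cfg$nCascades)
    for (m in casMirs) {
      mirnas$cascade[mirnas$mirna_id == m] <- TRUE
      pIdx <- which(sites$gene_id == m & sites$class == "mirna_promoter")
      pIdx <- pIdx[seq_len(min(3L, length(pIdx)))]
      sites$planted[pIdx] <- TRUE
      sites$direction[pIdx] <- "hyper"
      sites$shift[pIdx] <- cfg$dmsShiftPp / 100
      sites$purpose[pIdx] <- "cascade"
      tg <- sample(freeGenes, cfg$cascadeTargets)
      freeGenes <- setdiff(freeGenes, tg)
      genes$cascade_target[genes$gene_id %in% tg] <- TRUE
      genes$cascade_mirna[genes$gene_id %in% tg] <- m
      cascades <- rbind(cascades, data.frame(
        mirna_id = m, targets = paste(tg, collapse = ","),
        n_promoter_dms = length(pIdx), stringsAsFactors = FALSE))
      pairs <- rbind(pairs, data.frame(mirna_id = m, gene_id = tg,
                                       stringsAsFactors = FALSE))
    }
  }

  # promoter-coupled genes: variable shift, proportional expression response
  if (cfg$nCoupledGenes > 0) {
    coupled <- sample(freeGenes, cfg$nCoupledGenes)
    freeGenes <- setdiff(freeGenes, coupled)
    dirs <- rep(c("hyper", "hypo"), length.out = cfg$nCoupledGenes)
    shifts <- runif(cfg$nCoupledGenes, 0.30, 0.55)
    for (i in seq_along(coupled)) {
      gid <- coupled[i]
      pIdx <- which(sites$gene_id == gid & sites$class == "promoter")
      pIdx <- pIdx[seq_len(min(2L, length(pIdx)))]
      sites$planted[pIdx] <- TRUE
      sites$direction[pIdx] <- dirs[i]
      sites$shift[pIdx] <- shifts[i]
      sites$purpose[pIdx] <- "coupled"
      lfc <- cfg$couplingStrength * (1.2 + 2.8 * (shifts[i] - 0.30) / 0.25)
      genes$coupled[genes$gene_id == gid] <- TRUE
      genes$coupling_label[genes$gene_id == gid] <- paste0(dirs[i], "meth")
      genes$log2fc[genes$gene_id == gid] <-
        if (dirs[i] == "hyper") -lfc else lfc
    }
  }

  # plain planted DE genes
  nDE <- round(cfg$deFraction * cfg$nGenes)
  if (nDE > 0) {
    deg <- sample(freeGenes, nDE)
    genes$planted_de[genes$gene_id %in% deg] <- TRUE
    genes$log2fc[genes$gene_id %in% deg] <-
      sample(c(-1, 1), nDE, TRUE) * cfg$deLog2fc
  }
  nDEmir <- round(cfg$mirnaDeFraction * cfg$nMirnas)
  if (nDEmir > 0) {
    dm <- sample(mirnas$mirna_id[!mirnas$cascade], nDEmir)
    mirnas$log2fc[mirnas$mirna_id %in% dm] <-
      sample(c(-1, 1), nDEmir, TRUE) * cfg$deLog2fc
  }

  # randomly planted DMSs with feature-class weights
  nPlanted <- round(cfg$dmsFraction * nrow(sites))
  nRandom <- max(0L, nPlanted - sum(sites$planted))
  if (nRandom > 0) {
    wts <- c(promoter = 0.04, mirna_promoter = 0.04, exon = 0.08,
             intron = 0.44, intergenic = 0.44)
    avail <- which(!sites$planted)
    w <- wts[sites$class[avail]]
    w <- w / sum(w)
    pick <- sample(avail, min(nRandom, length(avail)), prob = w)
    sites$planted[pick] <- TRUE
    sites$direction[pick] <- sample(c("hyper", "hypo"), length(pick), TRUE)
    sites$shift[pick] <- cfg$dmsShiftPp / 100
    sites$purpose[pick] <- "random"
  }
  list(sites = sites, genes = genes, mirnas = mirnas,
       cascades = cascades, pairs = pairs)
}

.sampleNames <- function(cfg) {
  c(paste0(cfg$groupLabels[1], "_", seq_len(cfg$nPerGroup[1])),
    paste0(cfg$groupLabels[2], "_", seq_len(cfg$nPerGroup[2])))
}

#' Simulate a beta-binomial RRBS methylome with planted shifts
#'
#' Per CpG a region-class baseline proportion is drawn (promoters low,
#' bodies high); planted sites shift the first group's proportion by
#' their planted amount (hyper: up in group A), clipped to (0, 1).
#' Per-sample proportions are beta-distributed around the group value
#' (precision `bbPrecision`) and methylated counts binomial given
#' NB-distributed coverage.
#'
#' @param cfg a [simulationConfig()].
#' @param truth a [planTruth()] result.
#' @param seed RNG seed for this layer (default derives from the config).
#' @return a [MethylationSet-class].
#' @export
simulateMethylome <- function(cfg, truth, seed = cfg$seed + 2L) {
  set.seed(seed)
  st <- truth$sites
  n <- nrow(st)
  baseFor <- function(class) switch(class,
    promoter = , mirna_promoter = runif(1, 0.05, 0.20),
    exon = , intron = runif(1, 0.55, 0.85),
    intergenic = runif(1, 0.30, 0.70))
  base <- vapply(st$class, baseFor, numeric(1))
  # planted sites: direction-aware baseline so the shift stays in range
  pl <- which(st$planted)
  for (i in pl) {
    s <- st$shift[i]
    base[i] <- if (st$direction[i] == "hyper") runif(1, 0.03, 0.95 - s)
               else runif(1, 0.03 + s, 0.95)
  }
  pA <- base
  pA[pl] <- base[pl] + ifelse(st$direction[pl] == "hyper", 1, -1) * st$shift[pl]
  pB <- base
  clip <- function(p) pmin(pmax(p, 0.002), 0.998)
  pA <- clip(pA); pB <- clip(pB)

  samples <- .sampleNames(cfg)
  grp <- rep(cfg$groupLabels, cfg$nPerGroup)
  cov <- matrix(rnbinom(n * length(samples), mu = cfg$coverageMean,
                        size = cfg$coverageShape),
                nrow = n, dimnames = list(NULL, samples))
  met <- matrix(0L, nrow = n, ncol = length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    p <- if (grp[j] == cfg$groupLabels[1]) pA else pB
    theta <- rbeta(n, cfg$bbPrecision * p, cfg$bbPrecision * (1 - p))
    met[, j] <- rbinom(n, cov[, j], theta)
  }
  MethylationSet(coverage = cov, methylated = met, chrom = st$chrom,
                 pos = st$pos, strand = st$strand,
                 group = setNames(grp, samples))
}

#' Simulate coupled gene and miRNA count tables
#'
#' NB counts with log-normal gene baselines and per-sample library size
#' factors; planted DE genes and coupled genes receive their truth-table
#' log2 fold changes (group A over B). Cascade miRNAs and their targets
#' additionally load on a shared per-sample latent factor (miRNA
#' negatively, targets positively) so sample-level miRNA-target rank
#' correlations are strongly negative.
#'
#' @inheritParams simulateMethylome
#' @return list with `geneCounts` and `mirnaCounts`
#'   ([CountSet-class]) and the per-sample `latent` factors.
#' @export
simulateExpression <- function(cfg, truth, seed = cfg$seed + 3L) {
  set.seed(seed)
  samples <- .sampleNames(cfg)
  grp <- rep(cfg$groupLabels, cfg$nPerGroup)
  isA <- grp == cfg$groupLabels[1]
  nS <- length(samples)
  sfGene <- rlnorm(nS, 0, 0.15)
  sfMir <- rlnorm(nS, 0, 0.15)

  g <- truth$genes
  nG <- nrow(g)
  base <- rlnorm(nG, log(100), 1)
  special <- g$coupled | g$cascade_target
  base[special] <- rlnorm(sum(special), log(200), 0.4)
  alpha <- rlnorm(nG, log(0.05), 0.3)
  alpha[g$cascade_target] <- 0.02

  # latent per-sample factors, one per cascade
  latent <- NULL
  if (!is.null(truth$cascades)) {
    latent <- matrix(rnorm(nrow(truth$cascades) * nS, 0, 0.5),
                     nrow = nrow(truth$cascades),
                     dimnames = list(truth$cascades$mirna_id, samples))
    latent <- latent + 2 * rep(1, nrow(truth$cascades)) %o% as.numeric(isA)
  }

  mu <- base %o% sfGene
  mu <- mu * 2^(g$log2fc %o% as.numeric(isA))
  if (!is.null(latent)) {
    for (ci in seq_len(nrow(truth$cascades))) {
      m <- truth$cascades$mirna_id[ci]
      tg <- g$cascade_target & !is.na(g$cascade_mirna) & g$cascade_mirna == m
      # targets: up in A via the latent factor only (0.7 loading)
      mu[tg, ] <- (base[tg] %o% sfGene) *
        exp(matrix(0.7 * latent[ci, ], sum(tg), nS, byrow = TRUE))
    }
  }
  geneCounts <- matrix(rnbinom(nG * nS, mu = mu, size = 1 / alpha),
                       nrow = nG, dimnames = list(g$gene_id, samples))

  mt <- truth$mirnas
  nM <- nrow(mt)
  mirnaCounts <- NULL
  if (nM > 0) {
    mBase <- rlnorm(nM, log(300), 0.8)
    mAlpha <- rlnorm(nM, log(0.05), 0.3)
    mAlpha[mt$cascade] <- 0.02
    mMu <- mBase %o% sfMir
    mMu <- mMu * 2^(mt$log2fc %o% as.numeric(isA))
    if (!is.null(latent)) {
      for (ci in seq_len(nrow(truth$cascades))) {
        m <- truth$cascades$mirna_id[ci]
        k <- which(mt$mirna_id == m)
        mMu[k, ] <- (mBase[k] * sfMir) * exp(-1.0 * latent[ci, ])
      }
    }
    mirnaCounts <- matrix(rnbinom(nM * nS, mu = mMu, size = 1 / mAlpha),
                          nrow = nM, dimnames = list(mt$mirna_id, samples))
  }
  groups <- setNames(grp, samples)
  list(geneCounts = CountSet(geneCounts, groups),
       mirnaCounts = if (!is.null(mirnaCounts))
         CountSet(mirnaCounts, groups) else NULL,
       latent = latent)
}

#' Simulate mature miRNA and 3'UTR sequences
#'
#' Random sequences with the reverse complement of each cascade miRNA's
#' seed (nt 2-8) inserted into its planted targets' UTRs, so seed-match
#' target prediction recovers the planted pairs (plus chance decoys).
#'
#' @inheritParams simulateMethylome
#' @param utrLen 3'UTR length in nt.
#' @return list of named character vectors `mirna` and `utr` (DNA
#'   alphabet).
#' @export
simulateSequences <- function(cfg, truth, seed = cfg$seed + 4L,
                              utrLen = 500L) {
  set.seed(seed)
  rseq <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  mir <- setNames(rseq(nrow(truth$mirnas), 22L), truth$mirnas$mirna_id)
  utr <- setNames(rseq(nrow(truth$genes), utrLen), truth$genes$gene_id)
  if (!is.null(truth$pairs)) {
    for (i in seq_len(nrow(truth$pairs))) {
      m <- truth$pairs$mirna_id[i]; gid <- truth$pairs$gene_id[i]
      seed7 <- substr(mir[[m]], 2, 8)
      site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seed7)))
      at <- sample(utrLen - 7L, 1)
      substr(utr[[gid]], at, at + 6L) <- site
    }
  }
  list(mirna = mir, utr = utr)
}

#' Simulate a complete coupled tri-omics dataset
#'
#' Runs annotation, truth planning, methylome, expression and sequence
#' generation under one seed and returns everything, including the truth
#' tables used by [evaluateAgainstTruth()].
#'
#' @param cfg a [simulationConfig()].
#' @return list with `cfg`, `geneModels`, `mirnaModels`,
#'   `intergenicZones`, `truth`, `meth`, `geneCounts`, `mirnaCounts`,
#'   `latent`, `sequences`.
#' @export
simulateDataset <- function(cfg) {
  ann <- simulateAnnotation(cfg)
  truth <- planTruth(cfg, ann)
  meth <- simulateMethylome(cfg, truth)
  expr <- simulateExpression(cfg, truth)
  seqs <- simulateSequences(cfg, truth)
  list(cfg = cfg, geneModels = ann$geneModels,
       mirnaModels = ann$mirnaModels,
       intergenicZones = ann$intergenicZones, truth = truth,
       meth = meth, geneCounts = expr$geneCounts,
       mirnaCounts = expr$mirnaCounts, latent = expr$latent,
       sequences = seqs)
}
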