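# Strand-aware gene-region models. The promoter is the paper-style
# TSS1500: the 1500 bp strictly upstream of the TSS, union the annotated
# 5'UTR. The gene body is the transcribed span minus the 5'UTR and is
# partitioned into exon and intron parts. Positions in no promoter or body
# are intergenic.

#' Load collapsed gene models from a GTF/GFF3 file
#'
#' Multi-transcript genes are collapsed to the union of their exons and the
#' union of their 5'UTR intervals; the TSS is the 5'-most transcribed base
#' on the gene's strand. Ensembl-style GTF (gene_id attribute on every
#' feature) and GFF3 (ID/Parent chains) are both accepted.
#'
#' @param path GTF or GFF3 file.
#' @param featureTypes feature types treated as transcribed evidence.
#' @return A [GeneModels-class].
#' @export
loadGeneModels <- function(path, featureTypes = c("exon", "five_prime_utr")) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("malformed annotation file: ",
                                          conditionMessage(e)))
  type <- tolower(as.character(gr$type))
  gid <- .resolveGeneIds(gr, type)
  exon <- gr[type == "exon"]
  exonGid <- gid[type == "exon"]
  if (length(exon) == 0) stop("annotation contains no exon features")
  utr <- gr[type %in% c("five_prime_utr", "5utr", "five_prime_UTR")]
  utrGid <- gid[type %in% c("five_prime_utr", "5utr", "five_prime_UTR")]
  if (anyNA(exonGid)) stop("exon feature without resolvable gene_id")
  ids <- sort(unique(exonGid))
  exons <- GenomicRanges::reduce(
    GenomicRanges::split(exon, factor(exonGid, levels = ids)))
  utr5 <- GenomicRanges::reduce(
    GenomicRanges::split(utr, factor(utrGid, levels = ids)))
  genes <- unlist(range(exons))
  if (any(GenomicRanges::strand(genes) == "*"))
    stop("gene lacking strand (or mixed strands): ",
         paste(ids[GenomicRanges::strand(genes) == "*"], collapse = ", "))
  genes$gene_id <- ids
  names(genes) <- NULL
  new("GeneModels", genes = genes, exons = exons, utr5 = utr5)
}

# gene_id directly (GTF) or via Parent -> transcript -> gene (GFF3)
.resolveGeneIds <- function(gr, type) {
  mc <- S4Vectors::mcols(gr)
  if ("gene_id" %in% colnames(mc) && !all(is.na(mc$gene_id)))
    return(as.character(mc$gene_id))
  if (!all(c("ID", "Parent") %in% colnames(mc)))
    stop("annotation has neither gene_id attributes nor ID/Parent chains")
  parent <- vapply(mc$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  id <- as.character(mc$ID)
  txOwner <- setNames(parent[type %in% c("mrna", "transcript", "gene")],
                      id[type %in% c("mrna", "transcript", "gene")])
  isGene <- setNames(type == "gene", id)
  out <- parent
  leaf <- !is.na(parent) & !is.na(isGene[parent]) & !isGene[parent]
  out[leaf] <- txOwner[parent[leaf]]
  sub("^gene:", "", out)
}

#' Transcription start sites of collapsed gene models
#' @param models a [GeneModels-class].
#' @return named integer vector of 1-based TSS positions.
#' @export
geneTSS <- function(models) {
  g <- models@genes
  tss <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                GenomicRanges::start(g), GenomicRanges::end(g))
  setNames(as.integer(tss), g$gene_id)
}

#' Derive promoter / exon / intron regions and build an interval index
#'
#' For each gene the promoter is the strand-aware window covering
#' `tssWindow` bp strictly upstream of the TSS (excluding the TSS base)
#' union all annotated 5'UTR intervals; the gene body is the transcribed
#' span minus the 5'UTR, partitioned into exon and intron parts by the
#' collapsed exon union. Promoter and body never overlap by construction.
#'
#' @param models a [GeneModels-class].
#' @param tssWindow upstream window width in bp (default 1500).
#' @return A [RegionIndex-class].
#' @export
deriveRegions <- function(models, tssWindow = 1500L) {
  if (tssWindow <= 0) stop("tssWindow must be positive")
  tssWindow <- as.integer(tssWindow)
  genes <- models@genes
  upstream <- GenomicRanges::promoters(genes, upstream = tssWindow,
                                       downstream = 0L)
  upstream$gene_id <- genes$gene_id
  upstream <- GenomicRanges::restrict(upstream, start = 1L)
  upstream <- upstream[GenomicRanges::width(upstream) > 0]
  ids <- genes$gene_id
  exonU <- unlist(models@exons, use.names = TRUE)
  utrU <- unlist(models@utr5, use.names = TRUE)
  # pooled per-gene interval subtraction: shift each gene into its own
  # coordinate block so one IRanges::setdiff covers all genes at once
  off <- as.numeric(max(GenomicRanges::end(genes),
                        GenomicRanges::end(exonU), 1L)) + 2
  pooled <- off * length(ids) < .Machine$integer.max
  .blockDiff <- function(xStart, xEnd, xIdx, yStart, yEnd, yIdx) {
    shift <- function(v, idx) as.integer(v + (idx - 1L) * off)
    d <- IRanges::setdiff(IRanges::IRanges(shift(xStart, xIdx),
                                           shift(xEnd, xIdx)),
                          IRanges::IRanges(shift(yStart, yIdx),
                                           shift(yEnd, yIdx)))
    idx <- (IRanges::start(d) - 1) %/% off + 1
    data.frame(idx = as.integer(idx),
               start = as.integer(IRanges::start(d) - (idx - 1) * off),
               end = as.integer(IRanges::end(d) - (idx - 1) * off))
  }
  .asRegion <- function(df, region) {
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes)[df$idx],
      IRanges::IRanges(df$start, df$end),
      strand = GenomicRanges::strand(genes)[df$idx],
      gene_id = ids[df$idx], region = rep(region, nrow(df)))
  }
  if (pooled) {
    exIdx <- match(names(exonU), ids)
    utIdx <- match(names(utrU), ids)
    gIdx <- seq_along(ids)
    bodyEx <- .blockDiff(GenomicRanges::start(exonU),
                         GenomicRanges::end(exonU), exIdx,
                         GenomicRanges::start(utrU),
                         GenomicRanges::end(utrU), utIdx)
    intr <- .blockDiff(GenomicRanges::start(genes),
                       GenomicRanges::end(genes), gIdx,
                       c(GenomicRanges::start(exonU),
                         GenomicRanges::start(utrU)),
                       c(GenomicRanges::end(exonU),
                         GenomicRanges::end(utrU)),
                       c(exIdx, utIdx))
    exonRegion <- .asRegion(bodyEx, "exon")
    intronRegion <- .asRegion(intr, "intron")
  } else {
    exonParts <- S4Vectors::mendoapply(GenomicRanges::setdiff,
                                       models@exons, models@utr5)
    combined <- GenomicRanges::reduce(S4Vectors::pc(models@exons,
                                                    models@utr5))
    introns <- GenomicRanges::psetdiff(genes, combined)
    .tag <- function(grl, region) {
      gr <- unlist(grl, use.names = TRUE)
      if (length(gr) == 0)
        return(GenomicRanges::GRanges())
      gr$gene_id <- names(gr)
      gr$region <- region
      names(gr) <- NULL
      gr
    }
    exonRegion <- .tag(exonParts, "exon")
    intronRegion <- .tag(introns, "intron")
  }
  promUtr <- utrU
  promUtr$gene_id <- if (length(promUtr)) names(promUtr) else character(0)
  promUtr$region <- rep("promoter", length(promUtr))
  names(promUtr) <- NULL
  upstream$region <- "promoter"
  regions <- c(GenomicRanges::granges(upstream, use.mcols = TRUE),
               promUtr, exonRegion, intronRegion)
  regions <- regions[order(as.character(GenomicRanges::seqnames(regions)),
                           GenomicRanges::start(regions), regions$gene_id,
                           regions$region)]
  new("RegionIndex", regions = regions, tssWindow = tssWindow)
}

#' Assign genomic positions to gene regions
#'
#' Returns all overlapping (gene, region) assignments per site; a site
#' overlapping several genes is assigned to each. CpG strand is ignored:
#' regions are defined by the gene's strand. Sites with no assignment are
#' intergenic.
#'
#' @param sites a `GRanges` (or a [MethylationSet-class], whose row ranges
#'   are used).
#' @param index a [RegionIndex-class].
#' @return data.frame with columns `site` (chrom:pos:strand key),
#'   `gene_id`, `region`.
#' @export
assignSites <- function(sites, index) {
  if (is(sites, "MethylationSet")) sites <- SummarizedExperiment::rowRanges(sites)
  # sites on contigs the index has never seen are simply intergenic
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sites, index@regions, ignore.strand = TRUE))
  data.frame(
    site = siteKeys(sites)[S4Vectors::queryHits(hits)],
    gene_id = index@regions$gene_id[S4Vectors::subjectHits(hits)],
    region = index@regions$region[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
}

#' Single-class site classification
#'
#' Collapses the multi-assignment of [assignSites()] to one feature class
#' per site with priority promoter > exon > intron; unassigned sites are
#' intergenic. This is the classification used for feature-distribution
#' summaries.
#'
#' @inheritParams assignSites
#' @return character vector parallel to `sites` with values
#'   promoter/exon/intron/intergenic.
#' @export
classifySites <- function(sites, index) {
  if (is(sites, "MethylationSet")) sites <- SummarizedExperiment::rowRanges(sites)
  asg <- assignSites(sites, index)
  keys <- siteKeys(sites)
  cls <- rep("intergenic", length(sites))
  prio <- c(promoter = 1L, exon = 2L, intron = 3L)
  if (nrow(asg)) {
    asg$rank <- prio[asg$region]
    best <- tapply(asg$rank, asg$site, min)
    hit <- match(keys, names(best))
    cls[!is.na(hit)] <- names(prio)[best[hit[!is.na(hit)]]]
  }
  cls
}

#' Export region intervals as BED for inspection
#' @param index a [RegionIndex-class].
#' @param path output path.
#' @export
writeRegionBed <- function(index, path) {
  r <- index@regions
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
                    start = GenomicRanges::start(r) - 1L,
                    end = GenomicRanges::end(r),
                    name = paste(r$gene_id, r$region, sep = "|"),
                    score = 0,
                    strand = as.character(GenomicRanges::strand(r)))
  bed <- bed[order(bed$chrom, bed$start, bed$name), ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
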