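#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importFrom stats median pchisq pnorm pt cor sd quantile rbeta rbinom
#'   rlnorm rnbinom rnorm runif setNames complete.cases p.adjust dhyper
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' MethylationSet: per-CpG methylation calls across samples
#'
#' An S4 container for RRBS-style per-CpG methylation data, extending
#' [SummarizedExperiment::RangedSummarizedExperiment-class] with two integer
#' assays, `coverage` (total reads) and `methylated` (methylated reads).
#' Row ranges are width-1 CpG cytosine positions (1-based); sites on the
#' two strands of a symmetric CpG are kept distinct. Column data must carry
#' a `group` factor assigning each sample to a tissue group.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#'
#' @seealso [MethylationSet()] for construction,
#'   [readMethylationTable()] for import.
#' @export
setClass("MethylationSet", contains = "RangedSummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- NULL
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("coverage", "methylated") %in% a))
    msg <- c(msg, "assays must include 'coverage' and 'methylated'")
  else {
    cov <- SummarizedExperiment::assay(object, "coverage")
    met <- SummarizedExperiment::assay(object, "methylated")
    if (any(cov < 0) || any(met < 0))
      msg <- c(msg, "negative counts are not allowed")
    if (any(met > cov)) {
      bad <- which(met > cov, arr.ind = TRUE)[1, ]
      key <- siteKeys(object)[bad[1]]
      msg <- c(msg, sprintf("methylated > coverage at site %s (sample %s)",
                            key, colnames(object)[bad[2]]))
    }
  }
  if (anyDuplicated(siteKeys(object)))
    msg <- c(msg, "duplicate (chrom, pos, strand) site")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (any(is.na(SummarizedExperiment::colData(object)$group)))
    msg <- c(msg, "every sample needs a group label")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationSet
#'
#' @param coverage,methylated integer matrices (sites x samples) with
#'   identical dimensions and column names.
#' @param chrom,pos,strand site coordinates (1-based cytosine position).
#' @param group named character/factor of group labels, or a vector parallel
#'   to the sample columns.
#' @return A [MethylationSet-class].
#' @examples
#' ms <- MethylationSet(coverage = cbind(s1 = c(10L, 20L), s2 = c(12L, 8L)),
#'                      methylated = cbind(s1 = c(5L, 20L), s2 = c(0L, 8L)),
#'                      chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                      strand = c("+", "-"), group = c(s1 = "H", s2 = "LR"))
#' methPercent(ms)
#' @export
MethylationSet <- function(coverage, methylated, chrom, pos, strand, group) {
  stopifnot(identical(dim(coverage), dim(methylated)))
  samples <- colnames(coverage)
  if (is.null(samples)) stop("coverage matrix must have sample column names")
  if (!is.null(names(group))) {
    missing <- setdiff(samples, names(group))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    group <- group[samples]
  }
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coverage = as.matrix(coverage),
                  methylated = as.matrix(methylated)),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = samples))
  new("MethylationSet", se)
}

#' CountSet: a feature-by-sample raw count matrix with group labels
#'
#' Thin S4 wrapper over [SummarizedExperiment::SummarizedExperiment-class]
#' holding one non-negative integer assay `counts` and a `group` column in
#' `colData`. Used for both gene-level and miRNA-level tables.
#'
#' @seealso [CountSet()], [readCountTable()]
#' @export
setClass("CountSet", contains = "SummarizedExperiment")

setValidity("CountSet", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(k < 0)) msg <- c(msg, "negative counts are not allowed")
    if (any(k != round(k))) msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature ids")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CountSet
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param group group labels, optionally named by sample.
#' @return A [CountSet-class].
#' @export
CountSet <- function(counts, group) {
  samples <- colnames(counts)
  if (is.null(samples)) stop("counts must have sample column names")
  if (!is.null(names(group))) {
    missing <- setdiff(samples, names(group))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    group <- group[samples]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = samples))
  new("CountSet", se)
}

#' GeneModels: collapsed, strand-aware gene structures
#'
#' One entry per gene: the transcribed span (union over transcripts), the
#' union of exons and the union of annotated 5'UTR intervals. Multi-transcript
#' genes are collapsed; the TSS is the 5'-most transcribed base on the gene's
#' strand.
#'
#' @slot genes `GRanges`, one range per gene (mcols: `gene_id`).
#' @slot exons `GRangesList` named by gene, reduced exon unions.
#' @slot utr5 `GRangesList` named by gene, reduced 5'UTR unions (may be empty).
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList",
                        utr5 = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- NULL
  ids <- object@genes$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genes must carry unique gene_id mcols")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@utr5), ids))
    msg <- c(msg, "exons/utr5 lists must be named parallel to genes")
  if (any(GenomicRanges::strand(object@genes) == "*"))
    msg <- c(msg, "every gene needs a strand")
  if (is.null(msg)) TRUE else msg
})

#' RegionIndex: position -> (gene, region) interval lookup
#'
#' Holds the derived region intervals for a set of gene models: `promoter`
#' (the TSS1500 window strictly upstream of the TSS, union 5'UTR), `exon` and
#' `intron` (a partition of the gene body, i.e. the transcribed span minus the
#' 5'UTR). Positions overlapping no interval are intergenic.
#'
#' @slot regions `GRanges` with mcols `gene_id` and `region`
#'   (promoter/exon/intron).
#' @slot tssWindow integer, upstream window width in bp.
#' @export
setClass("RegionIndex",
         representation(regions = "GRanges", tssWindow = "integer"))

#' @describeIn MethylationSet-class "chrom:pos:strand" site keys.
#' @param x a `MethylationSet` (or any RangedSummarizedExperiment).
#' @export
siteKeys <- function(x) {
  rr <- if (is(x, "GRanges")) x else SummarizedExperiment::rowRanges(x)
  paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr),
        GenomicRanges::strand(rr), sep = ":")
}

#' @describeIn MethylationSet-class sample group labels, named by sample.
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$group), rownames(cd))
}

#' @describeIn MethylationSet-class per-site percent methylation matrix
#'   (NA where coverage is zero).
#' @export
methPercent <- function(x) {
  cov <- SummarizedExperiment::assay(x, "coverage")
  met <- SummarizedExperiment::assay(x, "methylated")
  pct <- 100 * met / cov
  pct[cov == 0] <- NA_real_
  pct
}

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet with", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  g <- table(sampleGroups(object))
  cat("groups:", paste(sprintf("%s(n=%d)", names(g), g), collapse = ", "), "\n")
})

setMethod("show", "CountSet", function(object) {
  cat("CountSet with", nrow(object), "features x", ncol(object), "samples\n")
  g <- table(sampleGroups(object))
  cat("groups:", paste(sprintf("%s(n=%d)", names(g), g), collapse = ", "), "\n")
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      "sequence(s)\n")
})

setMethod("show", "RegionIndex", function(object) {
  cat("RegionIndex:", length(object@regions), "region intervals",
      sprintf("(TSS window %d bp)\n", object@tssWindow))
  print(table(object@regions$region))
})

#' @describeIn GeneModels-class number of genes.
#' @param x a `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels-class gene identifiers.
#' @export
setMethod("names", "GeneModels", function(x) x@genes$gene_id)

#' @describeIn GeneModels-class the gene span GRanges.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn RegionIndex-class the region interval GRanges.
#' @param x a `RegionIndex`.
#' @export
regionRanges <- function(x) x@regions
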