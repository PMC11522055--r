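# Independent reference implementations used as oracles. These stay
# deliberately naive (quadratic scans, explicit enumeration, plain
# arithmetic) and never share code with the package internals.

# naive O(m^2) Benjamini-Hochberg step-up: q_i = min over all j with
# p_j >= p_i of p_j * m / rank_j, capped at 1
naiveBH <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(rk >= rk[i])
    min(1, min(p[js] * m / rk[js]))
  }, numeric(1))
}

# two-sided Fisher exact p by explicit enumeration of the conditional
# table probabilities computed from log-binomial coefficients
fisherEnum <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  logp <- lchoose(m, support) + lchoose(nn, k - support) -
    lchoose(m + nn, k)
  pr <- exp(logp)
  pObs <- pr[support == a]
  min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# all permutations of 1..n, built by insertion (independent of the
# package's generator)
allPermsOracle <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPermsOracle(n - 1L)
  out <- list()
  for (p in sub) for (at in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = at - 1L)
  }
  out
}

# exact two-sided Spearman p by full enumeration, rho via stats::cor
spearmanEnum <- function(x, y) {
  n <- length(x)
  rhoObs <- cor(rank(x), rank(y))
  rhos <- vapply(allPermsOracle(n), function(perm)
    cor(rank(x), rank(y)[perm]), numeric(1))
  list(rho = rhoObs, p = mean(abs(rhos) >= abs(rhoObs) - 1e-12))
}

# hand-built random gene models (overlaps allowed, both strands) plus a
# plain-arithmetic region oracle
randomGeneModels <- function(nGenes, seed, genomeLen = 100000L) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(nGenes))
  genes <- list(); exonsL <- list(); utrL <- list()
  for (i in seq_len(nGenes)) {
    len <- sample(2000:6000, 1)
    s <- sample(seq_len(genomeLen - len), 1)
    e <- s + len - 1L
    strand <- sample(c("+", "-"), 1)
    nEx <- sample(2:4, 1)
    exS <- sort(sample(s:(e - 200L), nEx))
    exE <- pmin(exS + sample(100:500, nEx, replace = TRUE), e)
    # force the span to stay [s, e]
    exS[1] <- s; exE[nEx] <- max(exE[nEx], e)
    exE <- pmin(exE, e)
    ex <- IRanges::reduce(IRanges::IRanges(exS, exE))
    hasUtr <- runif(1) < 0.7
    utr <- if (!hasUtr) IRanges::IRanges() else {
      w <- sample(50:300, 1)
      if (strand == "+") IRanges::IRanges(s, width = w)
      else IRanges::IRanges(end = e, width = w)
    }
    genes[[i]] <- data.frame(gene_id = ids[i], start = s, end = e,
                             strand = strand, stringsAsFactors = FALSE)
    exonsL[[i]] <- ex; utrL[[i]] <- utr
  }
  gdf <- do.call(rbind, genes)
  gr <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(gdf$start, gdf$end),
                               strand = gdf$strand)
  gr$gene_id <- ids
  .gr <- function(iv, strand) {
    if (length(iv) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chrT", iv, strand = rep(strand, length(iv)))
  }
  exGRL <- GenomicRanges::GRangesList(lapply(seq_len(nGenes), function(i)
    .gr(exonsL[[i]], gdf$strand[i])))
  utGRL <- GenomicRanges::GRangesList(lapply(seq_len(nGenes), function(i)
    .gr(utrL[[i]], gdf$strand[i])))
  names(exGRL) <- names(utGRL) <- ids
  models <- new("GeneModels", genes = gr, exons = exGRL, utr5 = utGRL)
  list(models = models, gdf = gdf, exons = exonsL, utr = utrL)
}

# brute-force (gene, region) assignment of one position by linear scan
bruteAssign <- function(pos, toy, tssWindow = 1500L) {
  out <- list()
  inIv <- function(p, iv) length(iv) > 0 &&
    any(p >= IRanges::start(iv) & p <= IRanges::end(iv))
  for (i in seq_len(nrow(toy$gdf))) {
    g <- toy$gdf[i, ]
    tss <- if (g$strand == "+") g$start else g$end
    upLo <- if (g$strand == "+") max(1, tss - tssWindow) else tss + 1
    upHi <- if (g$strand == "+") tss - 1 else tss + tssWindow
    inUtr <- inIv(pos, toy$utr[[i]])
    if ((pos >= upLo && pos <= upHi) || inUtr)
      out[[length(out) + 1]] <- c(g$gene_id, "promoter")
    if (pos >= g$start && pos <= g$end && !inUtr) {
      region <- if (inIv(pos, toy$exons[[i]])) "exon" else "intron"
      out[[length(out) + 1]] <- c(g$gene_id, region)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), region = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", "region")
  df[order(df$gene_id, df$region), , drop = FALSE]
}

# small literal MethylationSet builder
makeMeth <- function(cov, met, chrom = NULL, pos = NULL, strand = NULL,
                     group = NULL) {
  n <- nrow(cov)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(strand)) strand <- rep("+", n)
  if (is.null(group))
    group <- setNames(rep(c("A", "B"), length.out = ncol(cov)),
                      colnames(cov))
  MethylationSet(coverage = cov, methylated = met, chrom = chrom,
                 pos = pos, strand = strand, group = group)
}

# toy single-gene GTF text
writeToyGTF <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtfLine <- function(type, start, end, strand, gene, tx = paste0(gene, ".t1")) {
  sprintf("chrT\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          type, start, end, strand, gene, tx)
}
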