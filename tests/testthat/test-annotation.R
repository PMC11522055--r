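# Gene-model loading, promoter/body/exon/intron derivation, and the
# interval assignment of CpG positions.

test_that("GTF gene models collapse transcripts with a strand-aware TSS", {
  path <- writeToyGTF(c(
    gtfLine("exon", 100, 200, "+", "gA"),
    gtfLine("exon", 300, 400, "+", "gA")))
  m <- loadGeneModels(path)
  expect_equal(length(m), 1)
  expect_equal(GenomicRanges::start(geneRanges(m)), 100)
  expect_equal(GenomicRanges::end(geneRanges(m)), 400)
  expect_equal(unname(geneTSS(m)), 100L)

  pathMinus <- writeToyGTF(c(
    gtfLine("exon", 100, 200, "-", "gB"),
    gtfLine("exon", 300, 400, "-", "gB")))
  expect_equal(unname(geneTSS(loadGeneModels(pathMinus))), 400L)

  # two transcripts with different first exons: exon union, 5'-most TSS
  pathTwo <- writeToyGTF(c(
    gtfLine("exon", 100, 180, "+", "gC", "gC.t1"),
    gtfLine("exon", 300, 400, "+", "gC", "gC.t1"),
    gtfLine("exon", 150, 250, "+", "gC", "gC.t2"),
    gtfLine("exon", 300, 400, "+", "gC", "gC.t2")))
  mTwo <- loadGeneModels(pathTwo)
  expect_equal(unname(geneTSS(mTwo)), 100L)
  ex <- mTwo@exons[["gC"]]
  expect_equal(GenomicRanges::start(ex), c(100, 300))   # union [100,250]+[300,400]
  expect_equal(GenomicRanges::end(ex), c(250, 400))
})

test_that("promoter windows are strictly upstream, unioned with the 5'UTR", {
  # + strand, TSS 10000, UTR [10000,10199]
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10000, 14000),
                               strand = "+")
  gr$gene_id <- "g1"
  models <- new("GeneModels", genes = gr,
                exons = GenomicRanges::GRangesList(g1 =
                  GenomicRanges::GRanges("chrT",
                    IRanges::IRanges(c(10000, 12000), c(10500, 14000)),
                    strand = "+")),
                utr5 = GenomicRanges::GRangesList(g1 =
                  GenomicRanges::GRanges("chrT",
                    IRanges::IRanges(10000, 10199), strand = "+")))
  idx <- deriveRegions(models)
  prom <- regionRanges(idx)[regionRanges(idx)$region == "promoter"]
  expect_setequal(paste(GenomicRanges::start(prom),
                        GenomicRanges::end(prom)),
                  c("8500 9999", "10000 10199"))
  # gene body excludes the UTR
  body <- regionRanges(idx)[regionRanges(idx)$region %in% c("exon", "intron")]
  expect_equal(min(GenomicRanges::start(body)), 10200)

  expect_error(deriveRegions(models, tssWindow = 0), "positive")
})

test_that("minus-strand promoters mirror upstream of the TSS", {
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2000, 5000),
                               strand = "-")
  gr$gene_id <- "g1"
  models <- new("GeneModels", genes = gr,
                exons = GenomicRanges::GRangesList(g1 =
                  GenomicRanges::GRanges("chrT", IRanges::IRanges(2000, 5000),
                                         strand = "-")),
                utr5 = GenomicRanges::GRangesList(g1 =
                  GenomicRanges::GRanges()))
  idx <- deriveRegions(models)
  prom <- regionRanges(idx)[regionRanges(idx)$region == "promoter"]
  expect_equal(GenomicRanges::start(prom), 5001)
  expect_equal(GenomicRanges::end(prom), 6500)
  # no UTR: the body is the full span
  body <- regionRanges(idx)[regionRanges(idx)$region == "exon"]
  expect_equal(GenomicRanges::start(body), 2000)
  expect_equal(GenomicRanges::end(body), 5000)
})

test_that("per-gene regions partition correctly on random models", {
  for (seed in c(11, 12)) {
    toy <- randomGeneModels(10, seed)
    idx <- deriveRegions(toy$models)
    reg <- regionRanges(idx)
    for (gid in unique(reg$gene_id)) {
      sub <- reg[reg$gene_id == gid]
      prom <- IRanges::reduce(IRanges::ranges(sub[sub$region == "promoter"]))
      body <- IRanges::reduce(IRanges::ranges(
        sub[sub$region %in% c("exon", "intron")]))
      # promoter and body never overlap
      expect_equal(sum(IRanges::width(IRanges::intersect(prom, body))), 0)
      # exon and intron partition the body
      ex <- IRanges::reduce(IRanges::ranges(sub[sub$region == "exon"]))
      intr <- IRanges::reduce(IRanges::ranges(sub[sub$region == "intron"]))
      expect_equal(sum(IRanges::width(IRanges::intersect(ex, intr))), 0)
      expect_equal(sum(IRanges::width(IRanges::union(ex, intr))),
                   sum(IRanges::width(body)))
      # body equals span minus UTR
      i <- which(toy$gdf$gene_id == gid)
      span <- IRanges::IRanges(toy$gdf$start[i], toy$gdf$end[i])
      expect_equal(sum(IRanges::width(body)),
                   sum(IRanges::width(IRanges::setdiff(span, toy$utr[[i]]))))
    }
  }
})

test_that("site assignment returns all overlapping genes and matches a brute-force scan", {
  toy <- randomGeneModels(20, seed = 5)
  idx <- deriveRegions(toy$models)
  set.seed(99)
  pos <- sample.int(100000L, 300)
  sites <- GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, width = 1),
                                  strand = sample(c("+", "-"), 300, TRUE))
  asg <- assignSites(sites, idx)
  keys <- siteKeys(sites)
  for (i in seq_along(pos)) {
    got <- asg[asg$site == keys[i], c("gene_id", "region")]
    got <- got[order(got$gene_id, got$region), , drop = FALSE]
    want <- bruteAssign(pos[i], toy)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 info = paste("pos", pos[i]))
  }
  # a position on an unannotated contig is intergenic
  far <- GenomicRanges::GRanges("chrUn", IRanges::IRanges(5000, 5000),
                                strand = "+")
  expect_equal(nrow(assignSites(far, idx)), 0)
  expect_equal(classifySites(far, idx), "intergenic")
})

test_that("single-class priority is promoter > exon > intron", {
  toy <- randomGeneModels(20, seed = 6)
  idx <- deriveRegions(toy$models)
  set.seed(42)
  pos <- sample.int(100000L, 200)
  sites <- GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, width = 1),
                                  strand = "+")
  cls <- classifySites(sites, idx)
  for (i in seq_along(pos)) {
    want <- bruteAssign(pos[i], toy)
    expected <- if (nrow(want) == 0) "intergenic"
      else c("promoter", "exon", "intron")[min(match(want$region,
             c("promoter", "exon", "intron")))]
    expect_equal(cls[i], expected, info = paste("pos", pos[i]))
  }
})
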