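# Spearman machinery, site-gene pairing, stratum summaries,
# methylation-dependent gene selection and cross-comparison set algebra.

test_that("Spearman rho matches closed forms and stats::cor", {
  expect_equal(spearmanCor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  # n = 4, sum d^2 = 4: rho = 1 - 6*4/(4*15) = 0.6
  sc <- spearmanCor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(sc$rho, 0.6)
  set.seed(1)
  for (i in 1:15) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i %% 3 == 0) y[1:2] <- y[3]   # ties
    expect_equal(spearmanCor(x, y)$rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearmanCor(rep(1, 5), rnorm(5))$rho))
})

test_that("exact Spearman p-values match full permutation enumeration", {
  set.seed(7)
  for (n in c(4, 5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearmanCor(x, y)
    oracle <- spearmanEnum(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$rho, oracle$rho, tolerance = 1e-12)
    expect_equal(mine$p, oracle$p, tolerance = 1e-12)
  }
  # above the exact limit the t approximation is used
  big <- spearmanCor(rnorm(12), rnorm(12))
  expect_equal(big$method, "t-approximation")
  n <- 12; x <- rnorm(n); y <- rnorm(n)
  sc <- spearmanCor(x, y)
  tstat <- sc$rho * sqrt((n - 2) / (1 - sc$rho^2))
  expect_equal(sc$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
})

# a small fabricated comparison used by the pairing tests: two genes,
# one DMS in g1's promoter and g2's body (overlapping genes)
fakeExpr <- function() {
  norm <- rbind(g1 = c(100, 110, 90, 100, 10, 12, 8, 10),
                g2 = c(10, 12, 8, 10, 100, 110, 90, 100))
  colnames(norm) <- paste0("s", 1:8)
  expr <- data.frame(feature_id = c("g1", "g2"),
                     base_mean = rowMeans(norm),
                     log2fc = c(3.2, -3.2), se = 0.2,
                     pvalue = c(1e-6, 1e-6), padj = c(1e-5, 1e-5),
                     is_de = c(TRUE, TRUE), tier = c("Q3", "Q3"))
  attr(expr, "normalized") <- norm
  attr(expr, "groups") <- rep(c("A", "B"), each = 4)
  expr
}

test_that("pairing joins DMSs to overlapping gene regions", {
  dms <- data.frame(chrom = "chrT", pos = c(50L, 500L, 9000L),
                    strand = "+",
                    site = paste("chrT", c(50, 500, 9000), "+", sep = ":"),
                    meth_diff = c(40, -30, 35), pvalue = 1e-5,
                    qvalue = 1e-4,
                    direction = c("hyper", "hypo", "hyper"))
  asg <- data.frame(site = c("chrT:50:+", "chrT:500:+", "chrT:500:+"),
                    gene_id = c("g1", "g1", "g2"),
                    region = c("promoter", "intron", "exon"))
  pairs <- buildPairs(dms, asg, fakeExpr(), groupA = "A", groupB = "B")
  expect_equal(nrow(pairs), 3)   # intergenic site contributes nothing
  expect_setequal(pairs$region, c("promoter", "gene_body"))
  p1 <- pairs[pairs$site == "chrT:50:+", ]
  expect_equal(p1$region, "promoter")
  expect_equal(p1$expr_diff, 100 - 10)
  expect_equal(sum(pairs$site == "chrT:500:+"), 2)   # both genes
  expect_equal(attr(pairs, "dropped"), 0)
  # a gene missing from the expression table is dropped and counted
  asg2 <- rbind(asg, data.frame(site = "chrT:50:+", gene_id = "gX",
                                region = "promoter"))
  pairs2 <- buildPairs(dms, asg2, fakeExpr(), groupA = "A", groupB = "B")
  expect_equal(nrow(pairs2), 3)
  expect_equal(attr(pairs2, "dropped"), 1)
})

test_that("stratum rows split by tier, region and direction and swap cleanly", {
  set.seed(30)
  n <- 40
  pairs <- data.frame(
    site = paste0("chrT:", 1:n, ":+"),
    gene_id = sample(sprintf("g%02d", 1:12), n, TRUE),
    region = sample(c("promoter", "gene_body"), n, TRUE),
    meth_diff = c(runif(n / 2, 25, 60), runif(n / 2, -60, -25)),
    direction = rep(c("hyper", "hypo"), each = n / 2),
    expr_diff = rnorm(n, 0, 50),
    gene_log2fc = rnorm(n), gene_padj = runif(n),
    gene_is_de = FALSE,
    tier = sample(c("Q1", "Q2", "Q3"), n, TRUE))
  st <- stratumTable(pairs)
  expect_equal(nrow(st), 24)
  # direction-split counts reconcile with the totals per stratum
  all_all <- st[st$expr_class == "all" & st$region == "all", ]
  expect_equal(sum(all_all$n_cpg), n)
  byTier <- st[st$region == "all" & st$expr_class != "all", ]
  expect_equal(sum(byTier$n_cpg), n)
  expect_true(all(st$n_genes <= st$n_cpg))
  # swapping the comparison flips hyper and hypo rows
  sw <- pairs
  sw$meth_diff <- -sw$meth_diff
  sw$expr_diff <- -sw$expr_diff
  sw$direction <- c(hyper = "hypo", hypo = "hyper")[sw$direction]
  stSw <- stratumTable(sw)
  a <- st[st$direction == "hyper", ]
  b <- stSw[stSw$direction == "hypo", ]
  expect_equal(a$n_cpg, b$n_cpg)
  expect_equal(a$avg_meth_diff, -b$avg_meth_diff)
  expect_equal(abs(a$spearman_rho), abs(b$spearman_rho), tolerance = 1e-12)
})

test_that("planted promoter anti-coupling yields negative promoter-hyper correlations", {
  # coupled pairs respond proportionally to the methylation shift,
  # diluted by uncoupled promoter-hyper pairs
  set.seed(55)
  reps <- 40; neg <- 0; sig <- 0; usable <- 0
  for (r in seq_len(reps)) {
    shift <- runif(30, 28, 55)
    coupled <- data.frame(
      site = paste0("chrT:", 1:30, ":+"), gene_id = sprintf("c%02d", 1:30),
      region = "promoter", meth_diff = shift, direction = "hyper",
      expr_diff = -(40 + 14 * (shift - 28)) * rlnorm(30, 0, 0.4),
      gene_log2fc = -2, gene_padj = 1e-4, gene_is_de = TRUE, tier = "Q3")
    neutral <- data.frame(
      site = paste0("chrT:", 31:45, ":+"), gene_id = sprintf("n%02d", 1:15),
      region = "promoter", meth_diff = runif(15, 25, 55),
      direction = "hyper", expr_diff = rnorm(15, 0, 40),
      gene_log2fc = 0, gene_padj = 0.9, gene_is_de = FALSE, tier = "Q3")
    st <- stratumTable(rbind(coupled, neutral))
    row <- st[st$expr_class == "all" & st$region == "promoter" &
              st$direction == "hyper", ]
    if (row$n_cpg >= 30) {
      usable <- usable + 1
      neg <- neg + (row$spearman_rho < 0)
      sig <- sig + (row$spearman_p < 0.05)
    }
  }
  expect_equal(usable, reps)
  expect_gte(neg / usable, 0.95)
  expect_gte(sig / usable, 0.8)
})

test_that("methylation-dependent gene selection applies the direction rules", {
  base <- data.frame(site = "chrT:1:+", gene_id = "g1",
                     meth_diff = 40, direction = "hyper",
                     expr_diff = -50, tier = "Q3", gene_is_de = TRUE)
  # promoter hyper + strong downregulation: promoter-class hit
  p1 <- cbind(base, region = "promoter", gene_log2fc = -2,
              gene_padj = 0.001)
  sel <- selectMethylationDependent(p1)
  expect_equal(sel$promoter$gene_id, "g1")
  expect_equal(sel$promoter$label, "hypermeth")
  expect_equal(nrow(sel$body), 0)
  # promoter hyper + upregulation: not a promoter-class hit
  p2 <- cbind(base, region = "promoter", gene_log2fc = 2,
              gene_padj = 0.001)
  expect_equal(nrow(selectMethylationDependent(p2)$promoter), 0)
  # body hyper + upregulation: body-class hit
  p3 <- cbind(base, region = "gene_body", gene_log2fc = 2,
              gene_padj = 0.001)
  expect_equal(selectMethylationDependent(p3)$body$gene_id, "g1")
  # sub-threshold expression never qualifies
  p4 <- cbind(base, region = "promoter", gene_log2fc = -0.5,
              gene_padj = 0.001)
  expect_equal(nrow(selectMethylationDependent(p4)$promoter), 0)
})

test_that("cross-comparison patterns match brute-force set algebra", {
  l1 <- data.frame(gene_id = c("a", "b", "c"), label = "hypermeth")
  l2 <- data.frame(gene_id = c("b", "c", "d"), label = "hypometh")
  l3 <- data.frame(gene_id = c("c"), label = "hypermeth")
  cc <- crossComparisonSets(list(X = l1, Y = l2, Z = l3))
  expect_equal(cc$genes$pattern[cc$genes$gene_id == "c"],
               "X_hypermeth Y_hypometh Z_hypermeth")
  expect_equal(cc$genes$n_comparisons[cc$genes$gene_id == "c"], 3L)
  expect_equal(cc$patterns$n_genes[cc$patterns$pattern == "X_hypermeth"], 1L)
  # disjoint lists: every pattern is singleton membership
  d1 <- data.frame(gene_id = c("a", "b"), label = "hypermeth")
  d2 <- data.frame(gene_id = c("c", "d"), label = "hypometh")
  dd <- crossComparisonSets(list(X = d1, Y = d2))
  expect_true(all(dd$genes$n_comparisons == 1))
  # randomized lists against direct set computation
  set.seed(17)
  for (i in 1:5) {
    mk <- function() data.frame(
      gene_id = sample(letters, sample(5:15, 1)),
      label = "hypermeth")
    ls <- list(A = mk(), B = mk(), C = mk())
    cc2 <- crossComparisonSets(ls)
    for (g in cc2$genes$gene_id) {
      want <- sort(names(ls)[vapply(ls, function(df)
        g %in% df$gene_id, logical(1))])
      got <- sub("_hypermeth", "",
                 strsplit(cc2$genes$pattern[cc2$genes$gene_id == g],
                          " ")[[1]])
      expect_equal(got, want)
    }
  }
})
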