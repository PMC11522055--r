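# Differential methylation: coverage filtering, the exact and LRT tests
# against their oracles, BH adjustment, DMS calling conventions.

test_that("coverage filter keeps sites covered in every sample", {
  ms <- makeMeth(cov = cbind(s1 = c(12L, 12L, 30L), s2 = c(15L, 4L, 30L)),
                 met = cbind(s1 = c(1L, 1L, 1L), s2 = c(1L, 1L, 1L)))
  kept <- filterCoverage(ms, minCov = 10, maxPctile = 100)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "removed"), 1L)
  expect_error(filterCoverage(ms, minCov = 0), "minCov")
  low <- makeMeth(cov = cbind(s1 = 3L, s2 = 3L),
                  met = cbind(s1 = 0L, s2 = 0L))
  expect_warning(empty <- filterCoverage(low, minCov = 10), "every site")
  expect_equal(nrow(empty), 0)
})

test_that("Fisher exact p-values match enumeration and stats::fisher.test", {
  # strong separation: group1 18/2 methylated, group2 5/15
  p <- fisherExact2x2(18, 2, 5, 15)
  expect_equal(p, fisherEnum(18, 2, 5, 15), tolerance = 1e-12)
  expect_equal(p, fisher.test(matrix(c(18, 2, 5, 15), 2,
                                     byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # symmetric table: no effect, p = 1
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)
  # random tables against both oracles
  set.seed(31)
  for (i in 1:60) {
    tb <- sample(0:25, 4, replace = TRUE)
    mine <- fisherExact2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(mine, fisherEnum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    expect_equal(mine,
                 fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8, info = paste(tb, collapse = ","))
  }
})

test_that("the replicated-group LRT equals the binomial glm likelihood-ratio test", {
  set.seed(77)
  for (i in 1:25) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    cov <- matrix(rpois(nA + nB, 30) + 1L, nrow = 1)
    met <- matrix(rbinom(nA + nB, as.vector(cov), runif(1, 0.1, 0.9)),
                  nrow = 1)
    colnames(cov) <- colnames(met) <- paste0("s", seq_len(nA + nB))
    grp <- rep(c("A", "B"), c(nA, nB))
    ms <- makeMeth(cov, met, group = setNames(grp, colnames(cov)))
    mine <- testMethylation(ms, "A", "B")
    fit1 <- glm(cbind(met[1, ], cov[1, ] - met[1, ]) ~ factor(grp),
                family = binomial)
    fit0 <- glm(cbind(met[1, ], cov[1, ] - met[1, ]) ~ 1,
                family = binomial)
    pGlm <- anova(fit0, fit1, test = "LRT")$`Pr(>Chi)`[2]
    if (is.na(pGlm)) pGlm <- 1   # zero-deviance edge
    expect_equal(mine, pGlm, tolerance = 1e-6)
  }
  # identical per-sample proportions: LRT statistic 0, p = 1
  ms0 <- makeMeth(cov = cbind(a = 20L, b = 20L, c = 20L, d = 20L),
                  met = cbind(a = 10L, b = 10L, c = 10L, d = 10L),
                  group = c(a = "A", b = "A", c = "B", d = "B"))
  expect_equal(testMethylation(ms0, "A", "B"), 1)
})

test_that("BH adjustment matches the naive step-up reference", {
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustPvalues(0.2), 0.2)
  expect_equal(adjustPvalues(c(1, 1)), c(1, 1))
  expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:80, 1))
    expect_equal(adjustPvalues(p), naiveBH(p), tolerance = 1e-12)
  }
})

test_that("DMS calls apply the 25-point / q-value cutoffs and sign convention", {
  # 4 vs 4 with one strong, one moderate and many null sites
  set.seed(8)
  n <- 60
  cov <- matrix(30L, n, 8, dimnames = list(NULL, paste0("s", 1:8)))
  met <- matrix(rbinom(n * 8, 30, 0.5), n, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
  met[1, ] <- rbinom(8, 30, rep(c(0.8, 0.4), each = 4))   # diff ~ +40
  met[2, ] <- rbinom(8, 30, rep(c(0.8, 0.62), each = 4))  # diff ~ +18
  grp <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  ms <- makeMeth(cov, met, group = grp)
  dms <- callDMS(ms, "A", "B")
  expect_equal(dms$meth_diff, dms$mean_pct_a - dms$mean_pct_b)
  expect_true(dms$direction[1] == "hyper")
  expect_true(abs(dms$meth_diff[2]) < 25 || dms$direction[2] == "ns")
  # a 20-point difference never passes the 25-point cutoff
  expect_true(all(abs(dms$meth_diff[dms$direction != "ns"]) >= 25))
  s <- attr(dms, "summary")
  expect_equal(s$n_dms, s$n_hyper + s$n_hypo)

  # swapping group labels negates differences and swaps hyper/hypo
  rev <- callDMS(ms, "B", "A")
  expect_equal(rev$meth_diff, -dms$meth_diff)
  expect_equal(rev$pvalue, dms$pvalue, tolerance = 1e-12)
  map <- c(hyper = "hypo", hypo = "hyper", ns = "ns")
  expect_equal(unname(map[dms$direction]), rev$direction)
})

test_that("untestable sites (zero group coverage) are excluded", {
  ms <- makeMeth(cov = cbind(a = c(10L, 0L), b = c(10L, 10L)),
                 met = cbind(a = c(5L, 0L), b = c(2L, 3L)),
                 group = c(a = "A", b = "B"))
  p <- testMethylation(ms, "A", "B")
  expect_true(is.na(p[2]))
  dms <- callDMS(ms, "A", "B")
  expect_equal(nrow(dms), 1)
})

test_that("profile correlations behave on exact copies and inversions", {
  pct <- c(0, 50, 100)
  cov <- matrix(10L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  met <- cbind(a = as.integer(pct / 10), b = as.integer(pct / 10),
               c = as.integer(rev(pct) / 10))
  ms <- makeMeth(cov, met, group = c(a = "A", b = "A", c = "B"))
  r <- profileCorrelation(ms)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
})

test_that("feature distribution matches brute-force classification", {
  toy <- randomGeneModels(15, seed = 21)
  idx <- deriveRegions(toy$models)
  set.seed(3)
  pos <- sample.int(100000L, 120)
  dms <- data.frame(chrom = "chrT", pos = pos, strand = "+",
                    site = paste("chrT", pos, "+", sep = ":"),
                    meth_diff = 30, direction = "hyper")
  fd <- featureDistribution(dms, idx)
  expect_equal(sum(fd$fraction), 1)
  want <- table(factor(vapply(pos, function(p) {
    b <- bruteAssign(p, toy)
    if (nrow(b) == 0) "intergenic"
    else c("promoter", "exon", "intron")[min(match(b$region,
         c("promoter", "exon", "intron")))]
  }, character(1)), levels = fd$region))
  expect_equal(fd$n, as.integer(want))

  # degenerate inputs
  none <- featureDistribution(dms[0, ], idx)
  expect_true(all(none$n == 0))
  lonely <- data.frame(chrom = "chrUn", pos = 10L, strand = "+",
                       site = "chrUn:10:+", meth_diff = 30,
                       direction = "hyper")
  fdU <- featureDistribution(lonely, idx)
  expect_equal(fdU$fraction[fdU$region == "intergenic"], 1)
})
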