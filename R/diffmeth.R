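# Per-CpG differential methylation between two tissue groups.
#
# Unreplicated (or pooled) designs use a two-sided Fisher exact test on the
# pooled methylated/unmethylated x group 2x2 table. Replicated designs use
# the likelihood-ratio test of a group effect in a binomial logistic model
# of the per-sample (methylated, coverage) proportions; with a group-only
# covariate the fitted proportions are the group-pooled proportions, so the
# LRT statistic has a closed form and is computed vectorised across sites
# (p from chi-square, 1 df).

#' Coverage filtering for methylation tables
#'
#' Keeps sites where every sample has coverage at least `minCov` and no
#' more than that sample's `maxPctile` coverage percentile (PCR-duplicate
#' guard). The number of removed sites is recorded in the `removed`
#' attribute.
#'
#' @param x a [MethylationSet-class].
#' @param minCov minimum per-sample coverage (default 10).
#' @param maxPctile upper percentile cap per sample (default 99.9).
#' @return the filtered [MethylationSet-class].
#' @export
filterCoverage <- function(x, minCov = 10L, maxPctile = 99.9) {
  if (minCov < 1) stop("minCov must be >= 1")
  cov <- SummarizedExperiment::assay(x, "coverage")
  caps <- apply(cov, 2, quantile, probs = maxPctile / 100, names = FALSE)
  keep <- rowSums(cov < minCov) == 0 &
          rowSums(sweep(cov, 2, caps, `>`)) == 0
  if (!any(keep))
    warning("coverage filter removed every site")
  out <- x[keep, ]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Vectorised two-sided Fisher exact test for 2x2 tables
#'
#' Conditional hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables (at fixed margins) no more likely than the
#' observed one, with the customary `1 + 1e-7` relative tolerance on the
#' comparison.
#'
#' @param a,b successes/failures in group 1 (methylated/unmethylated).
#' @param c,d successes/failures in group 2.
#' @return numeric vector of p-values.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("table cells must be non-negative")
  m <- a + c                  # total successes
  nn <- b + d                 # total failures
  k <- a + b                  # group-1 size
  p <- numeric(n)
  relErr <- 1 + 1e-7
  groups <- split(seq_len(n), paste(m, nn, k))
  for (g in groups) {
    i <- g[1]
    support <- max(0L, k[i] - nn[i]):min(k[i], m[i])
    dens <- dhyper(support, m[i], nn[i], k[i])
    ord <- sort(dens)
    cum <- cumsum(ord)
    pAll <- cum[findInterval(dens * relErr, ord)]
    p[g] <- pmin(1, pAll[match(a[g], support)])
  }
  p
}

# closed-form binomial logistic LRT of a group effect, vectorised across
# sites; M*, C* are matrices (sites x samples) split by group
.binomialLRT <- function(met1, cov1, met2, cov2) {
  M1 <- rowSums(met1); C1 <- rowSums(cov1)
  M2 <- rowSums(met2); C2 <- rowSums(cov2)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll <- function(M, C, p) xlogy(M, p) + xlogy(C - M, 1 - p)
  p1 <- ifelse(C1 > 0, M1 / C1, NA_real_)
  p2 <- ifelse(C2 > 0, M2 / C2, NA_real_)
  p0 <- (M1 + M2) / (C1 + C2)
  stat <- 2 * (ll(M1, C1, p1) + ll(M2, C2, p2) -
               ll(M1, C1, p0) - ll(M2, C2, p0))
  stat <- pmax(stat, 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-site differential methylation test
#'
#' @param x a (filtered) [MethylationSet-class].
#' @param groupA,groupB group labels; the comparison is A minus B.
#' @param poolReplicates force pooling within groups and use the Fisher
#'   exact test even with replicates.
#' @return numeric p-values (NA where a group has zero total coverage).
#' @export
testMethylation <- function(x, groupA, groupB, poolReplicates = FALSE) {
  grp <- sampleGroups(x)
  if (!all(c(groupA, groupB) %in% grp))
    stop("group label(s) absent from the table: ",
         paste(setdiff(c(groupA, groupB), grp), collapse = ", "))
  cov <- SummarizedExperiment::assay(x, "coverage")
  met <- SummarizedExperiment::assay(x, "methylated")
  iA <- which(grp == groupA); iB <- which(grp == groupB)
  C1 <- rowSums(cov[, iA, drop = FALSE]); M1 <- rowSums(met[, iA, drop = FALSE])
  C2 <- rowSums(cov[, iB, drop = FALSE]); M2 <- rowSums(met[, iB, drop = FALSE])
  testable <- C1 > 0 & C2 > 0
  p <- rep(NA_real_, nrow(x))
  if (poolReplicates || (length(iA) == 1 && length(iB) == 1)) {
    t <- which(testable)
    p[t] <- fisherExact2x2(M1[t], C1[t] - M1[t], M2[t], C2[t] - M2[t])
  } else {
    p[testable] <- .binomialLRT(
      met[testable, iA, drop = FALSE], cov[testable, iA, drop = FALSE],
      met[testable, iB, drop = FALSE], cov[testable, iB, drop = FALSE])
  }
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values, monotone non-decreasing in p-rank, capped at 1.
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return adjusted q-values.
#' @export
adjustPvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated sites (DMSs)
#'
#' Coverage-weighted group mean methylation percentages are compared; a
#' site is `hyper` when the difference (A minus B) is at least `minDiff`
#' percentage points with q-value below `maxQ`, `hypo` when at most
#' `-minDiff`, and `ns` otherwise. Default cutoffs are a 25-point
#' difference at q < 0.01.
#'
#' @inheritParams testMethylation
#' @param minDiff minimum absolute methylation difference, percentage
#'   points (default 25).
#' @param maxQ q-value cutoff (default 0.01).
#' @return data.frame with one row per testable site: `chrom`, `pos`,
#'   `strand`, `site`, `mean_pct_a`, `mean_pct_b`, `meth_diff`, `pvalue`,
#'   `qvalue`, `direction`; the `summary` attribute records hyper/hypo
#'   counts and fractions.
#' @export
callDMS <- function(x, groupA, groupB, minDiff = 25, maxQ = 0.01,
                    poolReplicates = FALSE) {
  grp <- sampleGroups(x)
  cov <- SummarizedExperiment::assay(x, "coverage")
  met <- SummarizedExperiment::assay(x, "methylated")
  iA <- grp == groupA; iB <- grp == groupB
  pctA <- 100 * rowSums(met[, iA, drop = FALSE]) /
    rowSums(cov[, iA, drop = FALSE])
  pctB <- 100 * rowSums(met[, iB, drop = FALSE]) /
    rowSums(cov[, iB, drop = FALSE])
  p <- testMethylation(x, groupA, groupB, poolReplicates = poolReplicates)
  keep <- !is.na(p)
  rr <- SummarizedExperiment::rowRanges(x)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    strand = as.character(GenomicRanges::strand(rr))[keep],
    site = siteKeys(x)[keep],
    mean_pct_a = pctA[keep], mean_pct_b = pctB[keep],
    meth_diff = (pctA - pctB)[keep],
    pvalue = p[keep],
    stringsAsFactors = FALSE)
  out$qvalue <- adjustPvalues(out$pvalue)
  out$direction <- "ns"
  out$direction[out$qvalue < maxQ & out$meth_diff >= minDiff] <- "hyper"
  out$direction[out$qvalue < maxQ & out$meth_diff <= -minDiff] <- "hypo"
  nHyper <- sum(out$direction == "hyper")
  nHypo <- sum(out$direction == "hypo")
  attr(out, "summary") <- data.frame(
    n_tested = nrow(out), n_dms = nHyper + nHypo,
    n_hyper = nHyper, n_hypo = nHypo,
    frac_hyper = if (nHyper + nHypo > 0) nHyper / (nHyper + nHypo) else NA_real_)
  out
}

#' Sample-by-sample methylation profile correlation
#'
#' Pairwise Pearson correlation of per-site percent methylation over the
#' sites covered in both samples of each pair; cells with fewer than two
#' common sites are NA.
#'
#' @param x a [MethylationSet-class] with at least two samples.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
profileCorrelation <- function(x) {
  if (ncol(x) < 2) stop("need at least two samples")
  pct <- methPercent(x)
  r <- suppressWarnings(cor(pct, use = "pairwise.complete.obs"))
  ok <- !is.na(pct)
  common <- crossprod(ok)
  r[common < 2] <- NA_real_
  diag(r) <- 1
  r
}

#' Feature-class distribution of DMSs
#'
#' Classifies each DMS into promoter / exon / intron / intergenic with
#' [classifySites()] (one class per site, priority promoter > exon >
#' intron) and returns counts and fractions per class; fractions sum to 1.
#'
#' @param dms a [callDMS()] result (rows with direction `ns` are ignored).
#' @param index a [RegionIndex-class].
#' @return data.frame with columns `region`, `n`, `fraction`.
#' @export
featureDistribution <- function(dms, index) {
  dms <- dms[dms$direction != "ns", , drop = FALSE]
  classes <- c("promoter", "exon", "intron", "intergenic")
  if (nrow(dms) == 0)
    return(data.frame(region = classes, n = 0L, fraction = NA_real_))
  gr <- GenomicRanges::GRanges(dms$chrom,
                               IRanges::IRanges(dms$pos, width = 1L),
                               strand = dms$strand)
  cls <- factor(classifySites(gr, index), levels = classes)
  n <- as.integer(table(cls))
  data.frame(region = classes, n = n, fraction = n / nrow(dms))
}

#' Export DMS records as BED6 (score = methylation difference)
#' @param dms a [callDMS()] result.
#' @param path output path.
#' @param onlySignificant drop `ns` rows first (default TRUE).
#' @export
writeDMSBed <- function(dms, path, onlySignificant = TRUE) {
  if (onlySignificant) dms <- dms[dms$direction != "ns", , drop = FALSE]
  rec <- data.frame(chrom = dms$chrom, pos = dms$pos, strand = dms$strand,
                    name = paste(dms$site, dms$direction, sep = "|"),
                    score = round(dms$meth_diff, 3))
  writeBed(rec, path)
}
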