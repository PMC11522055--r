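# Negative-binomial differential expression for mRNA and miRNA count
# tables: median-of-ratios size factors, method-of-moments gene-wise
# dispersion, Wald test on moderated log2 fold changes, BH adjustment.
# The same engine serves gene and miRNA tables.

#' Median-of-ratios size factors
#'
#' Per-sample factor: the median over reference features of the ratio of
#' the sample's count to the feature's geometric mean across samples.
#' Features with a zero in any sample are excluded from the reference; if
#' none survive, the positive-count subset per sample is used instead.
#'
#' @param counts integer matrix (features x samples) or a
#'   [CountSet-class].
#' @return positive numeric vector, one factor per sample.
#' @export
sizeFactorsMedianRatios <- function(counts) {
  if (is(counts, "CountSet"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  logGeo <- rowMeans(log(counts))
  usable <- is.finite(logGeo)
  sf <- if (any(usable)) {
    apply(counts[usable, , drop = FALSE], 2, function(col)
      exp(median(log(col) - logGeo[usable])))
  } else {
    lg <- rowMeans(ifelse(counts > 0, log(counts), NA), na.rm = TRUE)
    apply(counts, 2, function(col) {
      pos <- col > 0 & is.finite(lg)
      if (!any(pos)) return(NA_real_)
      exp(median(log(col[pos]) - lg[pos]))
    })
  }
  if (anyNA(sf) || any(sf <= 0))
    stop("cannot estimate size factors: no usable reference features")
  sf
}

#' Normalised counts (counts divided by size factors)
#' @inheritParams sizeFactorsMedianRatios
#' @param sizeFactors optional precomputed factors.
#' @return numeric matrix of normalised counts.
#' @export
normalizedCounts <- function(counts, sizeFactors = NULL) {
  if (is(counts, "CountSet"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(counts)
  sweep(as.matrix(counts), 2, sizeFactors, `/`)
}

#' Method-of-moments NB dispersion per feature
#'
#' alpha = max(floor, (s^2 - mu) / mu^2) where mu is the overall mean of
#' normalised counts and s^2 the within-group pooled variance. Features
#' with zero mean get NA (untestable).
#'
#' @param norm normalised count matrix.
#' @param groups group label per sample.
#' @param floor lower bound for alpha (default 1e-8).
#' @return numeric vector of dispersions.
#' @export
estimateDispersionMoM <- function(norm, groups, floor = 1e-8) {
  if (ncol(norm) < 2) stop("need at least two samples")
  groups <- as.character(groups)
  mu <- rowMeans(norm)
  num <- 0; df <- 0
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    m <- rowMeans(norm[, cols, drop = FALSE])
    num <- num + rowSums((norm[, cols, drop = FALSE] - m)^2)
    df <- df + length(cols) - 1
  }
  s2 <- if (df > 0) num / df else rep(NA_real_, nrow(norm))
  alpha <- pmax(floor, (s2 - mu) / mu^2)
  alpha[mu == 0] <- NA_real_
  alpha
}

#' Negative-binomial Wald differential expression test
#'
#' Log2 fold change of group mean normalised counts (A over B) with a 0.5
#' pseudocount on each group mean; the Wald standard error comes from the
#' NB delta method, `Var(mean_g) = (mean_g + alpha * mean_g^2) / n_g`.
#' Two-sided normal p-values, BH adjustment. A feature is differentially
#' expressed when `padj < maxPadj` and `|log2fc| >= minLfc` (defaults:
#' 0.05 and 1).
#'
#' @param x a [CountSet-class].
#' @param groupA,groupB group labels; fold changes are A over B.
#' @param maxPadj,minLfc significance thresholds.
#' @param alphaFloor dispersion floor.
#' @param tierScheme passed to [assignTiers()]; `NULL` skips tiers.
#' @return data.frame with `feature_id`, `base_mean`, `log2fc`, `se`,
#'   `pvalue`, `padj`, `is_de`, `tier`; size factors in the
#'   `sizeFactors` attribute.
#' @export
testDE <- function(x, groupA, groupB, maxPadj = 0.05, minLfc = 1,
                   alphaFloor = 1e-8, tierScheme = "quartile") {
  grp <- sampleGroups(x)
  if (!all(c(groupA, groupB) %in% grp))
    stop("group label(s) absent from the count table: ",
         paste(setdiff(c(groupA, groupB), grp), collapse = ", "))
  iA <- which(grp == groupA); iB <- which(grp == groupB)
  if (length(iA) < 2 || length(iB) < 2)
    stop("the Wald test needs at least two samples per group")
  counts <- SummarizedExperiment::assay(x, "counts")[, c(iA, iB), drop = FALSE]
  sf <- sizeFactorsMedianRatios(counts)
  norm <- normalizedCounts(counts, sf)
  gg <- grp[c(iA, iB)]
  alpha <- estimateDispersionMoM(norm, gg, floor = alphaFloor)
  mA <- rowMeans(norm[, gg == groupA, drop = FALSE])
  mB <- rowMeans(norm[, gg == groupB, drop = FALSE])
  nA <- sum(gg == groupA); nB <- sum(gg == groupB)
  lfc <- log2(mA + 0.5) - log2(mB + 0.5)
  varA <- (mA + alpha * mA^2) / nA
  varB <- (mB + alpha * mB^2) / nB
  se <- sqrt(varA / ((mA + 0.5) * log(2))^2 + varB / ((mB + 0.5) * log(2))^2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  p[is.na(alpha)] <- NA_real_
  out <- data.frame(feature_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = lfc, se = se, pvalue = p,
                    padj = adjustPvalues(p),
                    stringsAsFactors = FALSE)
  out$is_de <- !is.na(out$padj) & out$padj < maxPadj & abs(out$log2fc) >= minLfc
  out$tier <- NA_character_
  if (!is.null(tierScheme)) out <- assignTiers(out, scheme = tierScheme)
  attr(out, "sizeFactors") <- sf
  attr(out, "normalized") <- norm
  attr(out, "groups") <- gg
  out
}

#' Assign expression tiers by mean normalised expression
#'
#' Features are ranked by `base_mean` (ties broken by feature id for
#' determinism): tier `Q1` is the lowest quartile, `Q3` the highest, and
#' `Q2` the interquartile half between them. With fewer than 4 features
#' all tiers are unset with a warning.
#'
#' @param records a [testDE()] result (or any data.frame with
#'   `feature_id` and `base_mean`).
#' @param scheme currently only `"quartile"`.
#' @return `records` with the `tier` column filled.
#' @export
assignTiers <- function(records, scheme = "quartile") {
  scheme <- match.arg(scheme, "quartile")
  n <- nrow(records)
  records$tier <- NA_character_
  if (n < 4) {
    warning("fewer than 4 features: tiers left unset")
    return(records)
  }
  ord <- order(records$base_mean, records$feature_id)
  k <- floor(n / 4)
  tier <- rep("Q2", n)
  tier[ord[seq_len(k)]] <- "Q1"
  tier[ord[seq(n - k + 1, n)]] <- "Q3"
  records$tier <- tier
  records
}
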