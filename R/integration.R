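# Methylation-expression integration: DMS x host-gene pairing, stratified
# Spearman summaries (expression tier x region x methylation direction),
# selection of methylation-dependent genes, and cross-comparison set
# algebra. Spearman is applied unconditionally (no normality gating).

.permCache <- new.env(parent = emptyenv())

.allPerms <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  perms <- matrix(1L, nrow = 1, ncol = 1)
  for (k in 2:n) {
    prev <- perms
    perms <- matrix(0L, nrow = nrow(prev) * k, ncol = k)
    row <- 1
    for (pos in seq_len(k)) {
      block <- cbind(prev, 0L)
      if (pos < k) block[, seq(pos + 1, k)] <- prev[, seq(pos, k - 1)]
      block[, pos] <- k
      perms[seq(row, row + nrow(prev) - 1), ] <- block
      row <- row + nrow(prev)
    }
  }
  .permCache[[key]] <- perms
  perms
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of average ranks (ties handled). The
#' two-sided p-value is computed by exhaustive enumeration over all rank
#' permutations for n <= `exactMaxN` (default 7) and by the t
#' approximation, `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df, for larger
#' n. Constant input yields NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exactMaxN largest n for exact permutation enumeration.
#' @return list with elements `rho`, `p`, `n`, `method`.
#' @export
spearmanCor <- function(x, y, exactMaxN = 7L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n, method = "none"))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "constant"))
  rho <- cor(rx, ry)
  if (n <= exactMaxN) {
    perms <- .allPerms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhoPerm <- as.vector(matrix(ryc[perms], ncol = n) %*% rxc) / denom
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Pair DMSs with host-gene expression results
#'
#' One pair per (DMS x overlapping gene-region); exon/intron assignments
#' collapse to `gene_body`, intergenic sites yield no pair. The expression
#' difference is the difference of group mean normalised counts (A minus
#' B), on the count scale. Pairs whose gene is absent from the expression
#' results are dropped and counted in the `dropped` attribute.
#'
#' @param dms a [callDMS()] result (only hyper/hypo rows are paired).
#' @param assignments an [assignSites()] result for the same sites.
#' @param expr a [testDE()] result computed on the same comparison (its
#'   `normalized` and `groups` attributes supply per-sample expression).
#' @param groupA,groupB the comparison's group labels (defaults recover
#'   them from `expr`).
#' @return data.frame of site-gene pairs.
#' @export
buildPairs <- function(dms, assignments, expr, groupA = NULL, groupB = NULL) {
  norm <- attr(expr, "normalized")
  grps <- attr(expr, "groups")
  if (is.null(norm) || is.null(grps))
    stop("expr must carry the 'normalized' and 'groups' attributes of testDE()")
  if (is.null(groupA)) groupA <- grps[1]
  if (is.null(groupB)) groupB <- setdiff(unique(grps), groupA)[1]
  sig <- dms[dms$direction != "ns", , drop = FALSE]
  asg <- assignments[assignments$site %in% sig$site, , drop = FALSE]
  asg$region <- ifelse(asg$region %in% c("exon", "intron"),
                       "gene_body", asg$region)
  asg <- unique(asg)
  hit <- match(asg$gene_id, expr$feature_id)
  dropped <- sum(is.na(hit))
  keep <- !is.na(hit)
  asg <- asg[keep, , drop = FALSE]; hit <- hit[keep]
  d <- match(asg$site, sig$site)
  exprDiff <- rowMeans(norm[, grps == groupA, drop = FALSE]) -
    rowMeans(norm[, grps == groupB, drop = FALSE])
  out <- data.frame(
    site = asg$site,
    gene_id = asg$gene_id,
    region = asg$region,
    meth_diff = sig$meth_diff[d],
    direction = sig$direction[d],
    expr_diff = exprDiff[hit],
    gene_log2fc = expr$log2fc[hit],
    gene_padj = expr$padj[hit],
    gene_is_de = expr$is_de[hit],
    tier = expr$tier[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$site, out$gene_id, out$region), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Stratified methylation-expression coupling summary
#'
#' One row per (expression class x region x methylation direction)
#' stratum, expression classes {all, Q3, Q2, Q1} and regions {all,
#' gene_body, promoter}: pair counts, distinct gene counts, mean
#' methylation difference (percentage points), mean expression difference
#' (normalised counts) and the Spearman correlation of (meth_diff,
#' expr_diff) across the stratum's pairs with its significance. Empty
#' strata keep zero counts and NA statistics; rho needs >= 3 pairs.
#'
#' @param pairs a [buildPairs()] result.
#' @return data.frame of stratum rows.
#' @export
stratumTable <- function(pairs) {
  exprClasses <- c("all", "Q3", "Q2", "Q1")
  regions <- c("all", "gene_body", "promoter")
  dirs <- c("hyper", "hypo")
  rows <- list()
  for (ec in exprClasses) for (rg in regions) for (dr in dirs) {
    sub <- pairs[pairs$direction == dr, , drop = FALSE]
    if (ec != "all") sub <- sub[!is.na(sub$tier) & sub$tier == ec, , drop = FALSE]
    if (rg != "all") sub <- sub[sub$region == rg, , drop = FALSE]
    sc <- if (nrow(sub) >= 3) spearmanCor(sub$meth_diff, sub$expr_diff)
          else list(rho = NA_real_, p = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      expr_class = ec, region = rg, direction = dr,
      n_cpg = nrow(sub), n_genes = length(unique(sub$gene_id)),
      avg_meth_diff = if (nrow(sub)) mean(sub$meth_diff) else NA_real_,
      avg_expr_diff = if (nrow(sub)) mean(sub$expr_diff) else NA_real_,
      spearman_rho = sc$rho, spearman_p = sc$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Select methylation-dependent genes
#'
#' Promoter class: genes with at least one promoter DMS whose direction
#' opposes a significant expression change (hyper with downregulation or
#' hypo with upregulation at `padj < maxPadj`, `|log2fc| >= minAbsLfc`).
#' Body class: genes with at least one gene-body DMS whose direction
#' matches the change. Each gene appears once, labelled `hypermeth`,
#' `hypometh` or `mixed` by its qualifying promoter (resp. body) DMS
#' directions.
#'
#' @param pairs a [buildPairs()] result.
#' @param maxPadj,minAbsLfc expression significance thresholds.
#' @return list with data.frames `promoter` and `body` (columns
#'   `gene_id`, `label`, `log2fc`, `n_cpg`).
#' @export
selectMethylationDependent <- function(pairs, maxPadj = 0.05, minAbsLfc = 1) {
  de <- !is.na(pairs$gene_padj) & pairs$gene_padj < maxPadj &
    abs(pairs$gene_log2fc) >= minAbsLfc
  opp <- (pairs$direction == "hyper" & pairs$gene_log2fc < 0) |
         (pairs$direction == "hypo" & pairs$gene_log2fc > 0)
  promHits <- pairs[de & pairs$region == "promoter" & opp, , drop = FALSE]
  bodyHits <- pairs[de & pairs$region == "gene_body" & !opp, , drop = FALSE]
  .collapse <- function(h) {
    if (nrow(h) == 0)
      return(data.frame(gene_id = character(0), label = character(0),
                        log2fc = numeric(0), n_cpg = integer(0),
                        stringsAsFactors = FALSE))
    sp <- split(h, h$gene_id)
    out <- do.call(rbind, lapply(sp, function(g) {
      dirs <- unique(g$direction)
      data.frame(gene_id = g$gene_id[1],
                 label = if (length(dirs) == 1)
                   paste0(dirs, "meth") else "mixed",
                 log2fc = g$gene_log2fc[1],
                 n_cpg = length(unique(g$site)),
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$gene_id), ]
    rownames(out) <- NULL
    out
  }
  list(promoter = .collapse(promHits), body = .collapse(bodyHits))
}

#' Partition genes by cross-comparison membership pattern
#'
#' Maps every gene occurring in any comparison's list to its exact
#' membership pattern with per-comparison direction labels, e.g.
#' `"HvsLR_hypermeth LvsH_hypometh"`, and counts genes per pattern.
#'
#' @param geneLists named list (one element per comparison) of data.frames
#'   with columns `gene_id` and `label`.
#' @return list with `genes` (gene_id, pattern, n_comparisons) and
#'   `patterns` (pattern, n_genes, gene_ids).
#' @export
crossComparisonSets <- function(geneLists) {
  if (length(geneLists) < 2) stop("need at least two comparisons")
  if (is.null(names(geneLists)) || any(names(geneLists) == ""))
    stop("geneLists must be named by comparison")
  tagged <- lapply(names(geneLists), function(cmp) {
    df <- geneLists[[cmp]]
    if (nrow(df) == 0) return(NULL)
    data.frame(gene_id = df$gene_id,
               tag = paste(cmp, df$label, sep = "_"),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tagged)
  if (is.null(all) || nrow(all) == 0)
    return(list(genes = data.frame(gene_id = character(0),
                                   pattern = character(0),
                                   n_comparisons = integer(0)),
                patterns = data.frame(pattern = character(0),
                                      n_genes = integer(0),
                                      gene_ids = character(0))))
  sp <- split(all$tag, all$gene_id)
  genes <- data.frame(
    gene_id = names(sp),
    pattern = vapply(sp, function(t) paste(sort(t), collapse = " "),
                     character(1)),
    n_comparisons = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  pat <- split(genes$gene_id, genes$pattern)
  patterns <- data.frame(
    pattern = names(pat),
    n_genes = vapply(pat, length, integer(1)),
    gene_ids = vapply(pat, function(g) paste(sort(g), collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$n_genes, patterns$pattern), ]
  rownames(patterns) <- NULL
  list(genes = genes, patterns = patterns)
}
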