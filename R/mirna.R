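# miRNA layer: canonical seed-match target prediction (a transparent
# stand-in for external consensus predictors), miRNA-target expression
# anti-correlation filtering, miRNA-promoter methylation linkage and
# methylation -> miRNA -> mRNA chain construction.

.asSeqSet <- function(x, what) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readBStringSet(x)
  seqs <- setNames(toupper(chartr("Uu", "Tt", as.character(x))), names(x))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGTU symbol in ", what, " sequence(s): ",
         paste(head(names(seqs)[bad], 3), collapse = ", "))
  seqs
}

#' Predict miRNA targets by canonical 7mer-m8 seed match
#'
#' A (miRNA, gene) pair is emitted when the reverse complement of the
#' miRNA seed (nucleotides 2-8) occurs at least once in the gene's 3'UTR
#' given 5'->3'. RNA and DNA alphabets are accepted (U is normalised to
#' T); anything else is an error. Genes with empty UTRs are skipped.
#'
#' @param mirnaSeqs mature miRNA sequences: FASTA path or named
#'   `XStringSet`/character.
#' @param utrSeqs 3'UTR sequences, named by gene.
#' @param seedStart,seedEnd seed positions within the mature miRNA
#'   (defaults 2 and 8).
#' @return data.frame target map with columns `mirna_id`, `gene_id`,
#'   `n_sites`, `source`.
#' @export
predictTargetsSeed <- function(mirnaSeqs, utrSeqs, seedStart = 2L,
                               seedEnd = 8L) {
  mir <- .asSeqSet(mirnaSeqs, "miRNA")
  utr <- .asSeqSet(utrSeqs, "3'UTR")
  utr <- utr[nchar(utr) > 0]
  if (any(nchar(mir) < seedEnd))
    stop("miRNA sequence(s) shorter than the seed region")
  if (is.null(names(mir)) || is.null(names(utr)))
    stop("miRNA and UTR sequences must be named")
  utrSet <- Biostrings::DNAStringSet(utr)
  rows <- list()
  for (m in names(mir)) {
    seed <- substr(mir[[m]], seedStart, seedEnd)
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seed)))
    hits <- Biostrings::vcountPattern(site, utrSet)
    if (any(hits > 0))
      rows[[m]] <- data.frame(mirna_id = m,
                              gene_id = names(utr)[hits > 0],
                              n_sites = hits[hits > 0],
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mirna_id = character(0), gene_id = character(0),
                         n_sites = integer(0), stringsAsFactors = FALSE)
  out$source <- "seed_match"
  rownames(out) <- NULL
  out[order(out$mirna_id, out$gene_id), ]
}

#' Correlate mapped miRNA-target pairs across samples
#'
#' Spearman correlation of normalised miRNA vs target-gene expression
#' across the matched samples of a comparison. A pair is retained when
#' rho < `rCutoff` (default -0.9) and the target is differentially
#' expressed.
#'
#' @param targetMap data.frame with `mirna_id`, `gene_id`.
#' @param mirnaNorm,geneNorm normalised expression matrices (features x
#'   samples) for the comparison's samples.
#' @param geneDE a [testDE()] result for the gene table.
#' @param rCutoff retention threshold on Spearman rho.
#' @return data.frame of pairs with `r`, `p`, `target_is_de`,
#'   `gene_log2fc`, `retained`; the `perMirna` attribute summarises
#'   retained gene counts per miRNA.
#' @export
correlatePairs <- function(targetMap, mirnaNorm, geneNorm, geneDE,
                           rCutoff = -0.9) {
  samples <- intersect(colnames(mirnaNorm), colnames(geneNorm))
  if (length(samples) == 0)
    stop("miRNA and gene expression matrices share no samples")
  keep <- targetMap$mirna_id %in% rownames(mirnaNorm) &
          targetMap$gene_id %in% rownames(geneNorm)
  tm <- targetMap[keep, , drop = FALSE]
  n <- nrow(tm)
  r <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sc <- spearmanCor(mirnaNorm[tm$mirna_id[i], samples],
                      geneNorm[tm$gene_id[i], samples])
    r[i] <- sc$rho; p[i] <- sc$p
  }
  hit <- match(tm$gene_id, geneDE$feature_id)
  out <- data.frame(mirna_id = tm$mirna_id, gene_id = tm$gene_id,
                    r = r, p = p,
                    target_is_de = !is.na(hit) & geneDE$is_de[hit],
                    gene_log2fc = ifelse(is.na(hit), NA_real_,
                                         geneDE$log2fc[hit]),
                    stringsAsFactors = FALSE)
  out$retained <- !is.na(out$r) & out$r < rCutoff & out$target_is_de
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  ret <- out[out$retained, , drop = FALSE]
  perMirna <- if (nrow(ret))
    data.frame(mirna_id = names(table(ret$mirna_id)),
               n_genes = as.integer(table(ret$mirna_id)),
               stringsAsFactors = FALSE)
  else data.frame(mirna_id = character(0), n_genes = integer(0))
  attr(out, "perMirna") <- perMirna
  attr(out, "meanGenesPerMirna") <-
    if (nrow(perMirna)) mean(perMirna$n_genes) else NA_real_
  out
}

#' DMSs in miRNA promoters
#'
#' Assigns called DMSs to the promoters of miRNA gene models (TSS1500
#' window, plus 5'UTR where annotated — typically absent for miRNA
#' genes).
#'
#' @param mirnaIndex a [RegionIndex-class] built from miRNA gene models.
#' @param dms a [callDMS()] result.
#' @return data.frame with `mirna_id`, `site`, `direction`, `meth_diff`.
#' @export
mirnaPromoterDMS <- function(mirnaIndex, dms) {
  sig <- dms[dms$direction != "ns", , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(mirna_id = character(0), site = character(0),
                      direction = character(0), meth_diff = numeric(0),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$pos, width = 1L),
                               strand = sig$strand)
  asg <- assignSites(gr, mirnaIndex)
  asg <- asg[asg$region == "promoter", , drop = FALSE]
  d <- match(asg$site, sig$site)
  out <- data.frame(mirna_id = asg$gene_id, site = asg$site,
                    direction = sig$direction[d],
                    meth_diff = sig$meth_diff[d],
                    stringsAsFactors = FALSE)
  unique(out[order(out$mirna_id, out$site), ])
}

#' Build methylation -> miRNA -> mRNA regulatory chains
#'
#' A chain is emitted for a miRNA that (i) carries at least one promoter
#' DMS, (ii) is differentially expressed, (iii) shows a negative Spearman
#' correlation between its mean promoter-DMS methylation percentage and
#' its normalised expression across individual samples, and (iv) has at
#' least one target link with negative expression correlation. All
#' negative-correlation links to differentially expressed targets are
#' reported; the `strong` flag marks those passing the rho < `rCutoff`
#' retention threshold.
#'
#' @param promoterMap a [mirnaPromoterDMS()] result.
#' @param mirnaDE a [testDE()] result for the miRNA table.
#' @param pairs a [correlatePairs()] result.
#' @param meth a [MethylationSet-class] (the comparison's samples).
#' @param mirnaNorm normalised miRNA expression matrix.
#' @param rCutoff strong-link threshold (default -0.9).
#' @return data.frame with one row per chain link; `chains` attribute
#'   holds per-miRNA chain summaries.
#' @export
buildChains <- function(promoterMap, mirnaDE, pairs, meth, mirnaNorm,
                        rCutoff = -0.9) {
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      target_r = numeric(0), target_p = numeric(0),
                      strong = logical(0), gene_log2fc = numeric(0),
                      mirna_log2fc = numeric(0), mirna_padj = numeric(0),
                      meth_mirna_r = numeric(0), meth_mirna_p = numeric(0),
                      n_promoter_dms = integer(0),
                      promoter_directions = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(promoterMap) == 0) {
    attr(empty, "chains") <- empty[0, c("mirna_id", "n_promoter_dms")]
    return(empty)
  }
  pct <- methPercent(meth)
  rownames(pct) <- siteKeys(meth)
  samples <- intersect(colnames(pct), colnames(mirnaNorm))
  rows <- list()
  chains <- list()
  for (m in unique(promoterMap$mirna_id)) {
    de <- mirnaDE[mirnaDE$feature_id == m, , drop = FALSE]
    if (nrow(de) == 0 || !isTRUE(de$is_de)) next
    pm <- promoterMap[promoterMap$mirna_id == m, , drop = FALSE]
    sites <- intersect(pm$site, rownames(pct))
    if (length(sites) == 0 || !(m %in% rownames(mirnaNorm))) next
    methMean <- colMeans(pct[sites, samples, drop = FALSE], na.rm = TRUE)
    sc <- spearmanCor(methMean, mirnaNorm[m, samples])
    if (is.na(sc$rho) || sc$rho >= 0) next
    links <- pairs[pairs$mirna_id == m & !is.na(pairs$r) & pairs$r < 0 &
                   pairs$target_is_de, , drop = FALSE]
    if (nrow(links) == 0) next
    rows[[m]] <- data.frame(
      mirna_id = m, gene_id = links$gene_id,
      target_r = links$r, target_p = links$p,
      strong = links$r < rCutoff,
      gene_log2fc = links$gene_log2fc,
      mirna_log2fc = de$log2fc, mirna_padj = de$padj,
      meth_mirna_r = sc$rho, meth_mirna_p = sc$p,
      n_promoter_dms = nrow(pm),
      promoter_directions = paste(sort(unique(pm$direction)), collapse = ","),
      stringsAsFactors = FALSE)
    chains[[m]] <- data.frame(
      mirna_id = m, n_promoter_dms = nrow(pm),
      promoter_directions = paste(sort(unique(pm$direction)), collapse = ","),
      mirna_log2fc = de$log2fc, mirna_padj = de$padj,
      meth_mirna_r = sc$rho, meth_mirna_p = sc$p,
      n_targets = nrow(links), n_strong_targets = sum(links$r < rCutoff),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  chainDf <- if (length(chains)) do.call(rbind, chains)
             else empty[0, c("mirna_id", "n_promoter_dms")]
  rownames(chainDf) <- NULL
  attr(out, "chains") <- chainDf
  out
}
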