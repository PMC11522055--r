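# Readers and writers for the external table dialects. All parsers are
# strict: malformed rows abort with an informative error, nothing is
# silently dropped. Internal coordinates are 1-based; BED output is the
# single place where 0-based half-open coordinates are produced.

#' Read a per-CpG methylation call table
#'
#' Parses a tab-separated table with columns `chrom`, `pos`, `strand`
#' followed by two columns per sample named `<sample>_coverage` and
#' `<sample>_methylated` (a Bismark-coverage-like dialect with explicit
#' counts). Positions are 1-based CpG cytosine coordinates.
#'
#' @param path file path.
#' @param sampleGroups named character vector mapping every sample in the
#'   file to its tissue group.
#' @return A [MethylationSet-class].
#' @export
readMethylationTable <- function(path, sampleGroups) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty methylation table: ", path)
  need <- c("chrom", "pos", "strand")
  if (!identical(colnames(df)[1:3], need))
    stop("methylation table must start with columns chrom, pos, strand")
  rest <- colnames(df)[-(1:3)]
  covCols <- grep("_coverage$", rest, value = TRUE)
  samples <- sub("_coverage$", "", covCols)
  metCols <- paste0(samples, "_methylated")
  if (!setequal(rest, c(covCols, metCols)))
    stop("sample columns must come in <sample>_coverage/<sample>_methylated pairs")
  missing <- setdiff(samples, names(sampleGroups))
  if (length(missing))
    stop("sample(s) absent from the sample sheet: ",
         paste(missing, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  pos <- df$pos
  if (!is.numeric(pos) || any(is.na(pos)) || any(pos != round(pos)) ||
      any(pos < 1))
    stop("pos must be positive integers")
  cov <- as.matrix(df[covCols]); colnames(cov) <- samples
  met <- as.matrix(df[metCols]); colnames(met) <- samples
  if (!is.numeric(cov) || !is.numeric(met) || anyNA(cov) || anyNA(met) ||
      any(cov != round(cov)) || any(met != round(met)))
    stop("coverage/methylated cells must be integers")
  bad <- which(met > cov, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("methylated > coverage at %s:%d (sample %s)",
                 df$chrom[bad[1, 1]], pos[bad[1, 1]], samples[bad[1, 2]]))
  key <- paste(df$chrom, pos, df$strand, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (chrom,pos,strand) row: ", key[which(duplicated(key))[1]])
  MethylationSet(coverage = cov, methylated = met, chrom = df$chrom,
                 pos = as.integer(pos), strand = df$strand,
                 group = sampleGroups[samples])
}

#' Write a methylation table in the dialect read by [readMethylationTable()]
#' @param x a [MethylationSet-class].
#' @param path output path.
#' @export
writeMethylationTable <- function(x, path) {
  rr <- SummarizedExperiment::rowRanges(x)
  cov <- SummarizedExperiment::assay(x, "coverage")
  met <- SummarizedExperiment::assay(x, "methylated")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    strand = as.character(GenomicRanges::strand(rr)),
                    check.names = FALSE)
  for (s in colnames(x)) {
    out[[paste0(s, "_coverage")]] <- cov[, s]
    out[[paste0(s, "_methylated")]] <- met[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample raw count table
#'
#' TSV with the feature identifier in the first column and one integer
#' column per sample.
#'
#' @param path file path.
#' @param sampleGroups named group labels for the sample columns.
#' @return A [CountSet-class].
#' @export
readCountTable <- function(path, sampleGroups) {
  df <- tryCatch(read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("unreadable count table: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("count table is empty or has no sample columns: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[which(duplicated(ids))[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    stop("non-numeric count cell in ", path)
  if (any(mat != round(mat))) stop("non-integer count cell in ", path)
  if (any(mat < 0)) stop("negative count in ", path)
  rownames(mat) <- ids
  missing <- setdiff(colnames(mat), names(sampleGroups))
  if (length(missing))
    stop("sample(s) absent from the sample sheet: ",
         paste(missing, collapse = ", "))
  CountSet(mat, sampleGroups[colnames(mat)])
}

#' Write a count table readable by [readCountTable()]
#' @param x a [CountSet-class].
#' @param path output path.
#' @param idColumn header for the feature id column.
#' @export
writeCountTable <- function(x, path, idColumn = "feature_id") {
  k <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(rownames(k), k, check.names = FALSE)
  colnames(out)[1] <- idColumn
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA -> target gene map
#'
#' TSV with columns `mirna_id` and `gene_id` (extra columns are kept).
#' Pairs must be unique.
#' @param path file path.
#' @param source provenance tag recorded on the pairs.
#' @return data.frame with columns mirna_id, gene_id, source.
#' @export
readTargetMap <- function(path, source = "user_supplied") {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% colnames(df)))
    stop("target map needs columns mirna_id and gene_id")
  if (anyDuplicated(df[c("mirna_id", "gene_id")]))
    stop("duplicate (mirna_id, gene_id) pair in target map")
  df$source <- source
  df
}

#' Write positioned records as BED6
#'
#' Converts 1-based single-base positions to BED's 0-based half-open
#' convention (`start = pos - 1`, `end = pos`) and writes rows in a
#' deterministic (chrom, start, name) order.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `strand`,
#'   and optionally `name` and `score`.
#' @param path output path.
#' @export
writeBed <- function(records, path) {
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(records$pos < 1)) stop("BED export: pos must be >= 1")
  name <- if ("name" %in% colnames(records)) as.character(records$name)
          else paste(records$chrom, records$pos, sep = ":")
  score <- if ("score" %in% colnames(records)) records$score else 0
  bed <- data.frame(chrom = records$chrom, start = records$pos - 1L,
                    end = records$pos, name = name, score = score,
                    strand = records$strand, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$name), ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# deterministic TSV writer used by the pipeline stages
writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
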