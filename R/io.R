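# Readers and writers for the plain-text formats the pipeline exchanges:
# BED / bedGraph via rtracklayer, tab-separated tables via base R.

#' Read a BED file into an interval data.frame
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  intervals_from_gr(gr)
}

#' Write intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end`; optional
#'   `name` and `score` columns are carried through.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  gr <- gr_from_intervals(intervals)
  if (!is.null(intervals$name)) gr$name <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write CNV segments as BED6+
#'
#' Name is the call, score is `round(1000 * |mean_log2|)`, and
#' `mean_log2`, `rt_score`, `rt_label` follow as extra columns.
#' @param segments Segment data.frame from [segment_track()].
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(chrom = segments$chrom, start = segments$start, end = segments$end,
                   name = segments$call,
                   score = round(1000 * abs(segments$mean_log2)),
                   strand = ".",
                   mean_log2 = segments$mean_log2,
                   rt_score = segments$rt_score,
                   rt_label = segments$rt_label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#' @param genome A `genome_model`.
#' @param value Per-bin numeric value.
#' @param path Output path.
#' @export
write_bedgraph <- function(genome, value, path) {
  gr <- gr_from_intervals(genome$bins)
  gr$score <- value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- intervals_from_gr(gr)
  df$value <- gr$score[order(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))]
  df
}

#' Write an expression dataset as counts + metadata TSV
#' @param data An `expression_dataset`.
#' @param counts_path,meta_path Output paths.
#' @export
write_expression_tsv <- function(data, counts_path, meta_path) {
  utils::write.table(data$counts, counts_path, sep = "\t", quote = FALSE)
  utils::write.table(data$cell_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read an expression dataset from counts + metadata TSV
#' @param counts_path,meta_path Paths written by [write_expression_tsv()].
#' @return An `expression_dataset`.
#' @export
read_expression_tsv <- function(counts_path, meta_path) {
  counts <- as.matrix(utils::read.table(counts_path, sep = "\t", header = TRUE,
                                        row.names = 1, check.names = FALSE))
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expression_dataset(counts, meta)
}

#' Write a methylation table as TSV
#' @param records Methylation data.frame.
#' @param path Output path.
#' @export
write_methylation_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation table from TSV
#' @param path Path written by [write_methylation_tsv()].
#' @return data.frame of CpG records.
#' @export
read_methylation_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
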