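#' Write fragments as 6-column BED
#'
#' chrom, start, end, name = pair id, score = weight, strand = "." (the
#' fragments are unstranded). Coordinates are 0-based half-open.
#'
#' @param frags fragment data.frame.
#' @param path output file.
#' @export
write_fragments_bed <- function(frags, path) {
  bed <- data.frame(frags$chrom, frags$start, frags$end, frags$pair_id,
                    ifelse(is.na(frags$weight), 0, frags$weight), ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read fragments from 6-column BED
#'
#' @param path BED file written by [write_fragments_bed()].
#' @param sample_id sample id to attach.
#' @return Fragment data.frame; weight 0 in the file is read back as NA
#'   (unweighted multi-map candidate).
#' @export
read_fragments_bed <- function(path, sample_id) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character"))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             pair_id = bed$name,
             weight = ifelse(bed$score == 0, NA_real_, bed$score),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write loci as BED6 plus a locus-type column
#' @param loci locus data.frame.
#' @param path output file.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start, loci$end, loci$locus_id, 0,
                    loci$strand, loci$locus_type)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read loci from BED6 + type
#' @param path file from [write_loci_bed()].
#' @return Locus data.frame with the strand-aware TSS recomputed.
#' @export
read_loci_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand", "type"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character",
                                   "character"))
  data.frame(locus_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, strand = bed$strand, locus_type = bed$type,
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Score table to a flat TSV-ready data.frame
#'
#' One row per locus: type, per-sample counts and scores; thresholds are
#' appended as a trailing comment-style attribute row when written by
#' [write_score_table()].
#'
#' @param st a [score_table()].
#' @return data.frame.
#' @export
score_table_df <- function(st) {
  out <- data.frame(locus_id = st$loci$locus_id,
                    locus_type = st$loci$locus_type,
                    stringsAsFactors = FALSE)
  for (sid in colnames(st$scores)) {
    out[[paste0("chip_", sid)]] <- st$chip_counts[, sid]
    out[[paste0("input_", sid)]] <- st$input_counts[, sid]
    out[[paste0("score_", sid)]] <- st$scores[, sid]
  }
  out
}

#' Write a score table (scores TSV + thresholds TSV)
#' @param st a [score_table()].
#' @param path scores file; thresholds go to `<path>.thresholds.tsv`.
#' @export
write_score_table <- function(st, path) {
  write_tsv(score_table_df(st), path)
  write_tsv(data.frame(sample_id = names(st$thresholds),
                       threshold = unname(st$thresholds),
                       norm_factor = unname(
                         st$norm_factors[names(st$thresholds)])),
            paste0(path, ".thresholds.tsv"))
}
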