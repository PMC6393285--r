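#' Depth-normalization factors relative to the median library
#'
#' Each sample's fragment mass is scaled to the median mass across all
#' samples (ChIPs and Inputs, all time points): factor_s = median / total_s.
#'
#' @param totals named numeric vector of per-sample fragment mass (> 0).
#' @return Named numeric vector of factors.
#' @export
normalization_factors <- function(totals) {
  if (any(totals <= 0)) stop("all sample totals must be > 0")
  median(totals) / totals
}

#' Extend a locus into its scoring window
#'
#' Pol III occupancy (RPC4) is scored on the annotated RNA-coding region
#' extended by 150 bp on each side (`mode = "pol3"`); H3K4me3 and RPB2 are
#' scored 1000 bp up- and downstream of the locus TSS
#' (`mode = "tss_window"`). Windows are clipped at chromosome bounds when
#' `genome` is supplied.
#'
#' @param loci locus data.frame (chrom, start, end, tss).
#' @param mode "pol3" or "tss_window".
#' @param genome optional named vector of chromosome lengths for clipping.
#' @param extension,tss_halfwidth the two window parameters (bp).
#' @return data.frame chrom, start, end (0-based half-open), one row per
#'   locus.
#' @export
extend_locus <- function(loci, mode = c("pol3", "tss_window"), genome = NULL,
                         extension = 150, tss_halfwidth = 1000) {
  mode <- match.arg(mode)
  if (mode == "pol3") {
    s <- loci$start - extension
    e <- loci$end + extension
  } else {
    s <- loci$tss - tss_halfwidth
    e <- loci$tss + tss_halfwidth
  }
  s <- pmax(s, 0)
  if (!is.null(genome)) e <- pmin(e, unname(genome[loci$chrom]))
  data.frame(chrom = loci$chrom, start = as.integer(s), end = as.integer(e),
             stringsAsFactors = FALSE)
}

#' Fractional weighted fragment counts over intervals
#'
#' One fragment is worth one count (its weight); a fragment partially
#' overlapping an interval contributes weight * overlap / fragment length.
#'
#' @param frags fragment data.frame with weights.
#' @param intervals data.frame chrom, start, end (0-based half-open).
#' @return Numeric vector, one count per interval row.
#' @export
count_fragments <- function(frags, intervals) {
  n <- nrow(intervals)
  if (!n) return(numeric())
  if (!nrow(frags)) return(numeric(n))
  fr <- df_to_granges(frags)
  iv <- df_to_granges(intervals)
  # disjoint chromosome sets are a legitimate empty result, not a warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(fr, iv))
  if (!length(ov)) return(numeric(n))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  ov_width <- pmin(frags$end[qi], intervals$end[si]) -
    pmax(frags$start[qi], intervals$start[si])
  contrib <- frags$weight[qi] * ov_width / (frags$end - frags$start)[qi]
  agg <- rowsum(contrib, si)
  out <- numeric(n)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Pseudocounted log2 ChIP/Input occupancy score
#'
#' score = log2((chip * chip_factor + pseudocount) /
#'              (input * input_factor + pseudocount)); the pseudocount
#' (default 16) is added to both depth-normalized counts, keeping the
#' score finite and exactly 0 when normalized counts agree.
#'
#' @param chip_count,input_count weighted fractional counts (vectorized).
#' @param chip_factor,input_factor normalization factors.
#' @param pseudocount added to both normalized counts (default 16).
#' @return Numeric log2 scores.
#' @export
compute_score <- function(chip_count, input_count, chip_factor = 1,
                          input_factor = 1, pseudocount = 16) {
  stopifnot(all(chip_count >= 0), all(input_count >= 0))
  log2((chip_count * chip_factor + pseudocount) /
         (input_count * input_factor + pseudocount))
}

#' Tile a genome into non-overlapping bins
#' @param genome named vector of chromosome lengths.
#' @param bin_size bp per bin; the trailing partial bin is kept.
#' @return data.frame chrom, start, end.
#' @export
genome_bins <- function(genome, bin_size) {
  stopifnot(bin_size > 0)
  out <- lapply(names(genome), function(ch) {
    s <- seq(0, genome[ch] - 1, by = bin_size)
    data.frame(chrom = ch, start = as.integer(s),
               end = as.integer(pmin(s + bin_size, genome[ch])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empirical-null peak threshold from genome-bin scores
#'
#' Scores computed in non-overlapping bins over the entire genome form the
#' empirical null; the peak cutoff is the quantile at level
#' 1 - alpha / n_loci (Bonferroni correction for the multiplicity of
#' loci), with linear interpolation between order statistics. A locus "has
#' a peak" for a factor iff its score exceeds this threshold.
#'
#' @param bin_scores numeric vector of bin scores (all bins retained,
#'   including empty ones).
#' @param n_loci number of loci tested (Bonferroni multiplicity).
#' @param alpha family-wise level (default 0.05).
#' @return The threshold (numeric scalar).
#' @export
null_threshold <- function(bin_scores, n_loci, alpha = 0.05) {
  stopifnot(n_loci >= 1, alpha > 0)
  level <- alpha / n_loci
  if (level >= 1) return(min(bin_scores))
  if (length(bin_scores) < 1 / level)
    stop("only ", length(bin_scores), " bins for quantile level ",
         format(1 - level), "; use a larger genome or alpha")
  unname(quantile(bin_scores, 1 - level, type = 7, names = FALSE))
}

#' Build the loci x samples occupancy score table
#'
#' For each ChIP sample, counts weighted fragments in the factor-specific
#' scoring window (RPC4: locus +/- 150 bp; H3K4me3/RPB2: TSS +/- 1 kb),
#' computes the pseudocounted log2 ChIP/Input score against the paired
#' Input, and derives the per-sample empirical-null threshold from
#' genome-wide bins (400 bp for RPC4, 2000 bp for H3K4me3/RPB2).
#'
#' @param frags_by_sample named list of processed fragment data.frames
#'   (ChIPs and Inputs).
#' @param loci locus data.frame.
#' @param sheet sample sheet (sample_id, factor, timepoint, replicate,
#'   input_id); ChIP rows must name an input_id present in
#'   `frags_by_sample`.
#' @param genome named vector of chromosome lengths.
#' @param pseudocount,alpha,extension,tss_halfwidth scoring parameters.
#' @param bin_sizes named bin sizes per factor (bp).
#' @return An object of class `score_table`: list with `loci`, `samples`
#'   (ChIP rows of the sheet), matrices `chip_counts`, `input_counts`,
#'   `scores` (loci x ChIP samples), `thresholds` and `norm_factors`.
#' @export
score_table <- function(frags_by_sample, loci, sheet, genome,
                        pseudocount = 16, alpha = 0.05, extension = 150,
                        tss_halfwidth = 1000,
                        bin_sizes = c(RPC4 = 400, H3K4me3 = 2000,
                                      RPB2 = 2000)) {
  chips <- sheet[sheet$factor != "Input", , drop = FALSE]
  missing_in <- setdiff(c(chips$sample_id, chips$input_id),
                        names(frags_by_sample))
  if (length(missing_in))
    stop("missing fragment sets for sample(s): ",
         paste(missing_in, collapse = ", "))

  totals <- vapply(frags_by_sample, function(f) sum(f$weight), numeric(1))
  nf <- normalization_factors(totals)

  n_loci <- nrow(loci)
  ids <- chips$sample_id
  chip_counts <- input_counts <- scores <-
    matrix(NA_real_, n_loci, length(ids),
           dimnames = list(loci$locus_id, ids))
  thresholds <- setNames(numeric(length(ids)), ids)

  windows <- list(
    pol3 = extend_locus(loci, "pol3", genome, extension = extension),
    tss = extend_locus(loci, "tss_window", genome,
                       tss_halfwidth = tss_halfwidth))
  bins <- lapply(bin_sizes[unique(chips$factor)], genome_bins,
                 genome = genome)
  bin_counts <- list()  # cache per-sample bin counts by (sample, bin size)

  count_bins <- function(sid, fac) {
    key <- paste(sid, bin_sizes[[fac]])
    if (is.null(bin_counts[[key]]))
      bin_counts[[key]] <<- count_fragments(frags_by_sample[[sid]],
                                            bins[[fac]])
    bin_counts[[key]]
  }

  for (j in seq_along(ids)) {
    sid <- ids[j]; fac <- chips$factor[j]; iid <- chips$input_id[j]
    win <- if (fac == "RPC4") windows$pol3 else windows$tss
    cc <- count_fragments(frags_by_sample[[sid]], win)
    ic <- count_fragments(frags_by_sample[[iid]], win)
    chip_counts[, j] <- cc
    input_counts[, j] <- ic
    scores[, j] <- compute_score(cc, ic, nf[sid], nf[iid], pseudocount)
    bsc <- compute_score(count_bins(sid, fac), count_bins(iid, fac),
                         nf[sid], nf[iid], pseudocount)
    thresholds[j] <- null_threshold(bsc, n_loci, alpha)
  }
  structure(list(loci = loci, samples = chips, chip_counts = chip_counts,
                 input_counts = input_counts, scores = scores,
                 thresholds = thresholds, norm_factors = nf,
                 pseudocount = pseudocount, alpha = alpha),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", nrow(x$scores), "loci x", ncol(x$scores),
      "ChIP samples\n")
  cat("factors:", paste(unique(x$samples$factor), collapse = ", "), "\n")
  cat("thresholds:\n")
  print(round(x$thresholds, 3))
  invisible(x)
}
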