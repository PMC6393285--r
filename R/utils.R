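#' @importFrom stats median quantile rnorm runif rpois rbinom setNames
#'   pt ks.test chisq.test phyper smooth.spline predict sd var cor lm
#' @importFrom utils write.table read.table head
NULL

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Each simulated sample draws from its own RNG stream so that adding or
#' reordering samples does not perturb the others. The sub-seed is a simple
#' multiplicative hash of the label folded into the master seed, kept below
#' 2^31 so it is a valid R integer.
#'
#' @param seed master integer seed.
#' @param label character scalar identifying the stream (e.g. a sample id).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

#' Truncated-normal fragment sizes (always >= 1 bp)
#' @keywords internal
rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < 1)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 1]
  }
  x
}

#' Empty fragment table with the canonical columns
#' @keywords internal
empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             pair_id = character(), weight = numeric(),
             sample_id = character(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact numeric key for (chrom, start, end) triples
#'
#' Packs coordinates into a double (exact below 2^53) for fast
#' duplicate detection; requires start and length < 2^22 (~4.2 Mb),
#' which holds for the miniature genomes used here and errors otherwise.
#' @keywords internal
coord_key <- function(chrom, start, end) {
  len <- end - start
  if (any(start >= 2^22) || any(len >= 2^22))
    return(paste(chrom, start, end))  # fall back to string keys
  ci <- as.integer(factor(chrom))
  ci * 2^44 + start * 2^22 + len
}

#' Convert a fragment or interval data.frame to a GRanges
#'
#' Coordinates throughout the package are 0-based half-open ([start, end)),
#' the BED convention; GRanges is 1-based closed, so start is shifted by one.
#' @keywords internal
df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
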