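#' Average tag-density profile around locus anchors (metagene plot)
#'
#' Per-base weighted fragment coverage in a strand-oriented window around
#' each locus TSS, averaged across loci, normalized per million fragments
#' of library mass, and binned by averaging. For minus-strand loci the
#' window is mirrored, so negative offsets are always upstream of the
#' locus in its transcription direction.
#'
#' @param frags weighted fragment data.frame.
#' @param loci locus data.frame (chrom, tss, strand).
#' @param window half-width in bp (default 2000).
#' @param bin bp per bin (default 10; must divide 2*window).
#' @param depth fragment mass used for per-million normalization
#'   (default: total weight of `frags`).
#' @return data.frame of class `tag_profile`: offset (bin start relative
#'   to the anchor), density (weighted fragments per bp per locus per
#'   million fragments), with attribute n_loci.
#' @export
tag_density_profile <- function(frags, loci, window = 2000, bin = 10,
                                depth = sum(frags$weight)) {
  if (!nrow(loci)) stop("empty locus set")
  stopifnot(window > 0, bin > 0, (2 * window) %% bin == 0)
  width <- 2L * as.integer(window)
  delta <- numeric(width + 1L)
  for (i in seq_len(nrow(loci))) {
    tss <- loci$tss[i]
    sel <- which(frags$chrom == loci$chrom[i] &
                   frags$start < tss + window & frags$end > tss - window)
    if (!length(sel)) next
    if (loci$strand[i] == "-") {
      ## genomic position p covered by [s, e) maps to offset tss - p
      o_s <- tss - frags$end[sel] + 1L
      o_e <- tss - frags$start[sel] + 1L
    } else {
      o_s <- frags$start[sel] - tss
      o_e <- frags$end[sel] - tss
    }
    o_s <- pmax(o_s, -window); o_e <- pmin(o_e, window)
    w <- frags$weight[sel]
    ## difference-array accumulation of per-base coverage
    for (k in seq_along(sel)) {
      a <- o_s[k] + window + 1L; b <- o_e[k] + window + 1L
      if (b > a) {
        delta[a] <- delta[a] + w[k]
        delta[b] <- delta[b] - w[k]
      }
    }
  }
  cov <- cumsum(delta[seq_len(width)])
  dens <- if (depth > 0) cov / nrow(loci) / (depth / 1e6) else cov
  nb <- width %/% bin
  binned <- vapply(seq_len(nb), function(j)
    mean(dens[((j - 1) * bin + 1):(j * bin)]), numeric(1))
  structure(data.frame(offset = seq(-window, window - bin, by = bin),
                       density = binned),
            n_loci = nrow(loci), class = c("tag_profile", "data.frame"))
}
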