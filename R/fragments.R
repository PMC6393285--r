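#' Collapse redundant fragments
#'
#' Fragments sequenced more than once (identical chrom, start, end) are
#' collapsed to a single record; the result is canonically sorted by
#' chrom, start, end so it does not depend on input order. Strand is
#' ignored: sequenced fragments are unstranded intervals.
#'
#' @param frags fragment data.frame (one sample).
#' @return The deduplicated, sorted fragment data.frame.
#' @export
dedup_fragments <- function(frags) {
  if (!nrow(frags)) return(frags)
  key <- coord_key(frags$chrom, frags$start, frags$end)
  out <- frags[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical fragment-size probability distribution
#'
#' Relative frequency of fragment lengths among uniquely mapped fragments,
#' at 1 bp resolution. Probabilities are floored at `floor_p` and
#' renormalized so that unseen (or extremely rare) sizes never receive a
#' zero weight when multi-mapped candidates are scored against the
#' distribution.
#'
#' @param unique_frags fragment data.frame of unique mappers.
#' @param floor_p minimum probability after flooring (default 1e-6).
#' @return An object of class `size_distribution`: list with `prob`
#'   (named numeric, names = length in bp) and `floor` (the floor applied,
#'   also returned for lengths absent from the table).
#' @export
estimate_size_distribution <- function(unique_frags, floor_p = 1e-6) {
  if (!nrow(unique_frags)) stop("cannot estimate size distribution: no fragments")
  len <- unique_frags$end - unique_frags$start
  tab <- table(len)
  p <- as.numeric(tab) / sum(tab)
  p <- pmax(p, floor_p)
  p <- p / sum(p)
  structure(list(prob = setNames(p, names(tab)), floor = floor_p),
            class = "size_distribution")
}

#' Look up size probabilities
#'
#' Lengths absent from the empirical table get the floor probability.
#' @param dist a [estimate_size_distribution()] result.
#' @param len integer vector of fragment lengths (bp).
#' @return Numeric vector of probabilities.
#' @export
size_probability <- function(dist, len) {
  p <- unname(dist$prob[as.character(len)])
  p[is.na(p)] <- dist$floor
  p
}

#' Weight the candidate fragments of one multi-mapped tag pair
#'
#' Each candidate receives the normalized size probability of its length,
#' so that the pair contributes total weight 1. Pairs with more than
#' `max_matches` candidates are discarded (empty result), mirroring the
#' alignment cap on matches per tag.
#'
#' @param candidates fragment data.frame, all rows sharing one pair_id.
#' @param dist a size distribution from [estimate_size_distribution()].
#' @param max_matches discard threshold (default 500).
#' @return The candidates with `weight` filled in (sums to 1), or a
#'   zero-row data.frame if the pair is discarded.
#' @export
weight_multimapped <- function(candidates, dist, max_matches = 500) {
  stopifnot(nrow(candidates) >= 1)
  if (length(unique(candidates$pair_id)) != 1L)
    stop("candidates must all share one pair_id")
  if (nrow(candidates) > max_matches)
    return(candidates[0, , drop = FALSE])
  p <- size_probability(dist, candidates$end - candidates$start)
  candidates$weight <- p / sum(p)
  candidates
}

#' Full fragment-level preprocessing for one sample
#'
#' Applies the ingestion contract: unique pairs (weight 1) are
#' deduplicated on exact coordinates; the fragment-size distribution is
#' estimated from them; multi-candidate pairs (weight NA) are weighted by
#' normalized size probability (pairs with more than `max_matches`
#' candidates dropped); finally, multi-candidates whose coordinates
#' duplicate a unique fragment are removed.
#'
#' @param frags fragment data.frame for one sample; rows with weight NA
#'   are treated as multi-map candidates grouped by pair_id.
#' @param max_matches candidate cap per pair (default 500).
#' @return List with `fragments` (weighted, deduplicated data.frame),
#'   `size_dist`, `n_unique_pairs`, `n_multi_pairs` (retained),
#'   `n_discarded_pairs`.
#' @export
process_fragments <- function(frags, max_matches = 500) {
  if (!nrow(frags))
    return(list(fragments = frags, size_dist = NULL, n_unique_pairs = 0L,
                n_multi_pairs = 0L, n_discarded_pairs = 0L))
  is_multi_pair <- frags$pair_id %in% frags$pair_id[is.na(frags$weight)]
  uni <- dedup_fragments(frags[!is_multi_pair, , drop = FALSE])
  if (!nrow(uni)) stop("no uniquely mapped fragments to anchor the size distribution")
  dist <- estimate_size_distribution(uni)

  mm <- frags[is_multi_pair, , drop = FALSE]
  n_disc <- 0L; n_kept <- 0L
  if (nrow(mm)) {
    sizes <- mm$end - mm$start
    p <- size_probability(dist, sizes)
    grp <- factor(mm$pair_id)
    cnt <- tabulate(grp)
    over <- cnt[as.integer(grp)] > max_matches
    n_disc <- length(unique(mm$pair_id[over]))
    mm <- mm[!over, , drop = FALSE]; p <- p[!over]; grp <- factor(mm$pair_id)
    if (nrow(mm)) {
      gi <- as.integer(grp)
      tot <- rowsum(p, gi)
      mm$weight <- p / tot[gi, 1]
      ## drop candidates duplicating a unique fragment's coordinates
      allkey <- coord_key(c(uni$chrom, mm$chrom), c(uni$start, mm$start),
                          c(uni$end, mm$end))
      mkey <- allkey[-seq_len(nrow(uni))]
      mm <- mm[!(mkey %in% allkey[seq_len(nrow(uni))]), , drop = FALSE]
      n_kept <- length(unique(mm$pair_id))
    }
  }
  out <- rbind(uni, mm)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  list(fragments = out, size_dist = dist, n_unique_pairs = nrow(uni),
       n_multi_pairs = n_kept, n_discarded_pairs = n_disc)
}
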