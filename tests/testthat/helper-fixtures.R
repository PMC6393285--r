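# Shared fixtures: everything is generated in code at test time.

# A fragment table from bare coordinates (weight 1, one sample).
make_frags <- function(chrom, start, end, weight = 1,
                       sample_id = "s1", pair_id = NULL) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), pair_id = pair_id %||%
               sprintf("%s_p%04d", rep_len(sample_id, n), seq_len(n)),
             weight = rep_len(weight, n), sample_id = rep_len(sample_id, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A locus table from bare coordinates.
make_loci <- function(start, end, chrom = "chr1", strand = "+",
                      type = "tRNA") {
  n <- length(start)
  strand <- rep_len(strand, n)
  data.frame(locus_id = sprintf("L%03d", seq_len(n)),
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), strand = strand,
             locus_type = rep_len(type, n),
             tss = as.integer(ifelse(strand == "+", start, end - 1L)),
             stringsAsFactors = FALSE)
}

# A minimal score_table object built directly from a score matrix.
make_score_table <- function(scores, thresholds, loci = NULL,
                             factors = NULL, timepoints = NULL,
                             replicates = NULL) {
  ids <- colnames(scores)
  if (is.null(loci))
    loci <- make_loci(start = seq_len(nrow(scores)) * 1000,
                      end = seq_len(nrow(scores)) * 1000 + 72)
  rownames(scores) <- loci$locus_id
  samples <- data.frame(
    sample_id = ids,
    factor = factors %||% rep("RPC4", length(ids)),
    timepoint = timepoints %||% rep("TP0", length(ids)),
    replicate = replicates %||% seq_along(ids),
    input_id = paste0("in_", ids), stringsAsFactors = FALSE)
  structure(list(loci = loci, samples = samples,
                 chip_counts = scores, input_counts = scores * 0,
                 scores = scores,
                 thresholds = setNames(rep_len(thresholds, length(ids)), ids),
                 norm_factors = setNames(rep(1, length(ids)), ids),
                 pseudocount = 16, alpha = 0.05),
            class = "score_table")
}

# A small, fast simulation config for integration-style tests.
cheap_cfg <- function(seed = 1L, ...) {
  args <- list(genome_length = 5e5, n_chromosomes = 4,
               n_loci_by_type = c(tRNA = 10, SINE = 4, Rn5s = 2,
                                  Rn4.5s = 1, other = 1),
               depth_per_sample = 3e4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Brute-force per-base fractional overlap count (oracle for count_fragments).
brute_count <- function(frags, interval) {
  tot <- 0
  for (i in seq_len(nrow(frags))) {
    if (frags$chrom[i] != interval$chrom) next
    len <- frags$end[i] - frags$start[i]
    bases <- seq(frags$start[i], frags$end[i] - 1)
    inside <- sum(bases >= interval$start & bases < interval$end)
    tot <- tot + frags$weight[i] * inside / len
  }
  tot
}
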