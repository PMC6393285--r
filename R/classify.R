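#' Flag isolated Pol III loci
#'
#' A locus is isolated iff its edge-to-edge distance to every other Pol
#' III locus is at least `min_gap` (default 1.5 kb); isolated loci avoid
#' confounding signal from overlapping peaks at closely spaced loci.
#'
#' @param loci locus data.frame.
#' @param min_gap bp (boundary counts as isolated).
#' @return Named logical vector (locus_id).
#' @export
flag_isolated <- function(loci, min_gap = 1500) {
  n <- nrow(loci)
  out <- setNames(rep(TRUE, n), loci$locus_id)
  if (n < 2) return(out)
  for (ch in unique(loci$chrom)) {
    i <- which(loci$chrom == ch)
    if (length(i) < 2) next
    s <- loci$start[i]; e <- loci$end[i]
    ## edge-to-edge distance between intervals a,b: max(s_a - e_b, s_b - e_a)
    d <- outer(s, e, "-")
    d <- pmax(d, t(d))
    diag(d) <- Inf
    out[i[apply(d, 1, min) < min_gap]] <- FALSE
  }
  out
}

#' Flag loci near Pol II genes
#'
#' TRUE iff the minimum distance from the locus interval to any Pol II
#' feature point (TSS or poly-A site) is at most `max_dist` (default
#' 2.65 kb, boundary inclusive).
#'
#' @param loci locus data.frame.
#' @param pol2 Pol II feature data.frame (chrom, pos, type).
#' @param max_dist bp.
#' @return Named logical vector (locus_id).
#' @export
flag_near_pol2 <- function(loci, pol2, max_dist = 2650) {
  out <- setNames(rep(FALSE, nrow(loci)), loci$locus_id)
  if (!nrow(pol2) || !nrow(loci)) return(out)
  for (ch in unique(loci$chrom)) {
    i <- which(loci$chrom == ch)
    p <- pol2$pos[pol2$chrom == ch]
    if (!length(p)) next
    for (k in i) {
      d <- pmax(loci$start[k] - p, p - (loci$end[k] - 1L), 0)
      if (min(d) <= max_dist) out[k] <- TRUE
    }
  }
  out
}

#' Flag loci with a CpG island near the TSS
#'
#' TRUE iff any CpG island overlaps the window `tss +/- window` (default
#' 1 kb, half-open).
#'
#' @param loci locus data.frame (with tss).
#' @param cpg CpG island intervals (chrom, start, end).
#' @param window bp around the TSS.
#' @return Named logical vector (locus_id).
#' @export
flag_cpg <- function(loci, cpg, window = 1000) {
  out <- setNames(rep(FALSE, nrow(loci)), loci$locus_id)
  if (!nrow(cpg) || !nrow(loci)) return(out)
  win <- data.frame(chrom = loci$chrom,
                    start = pmax(loci$tss - window, 0L),
                    end = loci$tss + window)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(df_to_granges(win), df_to_granges(cpg)))
  out[unique(S4Vectors::queryHits(ov))] <- TRUE
  out
}

.peak_group_levels <- c("RPC4+H3K4me3+RPB2", "RPC4+RPB2", "RPC4+H3K4me3",
                        "H3K4me3+RPB2", "RPC4", "RPB2", "H3K4me3", "none")

#' Assign loci to the eight peak-presence groups
#'
#' For one replicate combination (a mapping factor -> ChIP sample id), a
#' locus's group is the subset of {RPC4, H3K4me3, RPB2} whose score
#' exceeds the factor's empirical-null threshold in that sample: eight
#' possible groups including "none".
#'
#' @param st a [score_table()].
#' @param replicate_map named character vector mapping factor names to
#'   ChIP sample ids present in `st` (e.g. c(RPC4 = "RPC4_TP0_r1", ...)).
#' @return Factor vector (one of the 8 groups) named by locus_id.
#' @export
assign_groups <- function(st, replicate_map) {
  miss <- setdiff(replicate_map, colnames(st$scores))
  if (length(miss))
    stop("sample(s) not in score table: ", paste(miss, collapse = ", "))
  present <- sapply(names(replicate_map), function(f) {
    sid <- replicate_map[[f]]
    st$scores[, sid] > st$thresholds[sid]
  })
  lab <- apply(present, 1, function(z) {
    on <- names(replicate_map)[z]
    if (!length(on)) "none" else paste(on, collapse = "+")
  })
  canon <- function(s) {
    if (s == "none") return(s)
    parts <- strsplit(s, "+", fixed = TRUE)[[1]]
    paste(intersect(c("RPC4", "H3K4me3", "RPB2"), parts), collapse = "+")
  }
  lab <- vapply(lab, canon, character(1))
  factor(setNames(lab, rownames(st$scores)), levels = .peak_group_levels)
}

#' Peak-presence summary by locus type
#'
#' Counts and percentages of loci in each of the eight peak-presence
#' groups, per locus type, for one or two replicate combinations (the
#' two-replicate layout of the published grouping table).
#'
#' @param st a [score_table()].
#' @param replicate_maps list of named replicate maps (see
#'   [assign_groups()]); one summary column set per map.
#' @param loci_subset optional locus ids to restrict to (e.g. isolated
#'   loci).
#' @return data.frame: locus_type, n, group, then per map `count_<name>`
#'   and `pct_<name>` columns.
#' @export
peak_group_summary <- function(st, replicate_maps, loci_subset = NULL) {
  if (is.null(names(replicate_maps)))
    names(replicate_maps) <- paste0("rep", seq_along(replicate_maps))
  keep <- if (is.null(loci_subset)) st$loci$locus_id else loci_subset
  types <- st$loci$locus_type[match(keep, st$loci$locus_id)]
  base <- expand.grid(group = .peak_group_levels,
                      locus_type = unique(types),
                      stringsAsFactors = FALSE)
  for (nm in names(replicate_maps)) {
    g <- assign_groups(st, replicate_maps[[nm]])[keep]
    tab <- table(types, g)
    cnt <- mapply(function(ty, gr) tab[ty, gr], base$locus_type,
                  as.character(base$group))
    ntyp <- table(types)[base$locus_type]
    base[[paste0("count_", nm)]] <- as.integer(cnt)
    base[[paste0("pct_", nm)]] <- round(100 * cnt / as.numeric(ntyp), 1)
  }
  base$n_type <- as.integer(table(types)[base$locus_type])
  base[, c("locus_type", "n_type", "group",
           setdiff(names(base), c("locus_type", "n_type", "group")))]
}

#' Permutation-based Welch t test
#'
#' Two-sided p-value for a difference in means between two score sets,
#' computed by permuting group labels: p = (1 + #{|t*| >= |t|}) /
#' (n_perm + 1) with the Welch (unequal-variance) t statistic.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return List: statistic (observed Welch t), p_value, n_perm.
#' @export
permutation_t_test <- function(x, y, n_perm = 10000, seed = 1L) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  welch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    (mean(a) - mean(b)) / sqrt(va + vb)
  }
  if (var(x) == 0 && var(y) == 0) {
    warning("zero variance in both groups; p = 1")
    return(list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                p_value = 1, n_perm = n_perm))
  }
  t_obs <- welch(x, y)
  z <- c(x, y); nx <- length(x)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(z), nx)
    t_b <- welch(z[idx], z[-idx])
    if (!is.na(t_b) && abs(t_b) >= abs(t_obs)) hits <- hits + 1L
  }
  list(statistic = t_obs, p_value = (1 + hits) / (n_perm + 1),
       n_perm = n_perm)
}
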