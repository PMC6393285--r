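#' Call tRNA gene clusters
#'
#' A cluster is a maximal run of `min_size` or more tRNA genes on one
#' chromosome in which each gene is spaced less than `max_gap` from the
#' next (gap measured edge-to-edge: start of the next gene minus end of
#' the current one).
#'
#' @param trna_loci locus data.frame (tRNA genes).
#' @param max_gap bp, strict upper bound on inter-gene spacing (default
#'   5 kb).
#' @param min_size minimum genes per cluster (default 3).
#' @return data.frame: cluster_id, chrom, start, end (span), n_genes,
#'   members (comma-separated locus ids ordered by start).
#' @export
call_clusters <- function(trna_loci, max_gap = 5000, min_size = 3) {
  out <- list()
  cid <- 0
  for (ch in sort(unique(trna_loci$chrom))) {
    l <- trna_loci[trna_loci$chrom == ch, , drop = FALSE]
    l <- l[order(l$start, l$end), , drop = FALSE]
    n <- nrow(l)
    if (n < min_size) next
    gaps <- l$start[-1] - l$end[-n]
    run_start <- 1
    for (i in seq_len(n)) {
      chain_broken <- i == n || gaps[i] >= max_gap
      if (chain_broken) {
        size <- i - run_start + 1
        if (size >= min_size) {
          cid <- cid + 1
          idx <- run_start:i
          out[[cid]] <- data.frame(
            cluster_id = sprintf("cluster_%02d", cid), chrom = ch,
            start = l$start[run_start], end = l$end[i], n_genes = size,
            members = paste(l$locus_id[idx], collapse = ","),
            stringsAsFactors = FALSE)
        }
        run_start <- i + 1
      }
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_genes = integer(), members = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' KS tests of fold change inside versus outside clusters
#'
#' For each cluster, a two-sample two-sided Kolmogorov-Smirnov test
#' (asymptotic p) compares the fold-change distribution of its member
#' genes against non-clustered genes on the same chromosome. Clusters on
#' chromosomes without both groups are skipped.
#'
#' @param fold_changes named numeric vector (locus_id -> fold change,
#'   log2 units).
#' @param clusters from [call_clusters()].
#' @param trna_loci the locus table the clusters were called on.
#' @param alpha flag threshold (default 0.05).
#' @return data.frame: cluster_id, chrom, n_in, n_out, D, p_value, flagged.
#' @export
cluster_ks_tests <- function(fold_changes, clusters, trna_loci,
                             alpha = 0.05) {
  clustered_ids <- unlist(strsplit(clusters$members, ","))
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    ch <- clusters$chrom[i]
    members <- strsplit(clusters$members[i], ",")[[1]]
    on_ch <- trna_loci$locus_id[trna_loci$chrom == ch]
    outside <- setdiff(on_ch, clustered_ids)
    x <- fold_changes[members]; x <- x[is.finite(x)]
    y <- fold_changes[outside]; y <- y[is.finite(y)]
    if (!length(x) || !length(y)) {
      message("cluster ", clusters$cluster_id[i],
              " skipped: no finite fold changes in or outside clusters on ",
              ch)
      next
    }
    kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      cluster_id = clusters$cluster_id[i], chrom = ch,
      n_in = length(x), n_out = length(y),
      D = unname(kt$statistic), p_value = kt$p.value,
      flagged = kt$p.value < alpha, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(), chrom = character(),
                      n_in = integer(), n_out = integer(), D = numeric(),
                      p_value = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Chi-square test of chromosome association of changing loci
#'
#' Tests independence between chromosome and changing/stable status on
#' the chromosomes x {changing, stable} contingency table, without
#' continuity correction. Pearson residuals support a mosaic-style
#' reading of which chromosomes are enriched or depleted in changing
#' genes.
#'
#' @param status named character vector (locus_id -> "changing" or
#'   "stable"); loci with other values are dropped.
#' @param chrom named character vector (locus_id -> chromosome).
#' @return List: chi2, df, p_value, table (observed), expected,
#'   residuals (Pearson).
#' @export
chromosome_chisq <- function(status, chrom) {
  keep <- names(status)[status %in% c("changing", "stable")]
  tab <- table(chrom = chrom[keep], status = factor(status[keep],
               levels = c("changing", "stable")))
  if (nrow(tab) < 2) stop("need loci on at least two chromosomes")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab, expected = ct$expected,
       residuals = ct$residuals)
}

#' Hypergeometric enrichment of the overlap between two gene sets
#'
#' Given two subsets of a common universe and their observed overlap,
#' reports the expected overlap under independence (a*b/N), the
#' enrichment fold, and the upper-tail hypergeometric p-value
#' P(X >= overlap).
#'
#' @param set_a,set_b set sizes.
#' @param overlap observed intersection size.
#' @param universe universe size.
#' @return List: expected, fold, p_value.
#' @export
overlap_enrichment <- function(set_a, set_b, overlap, universe) {
  if (overlap > min(set_a, set_b) || max(set_a, set_b) > universe ||
      any(c(set_a, set_b, overlap, universe) < 0))
    stop("inconsistent counts: need overlap <= min(a, b) <= universe")
  expected <- set_a * set_b / universe
  list(expected = expected,
       fold = if (expected > 0) overlap / expected else NA_real_,
       p_value = phyper(overlap - 1, set_a, universe - set_a, set_b,
                        lower.tail = FALSE))
}
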