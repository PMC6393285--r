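#' Run the full occupancy-dynamics analysis on simulated data
#'
#' Orchestrates simulate -> fragment preprocessing -> scoring ->
#' classification -> differential dynamics -> spatial statistics ->
#' profiles, entirely determined by the generator configuration (and its
#' seed). Stages that need factors absent from `factors` are skipped.
#'
#' @param cfg a [sim_config()].
#' @param factors ChIP factors to simulate and analyse.
#' @param contrast time-point contrast for the dynamics stage.
#' @param fdr significance threshold on q-values.
#' @param outdir optional directory; when given, all tables are written
#'   there (BED/TSV) together with a plain-text run manifest.
#' @return List: cfg, annotation (loci/pol2/cpg/truth), sheet,
#'   fragment_stats, score_table, annotation_flags, groups (per replicate
#'   map), group_summary, dynamics, clusters, cluster_ks, chisq,
#'   profiles.
#' @export
run_pipeline <- function(cfg, factors = c("RPC4", "H3K4me3", "RPB2"),
                         contrast = "TP36-TP0", fdr = 0.05,
                         outdir = NULL) {
  ann <- simulate_annotation(cfg)
  sheet <- sim_sample_sheet(factors)
  genome <- sim_genome(cfg)

  frags <- list(); fstats <- list()
  for (i in seq_len(nrow(sheet))) {
    smp <- sheet[i, ]
    raw <- simulate_fragments(cfg, ann$loci, ann$truth, smp, ann$pol2)
    pf <- process_fragments(raw)
    frags[[smp$sample_id]] <- pf$fragments
    fstats[[smp$sample_id]] <- data.frame(
      sample_id = smp$sample_id, n_unique = pf$n_unique_pairs,
      n_multi = pf$n_multi_pairs, n_discarded = pf$n_discarded_pairs,
      mass = sum(pf$fragments$weight))
  }
  fstats <- do.call(rbind, fstats)

  st <- score_table(frags, ann$loci, sheet, genome)

  flags <- data.frame(locus_id = ann$loci$locus_id,
                      isolated = unname(flag_isolated(ann$loci)),
                      near_pol2 = unname(flag_near_pol2(ann$loci, ann$pol2)),
                      has_cpg = unname(flag_cpg(ann$loci, ann$cpg)),
                      stringsAsFactors = FALSE)

  ## peak-presence groups; the two published replicate combinations pair
  ## RPC4/RPB2 replicate r with H3K4me3 replicate 2 (r = 1) or 2 (r = 2)
  groups <- NULL; group_summary <- NULL
  class_factors <- intersect(c("RPC4", "H3K4me3", "RPB2"), factors)
  if (length(class_factors) && all(c("RPC4", "H3K4me3", "RPB2") %in%
                                   factors)) {
    rmaps <- list(
      rep1 = c(RPC4 = "RPC4_TP0_r1", RPB2 = "RPB2_TP0_r1",
               H3K4me3 = "H3K4me3_TP0_r2"),
      rep2 = c(RPC4 = "RPC4_TP0_r2", RPB2 = "RPB2_TP0_r2",
               H3K4me3 = "H3K4me3_TP0_r2"))
    groups <- lapply(rmaps, assign_groups, st = st)
    group_summary <- peak_group_summary(
      st, rmaps, loci_subset = flags$locus_id[flags$isolated])
  }

  dynamics <- NULL; clusters <- NULL; cluster_ks <- NULL; chisq <- NULL
  if ("RPC4" %in% factors) {
    dynamics <- call_significant(diff_occupancy(st, contrast, fdr), fdr)

    trna <- ann$loci[ann$loci$locus_type == "tRNA", , drop = FALSE]
    clusters <- call_clusters(trna)
    rpc4 <- st$samples$factor == "RPC4"
    tps <- strsplit(contrast, "-", fixed = TRUE)[[1]]
    mean_tp <- function(l) rowMeans(
      st$scores[, st$samples$sample_id[rpc4 & st$samples$timepoint == l],
                drop = FALSE])
    fc <- mean_tp(tps[1]) - mean_tp(tps[2])
    if (nrow(clusters))
      cluster_ks <- cluster_ks_tests(fc, clusters, trna)
    status <- setNames(ifelse(dynamics$status == "below_cutoff", "excluded",
                       ifelse(dynamics$significant, "changing", "stable")),
                       dynamics$locus_id)
    chrom <- setNames(ann$loci$chrom, ann$loci$locus_id)
    if (length(unique(chrom[names(status)[status != "excluded"]])) >= 2)
      chisq <- chromosome_chisq(status, chrom)
  }

  profiles <- NULL
  if (!is.null(groups)) {
    triple <- names(groups$rep2)[groups$rep2 == "RPC4+H3K4me3+RPB2"]
    anchor <- ann$loci[ann$loci$locus_id %in% triple, , drop = FALSE]
    if (nrow(anchor)) {
      prof_samples <- c(RPC4 = "RPC4_TP0_r2", H3K4me3 = "H3K4me3_TP0_r2",
                        RPB2 = "RPB2_TP0_r2")
      profiles <- lapply(prof_samples, function(sid)
        tag_density_profile(frags[[sid]], anchor))
    }
  }

  out <- list(cfg = cfg, annotation = ann, sheet = sheet,
              fragment_stats = fstats, score_table = st, flags = flags,
              groups = groups, group_summary = group_summary,
              dynamics = dynamics, clusters = clusters,
              cluster_ks = cluster_ks, chisq = chisq, profiles = profiles,
              fragments = frags)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Write all pipeline tables under a directory
#' @param res a [run_pipeline()] result.
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_loci_bed(res$annotation$loci, p("loci.bed"))
  write_tsv(res$annotation$truth, p("truth.tsv"))
  write_tsv(res$annotation$pol2, p("pol2_features.tsv"))
  write_tsv(res$annotation$cpg, p("cpg_islands.tsv"))
  write_tsv(res$sheet, p("sample_sheet.tsv"))
  write_tsv(res$fragment_stats, p("fragment_stats.tsv"))
  write_score_table(res$score_table, p("scores.tsv"))
  write_tsv(res$flags, p("locus_flags.tsv"))
  if (!is.null(res$group_summary))
    write_tsv(res$group_summary, p("peak_groups.tsv"))
  if (!is.null(res$dynamics))
    write_tsv(as.data.frame(res$dynamics), p("dynamics.tsv"))
  if (!is.null(res$clusters)) write_tsv(res$clusters, p("clusters.tsv"))
  if (!is.null(res$cluster_ks))
    write_tsv(res$cluster_ks, p("cluster_ks.tsv"))
  if (!is.null(res$profiles))
    for (nm in names(res$profiles))
      write_tsv(as.data.frame(res$profiles[[nm]]),
                p(sprintf("profile_%s.tsv", nm)))
  manifest <- c(sprintf("pol3dyn %s", as.character(utils::packageVersion("pol3dyn"))),
                sprintf("R %s", getRversion()),
                sprintf("seed %d", res$cfg$seed),
                vapply(names(res$cfg), function(k)
                  sprintf("%s = %s", k,
                          paste(format(res$cfg[[k]]), collapse = ",")),
                  character(1)))
  writeLines(manifest, p("manifest.txt"))
  invisible(outdir)
}

#' Replicate concordance of occupancy scores
#'
#' Pearson correlation between two replicate samples over loci whose
#' score exceeds the peak cutoff in at least one of the two replicates
#' (silent loci carry no signal and would inflate agreement).
#'
#' @param st a [score_table()].
#' @param sample1,sample2 ChIP sample ids.
#' @return List: r, n (loci used), scores (data.frame for scatter
#'   plotting).
#' @export
replicate_concordance <- function(st, sample1, sample2) {
  stopifnot(all(c(sample1, sample2) %in% colnames(st$scores)))
  s1 <- st$scores[, sample1]; s2 <- st$scores[, sample2]
  keep <- s1 > st$thresholds[sample1] | s2 > st$thresholds[sample2]
  if (sum(keep) < 3)
    stop("fewer than 3 loci above cutoff in either replicate")
  list(r = cor(s1[keep], s2[keep]), n = sum(keep),
       scores = data.frame(locus_id = rownames(st$scores)[keep],
                           score1 = s1[keep], score2 = s2[keep]))
}
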