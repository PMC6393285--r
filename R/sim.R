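#' Configuration for the synthetic Pol III ChIP-seq generator
#'
#' Builds the parameter set for a miniature genome carrying Pol III loci of
#' the study's three occupancy classes, Pol II features, CpG islands and
#' paired ChIP/Input fragment samples. Defaults emulate the statistical
#' structure of a liver-regeneration Pol III occupancy experiment at desk
#' scale: two classes of active loci (high stable occupancy near Pol II
#' TSSs; low occupancy strongly induced at 36 h) plus a silent class, with
#' roughly 40% of loci silent.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes (named chr1..chrN).
#' @param n_loci_by_type named counts for the locus-type vocabulary
#'   (tRNA, SINE, Rn5s, Rn4.5s, other).
#' @param frac_near_pol2 fraction of stable_high loci given a divergent
#'   Pol II TSS 200-600 bp upstream.
#' @param class_fractions named fractions (stable_high, dynamic_low,
#'   silent); must sum to 1.
#' @param base_enrichment named log2 ChIP/Input enrichment per class at
#'   time 0.
#' @param induction_log2fc log2 fold change of dynamic_low loci at TP36
#'   (held at TP48/TP60: the induced state persists through S/G2 phases).
#' @param enrichment_jitter_sd per-locus spread (log2) around the class
#'   base enrichment, truncated at two standard deviations; silent loci are
#'   exactly 0.
#' @param depth_per_sample expected background fragment count per sample.
#' @param replicate_cv lognormal coefficient of variation applied to each
#'   locus's expected ChIP fragment count, per sample.
#' @param frag_size_mean,frag_size_sd fragment-size distribution (bp),
#'   truncated normal.
#' @param multimap_fraction fraction of tag pairs emitted as multi-candidate
#'   records (true origin plus 1-3 uniform decoys with broader sizes).
#' @param min_gap minimum gap (bp) between placed locus units.
#' @param frac_trna_clustered fraction of tRNA genes placed in clusters of
#'   3-5 genes with intra-cluster gaps drawn from `cluster_gap_range`.
#' @param cluster_gap_range bp range for gaps between clustered tRNA genes
#'   (kept under the 5 kb cluster-calling threshold).
#' @param frac_cpg_at_pol2 fraction of Pol II TSSs given a CpG island
#'   (+/- 250 bp).
#' @param h3k4me3_enrichment,rpb2_enrichment log2 enrichment of the
#'   H3K4me3 / RPB2 signal placed at Pol II TSSs next to stable_high loci.
#' @param n_decoy_pol2 Pol II genes placed away (>= 3 kb) from all Pol III
#'   loci.
#' @param seed master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chromosomes = 16,
                       n_loci_by_type = c(tRNA = 27, SINE = 12, Rn5s = 5,
                                          Rn4.5s = 2, other = 4),
                       frac_near_pol2 = 0.8,
                       class_fractions = c(stable_high = 0.33,
                                           dynamic_low = 0.22,
                                           silent = 0.45),
                       base_enrichment = c(stable_high = 5,
                                           dynamic_low = 1.5,
                                           silent = 0),
                       induction_log2fc = 2,
                       enrichment_jitter_sd = 0.5,
                       depth_per_sample = 5e5,
                       replicate_cv = 0.2,
                       frag_size_mean = 200,
                       frag_size_sd = 40,
                       multimap_fraction = 0.05,
                       min_gap = 2000,
                       frac_trna_clustered = 0.4,
                       cluster_gap_range = c(800, 4500),
                       frac_cpg_at_pol2 = 0.7,
                       h3k4me3_enrichment = 3.5,
                       rpb2_enrichment = 3,
                       n_decoy_pol2 = 5,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              n_loci_by_type = n_loci_by_type,
              frac_near_pol2 = frac_near_pol2,
              class_fractions = class_fractions,
              base_enrichment = base_enrichment,
              induction_log2fc = induction_log2fc,
              enrichment_jitter_sd = enrichment_jitter_sd,
              depth_per_sample = depth_per_sample,
              replicate_cv = replicate_cv,
              frag_size_mean = frag_size_mean, frag_size_sd = frag_size_sd,
              multimap_fraction = multimap_fraction,
              min_gap = min_gap,
              frac_trna_clustered = frac_trna_clustered,
              cluster_gap_range = cluster_gap_range,
              frac_cpg_at_pol2 = frac_cpg_at_pol2,
              h3k4me3_enrichment = h3k4me3_enrichment,
              rpb2_enrichment = rpb2_enrichment,
              n_decoy_pol2 = n_decoy_pol2,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (any(cfg$class_fractions < 0)) stop("class_fractions must be >= 0")
  stopifnot(cfg$genome_length > 0, cfg$n_chromosomes >= 1,
            all(cfg$n_loci_by_type >= 0), cfg$depth_per_sample > 0,
            cfg$frac_near_pol2 >= 0, cfg$frac_near_pol2 <= 1,
            cfg$multimap_fraction >= 0, cfg$multimap_fraction < 1,
            cfg$frag_size_mean > 0, cfg$frag_size_sd >= 0,
            cfg$replicate_cv >= 0)
  invisible(cfg)
}

#' Chromosome lengths of the simulated genome
#' @param cfg a [sim_config()].
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
sim_genome <- function(cfg) {
  setNames(rep(cfg$genome_length, cfg$n_chromosomes),
           paste0("chr", seq_len(cfg$n_chromosomes)))
}

# Reference locus body lengths (bp) by type; tRNA genes are short (~72 bp),
# SINEs and type-3 genes somewhat longer.
.locus_lengths <- c(tRNA = 72, SINE = 150, Rn5s = 120, Rn4.5s = 100,
                    other = 300)

#' Simulate the locus annotation, Pol II features, CpG islands and truth
#'
#' Places Pol III loci non-overlapping (minimum gap `cfg$min_gap`) on the
#' miniature genome, with a configurable fraction of tRNA genes grouped
#' into clusters, assigns each locus an occupancy class, and generates the
#' Pol II TSS/poly-A features and CpG islands that the classification
#' module consumes. Ground truth records the class label, the true log2
#' enrichment per time point and the realized Pol II proximity.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `loci` (data.frame: locus_id, chrom, start,
#'   end, strand, locus_type, tss), `pol2` (data.frame: chrom, pos, type
#'   TSS/polyA, strand, gene_id, locus_id of the paired Pol III locus or
#'   NA), `cpg` (data.frame: chrom, start, end) and `truth` (data.frame:
#'   locus_id, class_label, near_pol2, tp0, tp36, tp48, tp60). All
#'   coordinates 0-based half-open.
#' @export
simulate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "annotation"))
  genome <- sim_genome(cfg)

  types <- rep(names(cfg$n_loci_by_type), cfg$n_loci_by_type)
  n <- length(types)
  if (n == 0L) {
    empty_loci <- data.frame(locus_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character(), locus_type = character(),
                             tss = integer(), stringsAsFactors = FALSE)
    return(list(loci = empty_loci,
                pol2 = data.frame(chrom = character(), pos = integer(),
                                  type = character(), strand = character(),
                                  gene_id = character(),
                                  locus_id = character(),
                                  stringsAsFactors = FALSE),
                cpg = data.frame(chrom = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE),
                truth = data.frame(locus_id = character(),
                                   class_label = character(),
                                   near_pol2 = logical(), tp0 = numeric(),
                                   tp36 = numeric(), tp48 = numeric(),
                                   tp60 = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  ids <- unlist(lapply(unique(types), function(ty)
    sprintf("%s_%03d", ty, seq_len(sum(types == ty)))))
  lens <- unname(.locus_lengths[types])

  ## --- group tRNA genes into cluster units, everything else is a singleton
  trna_idx <- which(types == "tRNA")
  n_clustered <- floor(length(trna_idx) * cfg$frac_trna_clustered)
  clustered <- if (n_clustered >= 3)
    sample(trna_idx, n_clustered) else integer()
  units <- lapply(setdiff(seq_len(n), clustered), function(i) i)
  rest <- clustered
  while (length(rest) >= 3) {
    k <- min(length(rest), sample(3:5, 1))
    if (length(rest) - k == 1 || length(rest) - k == 2) k <- length(rest)
    k <- min(k, length(rest))
    units <- c(units, list(rest[seq_len(k)]))
    rest <- rest[-seq_len(k)]
  }
  units <- units[sample(length(units))]

  ## intra-unit gaps (clustered genes sit closer than the 5 kb threshold)
  unit_gaps <- lapply(units, function(u) {
    if (length(u) == 1L) numeric() else
      round(runif(length(u) - 1L, cfg$cluster_gap_range[1],
                  cfg$cluster_gap_range[2]))
  })
  unit_len <- vapply(seq_along(units), function(j)
    sum(lens[units[[j]]]) + sum(unit_gaps[[j]]), numeric(1))

  ## --- distribute units over chromosomes. Clusters go to distinct
  ## chromosomes, and about half of the single tRNA genes are co-located
  ## with a cluster (real tRNA genes concentrate on a few chromosomes, and
  ## the in-versus-out-of-cluster comparison needs both groups on the same
  ## chromosome); everything else is load-balanced.
  chrom_of <- integer(length(units))
  load <- setNames(numeric(cfg$n_chromosomes), names(genome))
  is_cluster <- lengths(units) > 1
  cl_ch <- integer()
  for (j in which(is_cluster)) {
    k_ch <- which.min(load / genome)[1]
    chrom_of[j] <- k_ch
    cl_ch <- c(cl_ch, k_ch)
    load[k_ch] <- load[k_ch] + unit_len[j] + cfg$min_gap
  }
  trna_single <- which(!is_cluster &
                         vapply(units, function(u)
                           types[u[1]] == "tRNA", logical(1)))
  if (length(cl_ch))
    for (j in trna_single)
      if (runif(1) < 0.5) {
        k_ch <- cl_ch[sample.int(length(cl_ch), 1)]
        chrom_of[j] <- k_ch
        load[k_ch] <- load[k_ch] + unit_len[j] + cfg$min_gap
      }
  for (j in order(unit_len, decreasing = TRUE))
    if (chrom_of[j] == 0L) {
      k_ch <- which.min(load / genome)[1]
      chrom_of[j] <- k_ch
      load[k_ch] <- load[k_ch] + unit_len[j] + cfg$min_gap
    }
  for (k in seq_len(cfg$n_chromosomes)) {
    need <- sum(unit_len[chrom_of == k]) +
      (sum(chrom_of == k) + 1) * cfg$min_gap
    if (need > genome[k])
      stop("cannot place loci: chromosome length ", genome[k],
           " too small for ", sum(chrom_of == k), " units needing ", need,
           " bp (min_gap ", cfg$min_gap, ")")
  }

  ## --- place units uniformly per chromosome under the min-gap constraint
  start <- integer(n); end <- integer(n)
  for (k in seq_len(cfg$n_chromosomes)) {
    js <- which(chrom_of == k)
    if (!length(js)) next
    js <- js[sample(length(js))]
    m <- length(js)
    free <- genome[k] - sum(unit_len[js]) - (m - 1) * cfg$min_gap
    cuts <- sort(runif(m, 0, free))
    spac <- diff(c(0, cuts))
    pos <- 0
    for (ii in seq_len(m)) {
      j <- js[ii]
      pos <- pos + spac[ii] + if (ii > 1) cfg$min_gap else 0
      u <- units[[j]]
      p <- round(pos)
      for (uu in seq_along(u)) {
        i <- u[uu]
        start[i] <- p; end[i] <- p + lens[i]
        p <- end[i] + if (uu < length(u)) unit_gaps[[j]][uu] else 0
      }
      pos <- pos + unit_len[j]
    }
    for (j in js) chrom_of[j] <- k
  }
  chrom <- names(genome)[unlist(lapply(seq_along(units), function(j)
    rep(chrom_of[j], length(units[[j]]))))[order(unlist(units))]]

  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1L)
  loci <- data.frame(locus_id = ids, chrom = chrom, start = start, end = end,
                     strand = strand, locus_type = types, tss = as.integer(tss),
                     stringsAsFactors = FALSE)

  ## --- occupancy classes with exact fractions
  n_class <- floor(cfg$class_fractions * n)
  rem <- n - sum(n_class)
  if (rem > 0) {
    extra <- order(cfg$class_fractions * n - n_class, decreasing = TRUE)
    n_class[extra[seq_len(rem)]] <- n_class[extra[seq_len(rem)]] + 1
  }
  class_label <- sample(rep(names(cfg$class_fractions), n_class))

  ## --- per-locus true enrichment (log2), jitter truncated at 2 sd
  jit <- rnorm(n, 0, cfg$enrichment_jitter_sd)
  jit <- pmin(pmax(jit, -2 * cfg$enrichment_jitter_sd),
              2 * cfg$enrichment_jitter_sd)
  e0 <- unname(cfg$base_enrichment[class_label]) + jit
  e0[class_label == "silent"] <- 0
  e0[class_label != "silent"] <- pmax(e0[class_label != "silent"], 0.2)
  e_late <- e0 + ifelse(class_label == "dynamic_low", cfg$induction_log2fc, 0)

  ## --- Pol II features: divergent TSS upstream of chosen stable_high loci
  sh <- which(class_label == "stable_high")
  near <- sh[runif(length(sh)) < cfg$frac_near_pol2]
  pol2 <- list(); cpg <- list(); gi <- 0
  for (i in near) {
    gi <- gi + 1
    d <- round(runif(1, 200, 600))
    if (loci$strand[i] == "+") {
      tss_p <- loci$tss[i] - d; pa <- tss_p - 1500; gs <- "-"
    } else {
      tss_p <- loci$tss[i] + d; pa <- tss_p + 1500; gs <- "+"
    }
    tss_p <- min(max(tss_p, 0), genome[loci$chrom[i]] - 1)
    pa <- min(max(pa, 0), genome[loci$chrom[i]] - 1)
    pol2[[length(pol2) + 1]] <- data.frame(
      chrom = loci$chrom[i], pos = as.integer(c(tss_p, pa)),
      type = c("TSS", "polyA"), strand = gs,
      gene_id = sprintf("pol2_%03d", gi), locus_id = loci$locus_id[i],
      stringsAsFactors = FALSE)
    if (runif(1) < cfg$frac_cpg_at_pol2)
      cpg[[length(cpg) + 1]] <- data.frame(
        chrom = loci$chrom[i], start = as.integer(max(tss_p - 250, 0)),
        end = as.integer(tss_p + 250), stringsAsFactors = FALSE)
  }

  ## decoy Pol II genes well away (>= 3 kb) from every Pol III locus
  for (dd in seq_len(cfg$n_decoy_pol2)) {
    placed <- FALSE
    for (try in 1:200) {
      ch <- sample(names(genome), 1)
      p <- round(runif(1, 2000, genome[ch] - 2000))
      on_ch <- loci$chrom == ch
      if (!any(on_ch) ||
          min(pmax(loci$start[on_ch] - p, p - loci$end[on_ch], 0)) >= 3000) {
        gi <- gi + 1
        pol2[[length(pol2) + 1]] <- data.frame(
          chrom = ch, pos = as.integer(c(p, p + 1500)),
          type = c("TSS", "polyA"), strand = "+",
          gene_id = sprintf("pol2_%03d", gi), locus_id = NA_character_,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place decoy Pol II gene >= 3 kb from all loci after ",
           "200 retries; genome too crowded")
  }
  pol2 <- if (length(pol2)) do.call(rbind, pol2) else
    data.frame(chrom = character(), pos = integer(), type = character(),
               strand = character(), gene_id = character(),
               locus_id = character(), stringsAsFactors = FALSE)
  cpg <- if (length(cpg)) do.call(rbind, cpg) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  truth <- data.frame(locus_id = ids, class_label = class_label,
                      near_pol2 = unname(flag_near_pol2(loci, pol2)),
                      tp0 = e0, tp36 = e_late, tp48 = e_late, tp60 = e_late,
                      stringsAsFactors = FALSE)
  list(loci = loci, pol2 = pol2, cpg = cpg, truth = truth)
}

#' Default sample sheet for the simulated experiment
#'
#' RPC4 is profiled at all four time points in two replicates; H3K4me3 and
#' RPB2 at TP0 in two replicates (the time point used for peak-presence
#' classification); each ChIP is paired with the Input of its time point
#' and replicate.
#'
#' @param factors subset of c("RPC4", "H3K4me3", "RPB2") to include.
#' @return data.frame: sample_id, factor, timepoint, replicate, input_id.
#' @export
sim_sample_sheet <- function(factors = c("RPC4", "H3K4me3", "RPB2")) {
  factors <- match.arg(factors, several.ok = TRUE)
  rows <- list()
  add <- function(f, tp, r) {
    iid <- sprintf("Input_%s_r%d", tp, r)
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sprintf("%s_%s_r%d", f, tp, r), factor = f,
      timepoint = tp, replicate = r, input_id = iid,
      stringsAsFactors = FALSE)
  }
  if ("RPC4" %in% factors)
    for (tp in c("TP0", "TP36", "TP48", "TP60")) for (r in 1:2)
      add("RPC4", tp, r)
  for (f in intersect(c("H3K4me3", "RPB2"), factors))
    for (r in 1:2) add(f, "TP0", r)
  sheet <- do.call(rbind, rows)
  inputs <- unique(sheet$input_id)
  inp <- data.frame(sample_id = inputs, factor = "Input",
                    timepoint = sub("^Input_(TP\\d+)_r\\d$", "\\1", inputs),
                    replicate = as.integer(sub("^.*_r(\\d)$", "\\1", inputs)),
                    input_id = NA_character_, stringsAsFactors = FALSE)
  rbind(sheet, inp)
}

#' Simulate the fragment set for one sample
#'
#' Input samples are Poisson-uniform background over the genome at
#' `depth_per_sample`. ChIP samples add locus-centered fragments on top of
#' the same background, with expected extra count
#' `(2^e - 1) * local_input_rate` so that the pseudocounted log2
#' ChIP/Input score recovers the true enrichment `e` at high depth; the
#' per-locus rate carries lognormal replicate noise (CV
#' `cfg$replicate_cv`). RPC4 signal sits on the locus body; H3K4me3/RPB2
#' signal sits on the divergent Pol II TSS paired with stable_high loci
#' (spread sd 300 bp), upstream of the Pol III gene. A fraction of tag
#' pairs is emitted as multi-candidate records (weight NA): the true
#' origin plus 1-3 decoys at uniform positions whose lengths come from a
#' 3x broader size distribution.
#'
#' @param cfg a [sim_config()].
#' @param loci,truth from [simulate_annotation()].
#' @param sample one row of [sim_sample_sheet()] (or an equivalent list
#'   with sample_id, factor, timepoint).
#' @param pol2 Pol II features from [simulate_annotation()]; required for
#'   H3K4me3/RPB2 samples.
#' @return Fragment data.frame (chrom, start, end, pair_id, weight,
#'   sample_id); weight is 1 for unique pairs and NA for multi-candidate
#'   records (to be assigned by [weight_multimapped()]).
#' @export
simulate_fragments <- function(cfg, loci, truth, sample, pol2 = NULL) {
  validate_sim_config(cfg)
  fac <- sample$factor
  if (!fac %in% c("RPC4", "RPB2", "H3K4me3", "Input"))
    stop("unknown factor: ", fac)
  set.seed(derive_seed(cfg$seed, sample$sample_id))
  genome <- sim_genome(cfg)
  gsize <- sum(genome)

  ## background: Poisson-uniform over the genome
  n_bg <- rpois(1, cfg$depth_per_sample)
  bg_chrom <- sample(names(genome), n_bg, replace = TRUE,
                     prob = genome / gsize)
  bg_mid <- floor(runif(n_bg) * genome[bg_chrom])
  mids <- bg_mid; chroms <- bg_chrom

  ## locus-centered signal for ChIP factors
  if (fac != "Input" && nrow(loci)) {
    tp_col <- c(TP0 = "tp0", TP36 = "tp36", TP48 = "tp48",
                TP60 = "tp60")[sample$timepoint]
    if (fac == "RPC4") {
      e <- truth[[tp_col]]
      w_eff <- (loci$end - loci$start) + 300
      centers <- NULL  # uniform over locus body
    } else {
      on <- truth$class_label == "stable_high" & truth$near_pol2
      e <- ifelse(on, if (fac == "H3K4me3") cfg$h3k4me3_enrichment
                      else cfg$rpb2_enrichment, 0)
      w_eff <- rep(2000, nrow(loci))
      centers <- rep(NA_real_, nrow(loci))
      if (!is.null(pol2) && nrow(pol2)) {
        tssrec <- pol2[pol2$type == "TSS" & !is.na(pol2$locus_id), ]
        centers[match(tssrec$locus_id, loci$locus_id)] <- tssrec$pos
      }
    }
    sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
    noise <- exp(rnorm(nrow(loci), -sdlog^2 / 2, sdlog))
    lam <- (2^e - 1) * cfg$depth_per_sample * w_eff / gsize * noise
    lam[e <= 0] <- 0
    if (!is.null(centers)) lam[is.na(centers)] <- 0
    n_extra <- rpois(nrow(loci), lam)
    for (i in which(n_extra > 0)) {
      k <- n_extra[i]
      m <- if (is.null(centers))
        floor(runif(k, loci$start[i], loci$end[i]))
      else round(rnorm(k, centers[i], 300))
      mids <- c(mids, m)
      chroms <- c(chroms, rep(loci$chrom[i], k))
    }
  }

  n_tot <- length(mids)
  if (n_tot == 0L) return(empty_fragments())
  sizes <- round(rtruncnorm_pos(n_tot, cfg$frag_size_mean, cfg$frag_size_sd))
  start <- pmax(0, round(mids - sizes / 2))
  end <- pmin(unname(genome[chroms]), start + sizes)
  keep <- end > start
  frag <- data.frame(chrom = chroms[keep], start = as.integer(start[keep]),
                     end = as.integer(end[keep]),
                     pair_id = sprintf("%s_p%07d", sample$sample_id,
                                       seq_len(sum(keep))),
                     weight = 1, sample_id = sample$sample_id,
                     stringsAsFactors = FALSE)

  ## multi-candidate pairs: true origin + uniform decoys, broader sizes
  if (cfg$multimap_fraction > 0 && nrow(frag)) {
    is_mm <- runif(nrow(frag)) < cfg$multimap_fraction
    mm <- frag[is_mm, , drop = FALSE]
    if (nrow(mm)) {
      n_dec <- sample(1:3, nrow(mm), replace = TRUE)
      idx <- rep(seq_len(nrow(mm)), n_dec)
      dchrom <- sample(names(genome), length(idx), replace = TRUE,
                       prob = genome / gsize)
      dmid <- floor(runif(length(idx)) * genome[dchrom])
      dsize <- round(rtruncnorm_pos(length(idx), cfg$frag_size_mean,
                                    3 * cfg$frag_size_sd))
      ds <- pmax(0, round(dmid - dsize / 2))
      de <- pmin(unname(genome[dchrom]), ds + dsize)
      ok <- de > ds
      dec <- data.frame(chrom = dchrom[ok], start = as.integer(ds[ok]),
                        end = as.integer(de[ok]),
                        pair_id = mm$pair_id[idx[ok]], weight = NA_real_,
                        sample_id = sample$sample_id,
                        stringsAsFactors = FALSE)
      frag$weight[is_mm] <- NA_real_
      frag <- rbind(frag, dec)
    }
  }
  rownames(frag) <- NULL
  frag
}
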