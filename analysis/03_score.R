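#!/usr/bin/env Rscript
# Occupancy scoring: depth-normalized, pseudocounted log2 ChIP/Input
# scores over extended loci, empirical genome-bin null cutoffs per
# sample, and replicate concordance.

source("analysis/_common.R")

res <- load_pipeline(seed = 1)
st <- res$score_table
write_score_table(st, file.path(RESULTS, "scores.tsv"))

print(st)

tr <- res$annotation$truth
sc0 <- rowMeans(st$scores[, c("RPC4_TP0_r1", "RPC4_TP0_r2")])
cat("\nMean RPC4 score at TP0 by class:\n")
print(round(tapply(sc0, tr$class_label, mean), 2))

ns <- tr$class_label != "silent"
cat("\nSpearman correlation, true enrichment vs computed score (TP0,",
    "non-silent loci):", round(cor(tr$tp0[ns], sc0[ns],
                                   method = "spearman"), 3), "\n")

conc <- data.frame()
for (tp in c("TP0", "TP36", "TP48", "TP60")) {
  cc <- replicate_concordance(st, sprintf("RPC4_%s_r1", tp),
                              sprintf("RPC4_%s_r2", tp))
  conc <- rbind(conc, data.frame(factor = "RPC4", timepoint = tp,
                                 r = cc$r, n_loci = cc$n))
}
write_tsv(conc, file.path(RESULTS, "replicate_concordance.tsv"))
cat("\nReplicate concordance (Pearson r over above-cutoff loci):\n")
print(conc, row.names = FALSE)

below_all <- rowSums(sweep(st$scores[, st$samples$factor == "RPC4"], 2,
                           st$thresholds[st$samples$factor == "RPC4"],
                           ">")) == 0
cat("\nLoci below the RPC4 cutoff in all samples and time points:",
    sum(below_all), "of", nrow(st$scores), "\n")
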