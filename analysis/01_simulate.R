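#!/usr/bin/env Rscript
# Build the synthetic Pol III ChIP-seq experiment: a 16 x 2 Mb genome with
# 50 Pol III loci in three occupancy classes (stable high / dynamic low /
# silent), Pol II TSS-polyA features and CpG islands next to the stable
# class, and paired ChIP/Input fragment samples for RPC4 (4 time points x
# 2 replicates), H3K4me3 and RPB2 (TP0 x 2 replicates).

source("analysis/_common.R")

res <- load_pipeline(seed = 1, rebuild = TRUE)
ann <- res$annotation

outdir <- file.path(RESULTS, "simulation")
dir.create(outdir, showWarnings = FALSE)
write_loci_bed(ann$loci, file.path(outdir, "loci.bed"))
write_tsv(ann$truth, file.path(outdir, "truth.tsv"))
write_tsv(ann$pol2, file.path(outdir, "pol2_features.tsv"))
write_tsv(ann$cpg, file.path(outdir, "cpg_islands.tsv"))
write_tsv(res$sheet, file.path(outdir, "sample_sheet.tsv"))

# one small illustrative fragment BED (first 800 fragments of RPC4 TP0 r1)
demo <- head(res$fragments[["RPC4_TP0_r1"]], 800)
write_fragments_bed(demo, file.path(outdir, "fragments_demo.bed"))

cat("Simulated", nrow(ann$loci), "loci:\n")
print(table(ann$truth$class_label))
cat("\nLocus types:\n")
print(table(ann$loci$locus_type))
cat("\nPol II features:", nrow(ann$pol2), "; CpG islands:", nrow(ann$cpg),
    "\n")
cat("Stable-class loci near a Pol II TSS:",
    sum(ann$truth$near_pol2[ann$truth$class_label == "stable_high"]), "of",
    sum(ann$truth$class_label == "stable_high"), "\n")
cat("\nTables written under", outdir, "\n")
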