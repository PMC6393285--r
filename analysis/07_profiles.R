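#!/usr/bin/env Rscript
# Average tag-density profiles (metagene plots) around Pol III TSSs for
# the triple-peak locus group, per factor: the Pol II (RPB2) and H3K4me3
# signal should peak upstream of the Pol III anchor, where the divergent
# Pol II TSS sits.

source("analysis/_common.R")

res <- load_pipeline(seed = 1)
stopifnot(!is.null(res$profiles))

for (nm in names(res$profiles)) {
  prof <- res$profiles[[nm]]
  write_tsv(as.data.frame(prof),
            file.path(RESULTS, sprintf("profile_%s.tsv", nm)))
  up <- sum(prof$density[prof$offset < 0])
  down <- sum(prof$density[prof$offset >= 0])
  cat(sprintf("%-8s n_loci=%d peak at offset %+d bp; upstream/downstream mass ratio %.2f\n",
              nm, attr(prof, "n_loci"),
              prof$offset[which.max(prof$density)],
              up / down))
}
cat("\nProfiles written under", RESULTS, "(offset = bp from Pol III TSS,",
    "strand-oriented; density = fragments/bp/locus per million)\n")
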