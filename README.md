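# pol3dyn

Quantifying RNA polymerase III occupancy dynamics from paired-end ChIP-seq.

## What this is for

RNA polymerase III (Pol III) transcribes tRNA genes, 5S rRNA, SINEs and a
few other short non-coding genes. In a resting tissue such as adult liver,
roughly half of the annotated Pol III loci are silent; among active loci,
occupancy spans a wide range. When hepatocytes synchronously re-enter the
cell cycle after two-thirds partial hepatectomy, Pol III occupancy rises —
selectively: loci with high stable occupancy sit near Pol II TSSs and
H3K4me3 peaks, while a class of low-occupancy loci far from Pol II
activity is strongly induced by S phase (36 h post surgery).

`pol3dyn` is an R implementation of the complete quantitative pipeline for
this kind of study, aimed at computational biologists analysing Pol III
(RPC4), Pol II (RPB2) and H3K4me3 ChIP-seq time courses with matched
Inputs:

* **Fragments** — redundancy filtering of unique tag pairs; multi-mapped
  pairs weighted by the normalized size probability
  `w_i = P(len_i) / sum_j P(len_j)` estimated from unique fragments (1 bp
  histogram, floor 1e-6; pairs with > 500 placements discarded).
* **Scoring** — occupancy score
  `S = log2((n_chip * c_chip + 16) / (n_input * c_input + 16))` with
  fractional, weighted fragment counts over extended loci (locus ± 150 bp
  for RPC4; TSS ± 1 kb for H3K4me3/RPB2) and median-depth normalization;
  per-sample peak cutoffs are the `1 − 0.05/N` empirical quantile of
  genome-wide bin scores (400 bp bins for RPC4, 2 kb for H3K4me3/RPB2) —
  a Bonferroni-corrected empirical null.
* **Classification** — isolated loci (≥ 1.5 kb apart), Pol II proximity
  (≤ 2.65 kb to TSS/poly-A), CpG islands (TSS ± 1 kb), the eight
  peak-presence groups per replicate, and permutation-based Welch t tests
  between groups.
* **Dynamics** — per-locus one-way model over TP0/TP36/TP48/TP60,
  empirical-Bayes moderated t
  (`t = c'mu / (s_tilde * sqrt(c'(X'X)^-1 c))` with
  `s_tilde² = (d0 s0² + d s²)/(d0 + d)` fitted by method of moments on
  log s²), Storey smoothing-spline π0 q-values, significance at
  FDR < 0.05.
* **Spatial** — tRNA clusters (≥ 3 genes, gaps < 5 kb), per-chromosome KS
  tests of fold change in vs out of clusters, chromosome ×
  changing/stable chi-square with Pearson residuals, hypergeometric
  overlap enrichment of changing-gene sets.
* **Profiles** — strand-oriented average tag-density (metagene) profiles
  around Pol III TSSs.
* **Synthetic data** — a generator (`sim_config()`, `simulate_annotation()`,
  `simulate_fragments()`) producing a miniature genome with three locus
  classes (stable-high / dynamic-low / silent), Pol II features, CpG
  islands, multi-mapped pairs with known origins, and full ground truth —
  the basis of all calibration and recovery tests.

See `vignettes/pol3-occupancy-dynamics.Rmd` for the model details and the
reasoning behind every default.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic configuration and write tables under `results/` (and a cached
pipeline object under `scratch/`):

```sh
Rscript analysis/01_simulate.R   # genome, loci, classes, ground truth
Rscript analysis/03_score.R      # scores, cutoffs, replicate concordance
Rscript analysis/05_dynamics.R   # moderated-t calls for TP36 - TP0
```

`01_simulate.R` builds 50 loci (27 tRNA, 12 SINE, 5 Rn5s, 2 Rn4.5s,
4 other; 17 stable-high, 11 dynamic-low, 22 silent). `03_score.R` then
prints:

```
Mean RPC4 score at TP0 by class:
dynamic_low      silent stable_high
       0.63       -0.01        3.26

Spearman correlation, true enrichment vs computed score (TP0, non-silent loci): 0.95

Replicate concordance (Pearson r over above-cutoff loci):
 factor timepoint         r n_loci
   RPC4       TP0 0.9409124     24
   RPC4      TP36 0.9438607     28
```

Silent loci score ~0 (the pseudocounted log2 ratio of depth-matched
background), stable loci ~3.3, and replicate correlations exceed 0.9 —
the regime reported for real libraries. `05_dynamics.R` prints:

```
Contrast TP36 - TP0 (RPC4):
  significant (q < 0.05): 13 — of which 4 were below cutoff at TP0
             called
truth         FALSE TRUE
  dynamic_low     0   11
  silent         22    0
  stable_high    15    2
Significant TP48 - TP36 calls: 0
```

All 11 truly induced loci are recovered (several rising from below the
peak cutoff at TP0, the hallmark of the low-occupancy induced class), no
silent locus is called, and the later time points — simulated with the
induced state persisting — yield no TP48 vs TP36 calls.

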