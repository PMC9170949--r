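# clonescape

Paired single-cell TCR repertoire analysis of antigen-specific CD8 T
cells, built for studies that sort autoreactive cells with peptide–MHC
tetramers (e.g., islet-infiltrating IGRP-reactive CD8 T cells in NOD
mice) and sequence them with 10x-style paired scRNA-seq + scVDJ-seq.

It is aimed at immunologists and computational biologists who have contig
annotation tables, per-cell metadata with phenotype cluster labels, and an
expression count matrix, and who want the clonal statistics such studies
report:

* **Clonotyping** — consolidate one α and one β chain per cell
  (deterministic UMI/read/sequence tie-breaks) and partition cells into
  clones. The default clone definition is *identical paired α+β CDR3
  nucleotide sequences*; single-chain (`alpha_nt`, `beta_nt`) and
  amino-acid (`paired_aa`) definitions are provided for comparison.
* **Repertoire statistics** — clonal overlap between samples and
  experiments (singlet clones excluded, percentage over the union of the
  restricted sets), UpSet-style membership patterns, clone-size class
  frequencies, mean expanded-clone size, and joint V–J usage matrices
  with chord-diagram display annotations.
* **CDR3 motif analysis** — a TCRdist-style amino-acid distance
  (BLOSUM62 penalties capped at 4, gap cost 4, CDR3 weight 3, 2-residue
  terminal trims), agglomerative motif-group clustering with per-group
  position-frequency matrices and consensus patterns, germline
  segment-origin attribution of every junction position
  (V / N / D / J), and motif-frequency reporting with `-` wildcards.
* **Module scoring** — per-cell gene-set scores against
  expression-matched control genes (equal-frequency abundance bins,
  seeded control draws), with pairwise Wilcoxon rank-sum comparisons
  under Holm or Holm–Šidák family-wise adjustment.
* **Clone–phenotype coupling** — entropy-based pairwise cluster
  transition indices (cell-weighted binary entropy of each shared
  clone's split, in [0, 1]), cluster composition tables, cluster
  distribution by V/J gene usage with chi-squared homogeneity tests, and
  logistic regression of gene usage on log2 clone size with a
  likelihood-ratio test.
* **Synthetic data** — a fully parameterised generator that emulates a
  two-experiment tetramer-sorting study (restricted tet+ gene usage,
  planted CDR3 motifs per β-J family, heavy-tailed clone sizes, planted
  progenitor–effector clone sharing, planted gene-set effects, QC-failing
  cells) with complete planted-truth bookkeeping, so every statistic in
  the package is validated against known ground truth.

## The statistics in brief

A clone is an equivalence class of cells under exact string equality of
the defining CDR3 sequence(s). Overlap between two clone sets A and B
restricted to clones of ≥ 2 cells is `100 · |A ∩ B| / |A ∪ B|`, reported
round-half-up to one decimal. The pairwise transition index between
clusters *i* and *j* is

```
T(i,j) = Σ_c w_c · H2( n_ci / (n_ci + n_cj) ),   w_c ∝ n_ci + n_cj
```

over clones *c* with ≥ 2 cells in the two clusters, where `H2` is binary
Shannon entropy — 0 when no clone spans both clusters, 1 when every
shared clone splits evenly. Module scores are
`mean(set genes) − mean(matched controls)` per cell on log-normalized
expression, as in the standard single-cell gene-set scoring procedure.

## Worked example

```r
library(clonescape)

cfg <- sim_config()                      # the default two-experiment study
out <- run_pipeline(cfg, "run1", seed = 1)
r <- out$results

r$pairing_percent
#> [1] 60.4
r$overlap_combined$percent               # paired-nt between-experiment overlap
#> [1] 0.7
r$overlap_alpha$percent                  # alpha-chain-only definition
#> [1] 5.1
round(100 * r$usage_trav16n, 1)          # tet+ cells using TRAV16N
#> [1] 99.8
r$motif_rdsg$percent                     # tet+ clones with the RDSG alpha motif
#> [1] 67.8
round(r$`logit_TRBJ2-2`$slope, 2)        # log-odds of TRBJ2-2 per clone-size doubling
#> [1] 0.08
```

60.4% of simulated cells recover both chains; between-experiment clonal
overlap is far lower under the paired nucleotide definition (0.7%) than
under single-chain definitions (5.1% for α), reflecting the extra
resolution of paired sequencing; tetramer-sorted cells show the planted
restricted V usage and α-chain motif; and TRBJ2-2 usage rises with clone
size. `run1/` holds every table (clones, overlap patterns, usage
matrices, motif groups, transition matrix, test results) plus a manifest
with MD5 checksums and the echoed configuration.

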