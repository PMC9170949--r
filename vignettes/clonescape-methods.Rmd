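---
title: "Methods: clonal analysis of tetramer-sorted CD8 T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal analysis of tetramer-sorted CD8 T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in
`clonescape`, the choices made where a convention had to be fixed, and
what the synthetic-data generator does and does not emulate.

## Clone calling

Single-cell V(D)J assembly yields several contigs per cell barcode. We
keep TRA/TRB contigs with a CDR3 call and consolidate one α and one β
chain per cell: among productive candidates of a locus the contig with
the most UMIs wins, ties broken by read count and then by
lexicographically smallest CDR3 nucleotide sequence. The tie-break chain
matters only for determinism — cells with two productive chains of one
locus (frequent biological doublets of the α locus, since allelic
exclusion is leaky there) are *not* split into two clonotypes; they are
flagged (`multi_alpha`/`multi_beta`) and one chain is chosen. This keeps
every clone partition well defined at the cost of discarding a minority
chain whose true pairing is unknowable without more evidence.

A clone is then an equivalence class of cells under exact equality of
the defining CDR3 string(s). Four definitions are supported; the
default, `paired_nt`, uses both chains at the nucleotide level, the
strictest operational definition available to single-cell data: the
junction nucleotides record the V(D)J recombination event itself, so two
cells agreeing there almost surely descend from one naïve T cell. The
`alpha_nt`/`beta_nt` definitions emulate what bulk TCR-seq could see and
are deliberately coarser (the paired partition refines both — a tested
invariant); `paired_aa` collapses synonymous junctions and quantifies
convergent recombination. Clone identifiers are FNV-1a hashes of
(definition, key), so they are stable across runs and subsetting.

## Overlap and expansion statistics

Overlap between two clone sets uses three conventions, fixed once and
applied everywhere: clones with fewer than 2 cells are excluded (a
singlet cannot be observed "shared" without being a different kind of
evidence), the denominator is the union of the two restricted sets, and
percentages are rounded half-up to one decimal. Round-half-up rather
than banker's rounding is deliberate: summary ratios like 42/192 =
21.875% must print as 21.9.

Mean expanded-clone size is the arithmetic mean over clones of ≥ 2
cells. Note that recovered clone size is attenuated by chain dropout:
with a ~60% paired-recovery rate, a clone of true size *s* is observed
with roughly 0.6 · *s* paired cells, so observed means sit below the
generative ones. We report observed sizes and make the attenuation
explicit rather than inflating.

V–J usage matrices store exact joint frequencies; the chord-diagram
conventions (hide genes under 2% usage, label only genes at 10%+) are
attached as display annotations and never alter the stored numbers.

## CDR3 distance and motif groups

The amino-acid distance between two CDR3s follows the conventions of
similarity-weighted TCR clustering: trim 2 residues from each terminus
(the germline-invariant C... and ...F ends carry little specificity
information), equalize lengths with a single contiguous gap block at the
midpoint of the shorter sequence (left-biased on ties — a deterministic
stand-in for the profile alignment a full implementation would use),
then charge 0 for identity, `min(4, 4 − BLOSUM62)` per mismatch, 4 per
gap position, and scale the CDR3 sum by 3. The paired-clone distance is
the sum over both chains. The triangle inequality is not guaranteed and
not used. These four constants are exposed in `distance_params()`; the defaults
are the published conventions of that clustering approach.

Motif groups are average-linkage agglomerative clusters of the paired
distance, cut at a user-chosen height; the analysis is restricted to
clones with at least two cells. A negative cut places each clone alone;
a zero cut merges only distance-zero clones, i.e. groups equal distinct
(α, β) amino-acid pairs. Each group carries a per-chain gapped alignment
(same centered-gap rule, padded to the longest member), a
position-frequency matrix over the 20 amino acids plus gap, and a
consensus string (a letter where the modal residue reaches 0.6 — a
threshold chosen so that published-style patterns like "S-DW" emerge
with wildcards at variable positions; configurable).

Motif *frequencies* are computed by explicit pattern scan (`-` matches
any single residue, contiguous substring), not by cluster membership, so
a stated pattern is testable as given — a deliberate choice, since
reported motif percentages could in principle count either cluster
members or pattern matches, and only the latter is unambiguous.

## Junction segment attribution

Each CDR3 nucleotide position is attributed to V, D, J or N
(non-templated): the V label is the longest CDR3 prefix matching the
germline V gene from its annotated Cys-codon boundary; the J label is
the longest suffix matching the germline J up to its Phe-codon boundary;
when the candidates overlap, V takes the contested positions (any split
attains the same total match, so the tie-break is free and fixed).
Within the remaining middle, the longest ≥ 3 nt match to any D gene
(ties: leftmost, then D list order) is labeled D; everything else is N.
The 3 nt floor keeps 1–2 nt chance matches from being called D.
Per-amino-acid labels take the majority origin of the codon, ties going
to N. Attribution is maximal-matching, so where a planted N region
happens to extend a germline match the recovered boundary exceeds the
planted one — the generator's bookkeeping records planted boundaries, and
tests compare exactly on ambiguity-free junctions.

## Module scores and comparisons

Gene-set module scores follow the standard binned-control procedure:
genes are placed into 24 equal-frequency bins by average expression over
cells; for each set gene, 100 control genes are drawn uniformly with
replacement from its bin (duplicates retained); the score is the mean
set expression minus the mean control expression per cell, on
log-normalized values. The control draw is seeded and reproducible
bit-for-bit. The score is exactly invariant to per-cell additive shifts
(both means move together), which is why library-size differences
between cell groups do not masquerade as programme activity.

One caveat the synthetic experiments made vivid: if a gene set's members
dominate their own abundance bins, the controls are drawn largely from
the set itself and the score attenuates toward zero. This is a property
of the published procedure, not of this implementation; it matters
whenever a scored set is both strongly differentially expressed and
abundance-clustered.

Between-group comparisons are two-sided Wilcoxon rank-sum tests over all
group pairs with step-down family-wise adjustment; Holm–Šidák
(`1 − (1 − p)^(m − i + 1)`, cummax-monotonized) is the default, plain
Holm is available.

## Transition indices

The pairwise transition index between clusters *i* and *j* restricts to
clones with ≥ 2 cells in the pair, computes the binary entropy of each
clone's split, and combines clones with cell-count weights. Cell
weighting (rather than clone-uniform) is the default because expanded
clones carry most of the differentiation signal; clone-uniform weighting
is offered as an option. The index is symmetric, lies in [0, 1], is
invariant to duplicating every cell, and is reported as missing (not 0)
when no clone qualifies. Pairwise transition indices appear in several
clonal-analysis toolkits with unstated details; the explicit entropy
definition above is this package's own, validated against a brute-force
implementation.

## Gene usage vs clone size

The association between use of a β-J gene and clonal expansion is a
logistic regression of usage (binary, per clone, non-singlet clones) on
log2 clone size, fitted by IRLS (`glm`, tolerance 1e-10, 100 iterations
max), reported with the 1-df likelihood-ratio test. Usage is the
response and size the predictor; under this model family the LRT is the
same in either orientation, which is why it is the primary statistic.
Complete separation is detected (non-convergence or runaway
coefficients) and flagged instead of silently reported.

## The synthetic study

`sim_config()` defaults describe a two-experiment tetramer-sorting
study: per-sample cell counts at the recovered-cell scale of the
emulated design (5,550 / 1,011 / 2,959 and 8,495 / 1,585 / 2,361 cells
for islet tet−, islet tet+, spleen tet+), a 60.4% paired-recovery rate,
power-law clone sizes (exponent 1.5 truncated at 400 for tet+, 2.2 at
250 for tet−, chosen to give mean expanded-clone sizes near 24 and 6
cells), tet+ gene usage with one dominant αV (0.99), αJ (0.89) and βV
(0.90) and a β-J distribution targeting cell-level usage
(0.40, 0.30, 0.25, 0.05) over TRBJ2-2/2-4/2-7/other. The β-J choice is
size-coupled (log-odds +0.15 per doubling for TRBJ2-2, −0.10 for
TRBJ2-7); the clone-level base logits are solved deterministically from
the size law so the cell-level target still holds. Junctions are built
as germline-V prefix + N insertions (+ D + N for β) + germline-J suffix
with geometric N-insertion lengths (mean 4 nt); planted amino-acid
motifs (α "RDSG"; β "SDP"/"GDN"/"S-DW" per dominant β-J family, with
planting probabilities 0.80 / 0.78 / 0.29 / 0.24 calibrated so the
clone-level motif fractions among expanded clones land near 70 / 22 / 8
/ 9%) are reverse-translated codon-aligned into the junction. A small
tet− convergent family (restricted genes, "E-RGS"/"RGQSN" motifs) is
planted at rate 0.015.

Phenotype clusters are drawn per cell from clone-coupled softmax logits:
six islet and six spleen labels, a planted progenitor–effector axis
(35% of tet+ clones, +3.5 logits on both clusters with correlated
noise so the axis stays balanced), a TRBJ2-2 effector bonus (+1.0), a
clone-size effector/mitotic coupling (+0.25 per doubling), and
per-clone noise (sd 2.5) that concentrates each clone's phenotype — as
real clones are concentrated — so that chance split doublets do not
dominate small-cluster transition pairs. Tissue assignment of tet+
clones uses a U-shaped Beta(0.8, 0.8) clone propensity: most clones live
mainly in one tissue, expanded clones span both.

Between-experiment clone sharing is planted explicitly (7 paired, 16
α-only, 4 β-only tet+ clones, 2 tet− clones); the restricted α
repertoire additionally produces emergent convergent α collisions,
mirroring the real observation that single-chain definitions show the
most overlap. Expression is negative binomial (size 4) with gene means
log-normal (median 2, log-sd 0.8) shared between planted-set and
background genes — deliberately, so module-score control bins stay
mostly neutral (see caveat above); four 10-gene programmes are planted
at log effect 0.5 in designated clusters or in TRBJ2-2 cells;
mitochondrial genes run at ~2.5% of counts with a 2% apoptotic
subpopulation at 4× and 2% low-complexity cells at 0.15× library scale,
so the QC filters (<5% mitochondrial, 200–3,500 detected genes) have
true positives to find.

All randomness derives from one master seed through named streams
(`derive_seed(seed, "clones_e1")` etc.), so stages are independently
reproducible.

**What the generator does not emulate:** transcriptome-wide
co-expression and batch structure, empty droplets and ambient RNA,
allelic TRAV16 variants that real alignment pipelines conflate,
read-level errors, and cell-type contamination across sort gates (real
sorting experiments see a handful of tet+/tet− shared clones from
imperfect gating; the generator plants none). Passing tests therefore show the
statistics are computed correctly and recover known structure at
realistic scale and noise — not that the pipeline is robust to every
artifact of real droplet data.

## Problem sizes used in validation

The validation suite runs the partition checks on one hundred ~2,000-cell
fixtures, the transition-coupling and end-to-end checks on the full
default study (~22,000 cells, 600 genes), module-score recovery on
twenty 2,000-cell fixtures, and the logistic calibration on 1,000
simulated null fits — sizes at which the planted effects are comfortably
identified while the whole suite stays quick on a laptop.
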