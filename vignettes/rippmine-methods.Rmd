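---
title: "Methods: bait-anchored RiPP precursor mining, networking, motif
  discovery and intact-mass annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait-anchored RiPP mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippmine)
```

`rippmine` is a desk-scale reimplementation of a RiPP discovery pipeline
anchored on YcaO-domain bait enzymes. This vignette documents the models,
the parameters that matter, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate about real data.

## Genome mining

Bait CDS features are located by case-insensitive keyword match against any
qualifier, by protein/locus id, or by a regular expression on the
translation. Bait proteins can be dereplicated by greedy longest-first
clustering: sequences are visited by decreasing length and join an existing
representative at or above the identity ceiling (default 0.95), so no two
representatives are 95% identical or more. The greedy order makes the
result deterministic and biases representatives toward full-length
proteins.

Around each bait a window of `flank_nt` (default 8 000 nt) on **each side**
is cut. The flank is symmetric because precursor genes occur on either side
of the tailoring gene; the distance to the bait is measured **edge to
edge** (0 for overlapping or adjacent features). Circular contigs wrap; the
window is represented as up to two linear segments in forward genome
coordinates, and ORFs spanning the origin junction itself are not called —
a deliberate simplification that loses at most one candidate per circular
contig.

Short-ORF calling scans all six frames for a permitted start codon
(ATG/GTG/TTG, all rendered as M, genetic code table 11) followed by the
next in-frame stop inside the window. Codons containing ambiguous bases
abort translation and reject the ORF. The default peptide length bounds are
20–120 aa: an envelope with margin around the 31–89 aa range this precursor
family spans, wide enough not to lose outliers while still excluding
ordinary genes. For nested starts sharing a stop the longest *eligible* ORF
is reported (the nesting policy is configurable with `report_all`); the
choice among eligible starts matters because an over-long or untranslatable
outer ORF should not mask a valid precursor candidate. Candidate selection
orders deterministically by distance to bait, then start coordinate, then
strand, and keeps the nearest `max_per_window` (default 5). Annotated and
unannotated ORFs both pass by default, since genuine precursor genes are
mostly — but not exclusively — unannotated.

A brute-force oracle that enumerates every (position, frame, strand) triple
independently, translating through a second code path, pins the scanner on
random windows in the test suite.

## Peptide networking

Pairwise similarity is the identity of the optimal global (end-to-end)
affine-gap alignment: BLOSUM62, gap open 10, gap extend 0.5 — the standard
protein defaults, fully configurable. **Identity is defined as identical
aligned columns divided by the full alignment length, gap columns
(including terminal ones) counted in the denominator.** This is the
strictest common convention and is stated prominently because the 40/80/95%
thresholds used by the pipeline are sensitive to it; equivalence with
groupings produced by other networking software is not claimed. A
hand-coded Gotoh dynamic programme in the test suite verifies the scores on
random pairs.

Networks keep an edge when identity reaches the threshold (40% for
families, 80% for sub-families); families are connected components,
numbered by descending size with ties broken by the smallest member id, so
every output is byte-reproducible. Raising the threshold can only refine
the partition — this monotonicity is property-tested on random graphs.

## Motif discovery

Motifs are discovered with a self-contained EM in the spirit of MEME's
any-number-of-repeats model, not by wrapping the MEME suite: the original
analysis reports no MEME parameters, and a self-contained implementation
keeps the pipeline dependency-free and testable. It is documented as *not*
numerically identical to MEME.

Every width-w window of every peptide is either an instance of one position
weight matrix or background (pooled residue frequencies of the input). The
E-step computes per-window posterior responsibilities; the M-step
re-estimates the PWM from responsibility-weighted counts with pseudocount
0.1 and the mixing weight as the mean responsibility. The pseudocount acts
as a Dirichlet prior, so the quantity EM increases monotonically is the
*penalised* log-likelihood; that is what `loglik_trace` records and what
the implementation asserts non-decreasing at every iteration (the raw
likelihood can dip by the prior term, which we observed on legitimate
runs). Restarts are deterministic: windows are ranked by how many other
windows agree with them at half their positions or more, and EM restarts
from the top `n_seeds` (default 20). Widths 8–20 are swept by default and
the model with the highest mean information content per column is kept;
the benchmark motif width is 12.

Scanning reports all non-overlapping windows whose log-odds score (bits; X
residues score 0) reaches `min_bits`, selected greedily best-score-first
with ties to the smaller offset. The default threshold of 8 bits is a
stated choice, not derived from the original analysis: a planted motif
occurrence at the benchmark conservation scores ~40 bits, random windows
score below 0, so the decision boundary is insensitive over a wide range.
Classification assigns each peptide to the model (A/B) with the highest
total occurrence score, `none` when no model fires, retaining all scans as
diagnostics. `shared_kmer_report()` surfaces conserved cores shared between
motif consensi, such as the ALV tripeptide common to the two family motifs.

## Mass annotation

Monoisotopic masses are computed from fixed constants (C 12.0, H
1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069, Na
22.98976928; proton 1.00727646688 u; electron 0.00054858 u). Protonated
adducts add protons (already electron-corrected); `[M+Na]+` adds Na minus
one electron — this choice reproduces the printed sodiated value to under
1 mu. Computed `[M+H]+` for dehydrated HLSA is 409.2194, 0.2 mu from one
published calculated value (409.2196), suggesting marginally different
constants there; the adopted comparison tolerance is ±0.001 u.

The default modification library is dehydration/cyclodehydration (−H₂O, up
to 3), azole (−H₂O−H₂, requires Ser/Thr/Cys at position ≥ 2, up to 2),
dehydrogenation (−H₂, up to 2) and N-terminal acetylation (+C₂H₂O, once,
requires a free N-terminus). Amidine-ring formation and azoline formation
are mass-degenerate with dehydration (all net −H₂O); the default library
collapses them into the single `dehydration` entry and every candidate
carries a `degenerate_with` flag naming the alternatives whose site rules
hold, so reports never assert chemistry that intact mass cannot
distinguish (`modification_library(collapse_degenerate = FALSE)` exposes
them explicitly; modifications competing for the free N-terminus are
mutually exclusive). Cys carries S in the residue table even though the
benchmark core lacks it, for Ser-to-Cys mutant scenarios.

Enumeration is exhaustive over contiguous subsequences (default 2–15
residues), legal modification multisets (default ≤ 3 total) and adducts
consistent with each ion's charge (all three when unknown), retaining
matches within the per-ion ppm tolerance (default 10 ppm; all published
observed/calculated pairs agree within ~6 ppm). Ranking is by absolute ppm
error, then fewer modifications, then longer subsequence, then
lexicographic — a deterministic parsimony order. Exact isobars are a fact
of life here (sequence permutations; Ala+Glu ≡ Leu+Ser+acetyl): they tie in
ppm and are resolved by the stated tie-break, and the full result table
retains every tied assignment.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and seed
(byte-identical reruns). Defaults encode the benchmark conditions:

* genomes: 30 kb contigs at 70% GC (actinobacterial composition; GC
  affects the spurious short-ORF rate), a planted 400-aa bait CDS
  (product "YcaO-like protein"), a planted 60-aa precursor ORF at a
  controlled edge-to-edge distance, decoy CDS features, precursor
  unannotated by default. An in-frame stop guard immediately upstream of
  the planted start makes the planted coordinates exactly recoverable,
  isolating window/scan correctness from background ORF structure.
* peptide families: 31–89 aa, within-family identity target 0.85,
  between-family ceiling 0.20, 1–3 planted motif occurrences per peptide,
  every motif consensus carrying ALV. Members are substitution-only mutants
  of a family ancestor at rate 1 − √target, which makes the pairwise
  identity analytically controllable (indels would not be); achieved
  identities are re-measured with the pipeline's own aligner and a family
  is redrawn when sampling noise leaves the ±5 pp band. A separate
  generator plants sub-clusters (within 0.85 / across 0.60) for sub-family
  splitting, and `make_motif_peptides` controls per-column motif
  conservation (benchmark 0.9) on an i.i.d. background.
* ion lists: true ions are theoretical species plus Gaussian ppm noise
  (noise ≤ tolerance/3); decoys are uniform over the observed range and
  rejected within 3× tolerance of *any* theoretical species, which makes
  the zero-decoy-match assertion sound rather than probabilistic.

What passing these benchmarks does **not** show: real intergenic grammar,
promoters, codon usage, indel-rich family evolution, MS/MS fragmentation or
isotope envelopes are not simulated, and corpus-scale figures (thousands of
baits from public databases, hundreds of family members across phyla)
cannot be reproduced at desk scale — the pipeline's behaviour at that scale
is covered only by the properties tested here. Problem sizes in the test
suite (20 genomes per recovery arm, 5×10-member families, 30-peptide motif
sets, 200 random enumeration instances) were chosen as the smallest sizes
at which the planted-truth assertions are statistically meaningful.

## Degenerate inputs and numerical choices

Windows shorter than the minimal ORF and all-N windows return empty
results rather than errors; empty networks and singleton families are
legal; EM refuses fewer than 5 peptides or a width exceeding the shortest
peptide; formula arithmetic rejects negative final element counts; illegal
residues raise typed errors naming the position. EM convergence uses an
absolute objective improvement below 1e-6 (max 100 iterations); identity
thresholds are inclusive (≥); all ordering rules (candidate selection,
family numbering, candidate ranking, scan tie-breaks) are total, so every
pipeline output is reproducible bit for bit under a fixed seed.
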