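# rippmine

Bait-anchored genome mining, peptide networking, motif discovery and
intact-mass annotation for RiPP natural products, in R.

Ribosomally synthesised and post-translationally modified peptides (RiPPs)
are made from short precursor peptides that genome annotation pipelines
routinely miss. A productive way to find new RiPP families is to anchor the
search on a *bait* tailoring enzyme — here, YcaO-domain proteins, the
ATP-dependent enzymes behind azoline heterocycles, amidine rings and
thioamides — and look for unannotated short open reading frames (ORFs) in
the surrounding DNA. `rippmine` implements that discovery pipeline end to
end at desk scale:

1. **genome mining** — parse GenBank records, find bait CDS features
   (product keyword, protein id, or translation regex), dereplicate baits by
   greedy clustering at a 95% identity ceiling, cut a window of 8 kb on each
   side of the bait, and call candidate short ORFs (20–120 aa, start codons
   ATG/GTG/TTG, genetic code table 11) in all six frames;
2. **peptide networking** — all-vs-all global affine-gap alignment
   (BLOSUM62, gap open 10 / extend 0.5); percent identity is defined as
   identical aligned columns over the *full* alignment length including gap
   columns; edges at a 40% identity cut-off, families as connected
   components, sub-families at 80%;
3. **motif discovery** — a self-contained MEME-style EM over an
   any-number-of-repeats model: every width-w window is motif or background,
   a position weight matrix is re-estimated from posterior responsibilities
   (pseudocount 0.1), and peptides are classified A/B/none by motif content
   with per-peptide occurrence counts (1–3 in this family);
4. **mass annotation** — exhaustive enumeration of contiguous core
   subsequences times a modification library (dehydration/cyclodehydration
   −H₂O, azole −H₂O−H₂, dehydrogenation −H₂, N-terminal acetylation
   +C₂H₂O) times adducts ([M+H]⁺, [M+2H]²⁺, [M+Na]⁺), matched to observed
   ions within a ppm tolerance: `m/z = (M + shift)/z`,
   `ppm = (obs − calc)/calc × 10⁶`;
5. **synthetic data** — seeded generators for genomes with planted
   bait+precursor clusters, peptide families with controlled pairwise
   identities and planted motifs (always carrying the ALV tripeptide shared
   by the two family motifs), and ion lists with decoys, each with a ground
   truth table — so the whole pipeline is testable offline.

## Worked example

Mine a synthetic genome with a planted precursor 3 kb from a YcaO bait, then
match the flagship ions of the mature product against the precursor:

```r
library(rippmine)

g <- make_genome(seed = 7)                      # 30 kb contig, planted BGC
baits <- find_baits(g$genome, product_keywords = "ycaO")
w     <- extract_window(g$genome, baits[[1]], flank_nt = 8000)
orfs  <- find_short_orfs(w, min_aa = 20, max_aa = 120)
cand  <- select_precursor_candidates(orfs, max_per_window = 5)
subset(orfs, start == g$truth$precursor$start)[,
    c("start","end","strand","length_aa","distance_to_bait_nt")]
#>    start   end strand length_aa distance_to_bait_nt
#> 89 11817 12000      1        60                3000

parent <- paste0("MTQETAAELLDAAELAELSEADGG", "HLSATH", "GGSDAEAVESFWDGELAED")
ions   <- ion_table(c(647.3251, 510.27, 409.22), tolerance_ppm = 10)
res    <- enumerate_candidates(parent, ions)
res[!duplicated(res$observed_mz),
    c("subsequence","mods","adduct","theoretical_mz","observed_mz","ppm")]
#>   subsequence        mods adduct theoretical_mz observed_mz       ppm
#> 1      HLSATH dehydration [M+H]+       647.3260    647.3251 -1.366909
#> 2        HLSA dehydration [M+H]+       409.2194    409.2200  1.479642
#> 3       HLSAT dehydration [M+H]+       510.2671    510.2700  5.736262
```

The planted 60-residue precursor is recovered at its exact genomic
coordinates, 3 kb from the bait.

Each ion resolves to a dehydrated fragment of the HLSATH core: the intact
product (one net loss of water — an amidine ring or azoline, which are
mass-degenerate with a backbone dehydration and flagged as such in the
`degenerate_with` column) and its two truncation products. Family and motif
analysis run the same way from `build_network()` / `connected_components()`
and `discover_motif()` / `classify_peptides()`; see the vignette in
`vignettes/` for the models and parameter choices.

A thin CLI wrapping the same functions is installed as `exec/rippmine`
(subcommands `mine`, `network`, `motifs`, `massmatch`).

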