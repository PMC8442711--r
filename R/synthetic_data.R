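# Synthetic-data generators with ground truth: genomes with planted gene
# clusters, peptide families with controlled identities and planted motifs,
# and ion lists mixing true species with decoys. Every generator is a pure
# function of its arguments plus the seed, so reruns are byte-identical.

.sample_dna <- function(n, gc = 0.7) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.sample_protein <- function(n) {
  paste(sample(.MOTIF_ALPHABET, n, replace = TRUE), collapse = "")
}

# Codons per amino acid under genetic code table 11 (sense codons only).
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      code <- Biostrings::getGeneticCode("11")
      tab <<- split(names(code), code)
    }
    tab
  }
})

# Reverse-translate a peptide into a valid ORF: ATG start, random
# synonymous codons, random stop. First residue must be (or is forced to) M.
.reverse_translate_orf <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  tab <- .codons_by_aa()
  codons <- vapply(aa, function(r) sample(tab[[r]], 1), character(1))
  codons[1] <- "ATG"
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
  paste(c(codons, stop_codon), collapse = "")
}

.overwrite <- function(sequence, at, replacement) {
  # at: 0-based start
  paste0(substr(sequence, 1, at),
         replacement,
         substr(sequence, at + nchar(replacement) + 1, nchar(sequence)))
}

#' Generate a synthetic genome with a planted bait and precursor ORF
#'
#' Builds a random-background contig (default 70% GC, typical of
#' actinobacterial genomes) and plants: a bait CDS (annotated with
#' `bait_product` and its translation), a short precursor ORF at a
#' controlled edge-to-edge distance from the bait, and decoy CDS features.
#' An in-frame stop codon is written immediately upstream of the precursor
#' start so that the planted start is the longest ORF for its stop codon,
#' making the planted coordinates exactly recoverable. The precursor ORF is
#' unannotated by default, emulating the typical annotation status of RiPP
#' precursor genes.
#'
#' @param contig_length contig size in nt (default 30000).
#' @param bait_product product string of the bait CDS.
#' @param bait_aa_len bait protein length (default 400 aa).
#' @param precursor_peptide amino-acid sequence of the planted precursor
#'   (first residue forced to M); default a random 60-mer.
#' @param precursor_distance edge-to-edge distance from the bait CDS in nt.
#' @param precursor_strand +1 or -1.
#' @param decoy_cds number of decoy CDS features (random proteins).
#' @param gc background GC content.
#' @param annotate_precursor also annotate the precursor as a CDS feature.
#' @param topology contig topology.
#' @param record_id LOCUS name.
#' @param seed RNG seed.
#' @param path optional file path; when given the record is written as
#'   GenBank.
#' @return list with `genome` (a [genome_record()]), `truth` (planted
#'   coordinates: `bait`, `precursor`, `decoys`), and `path` (NULL unless
#'   written).
#' @export
make_genome <- function(contig_length = 30000,
                        bait_product = "YcaO-like protein",
                        bait_aa_len = 400, precursor_peptide = NULL,
                        precursor_distance = 3000, precursor_strand = 1L,
                        decoy_cds = 3, gc = 0.7, annotate_precursor = FALSE,
                        topology = c("linear", "circular"),
                        record_id = "synctg1", seed = 1, path = NULL) {
  topology <- match.arg(topology)
  set.seed(seed)
  sequence <- .sample_dna(contig_length, gc)

  if (is.null(precursor_peptide)) precursor_peptide <- .sample_protein(60)
  if (substr(precursor_peptide, 1, 1) != "M") {
    precursor_peptide <- paste0("M", substr(precursor_peptide, 2,
                                            nchar(precursor_peptide)))
  }

  bait_protein <- .sample_protein(bait_aa_len)
  bait_protein <- paste0("M", substr(bait_protein, 2, nchar(bait_protein)))
  bait_nt <- .reverse_translate_orf(bait_protein)
  bait_len <- nchar(bait_nt)
  bait_start <- contig_length %/% 2
  bait_end <- bait_start + bait_len
  if (bait_end > contig_length) {
    stop("make_genome(): infeasible packing — contig too short for the bait",
         call. = FALSE)
  }
  sequence <- .overwrite(sequence, bait_start, bait_nt)

  prec_nt <- .reverse_translate_orf(precursor_peptide)
  prec_len <- nchar(prec_nt)
  # plant upstream of the bait at the requested edge-to-edge distance,
  # guarded by an in-frame stop immediately before the start codon
  prec_end <- bait_start - precursor_distance
  prec_start <- prec_end - prec_len
  if (prec_start < 3) {
    stop("make_genome(): infeasible packing — precursor does not fit upstream",
         call. = FALSE)
  }
  if (precursor_strand == 1L) {
    sequence <- .overwrite(sequence, prec_start - 3L, paste0("TAA", prec_nt))
  } else {
    fwd <- .revcomp(prec_nt)
    sequence <- .overwrite(sequence, prec_start, paste0(fwd, "TTA"))
  }

  occupied <- list(c(prec_start - 3L, prec_end + 3L), c(bait_start, bait_end))
  decoys <- list()
  tries <- 0L
  while (length(decoys) < decoy_cds) {
    tries <- tries + 1L
    if (tries > 200L) {
      stop("make_genome(): infeasible packing — cannot place decoy CDS",
           call. = FALSE)
    }
    aa_len <- sample(80:200, 1)
    prot <- paste0("M", substr(.sample_protein(aa_len), 2, aa_len))
    nt <- .reverse_translate_orf(prot)
    len <- nchar(nt)
    pos <- sample(0:(contig_length - len), 1)
    clash <- any(vapply(occupied, function(iv) {
      min(iv[2], pos + len) > max(iv[1], pos)
    }, logical(1)))
    if (clash) next
    strand <- sample(c(1L, -1L), 1)
    sequence <- .overwrite(sequence, pos,
                           if (strand == 1L) nt else .revcomp(nt))
    occupied <- c(occupied, list(c(pos, pos + len)))
    decoys[[length(decoys) + 1L]] <- list(start = pos, end = pos + len,
                                          strand = strand, protein = prot)
  }

  features <- list(annotated_feature(
    "CDS", bait_start, bait_end, strand = 1L,
    qualifiers = list(product = bait_product,
                      locus_tag = paste0(record_id, "_bait"),
                      translation = bait_protein)))
  for (i in seq_along(decoys)) {
    d <- decoys[[i]]
    features[[length(features) + 1L]] <- annotated_feature(
      "CDS", d$start, d$end, strand = d$strand,
      qualifiers = list(product = "hypothetical protein",
                        locus_tag = sprintf("%s_d%02d", record_id, i),
                        translation = d$protein))
  }
  if (annotate_precursor) {
    features[[length(features) + 1L]] <- annotated_feature(
      "CDS", prec_start, prec_end, strand = precursor_strand,
      qualifiers = list(product = "putative precursor peptide",
                        locus_tag = paste0(record_id, "_prec"),
                        translation = precursor_peptide))
  }
  ord <- order(vapply(features, `[[`, integer(1), "start"))
  genome <- genome_record(record_id, sequence, features[ord], topology)

  truth <- list(
    bait = list(start = bait_start, end = bait_end, strand = 1L,
                protein = bait_protein),
    precursor = list(start = prec_start, end = prec_end,
                     strand = as.integer(precursor_strand),
                     peptide = precursor_peptide,
                     distance_to_bait_nt = precursor_distance),
    decoys = decoys)
  if (!is.null(path)) write_genbank(genome, path)
  list(genome = genome, truth = truth, path = path)
}

# Plant a motif consensus containing "ALV" at a random position.
.random_motif_consensus <- function(width = 12) {
  stopifnot(width >= 4)
  cons <- strsplit(.sample_protein(width), "", fixed = TRUE)[[1]]
  at <- sample(seq_len(width - 2), 1)
  cons[at:(at + 2)] <- c("A", "L", "V")
  paste(cons, collapse = "")
}

# Substitute a fraction p of positions with different residues.
.mutate_peptide <- function(peptide, p) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(aa)) < p)
  for (i in hit) {
    aa[i] <- sample(setdiff(.MOTIF_ALPHABET, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

#' Generate peptide families with controlled identities and planted motifs
#'
#' Each family descends from a random ancestor carrying
#' `occurrences_per_peptide` non-overlapping copies of a family motif
#' consensus (which always contains the tripeptide ALV). Members are
#' derived from the ancestor by random substitutions at rate
#' `1 - sqrt(within_identity)`, so the expected pairwise identity between
#' members is the target. Ancestors are rejection-sampled until all
#' between-family ancestor identities fall below `between_ceiling` minus a
#' safety margin, and achieved identities are re-measured with
#' [pairwise_identity()].
#'
#' @param n_families number of families.
#' @param peptides_per_family members per family.
#' @param length_range ancestor length range in residues (default 31-89,
#'   the length envelope typical of this precursor family).
#' @param within_identity target mean pairwise identity inside a family.
#' @param between_ceiling maximum tolerated between-family identity.
#' @param motif_width width of each family's planted motif consensus.
#' @param occurrences_per_peptide motif copies planted per ancestor (1-3).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget for ancestors.
#' @param verify re-measure achieved identities and error if the within
#'   target is missed by more than 5 percentage points.
#' @param path optional FASTA output path.
#' @return list with `peptides` (data.frame `id`, `family`, `sequence`),
#'   `truth` (per-family `consensus`, `ancestor`, `motif_offsets`), `path`.
#' @export
make_peptide_families <- function(n_families = 5, peptides_per_family = 20,
                                  length_range = c(31, 89),
                                  within_identity = 0.85,
                                  between_ceiling = 0.20, motif_width = 12,
                                  occurrences_per_peptide = 1, seed = 1,
                                  max_tries = 200, verify = TRUE,
                                  path = NULL) {
  stopifnot(within_identity > 0, within_identity <= 1,
            within_identity > between_ceiling)
  set.seed(seed)
  occ <- rep_len(occurrences_per_peptide, n_families)
  margin <- 0.03

  ancestors <- character(0)
  consensi <- character(0)
  offsets <- list()
  tries <- 0L
  while (length(ancestors) < n_families) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("make_peptide_families(): cannot achieve the between-family ",
           "identity ceiling — targets unattainable", call. = FALSE)
    }
    k <- length(ancestors) + 1L
    need <- occ[k] * motif_width + 4L
    len <- sample(max(length_range[1], need):max(length_range[2], need), 1)
    cons <- .random_motif_consensus(motif_width)
    anc <- strsplit(.sample_protein(len), "", fixed = TRUE)[[1]]
    # non-overlapping motif offsets (0-based)
    slots <- floor(len / motif_width)
    slot_pick <- sort(sample(seq_len(slots), occ[k]))
    offs <- (slot_pick - 1L) * motif_width
    for (o in offs) {
      anc[(o + 1):(o + motif_width)] <- strsplit(cons, "", fixed = TRUE)[[1]]
    }
    anc <- paste(anc, collapse = "")
    ok <- all(vapply(ancestors, function(a) {
      pairwise_identity(a, anc) <= between_ceiling - margin
    }, logical(1)))
    if (!ok) next
    ancestors <- c(ancestors, anc)
    consensi <- c(consensi, cons)
    offsets[[k]] <- offs
  }

  p_sub <- 1 - sqrt(within_identity)
  draw_family <- function(f) {
    vapply(seq_len(peptides_per_family), function(m) {
      if (within_identity >= 1) ancestors[f] else
        .mutate_peptide(ancestors[f], p_sub)
    }, character(1))
  }
  mean_within <- function(seqs) {
    pick <- utils::combn(seq_len(min(length(seqs), 8)), 2)
    mean(apply(pick, 2, function(ij) {
      pairwise_identity(seqs[ij[1]], seqs[ij[2]])
    }))
  }
  rows <- list()
  for (f in seq_len(n_families)) {
    seqs <- draw_family(f)
    if (verify && peptides_per_family >= 2) {
      # sampling noise can push a family off target; redraw a few times
      # before declaring the target unattainable
      attempt <- 1L
      while (abs(mean_within(seqs) - within_identity) > 0.05) {
        attempt <- attempt + 1L
        if (attempt > 10L) {
          stop(sprintf(paste0("make_peptide_families(): family %d cannot ",
                              "reach identity %.3f +/- 0.05 — target ",
                              "unattainable"), f, within_identity),
               call. = FALSE)
        }
        seqs <- draw_family(f)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("fam%02d_p%03d", f, seq_len(peptides_per_family)),
      family = f, sequence = seqs, stringsAsFactors = FALSE)
  }
  peptides <- do.call(rbind, rows)

  if (!is.null(path)) {
    aas <- Biostrings::AAStringSet(peptides$sequence)
    names(aas) <- peptides$id
    Biostrings::writeXStringSet(aas, path)
  }
  truth <- list(consensus = consensi, ancestor = ancestors,
                motif_offsets = offsets)
  list(peptides = peptides, truth = truth, path = path)
}

#' Generate one family containing planted sub-clusters
#'
#' Derives `n_sub` sub-ancestors from a single family ancestor and mutates
#' members from each, so that within-sub-cluster identity targets
#' `within_identity` while cross-sub-cluster identity targets
#' `between_identity` (both verified on a sample of pairs). Useful for
#' testing sub-family splitting at a stricter threshold.
#'
#' @param n_sub number of sub-clusters.
#' @param members_per_sub members per sub-cluster.
#' @param length ancestor length in residues.
#' @param within_identity target pairwise identity inside a sub-cluster.
#' @param between_identity target pairwise identity across sub-clusters
#'   (must be below `within_identity`).
#' @param seed RNG seed.
#' @return list with `peptides` (data.frame `id`, `subcluster`, `sequence`)
#'   and `truth` (`ancestor`, `sub_ancestors`).
#' @export
make_subclustered_family <- function(n_sub = 2, members_per_sub = 10,
                                     length = 60, within_identity = 0.85,
                                     between_identity = 0.60, seed = 1) {
  stopifnot(between_identity < within_identity)
  set.seed(seed)
  ancestor <- .sample_protein(length)
  # cross-member identity ~ (sub-ancestor identity) x (within target):
  # pick the sub-ancestor divergence to land cross pairs on the target
  p_b <- 1 - sqrt(between_identity / within_identity)
  p_w <- 1 - sqrt(within_identity)
  subanc <- vapply(seq_len(n_sub), function(k) {
    .mutate_peptide(ancestor, p_b)
  }, character(1))
  rows <- list()
  for (k in seq_len(n_sub)) {
    for (m in seq_len(members_per_sub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("sub%02d_p%03d", k, m), subcluster = k,
        sequence = .mutate_peptide(subanc[k], p_w),
        stringsAsFactors = FALSE)
    }
  }
  list(peptides = do.call(rbind, rows),
       truth = list(ancestor = ancestor, sub_ancestors = subanc))
}

#' Generate peptides with a planted motif at controlled conservation
#'
#' Background residues are i.i.d. uniform; each peptide carries
#' `occurrences` non-overlapping copies of the consensus in which every
#' column shows the consensus residue with probability `conservation` and a
#' random different residue otherwise.
#'
#' @param n_peptides number of peptides.
#' @param length peptide length.
#' @param consensus motif consensus string (default a random ALV-bearing
#'   12-mer).
#' @param conservation per-column consensus probability (default 0.9).
#' @param occurrences motif copies per peptide.
#' @param seed RNG seed.
#' @return list with `peptides` (data.frame `id`, `sequence`), `truth`
#'   (`consensus`, per-peptide `offsets` list).
#' @export
make_motif_peptides <- function(n_peptides = 30, length = 60,
                                consensus = NULL, conservation = 0.9,
                                occurrences = 1, seed = 1) {
  set.seed(seed)
  if (is.null(consensus)) consensus <- .random_motif_consensus(12)
  w <- nchar(consensus)
  stopifnot(length >= occurrences * w)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  rows <- list(); offs <- list()
  slots <- floor(length / w)
  for (i in seq_len(n_peptides)) {
    aa <- strsplit(.sample_protein(length), "", fixed = TRUE)[[1]]
    slot_pick <- sort(sample(seq_len(slots), occurrences))
    o <- (slot_pick - 1L) * w
    for (s in o) {
      for (j in seq_len(w)) {
        aa[s + j] <- if (stats::runif(1) < conservation) cons[j] else
          sample(setdiff(.MOTIF_ALPHABET, cons[j]), 1)
      }
    }
    rows[[i]] <- data.frame(id = sprintf("pep%03d", i),
                            sequence = paste(aa, collapse = ""),
                            stringsAsFactors = FALSE)
    offs[[i]] <- o
  }
  list(peptides = do.call(rbind, rows),
       truth = list(consensus = consensus, offsets = offs))
}

#' Generate an observed-ion list with ground truth
#'
#' True ions are theoretical m/z values of randomly drawn legal candidate
#' species of the parents, perturbed with Gaussian ppm noise. Decoy ions
#' are uniform over the observed m/z range and rejected if they fall within
#' three times the tolerance of *any* theoretical species, which makes the
#' zero-match guarantee for decoys sound.
#'
#' @param parents named character vector of parent peptides.
#' @param mod_library see [modification_library()].
#' @param n_true,n_decoys number of true and decoy ions.
#' @param ppm_noise_sd Gaussian m/z noise in ppm (must be at most
#'   `tolerance_ppm / 3`).
#' @param tolerance_ppm matching tolerance recorded on each ion.
#' @param max_total_mods,min_len,max_len passed to
#'   [theoretical_candidates()].
#' @param seed RNG seed.
#' @param path optional CSV output path.
#' @return list with `ions` (data.frame `mz`, `charge`, `tolerance_ppm`),
#'   `truth` (data.frame of the drawn species: parent, subsequence, mods,
#'   adduct, theoretical m/z; decoy rows have NA), `path`.
#' @export
make_ion_list <- function(parents, mod_library = modification_library(),
                          n_true = 10, n_decoys = 10, ppm_noise_sd = 1,
                          tolerance_ppm = 10, max_total_mods = 2,
                          min_len = 2, max_len = 10, seed = 1, path = NULL) {
  stopifnot(ppm_noise_sd <= tolerance_ppm / 3)
  set.seed(seed)
  if (is.null(names(parents))) {
    names(parents) <- sprintf("parent%02d", seq_along(parents))
  }
  theo <- do.call(rbind, lapply(names(parents), function(id) {
    theoretical_candidates(parents[[id]], mod_library, max_total_mods,
                           min_len, max_len, parent_id = id)
  }))
  all_mz <- sort(theo$theoretical_mz)

  truth_rows <- list(); ions <- list()
  if (n_true > 0) {
    pick <- sample(nrow(theo), n_true, replace = n_true > nrow(theo))
    for (i in pick) {
      noisy <- theo$theoretical_mz[i] *
        (1 + stats::rnorm(1, 0, ppm_noise_sd) / 1e6)
      ions[[length(ions) + 1L]] <- data.frame(
        mz = noisy, charge = theo$charge[i], tolerance_ppm = tolerance_ppm,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        is_decoy = FALSE, parent_id = theo$parent_id[i],
        subsequence = theo$subsequence[i], mods = theo$mods[i],
        adduct = theo$adduct[i], theoretical_mz = theo$theoretical_mz[i],
        stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0) {
    lo <- min(all_mz); hi <- max(all_mz)
    made <- 0L; tries <- 0L
    while (made < n_decoys) {
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("make_ion_list(): cannot place decoys clear of the theoretical",
             " spectrum", call. = FALSE)
      }
      cand <- stats::runif(1, lo, hi)
      # nearest theoretical species in ppm
      near <- min(abs(ppm_error(cand, all_mz)))
      if (near <= 3 * tolerance_ppm) next
      ions[[length(ions) + 1L]] <- data.frame(
        mz = cand, charge = NA_integer_, tolerance_ppm = tolerance_ppm,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        is_decoy = TRUE, parent_id = NA_character_,
        subsequence = NA_character_, mods = NA_character_,
        adduct = NA_character_, theoretical_mz = NA_real_,
        stringsAsFactors = FALSE)
      made <- made + 1L
    }
  }
  ions <- do.call(rbind, ions)
  truth <- do.call(rbind, truth_rows)
  if (!is.null(path)) {
    utils::write.csv(ions, path, row.names = FALSE, quote = FALSE)
  }
  list(ions = ions, truth = truth, path = path)
}
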