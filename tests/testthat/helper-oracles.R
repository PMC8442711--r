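# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths: the aligner is a plain Gotoh dynamic
# programme, the mass oracle carries its own residue composition table, and
# the ORF oracle walks codons one by one (translating via seqinr).

# ---- brute-force affine-gap global aligner ---------------------------------

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_global_score <- function(a, b, S = oracle_blosum62,
                                open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# ---- independent monoisotopic mass oracle ----------------------------------

# element masses typed here independently of the package source
.om_el <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
.om_proton <- 1.00727646688
.om_sodium_cation <- 22.98976928 - 0.00054857990946

# residue compositions (amino acid minus water): C, H, N, O, S
.om_residues <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracle_residue_mass <- vapply(.om_residues, function(v) {
  sum(v * .om_el[c("C", "H", "N", "O", "S")])
}, numeric(1))

oracle_water <- 2 * .om_el[["H"]] + .om_el[["O"]]

oracle_peptide_mass <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  sum(oracle_residue_mass[aa]) + oracle_water
}

# modification mass deltas and independent legality rules mirroring the
# default library's chemistry
.om_mod_delta <- c(dehydration = -(2 * .om_el[["H"]] + .om_el[["O"]]),
                   azole = -(4 * .om_el[["H"]] + .om_el[["O"]]),
                   dehydrogenation = -2 * .om_el[["H"]],
                   acetylation = 2 * .om_el[["C"]] + 2 * .om_el[["H"]] +
                     .om_el[["O"]])

.om_n_stc <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  if (length(aa) < 2) 0L else sum(aa[-1] %in% c("S", "T", "C"))
}

# exhaustively enumerate matches the slow way: every substring, every
# modification count vector, every adduct, every ion
oracle_enumerate <- function(parent, ions, max_total_mods = 3,
                             min_len = 2, max_len = 15) {
  n <- nchar(parent)
  adducts <- data.frame(name = c("[M+H]+", "[M+2H]2+", "[M+Na]+"),
                        z = c(1, 2, 1),
                        shift = c(.om_proton, 2 * .om_proton,
                                  .om_sodium_cation))
  out <- list()
  for (len in min_len:min(max_len, n)) {
    for (s in 0:(n - len)) {
      sub <- substr(parent, s + 1, s + len)
      max_deh <- min(3, len - 1)
      max_azo <- min(2, .om_n_stc(sub))
      max_dhg <- min(2, len - 1)
      for (deh in 0:max_deh) for (azo in 0:max_azo)
        for (dhg in 0:max_dhg) for (ace in 0:1) {
          if (deh + azo + dhg + ace > max_total_mods) next
          mass <- oracle_peptide_mass(sub) +
            deh * .om_mod_delta[["dehydration"]] +
            azo * .om_mod_delta[["azole"]] +
            dhg * .om_mod_delta[["dehydrogenation"]] +
            ace * .om_mod_delta[["acetylation"]]
          mods <- sort(rep(c("acetylation", "azole", "dehydration",
                             "dehydrogenation"), c(ace, azo, deh, dhg)))
          for (ai in seq_len(nrow(adducts))) {
            theo <- (mass + adducts$shift[ai]) / adducts$z[ai]
            for (ii in seq_len(nrow(ions))) {
              if (!is.na(ions$charge[ii]) &&
                  ions$charge[ii] != adducts$z[ai]) next
              ppm <- (ions$mz[ii] - theo) / theo * 1e6
              if (abs(ppm) <= ions$tolerance_ppm[ii]) {
                out[[length(out) + 1L]] <- sprintf(
                  "%d|%d|%s|%s|%d", s, s + len,
                  paste(mods, collapse = ","), adducts$name[ai], ii)
              }
            }
          }
        }
    }
  }
  keys <- unlist(out)
  if (is.null(keys)) character(0) else sort(keys)
}

# ---- brute-force ORF oracle -------------------------------------------------

oracle_revcomp <- function(nt) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

# every (position, strand) start codon walked codon-by-codon to its stop;
# translation through seqinr; returns all eligible ORFs in forward coords
oracle_orfs <- function(seq, min_aa, max_aa,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c(1L, -1L)) {
    s_seq <- if (strand == 1L) seq else oracle_revcomp(seq)
    L <- nchar(s_seq)
    for (pos in 0:(L - 3)) {
      codon <- substr(s_seq, pos + 1, pos + 3)
      if (!codon %in% starts) next
      j <- pos + 3
      stop_at <- NA
      while (j + 3 <= L) {
        cj <- substr(s_seq, j + 1, j + 3)
        if (cj %in% stops) { stop_at <- j; break }
        j <- j + 3
      }
      if (is.na(stop_at)) next
      len_aa <- (stop_at - pos) / 3
      if (len_aa < min_aa || len_aa > max_aa) next
      nt <- substr(s_seq, pos + 1, stop_at + 3)
      if (grepl("N", nt)) next
      pep <- paste(seqinr::translate(strsplit(nt, "")[[1]], numcode = 11),
                   collapse = "")
      pep <- sub("\\*$", "", pep)
      if (grepl("\\*", pep)) next   # internal stop cannot happen, guard
      substr(pep, 1, 1) <- "M"
      if (strand == 1L) {
        gs <- pos; ge <- stop_at + 3
      } else {
        gs <- L - (stop_at + 3); ge <- L - pos
      }
      res[[length(res) + 1L]] <- list(start = gs, end = ge, strand = strand,
                                      stop_key = paste(strand, stop_at),
                                      scan_start = pos, peptide = pep)
    }
  }
  res
}

# longest-per-stop reduction matching the package default
oracle_orfs_longest <- function(seq, min_aa, max_aa) {
  all <- oracle_orfs(seq, min_aa, max_aa)
  if (!length(all)) return(all)
  keys <- vapply(all, `[[`, character(1), "stop_key")
  sc <- vapply(all, `[[`, numeric(1), "scan_start")
  keep <- logical(length(all))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    keep[idx[which.min(sc[idx])]] <- TRUE
  }
  all[keep]
}

orf_key <- function(df) {
  sort(sprintf("%d|%d|%d", df$start, df$end, df$strand))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, prob = p), collapse = "")
}
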