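# Exhaustive core-peptide / modification enumeration against observed ions.
#
# A RiPP precursor is cleaved to an unknown contiguous core which may carry a
# small multiset of modifications; intact-mass matching enumerates every
# (subsequence, modification multiset, adduct) combination and retains those
# whose theoretical m/z falls within each observed ion's ppm tolerance.

#' Read an observed-ion table
#'
#' @param path CSV/TSV with columns `mz`, optional `charge` (NA = unknown)
#'   and optional `tolerance_ppm` (default filled with `default_tolerance`).
#' @param default_tolerance ppm tolerance used where the file gives none.
#' @return data.frame with columns `mz`, `charge`, `tolerance_ppm`.
#' @export
read_ions <- function(path, default_tolerance = 10) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) stop("read_ions(): missing 'mz' column", call. = FALSE)
  if (!"charge" %in% names(df)) df$charge <- NA_integer_
  if (!"tolerance_ppm" %in% names(df)) df$tolerance_ppm <- default_tolerance
  df$tolerance_ppm[is.na(df$tolerance_ppm)] <- default_tolerance
  stopifnot(all(df$mz > 0), all(df$tolerance_ppm > 0))
  df[, c("mz", "charge", "tolerance_ppm")]
}

#' Build the ion table in code
#' @param mz observed m/z values.
#' @param charge integer charges (NA = unknown; all adducts are tried).
#' @param tolerance_ppm per-ion matching tolerance.
#' @return data.frame usable by [enumerate_candidates()].
#' @export
ion_table <- function(mz, charge = NA_integer_, tolerance_ppm = 10) {
  stopifnot(all(mz > 0), all(tolerance_ppm > 0))
  data.frame(mz = mz, charge = as.integer(charge),
             tolerance_ppm = tolerance_ppm)
}

# Enumerate all legal modification multisets of total size <= max_total_mods
# for one sequence. Returns a list of character vectors (possibly repeating
# names), including the empty multiset.
.legal_mod_multisets <- function(sequence, library, max_total_mods) {
  names_lib <- names(library)
  max_counts <- vapply(names_lib, function(n) {
    as.integer(min(library[[n]]$max_count, library[[n]]$sites(sequence)))
  }, integer(1))
  grids <- lapply(max_counts, function(m) 0:max(0L, m))
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names_lib
  keep <- rowSums(grid) <= max_total_mods
  # free-N-terminus exclusivity
  nterm <- vapply(names_lib, function(n) library[[n]]$needs_free_nterm,
                  logical(1))
  if (any(nterm)) {
    keep <- keep & rowSums(grid[, nterm, drop = FALSE] > 0) <= 1
  }
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    rep(names_lib, times = as.integer(grid[i, ]))
  })
}

# Mass-degenerate named alternatives for the generic dehydration: intact
# mass cannot distinguish backbone dehydration, amidine-ring formation and
# azoline formation (all net -H2O), so candidates flag which named
# chemistries are placeable instead of asserting one.
.dehydration_alternatives <- function(sequence) {
  alt <- character(0)
  if (nchar(sequence) >= 2L) alt <- c(alt, "amidine")
  if (.n_stc_internal(sequence) >= 1L) alt <- c(alt, "azoline")
  alt
}

#' All theoretical candidate species of a precursor
#'
#' Enumerates every contiguous subsequence in `[min_len, max_len]` crossed
#' with every legal modification multiset of size at most `max_total_mods`
#' and every supported adduct.
#'
#' @param parent_sequence amino-acid string of the precursor peptide.
#' @param mod_library see [modification_library()].
#' @param max_total_mods maximum modification multiset size (default 3).
#' @param min_len,max_len subsequence length bounds (defaults 2 and 15).
#' @param parent_id label recorded in the output.
#' @return data.frame with columns `parent_id`, `start`, `end` (0-based
#'   half-open in the parent), `subsequence`, `mods` (comma-joined sorted,
#'   "" for none), `n_mods`, `formula`, `neutral_mass`, `adduct`, `charge`,
#'   `theoretical_mz`, `degenerate_with`.
#' @export
theoretical_candidates <- function(parent_sequence,
                                   mod_library = modification_library(),
                                   max_total_mods = 3, min_len = 2,
                                   max_len = 15, parent_id = "parent") {
  stopifnot(nchar(parent_sequence) > 0, min_len >= 1,
            max_len >= min_len, max_total_mods >= 0)
  .check_peptide_alphabet(parent_sequence, "parent sequence")
  n <- nchar(parent_sequence)
  if (n < min_len) {
    stop("theoretical_candidates(): parent shorter than min_len", call. = FALSE)
  }
  species <- list()
  for (len in seq(min_len, min(max_len, n))) {
    for (start in 0:(n - len)) {
      subseq <- substr(parent_sequence, start + 1L, start + len)
      base_formula <- peptide_formula(subseq)
      for (mods in .legal_mod_multisets(subseq, mod_library, max_total_mods)) {
        f <- base_formula
        for (m in mods) f <- f + mod_library[[m]]$delta
        if (any(unclass(f) < 0)) next
        alt <- if ("dehydration" %in% mods) {
          paste(.dehydration_alternatives(subseq), collapse = ",")
        } else ""
        species[[length(species) + 1L]] <- list(
          start = start, end = start + len, subsequence = subseq,
          mods = paste(sort(mods), collapse = ","), n_mods = length(mods),
          formula = formula_string(f), neutral_mass = monoisotopic_mass(f),
          degenerate_with = alt)
      }
    }
  }
  sp <- data.frame(
    parent_id = parent_id,
    start = vapply(species, `[[`, numeric(1), "start"),
    end = vapply(species, `[[`, numeric(1), "end"),
    subsequence = vapply(species, `[[`, character(1), "subsequence"),
    mods = vapply(species, `[[`, character(1), "mods"),
    n_mods = vapply(species, `[[`, numeric(1), "n_mods"),
    formula = vapply(species, `[[`, character(1), "formula"),
    neutral_mass = vapply(species, `[[`, numeric(1), "neutral_mass"),
    degenerate_with = vapply(species, `[[`, character(1), "degenerate_with"),
    stringsAsFactors = FALSE)
  adducts <- adduct_table()
  out <- do.call(rbind, lapply(seq_len(nrow(adducts)), function(ai) {
    x <- sp
    x$adduct <- adducts$name[ai]
    x$charge <- adducts$charge[ai]
    x$theoretical_mz <- (sp$neutral_mass + adducts$shift[ai]) /
      adducts$charge[ai]
    x
  }))
  rownames(out) <- NULL
  out
}

#' Enumerate core-peptide candidates matching observed ions
#'
#' Matches every theoretical species of the parent (see
#' [theoretical_candidates()]) against each observed ion under every adduct
#' consistent with the ion's charge (all adducts when the charge is
#' unknown). Candidates within the ion's ppm tolerance are returned ranked
#' by absolute ppm error, ties broken by fewer modifications, then longer
#' subsequence, then lexicographically by subsequence and modification
#' string.
#'
#' @inheritParams theoretical_candidates
#' @param ions data.frame from [ion_table()] or [read_ions()].
#' @return data.frame with one row per (candidate, matched ion): the
#'   [theoretical_candidates()] columns plus `observed_mz` and `ppm`.
#' @export
enumerate_candidates <- function(parent_sequence, ions,
                                 mod_library = modification_library(),
                                 max_total_mods = 3, min_len = 2,
                                 max_len = 15, parent_id = "parent") {
  stopifnot(nrow(ions) > 0)
  theo <- theoretical_candidates(parent_sequence, mod_library,
                                 max_total_mods, min_len, max_len, parent_id)
  rows <- lapply(seq_len(nrow(ions)), function(ii) {
    t <- theo
    if (!is.na(ions$charge[ii])) {
      t <- t[t$charge == ions$charge[ii], , drop = FALSE]
    }
    ppm <- ppm_error(ions$mz[ii], t$theoretical_mz)
    hit <- abs(ppm) <= ions$tolerance_ppm[ii]
    t <- t[hit, , drop = FALSE]
    t$observed_mz <- rep(ions$mz[ii], nrow(t))
    t$ppm <- ppm[hit]
    t
  })
  out <- do.call(rbind, rows)
  ord <- order(abs(out$ppm), out$n_mods, -(out$end - out$start),
               out$subsequence, out$mods)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate shunt-product ions from a tripeptide-bearing parent
#'
#' Convenience wrapper over [enumerate_candidates()] for the short shunt
#' metabolites that accumulate when tailoring genes are disabled (e.g.
#' dehydrated or N-acetylated Leu-Ser-Ala peptides): the acetylation-enabled
#' default library, short subsequences, up to two modifications.
#'
#' @inheritParams enumerate_candidates
#' @export
annotate_shunt_products <- function(parent_sequence, ions,
                                    mod_library = modification_library(),
                                    max_total_mods = 2, min_len = 2,
                                    max_len = 8, parent_id = "parent") {
  enumerate_candidates(parent_sequence, ions, mod_library = mod_library,
                       max_total_mods = max_total_mods, min_len = min_len,
                       max_len = max_len, parent_id = parent_id)
}

#' Write a candidate report as TSV
#' @param candidates data.frame from [enumerate_candidates()].
#' @param path output file.
#' @export
write_candidate_report <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
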