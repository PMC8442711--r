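# Bait-anchored mining: locate bait CDS features, extract flanking windows,
# and call candidate short ORFs that may encode RiPP precursor peptides.

#' Find bait CDS features in a genome
#'
#' A CDS is a bait hit when it satisfies at least one criterion:
#' case-insensitive substring match of `product_keywords` against any
#' qualifier value, membership of `protein_ids` in the `protein_id` or
#' `locus_tag` qualifiers, or a match of `translation_regex` against the
#' protein sequence.
#'
#' @param genome a [genome_record()].
#' @param product_keywords character vector of keywords (e.g. `"ycaO"`).
#' @param protein_ids exact protein/locus identifiers.
#' @param translation_regex regular expression applied to the translation.
#' @return list of bait hits (class `bait_hit`) in genome order; each has
#'   `record_id`, `feature`, `matched_by`, `protein_sequence`.
#' @export
find_baits <- function(genome, product_keywords = NULL, protein_ids = NULL,
                       translation_regex = NULL) {
  if (is.null(product_keywords) && is.null(protein_ids) &&
      is.null(translation_regex)) {
    stop("find_baits(): supply at least one criterion", call. = FALSE)
  }
  hits <- list()
  for (f in genome$features) {
    if (f$kind != "CDS") next
    matched <- NULL
    if (!is.null(product_keywords)) {
      vals <- unlist(f$qualifiers, use.names = FALSE)
      if (length(vals) && any(vapply(product_keywords, function(kw) {
        any(grepl(kw, vals, ignore.case = TRUE, fixed = FALSE))
      }, logical(1)))) matched <- "product_keyword"
    }
    if (is.null(matched) && !is.null(protein_ids)) {
      ids <- c(f$qualifiers[["protein_id"]], f$qualifiers[["locus_tag"]])
      if (length(intersect(ids, protein_ids))) matched <- "id_list"
    }
    prot <- NULL
    if (is.null(matched) && !is.null(translation_regex)) {
      prot <- tryCatch(feature_translation(genome, f), error = function(e) NULL)
      if (!is.null(prot) && grepl(translation_regex, prot)) {
        matched <- "translation_regex"
      }
    }
    if (!is.null(matched)) {
      if (is.null(prot)) {
        prot <- tryCatch(feature_translation(genome, f),
                         error = function(e) NA_character_)
      }
      hits[[length(hits) + 1L]] <- structure(
        list(record_id = genome$record_id, feature = f, matched_by = matched,
             protein_sequence = prot),
        class = "bait_hit")
    }
  }
  hits
}

#' Dereplicate bait proteins by greedy identity clustering
#'
#' Greedy longest-first clustering: sequences are visited by decreasing
#' length (ties by id); a sequence joins an existing representative when its
#' pairwise global-alignment identity (see [pairwise_identity()]) reaches
#' `max_identity`, otherwise it becomes a new representative. No two
#' representatives share identity at or above the cut-off.
#'
#' @param ids,sequences parallel vectors of protein ids and sequences.
#' @param max_identity identity ceiling in (0, 1]; default 0.95.
#' @return character vector of representative ids.
#' @export
dereplicate_baits <- function(ids, sequences, max_identity = 0.95) {
  stopifnot(length(ids) == length(sequences),
            max_identity > 0, max_identity <= 1)
  if (!length(ids)) return(character(0))
  # drop exact duplicate records so duplication of input cannot change output
  keep <- !duplicated(paste(ids, sequences, sep = "\r"))
  ids <- ids[keep]; sequences <- sequences[keep]
  ord <- order(-nchar(sequences), ids)
  ids <- ids[ord]; sequences <- sequences[ord]
  reps_id <- character(0)
  reps_seq <- character(0)
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (j in seq_along(reps_seq)) {
      if (pairwise_identity(sequences[i], reps_seq[j]) >= max_identity) {
        joined <- TRUE; break
      }
    }
    if (!joined) {
      reps_id <- c(reps_id, ids[i])
      reps_seq <- c(reps_seq, sequences[i])
    }
  }
  reps_id
}

#' Extract a mining window around a bait
#'
#' The window spans `flank_nt` nucleotides on each side of the bait CDS,
#' clipped at contig edges for linear topology. On circular contigs the
#' window wraps and is represented internally as up to two linear segments,
#' reported in forward genome coordinates.
#'
#' @param genome a [genome_record()].
#' @param bait a bait hit from [find_baits()].
#' @param flank_nt flank size in nucleotides each side (default 8000).
#' @return object of class `mining_window` with fields `record_id`,
#'   `segments` (list of 0-based half-open intervals), `bait`, `flank_nt`,
#'   `genome`.
#' @export
extract_window <- function(genome, bait, flank_nt = 8000) {
  stopifnot(identical(bait$record_id, genome$record_id))
  L <- nchar(genome$sequence)
  f <- bait$feature
  flank_nt <- as.integer(flank_nt)
  lo <- f$start - flank_nt
  hi <- f$end + flank_nt
  if (genome$topology == "linear" || (hi - lo) >= L) {
    segments <- list(c(max(0L, lo), min(L, hi)))
    if ((hi - lo) >= L && genome$topology == "circular") {
      segments <- list(c(0L, L))
    }
  } else {
    segments <- list()
    if (lo < 0) {
      segments <- c(segments, list(c(L + lo, L)))  # wrapped head
      lo <- 0L
    }
    wrap_hi <- NULL
    if (hi > L) {
      wrap_hi <- c(0L, hi - L)
      hi <- L
    }
    segments <- c(segments, list(c(lo, hi)))
    if (!is.null(wrap_hi)) segments <- c(segments, list(wrap_hi))
  }
  structure(list(record_id = genome$record_id, segments = segments,
                 bait = bait, flank_nt = flank_nt, genome = genome),
            class = "mining_window")
}

#' Total nucleotide coverage of a mining window
#' @param window a `mining_window`.
#' @return integer number of covered nucleotides.
#' @export
window_coverage <- function(window) {
  sum(vapply(window$segments, function(s) s[2] - s[1], numeric(1)))
}

#' Call candidate short ORFs inside a mining window
#'
#' Scans all six frames of every window segment. An ORF is a permitted start
#' codon followed by the next in-frame stop codon within the segment, with
#' peptide length (stop excluded) in `[min_aa, max_aa]`. For nested starts
#' sharing a stop the longest ORF is reported by default
#' (`report_all = TRUE` reports every start). Codons containing ambiguous
#' bases abort translation and reject the ORF. Frame is reported relative to
#' the scanned strand of the segment (0, 1, 2).
#'
#' @param window a [extract_window()] result.
#' @param min_aa,max_aa peptide length bounds (defaults 20 and 120 — an
#'   envelope around the 31-89 aa range typical of this precursor family).
#' @param starts permitted start codons.
#' @param report_all report all nested starts instead of longest-per-stop.
#' @return data.frame of candidate ORFs: `record_id`, `start`, `end`
#'   (0-based half-open genomic, forward coordinates), `strand`, `frame`,
#'   `length_aa`, `nt_sequence`, `peptide`, `distance_to_bait_nt`,
#'   `overlaps_annotated_cds`, `annotated`.
#' @export
find_short_orfs <- function(window, min_aa = 20, max_aa = 120,
                            starts = c("ATG", "GTG", "TTG"),
                            report_all = FALSE) {
  stopifnot(min_aa >= 2, max_aa >= min_aa)
  genome <- window$genome
  rows <- list()
  for (seg in window$segments) {
    if (seg[2] - seg[1] < (min_aa + 1L) * 3L) next
    seg_seq <- substr(genome$sequence, seg[1] + 1L, seg[2])
    for (strand in c(1L, -1L)) {
      scan_seq <- if (strand == 1L) seg_seq else .revcomp(seg_seq)
      orfs <- .scan_orfs(scan_seq, min_aa, max_aa, starts, report_all)
      if (!length(orfs)) next
      s <- vapply(orfs, `[[`, integer(1), "start")
      e <- vapply(orfs, `[[`, integer(1), "end")
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = genome$record_id,
        start = if (strand == 1L) seg[1] + s else seg[2] - e,
        end = if (strand == 1L) seg[1] + e else seg[2] - s,
        strand = strand,
        frame = vapply(orfs, `[[`, integer(1), "frame"),
        length_aa = vapply(orfs, function(o) nchar(o$peptide), integer(1)),
        nt_sequence = vapply(orfs, `[[`, character(1), "nt"),
        peptide = vapply(orfs, `[[`, character(1), "peptide"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_orf_frame())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("start", "end", "strand")]), , drop = FALSE]
  bait_f <- window$bait$feature
  out$distance_to_bait_nt <- pmax(0L, pmax(bait_f$start - out$end,
                                           out$start - bait_f$end))
  cds <- Filter(function(f) f$kind == "CDS", genome$features)
  out$overlaps_annotated_cds <- vapply(seq_len(nrow(out)), function(i) {
    any(vapply(cds, function(f) {
      min(f$end, out$end[i]) > max(f$start, out$start[i])
    }, logical(1)))
  }, logical(1))
  max_nt <- (max_aa + 1L) * 3L
  out$annotated <- vapply(seq_len(nrow(out)), function(i) {
    any(vapply(cds, function(f) {
      f$start == out$start[i] && f$end == out$end[i] &&
        f$strand == out$strand[i] && (f$end - f$start) <= max_nt
    }, logical(1)))
  }, logical(1))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_orf_frame <- function() {
  data.frame(record_id = character(0), start = integer(0), end = integer(0),
             strand = integer(0), frame = integer(0), length_aa = integer(0),
             nt_sequence = character(0), peptide = character(0),
             distance_to_bait_nt = integer(0),
             overlaps_annotated_cds = logical(0), annotated = logical(0),
             stringsAsFactors = FALSE)
}

# Scan one strand of a linear sequence for ORFs. Returns a list of
# list(start, end, frame, nt, peptide) in scan coordinates (0-based
# half-open on the scanned strand).
.scan_orfs <- function(seq, min_aa, max_aa, starts, report_all) {
  n <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    codon_pos <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (!length(codon_pos)) next
    codons <- substring(seq, codon_pos, codon_pos + 2L)
    start_idx <- which(codons %in% starts)
    stop_idx <- which(codons %in% stops)
    if (!length(start_idx) || !length(stop_idx)) next
    # next stop strictly after each start
    nxt <- findInterval(start_idx, stop_idx) + 1L
    ok <- nxt <= length(stop_idx)
    start_idx <- start_idx[ok]; nxt <- nxt[ok]
    if (!length(start_idx)) next
    cand <- list()
    for (k in seq_along(start_idx)) {
      s <- codon_pos[start_idx[k]] - 1L           # 0-based
      e <- codon_pos[stop_idx[nxt[k]]] + 2L       # 0-based half-open end
      len_aa <- (e - s) %/% 3L - 1L
      if (len_aa < min_aa || len_aa > max_aa) next
      nt <- substr(seq, s + 1L, e)
      pep <- translate_orf(nt, starts = starts)
      if (is.na(pep)) next
      cand[[length(cand) + 1L]] <- list(start = s, end = e, frame = frame,
                                        nt = nt, peptide = pep,
                                        stop_id = nxt[k])
    }
    if (!report_all && length(cand)) {
      # longest eligible ORF per stop = earliest eligible start
      seen <- duplicated(vapply(cand, `[[`, integer(1), "stop_id"))
      cand <- cand[!seen]
    }
    out <- c(out, lapply(cand, function(x) x[setdiff(names(x), "stop_id")]))
  }
  out
}

#' Select precursor candidates from called ORFs
#'
#' Deterministic prioritisation feeding the networking stage: ascending
#' distance to bait, ties by ascending start coordinate, then strand (+
#' before -). Annotated and unannotated ORFs both pass by default, since
#' genuine precursor genes are frequently unannotated but occasionally
#' present in the source annotation.
#'
#' @param orfs data.frame from [find_short_orfs()].
#' @param exclude_annotated_overlaps drop ORFs overlapping annotated CDS
#'   (other than the bait; default FALSE).
#' @param max_per_window retain at most this many, nearest to bait first
#'   (default 5).
#' @return the filtered, ordered data.frame.
#' @export
select_precursor_candidates <- function(orfs, exclude_annotated_overlaps = FALSE,
                                        max_per_window = 5) {
  if (!nrow(orfs)) return(orfs)
  if (exclude_annotated_overlaps) {
    orfs <- orfs[!orfs$overlaps_annotated_cds, , drop = FALSE]
  }
  ord <- order(orfs$distance_to_bait_nt, orfs$start, -orfs$strand)
  orfs <- orfs[ord, , drop = FALSE]
  if (nrow(orfs) > max_per_window) orfs <- orfs[seq_len(max_per_window), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Mine one genome end to end
#'
#' [find_baits()] then, per bait, [extract_window()], [find_short_orfs()]
#' and [select_precursor_candidates()].
#'
#' @param genome a [genome_record()].
#' @param bait_keyword product keyword for bait detection.
#' @param flank_nt window flank per side.
#' @param min_aa,max_aa peptide length bounds.
#' @param max_per_window candidate cap per bait window.
#' @return data.frame of selected candidate ORFs across all bait windows.
#' @export
mine_genome <- function(genome, bait_keyword = "ycaO", flank_nt = 8000,
                        min_aa = 20, max_aa = 120, max_per_window = 5) {
  baits <- find_baits(genome, product_keywords = bait_keyword)
  res <- lapply(baits, function(b) {
    w <- extract_window(genome, b, flank_nt = flank_nt)
    orfs <- find_short_orfs(w, min_aa = min_aa, max_aa = max_aa)
    select_precursor_candidates(orfs, max_per_window = max_per_window)
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (!length(res)) return(.empty_orf_frame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write candidate ORFs as protein FASTA and TSV
#'
#' FASTA headers follow `record|start-end|strand|dist=<nt>`.
#'
#' @param orfs data.frame from [find_short_orfs()] or [mine_genome()].
#' @param fasta_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_candidates <- function(orfs, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    headers <- sprintf("%s|%d-%d|%s|dist=%d", orfs$record_id, orfs$start,
                       orfs$end, ifelse(orfs$strand > 0, "+", "-"),
                       orfs$distance_to_bait_nt)
    aas <- Biostrings::AAStringSet(orfs$peptide)
    names(aas) <- headers
    Biostrings::writeXStringSet(aas, fasta_path)
  }
  if (!is.null(tsv_path)) {
    cols <- c("record_id", "start", "end", "strand", "frame", "length_aa",
              "distance_to_bait_nt", "overlaps_annotated_cds", "annotated",
              "peptide")
    utils::write.table(orfs[, cols], tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(orfs)
}
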