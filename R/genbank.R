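# GenBank flat-file I/O.
#
# Internal coordinates are 0-based half-open on the forward strand; GenBank
# locations (1-based inclusive) are converted on read and write. Only simple
# `start..end` and `complement(start..end)` locations are supported — joins
# and fuzzy coordinates raise a typed parse error naming the record.

#' Construct a genome record
#'
#' @param record_id LOCUS name.
#' @param sequence DNA string over A/C/G/T/N (case-insensitive; stored
#'   upper-case).
#' @param features list of features from [annotated_feature()], kept in
#'   source order.
#' @param topology `"linear"` or `"circular"`.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(record_id, sequence, features = list(),
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0)
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome_record(): sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  for (f in features) {
    if (f$start < 0 || f$end > nchar(sequence)) {
      stop(sprintf("genome_record(): feature [%d,%d) outside sequence bounds of %s",
                   f$start, f$end, record_id), call. = FALSE)
    }
  }
  structure(list(record_id = record_id, sequence = sequence,
                 features = features, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp (%s), %d features\n",
              x$record_id, nchar(x$sequence), x$topology, length(x$features)))
  invisible(x)
}

#' Construct an annotated feature
#'
#' @param kind feature key (CDS, gene, ...).
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand +1 or -1.
#' @param qualifiers named list; each element a character vector (GenBank
#'   qualifiers may repeat).
#' @return object of class `annotated_feature`.
#' @export
annotated_feature <- function(kind, start, end, strand = 1L,
                              qualifiers = list()) {
  stopifnot(start >= 0, start < end, strand %in% c(1L, -1L))
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 strand = as.integer(strand), qualifiers = qualifiers),
            class = "annotated_feature")
}

#' Read GenBank flat files
#'
#' @param path a `.gb`/`.gbk` file, possibly multi-record.
#' @return list of [genome_record()] objects, one per LOCUS. An empty file
#'   yields an empty list with a warning. Unparseable records raise an error
#'   naming the record.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("read_genbank(): no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    warning("read_genbank(): no LOCUS entries in ", path)
    return(list())
  }
  starts <- grep("^LOCUS", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    chunk <- lines[starts[i]:ends[i]]
    records[[i]] <- .parse_genbank_record(chunk, path)
  }
  records
}

.parse_genbank_record <- function(lines, path) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- if (length(locus_fields) >= 2) locus_fields[2] else
    stop("read_genbank(): malformed LOCUS line in ", path, call. = FALSE)
  topology <- if (any(grepl("circular", lines[1]))) "circular" else "linear"

  fail <- function(msg) {
    stop(sprintf("read_genbank(): record '%s': %s", record_id, msg), call. = FALSE)
  }

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) fail("missing ORIGIN section")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) fail("empty sequence")

  features <- list()
  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at)) {
    body <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    # A new feature starts at column 6 with a non-blank key.
    is_key <- grepl("^ {5}\\S", body)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      first <- key_idx[k]
      last <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(body)
      block <- body[first:last]
      kind <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      # location may continue on lines that are not qualifiers
      j <- 2L
      while (j <= length(block) && !grepl("^\\s+/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      if (kind == "source") next  # contig-level metadata, not a feature
      parsed_loc <- .parse_location(loc)
      if (is.null(parsed_loc)) fail(sprintf("unsupported location '%s'", loc))
      quals <- .parse_qualifiers(block[seq_len(length(block)) >= j])
      features[[length(features) + 1L]] <- annotated_feature(
        kind = kind, start = parsed_loc$start, end = parsed_loc$end,
        strand = parsed_loc$strand, qualifiers = quals)
    }
  }
  genome_record(record_id, sequence, features, topology)
}

# "123..456" or "complement(123..456)" -> 0-based half-open + strand.
.parse_location <- function(loc) {
  strand <- 1L
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(.*\\)$", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc)) return(NULL)
  parts <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  list(start = parts[1] - 1L, end = parts[2], strand = strand)
}

.parse_qualifiers <- function(lines) {
  quals <- list()
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      val <- gsub("^\"|\"$", "", cur_val)
      quals[[cur_key]] <<- c(quals[[cur_key]], val)
    }
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      flush()
      eq <- regexpr("=", t, fixed = TRUE)
      if (eq > 0) {
        cur_key <- substr(t, 2L, eq - 1L)
        cur_val <- substr(t, eq + 1L, nchar(t))
      } else {
        cur_key <- substr(t, 2L, nchar(t))
        cur_val <- ""
      }
    } else if (!is.null(cur_key)) {
      # continuation: translations concatenate without space, free text with
      sep <- if (cur_key == "translation") "" else " "
      cur_val <- paste(cur_val, t, sep = sep)
    }
  }
  flush()
  quals
}

#' Translation of a CDS feature
#'
#' Returns the `/translation` qualifier when present, otherwise translates
#' the genomic slice with genetic code table 11 (strand-aware, stop removed,
#' initiator rendered as M).
#'
#' @param genome a [genome_record()].
#' @param feature an [annotated_feature()] of kind CDS.
#' @return amino-acid string.
#' @export
feature_translation <- function(genome, feature) {
  tr <- feature$qualifiers[["translation"]]
  if (!is.null(tr) && nchar(tr[1]) > 0) return(tr[1])
  nt <- substr(genome$sequence, feature$start + 1L, feature$end)
  if (feature$strand < 0) nt <- .revcomp(nt)
  pep <- translate_orf(nt)
  if (is.na(pep)) {
    stop(sprintf("feature_translation(): cannot translate CDS [%d,%d) of %s",
                 feature$start, feature$end, genome$record_id), call. = FALSE)
  }
  pep
}

.revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Bacterial/archaeal genetic code (table 11) from Biostrings, cached.
.gc11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

#' Translate an ORF nucleotide sequence (table 11)
#'
#' The first codon must be a permitted start (rendered as M); the last codon
#' must be a stop (dropped). Any codon containing an ambiguous base (N)
#' aborts translation.
#'
#' @param nt nucleotide string, length divisible by 3.
#' @param starts permitted start codons.
#' @return peptide string, or `NA_character_` if the sequence is not a valid
#'   ORF (bad start, internal stop, missing terminal stop, ambiguous base).
#' @export
translate_orf <- function(nt, starts = c("ATG", "GTG", "TTG")) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3 != 0 || n < 6) return(NA_character_)
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  if (any(grepl("N", codons, fixed = TRUE))) return(NA_character_)
  if (!codons[1] %in% starts) return(NA_character_)
  aa <- .gc11()[codons]
  if (anyNA(aa)) return(NA_character_)
  k <- length(aa)
  if (aa[k] != "*") return(NA_character_)
  if (any(aa[-k] == "*")) return(NA_character_)
  aa[1] <- "M"
  paste(aa[-k], collapse = "")
}

#' Write genome records as a GenBank flat file
#'
#' Emits the dialect [read_genbank()] parses (simple and complement
#' locations, wrapped qualifiers, 60-bp ORIGIN lines). Output is
#' byte-deterministic: no timestamps.
#'
#' @param records a [genome_record()] or list of them.
#' @param path output file.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) .write_genbank_record(rec, con)
  invisible(path)
}

.write_genbank_record <- function(rec, con) {
  n <- nchar(rec$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                     rec$record_id, n,
                     if (rec$topology == "circular") "circular" else "linear"),
             con)
  writeLines(sprintf("DEFINITION  %s synthetic sequence.", rec$record_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in rec$features) {
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", f$kind, loc), con)
    for (key in names(f$qualifiers)) {
      for (val in f$qualifiers[[key]]) {
        .write_qualifier(con, key, val)
      }
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1, n, 60)
  for (s in starts) {
    blockseq <- substr(rec$sequence, s, min(s + 59, n))
    tens <- substring(blockseq, seq(1, nchar(blockseq), 10),
                      pmin(seq(10, nchar(blockseq) + 9, 10), nchar(blockseq)))
    writeLines(sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")), con)
  }
  writeLines("//", con)
}

# Only /translation is wrapped (rejoined without spaces on read); other
# qualifier values are short and written on one line.
.write_qualifier <- function(con, key, val) {
  indent <- "                     "
  if (key == "translation") {
    text <- sprintf("/%s=\"%s\"", key, val)
    width <- 58L
    pieces <- substring(text, seq(1, nchar(text), width),
                        pmin(seq(width, nchar(text) + width - 1, width),
                             nchar(text)))
    writeLines(paste0(indent, pieces), con)
  } else {
    writeLines(sprintf("%s/%s=\"%s\"", indent, key, val), con)
  }
}
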