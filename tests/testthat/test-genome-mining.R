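# Bait detection, windows, short-ORF calling and candidate selection.

test_that("find_baits honours each criterion and genome order", {
  g <- genome_record("g1", strrep("ACGT", 300), features = list(
    annotated_feature("CDS", 0, 300, 1L,
                      qualifiers = list(product = "YcaO-like protein",
                                        translation = "MAAALVPK")),
    annotated_feature("gene", 310, 400, 1L,
                      qualifiers = list(product = "ycaO but not a CDS")),
    annotated_feature("CDS", 400, 700, -1L,
                      qualifiers = list(product = "hypothetical",
                                        protein_id = "WP_000001",
                                        translation = "MSPQRALV")),
    annotated_feature("CDS", 720, 900, 1L,
                      qualifiers = list(product = "YcaO domain protein",
                                        translation = "MKKALVHH"))))
  hits <- find_baits(g, product_keywords = "ycaO")
  expect_length(hits, 2)
  expect_identical(vapply(hits, function(h) h$feature$start, integer(1)),
                   c(0L, 720L))
  expect_identical(hits[[1]]$matched_by, "product_keyword")
  expect_length(find_baits(g, product_keywords = "thioamide"), 0)
  expect_length(find_baits(g, protein_ids = "WP_000001"), 1)
  expect_length(find_baits(g, translation_regex = "^MSPQ"), 1)
  expect_error(find_baits(g), "at least one criterion")
})

test_that("bait dereplication clusters greedily at the identity cut-off", {
  expect_identical(
    dereplicate_baits(c("a", "b"), c("MKLVHH", "MKLVHH"), 0.95), "a")
  # two sequences at exactly 90% identity (2 substitutions in 20)
  s1 <- "MKLVAAAAAAAAAAAAAAHH"
  s2 <- "MKLVAAAAAAAAAAAAAAYY"
  expect_equal(pairwise_identity(s1, s2), 0.9)
  expect_length(dereplicate_baits(c("a", "b"), c(s1, s2), 0.95), 2)
  expect_length(dereplicate_baits(c("a", "b"), c(s1, s2), 0.90), 1)
  # mutually dissimilar sequences stay distinct
  set.seed(31)
  seqs <- vapply(1:10, function(i) random_peptide(40), character(1))
  reps <- dereplicate_baits(paste0("p", 1:10), seqs, 0.95)
  expect_length(reps, 10)
  # invariant to duplication of the input records
  reps2 <- dereplicate_baits(rep(paste0("p", 1:10), 2), rep(seqs, 2), 0.95)
  expect_identical(sort(reps), sort(reps2))
  expect_length(dereplicate_baits(character(0), character(0)), 0)
})

test_that("extract_window clips at contig edges and wraps circular contigs", {
  seq <- strrep("A", 30000)
  mkgenome <- function(len, topo) {
    genome_record("g", strrep("A", len), features = list(
      annotated_feature("CDS", 1, 2, 1L, list(product = "x"))), topo)
  }
  mkbait <- function(g, s, e) {
    structure(list(record_id = g$record_id,
                   feature = annotated_feature("CDS", s, e, 1L,
                                               list(product = "ycaO")),
                   matched_by = "product_keyword", protein_sequence = "M"),
              class = "bait_hit")
  }
  g <- mkgenome(30000, "linear")
  w <- extract_window(g, mkbait(g, 10000, 11000))
  expect_identical(w$segments, list(c(2000L, 19000L)))
  w2 <- extract_window(g, mkbait(g, 1000, 2000))
  expect_identical(w2$segments, list(c(0L, 10000L)))
  gc <- mkgenome(20000, "circular")
  # wrapped coverage = bait (900) + 8000 on each side
  w3 <- extract_window(gc, mkbait(gc, 19000, 19900))
  expect_equal(window_coverage(w3), 16900)
  expect_identical(w3$segments, list(c(11000L, 20000L), c(0L, 7900L)))
  for (s in w3$segments) {
    expect_true(s[1] >= 0 && s[2] <= 20000)
  }
  # linear windows never exceed bait + 2 * flank
  expect_lte(window_coverage(w), 1000 + 2 * 8000)
})

test_that("find_short_orfs matches the brute-force oracle on random windows", {
  set.seed(101)
  for (rep in 1:12) {
    seq <- random_dna(sample(500:2000, 1), gc = sample(c(0.4, 0.6, 0.7), 1))
    w <- make_test_window(seq)
    got <- find_short_orfs(w, min_aa = 10, max_aa = 80)
    want <- oracle_orfs_longest(seq, 10, 80)
    want_keys <- sort(vapply(want, function(o) {
      sprintf("%d|%d|%d", o$start, o$end, o$strand)
    }, character(1)))
    expect_identical(orf_key(got), want_keys)
    # peptides agree with the oracle translation
    if (nrow(got)) {
      want_pep <- vapply(want, `[[`, character(1), "peptide")
      names(want_pep) <- vapply(want, function(o) {
        sprintf("%d|%d|%d", o$start, o$end, o$strand)
      }, character(1))
      got_keys <- sprintf("%d|%d|%d", got$start, got$end, got$strand)
      expect_identical(got$peptide, unname(want_pep[got_keys]))
    }
  }
})

test_that("reported ORFs re-translate exactly from genomic coordinates", {
  g <- make_genome(seed = 77, precursor_distance = 2000)
  w <- extract_window(g$genome, find_baits(g$genome, "ycaO")[[1]])
  orfs <- find_short_orfs(w)
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    nt <- substr(g$genome$sequence, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] < 0) {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    expect_identical(translate_orf(nt), orfs$peptide[i])
  }
})

test_that("nested starts report the longest ORF unless report_all is set", {
  # ATG ATG (10 codons) TAA: two starts sharing one stop
  inner <- strrep("GCT", 10)
  orf <- paste0("ATG", "ATG", inner, "TAA")
  seq <- paste0(strrep("C", 90), "TAA", orf, strrep("C", 90))
  w <- make_test_window(seq)
  deflt <- find_short_orfs(w, min_aa = 5, max_aa = 50)
  expect_equal(nrow(deflt), 1)
  expect_equal(deflt$length_aa, 12)   # MM + 10 alanines
  all_orfs <- find_short_orfs(w, min_aa = 5, max_aa = 50, report_all = TRUE)
  expect_equal(nrow(all_orfs), 2)
  expect_setequal(all_orfs$length_aa, c(12, 11))
})

test_that("length bounds include and exclude planted ORFs as configured", {
  pep130 <- paste0("M", random_peptide(129))
  g <- make_genome(seed = 13, precursor_peptide = pep130,
                   precursor_distance = 1500)
  w <- extract_window(g$genome, find_baits(g$genome, "ycaO")[[1]])
  tr <- g$truth$precursor
  o120 <- find_short_orfs(w, min_aa = 20, max_aa = 120)
  expect_equal(sum(o120$start == tr$start & o120$end == tr$end &
                     o120$strand == tr$strand), 0)
  o150 <- find_short_orfs(w, min_aa = 20, max_aa = 150)
  hit <- o150[o150$start == tr$start & o150$end == tr$end &
                o150$strand == tr$strand, ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$peptide, tr$peptide)
})

test_that("all-N windows and too-short windows yield no ORFs", {
  w <- make_test_window(strrep("N", 600))
  expect_equal(nrow(find_short_orfs(w)), 0)
  w2 <- make_test_window(strrep("ACG", 15))
  expect_equal(nrow(find_short_orfs(w2, min_aa = 20)), 0)
})

test_that("candidate selection orders by distance with stated tie-breaks", {
  orfs <- data.frame(
    record_id = "g", start = c(100L, 50L, 900L, 400L, 400L, 700L, 20L),
    end = c(200L, 150L, 1000L, 500L, 500L, 800L, 120L),
    strand = c(1L, -1L, 1L, -1L, 1L, 1L, 1L),
    frame = 0L, length_aa = 30L, nt_sequence = "x", peptide = "M",
    distance_to_bait_nt = c(10L, 40L, 40L, 25L, 25L, 90L, 120L),
    overlaps_annotated_cds = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    annotated = FALSE, stringsAsFactors = FALSE)
  sel <- select_precursor_candidates(orfs, max_per_window = 5)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$distance_to_bait_nt, c(10L, 25L, 25L, 40L, 40L))
  # equidistant pair: same start -> + strand first; different starts ->
  # lower start first
  expect_equal(sel$strand[2:3], c(1L, -1L))
  expect_equal(sel$start[4:5], c(50L, 900L))
  excl <- select_precursor_candidates(orfs, exclude_annotated_overlaps = TRUE,
                                      max_per_window = 10)
  expect_false(any(excl$overlaps_annotated_cds))
  empty <- select_precursor_candidates(orfs[0, ], max_per_window = 5)
  expect_equal(nrow(empty), 0)
})
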