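# EM motif discovery, scanning and classification.

test_that("a planted conserved motif is recovered as the consensus", {
  mp <- make_motif_peptides(n_peptides = 30, length = 60,
                            conservation = 0.9, seed = 41)
  m <- discover_motif(mp$peptides$sequence, width = 12, seed = 41)
  expect_identical(m$consensus, mp$truth$consensus)
  # PWM rows stay on the simplex
  expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-9))
  expect_true(all(m$pwm > 0))
  # the EM objective is non-decreasing across iterations
  expect_true(all(diff(m$loglik_trace) >= -1e-8))
})

test_that("motif discovery is deterministic given the seed", {
  mp <- make_motif_peptides(n_peptides = 20, length = 50, seed = 43)
  m1 <- discover_motif(mp$peptides$sequence, width = 12, seed = 7)
  m2 <- discover_motif(mp$peptides$sequence, width = 12, seed = 7)
  expect_identical(m1$pwm, m2$pwm)
  expect_identical(m1$loglik, m2$loglik)
})

test_that("planted motifs carry more information than motif-free peptides", {
  mp <- make_motif_peptides(n_peptides = 25, length = 50,
                            conservation = 0.9, seed = 47)
  planted <- discover_motif(mp$peptides$sequence, width = 10, seed = 3)
  set.seed(48)
  flat <- vapply(1:25, function(i) random_peptide(50), character(1))
  unplanted <- discover_motif(flat, width = 10, seed = 3)
  expect_gt(mean(planted$info_per_col), mean(unplanted$info_per_col))
})

test_that("scanning finds non-overlapping occurrences deterministically", {
  mp <- make_motif_peptides(n_peptides = 30, length = 60,
                            conservation = 0.9, seed = 51)
  m <- discover_motif(mp$peptides$sequence, width = 12, seed = 51)
  w <- m$width
  # consensus itself: single occurrence at offset 0
  sc <- scan_motif(m, m$consensus)
  expect_equal(sc$offset, 0)
  # consensus twice: occurrences at 0 and width
  sc2 <- scan_motif(m, strrep(m$consensus, 2))
  expect_equal(sc2$offset, c(0, w))
  # residues absent from the consensus never reach the threshold
  absent <- setdiff(c("A", "C", "D", "E", "F", "G", "W"),
                    strsplit(m$consensus, "")[[1]])[1]
  expect_equal(nrow(scan_motif(m, strrep(absent, 40))), 0)
  # occurrences never overlap and are reproducible
  for (p in mp$peptides$sequence[1:5]) {
    occ <- scan_motif(m, p)
    if (nrow(occ) > 1) expect_true(all(diff(occ$offset) >= w))
    expect_identical(occ, scan_motif(m, p))
  }
})

test_that("two-copy plants are recovered by discovery plus scanning", {
  mp <- make_motif_peptides(n_peptides = 30, length = 60,
                            conservation = 0.95, occurrences = 2, seed = 53)
  m <- discover_motif(mp$peptides$sequence, width = 12, seed = 53)
  expect_identical(m$consensus, mp$truth$consensus)
  found <- 0L; total <- 0L
  for (i in seq_len(nrow(mp$peptides))) {
    occ <- scan_motif(m, mp$peptides$sequence[i])
    truth <- mp$truth$offsets[[i]]
    total <- total + length(truth)
    found <- found + sum(truth %in% occ$offset)
  }
  expect_gte(found / total, 0.95)
})

test_that("classification assigns peptides to their family motif", {
  a <- make_motif_peptides(n_peptides = 20, length = 50, conservation = 0.9,
                           seed = 57)
  b <- make_motif_peptides(n_peptides = 20, length = 50, conservation = 0.9,
                           seed = 58)
  ma <- discover_motif(a$peptides$sequence, width = 12, seed = 5, label = "A")
  mb <- discover_motif(b$peptides$sequence, width = 12, seed = 5, label = "B")
  models <- list(A = ma, B = mb)
  cla <- classify_peptides(a$peptides$id, a$peptides$sequence, models)
  clb <- classify_peptides(b$peptides$id, b$peptides$sequence, models)
  expect_true(all(cla$label == "A"))
  expect_true(all(clb$label == "B"))
  # occurrence counts stay in the 1-3 range planted by the generator
  expect_true(all(cla$n_occurrences >= 1))
  set.seed(59)
  flat <- vapply(1:10, function(i) random_peptide(50), character(1))
  cln <- classify_peptides(paste0("r", 1:10), flat, models)
  expect_true(all(cln$label == "none"))
  expect_true(all(cln$n_occurrences == 0))
  # diagnostics retain scans for every model
  occ <- attr(cla, "occurrences")
  expect_length(occ[[cla$peptide_id[1]]], 2)
})

test_that("shared k-mer report surfaces the conserved ALV tripeptide", {
  # both family consensi contain ALV by construction
  a <- make_motif_peptides(n_peptides = 20, length = 50, seed = 61)
  b <- make_motif_peptides(n_peptides = 20, length = 50, seed = 62)
  ma <- discover_motif(a$peptides$sequence, width = 12, seed = 5, label = "A")
  mb <- discover_motif(b$peptides$sequence, width = 12, seed = 5, label = "B")
  rep <- shared_kmer_report(ma, mb, k = 3)
  expect_true("ALV" %in% rep$kmer)
  # identical consensi share L - k + 1 k-mers
  self <- shared_kmer_report(ma, ma, k = 3)
  expect_gte(nrow(self), ma$width - 3 + 1)
  expect_true(all(self$kmer %in% substring(ma$consensus, 1:(ma$width - 2),
                                           3:ma$width)))
  # disjoint consensi share nothing
  m1 <- ma; m1$consensus <- "AAAAAA"
  m2 <- mb; m2$consensus <- "GGGGGG"
  expect_equal(nrow(shared_kmer_report(m1, m2)), 0)
})

test_that("width sweep retains the most informative model", {
  mp <- make_motif_peptides(n_peptides = 20, length = 40,
                            conservation = 0.95, seed = 67)
  m <- discover_motif_sweep(mp$peptides$sequence, widths = c(8, 12, 16),
                            n_seeds = 10, seed = 3)
  expect_true(m$width %in% c(8, 12, 16))
  # the planted 12-mer consensus should appear inside the winner or contain it
  joint <- paste0(mp$truth$consensus, "|", m$consensus)
  expect_true(grepl(m$consensus, mp$truth$consensus, fixed = TRUE) ||
                grepl(mp$truth$consensus, m$consensus, fixed = TRUE) ||
                m$width == 12 && m$consensus == mp$truth$consensus)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(discover_motif(c("ALVALVAL"), width = 4), "at least 5")
  expect_error(discover_motif(rep("ALVALV", 6), width = 8),
               "width exceeds")
})

test_that("MEME minimal export round-trips the matrix dimensions", {
  mp <- make_motif_peptides(n_peptides = 10, length = 30, seed = 71)
  m <- discover_motif(mp$peptides$sequence, width = 8, n_seeds = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_meme_minimal(list(m), path)
  txt <- readLines(path)
  expect_true(any(grepl("^MOTIF A", txt)))
  expect_equal(sum(grepl("^0\\.|^1\\.", txt)), m$width)
})
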