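# Pairwise identity, threshold networks and family extraction.

test_that("alignment scores match the brute-force Gotoh oracle", {
  set.seed(11)
  for (k in 1:25) {
    a <- random_peptide(sample(3:12, 1))
    b <- random_peptide(sample(3:12, 1))
    got <- global_align(a, b)
    expect_equal(got$score, oracle_global_score(a, b), tolerance = 1e-9)
    # stripping gaps recovers the inputs; aligned strings define identity
    expect_identical(gsub("-", "", got$aligned_a), a)
    expect_identical(gsub("-", "", got$aligned_b), b)
    ca <- strsplit(got$aligned_a, "")[[1]]
    cb <- strsplit(got$aligned_b, "")[[1]]
    expect_equal(got$identity, sum(ca == cb & ca != "-") / length(ca))
    # the fast identity path agrees with the aligned-string definition
    expect_equal(pairwise_identity(a, b), got$identity, tolerance = 1e-12)
  }
})

test_that("identity has the documented values and properties", {
  p <- random_peptide(50)
  expect_equal(pairwise_identity(p, p), 1.0)
  expect_equal(pairwise_identity("ALV", "ALV"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAG"), 0.75)
  expect_equal(pairwise_identity("ALVAAAAA", "ALVGGGGG"), 0.375)
  set.seed(12)
  for (k in 1:10) {
    a <- random_peptide(sample(5:40, 1))
    b <- random_peptide(sample(5:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-12)
  }
  expect_error(pairwise_identity("ALZ", "ALV"), "illegal residue 'Z'")
})

test_that("build_network keeps edges at or above the threshold only", {
  ids <- c("p1", "p2", "p3")
  seqs <- rep(random_peptide(30), 3)
  net <- build_network(ids, seqs, 0.40)
  expect_equal(nrow(net$edges), 3)  # triangle
  expect_true(all(net$edges$id_a < net$edges$id_b))
  expect_true(all(net$edges$identity >= net$threshold))
  set.seed(13)
  distinct <- vapply(1:4, function(i) random_peptide(30), character(1))
  net2 <- build_network(paste0("q", 1:4), distinct, 1.0)
  expect_equal(nrow(net2$edges), 0)
  expect_error(build_network(c("a", "a"), c("ALV", "ALV")), "duplicate")
})

test_that("families partition nodes and are numbered by size then id", {
  ids <- c("t1", "t2", "t3", "iso")
  base <- random_peptide(30)
  seqs <- c(base, base, base, random_peptide(30))
  fam <- connected_components(build_network(ids, seqs, 0.9))
  expect_equal(fam$size, c(3, 1))
  expect_identical(family_members(fam)[["1"]], c("t1", "t2", "t3"))
  expect_identical(family_members(fam)[["2"]], "iso")
  # partition: every node exactly once
  all_members <- unlist(family_members(fam))
  expect_setequal(all_members, ids)
  expect_equal(length(all_members), length(ids))
  empty <- connected_components(build_network(character(0), character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("planted families are recovered as exactly five components", {
  fam <- make_peptide_families(n_families = 5, peptides_per_family = 8,
                               seed = 19)
  net <- build_network(fam$peptides$id, fam$peptides$sequence, 0.40)
  comp <- connected_components(net)
  expect_equal(nrow(comp), 5)
  mem <- family_members(comp)
  for (m in mem) {
    planted <- fam$peptides$family[match(m, fam$peptides$id)]
    expect_length(unique(planted), 1)
  }
})

test_that("raising the threshold refines components (monotonicity)", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    ids <- paste0("n", seq_len(n))
    # random symmetric identity matrix, no alignments needed
    idm <- matrix(stats::runif(n * n), n)
    idm <- (idm + t(idm)) / 2
    mk <- function(thr) {
      edges <- which(upper.tri(idm) & idm >= thr, arr.ind = TRUE)
      structure(list(
        nodes = data.frame(id = ids, sequence = "", stringsAsFactors = FALSE),
        edges = data.frame(id_a = ids[edges[, 1]], id_b = ids[edges[, 2]],
                           identity = idm[edges], stringsAsFactors = FALSE),
        threshold = thr), class = "peptide_network")
    }
    lo <- connected_components(mk(0.3))
    hi <- connected_components(mk(0.7))
    # each high-threshold component lies inside one low-threshold component
    lo_of <- rep(lo$family_id, lo$size)
    names(lo_of) <- unlist(family_members(lo))
    for (m in family_members(hi)) {
      expect_length(unique(lo_of[m]), 1)
    }
    expect_gte(nrow(hi), nrow(lo))
  }
})

test_that("subfamily_split separates planted sub-clusters at 80%", {
  scf <- make_subclustered_family(n_sub = 2, members_per_sub = 8, seed = 29)
  sf <- subfamily_split(scf$peptides$id, scf$peptides$sequence, 0.80)
  expect_equal(nrow(sf), 2)
  for (m in family_members(sf)) {
    sub <- scf$peptides$subcluster[match(m, scf$peptides$id)]
    expect_length(unique(sub), 1)
  }
  # at the within-identity threshold the family holds together
  one <- subfamily_split(scf$peptides$id, scf$peptides$sequence, 0.40)
  expect_equal(nrow(one), 1)
  # singleton family
  s <- subfamily_split("solo", random_peptide(40), 0.80)
  expect_equal(s$size, 1)
})

test_that("network exports are loadable and faithful", {
  fam <- make_peptide_families(n_families = 2, peptides_per_family = 4,
                               seed = 33)
  net <- build_network(fam$peptides$id, fam$peptides$sequence, 0.40)
  gml <- withr::local_tempfile(fileext = ".graphml")
  edg <- withr::local_tempfile(fileext = ".tsv")
  famtsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, edg, famtsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  edges_back <- utils::read.table(edg, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  expect_equal(nrow(edges_back), nrow(net$edges))
})
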