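# Identity-based peptide networking: pairwise global alignment, threshold
# graphs, and connected-component families.
#
# Identity is defined as (identical aligned columns) / (alignment length
# including gap columns) of the optimal end-to-end affine-gap alignment —
# the strictest common convention. The 40/80/95% thresholds used downstream
# are sensitive to this definition, so it is centralised here and used by
# both the networking and the bait-dereplication code paths.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.check_peptide_alphabet <- function(seq, what = "sequence") {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% .AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d of %s",
                 aa[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(TRUE)
}

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Optimal global alignment of two peptides
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gaps, BLOSUM62
#' scoring by default.
#'
#' @param a,b amino-acid strings (20 canonical residues plus X).
#' @param substitution_matrix scoring matrix name or matrix.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return list with `score`, `aligned_a`, `aligned_b`, `identity`.
#' @examples
#' global_align("ALVAAAAA", "ALVGGGGG")$identity  # 0.375
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  .check_peptide_alphabet(a, "first sequence")
  .check_peptide_alphabet(b, "second sequence")
  if (identical(substitution_matrix, "BLOSUM62")) {
    substitution_matrix <- .blosum62()
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  list(score = Biostrings::score(aln), aligned_a = pa, aligned_b = pb,
       identity = .aligned_identity(pa, pb))
}

.aligned_identity <- function(pa, pb) {
  ca <- strsplit(pa, "", fixed = TRUE)[[1]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb & ca != "-") / length(ca)
}

# Identity from a PairwiseAlignments object without materialising aligned
# strings: alignment length (end gaps included) is
# len_a + len_b - aligned residue pairs.
.alignment_identity <- function(aln, len_a, len_b) {
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  Biostrings::nmatch(aln) / (len_a + len_b - pairs)
}

#' Pairwise global-alignment identity
#'
#' Identical columns of the optimal global alignment divided by the full
#' alignment length (gap columns, terminal ones included, count in the
#' denominator).
#'
#' @inheritParams global_align
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  .check_peptide_alphabet(a, "first sequence")
  .check_peptide_alphabet(b, "second sequence")
  if (identical(substitution_matrix, "BLOSUM62")) {
    substitution_matrix <- .blosum62()
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  .alignment_identity(aln, nchar(a), nchar(b))
}

#' Build an identity-threshold peptide network
#'
#' Evaluates every unordered pair and keeps an edge when the pairwise
#' identity reaches `min_identity`. Edges are stored once with `id_a < id_b`.
#'
#' @param ids unique peptide ids.
#' @param sequences amino-acid strings, parallel to `ids`.
#' @param min_identity edge threshold (default 0.40).
#' @return object of class `peptide_network`: `nodes` (data.frame id,
#'   sequence), `edges` (data.frame id_a, id_b, identity), `threshold`.
#' @export
build_network <- function(ids, sequences, min_identity = 0.40) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) {
    stop("build_network(): duplicate peptide ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequences)) .check_peptide_alphabet(sequences[i], ids[i])
  n <- length(ids)
  edges <- list()
  if (n >= 2) {
    subs <- .blosum62()
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(sequences[js]),
        Biostrings::AAString(sequences[i]),
        substitutionMatrix = subs, gapOpening = 10, gapExtension = 0.5,
        type = "global")
      idents <- .alignment_identity(aln, nchar(sequences[js]),
                                    nchar(sequences[i]))
      hit <- which(idents >= min_identity)
      if (length(hit)) {
        other <- ids[js[hit]]
        edges[[length(edges) + 1L]] <- data.frame(
          id_a = pmin(ids[i], other), id_b = pmax(ids[i], other),
          identity = idents[hit], stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id_a = character(0), id_b = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(id = ids, sequence = sequences,
                                    stringsAsFactors = FALSE),
                 edges = edges, threshold = min_identity),
            class = "peptide_network")
}

#' @export
print.peptide_network <- function(x, ...) {
  cat(sprintf("<peptide_network> %d nodes, %d edges (identity >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

.as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(network$nodes), name = network$nodes$id)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(network$edges$id_a, network$edges$id_b),
                           weight = network$edges$identity)
  }
  g
}

#' Peptide families as connected components
#'
#' Undirected connected components of the identity network. Families are
#' numbered by descending size, ties by the lexicographically smallest
#' member id, so output is deterministic.
#'
#' @param network a [build_network()] result.
#' @return data.frame with columns `family_id`, `size`, `member_ids`
#'   (comma-joined sorted ids); and attribute-free list column free shape —
#'   use [family_members()] to get a plain list.
#' @export
connected_components <- function(network) {
  if (!nrow(network$nodes)) {
    return(data.frame(family_id = integer(0), size = integer(0),
                      member_ids = character(0), stringsAsFactors = FALSE))
  }
  g <- .as_igraph(network)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, `[`, character(1), 1))
  members <- members[ord]
  data.frame(
    family_id = seq_along(members),
    size = vapply(members, length, integer(1)),
    member_ids = vapply(members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Member ids of each family as a list
#' @param families data.frame from [connected_components()].
#' @return named list of character vectors, names = family ids.
#' @export
family_members <- function(families) {
  out <- strsplit(families$member_ids, ",", fixed = TRUE)
  names(out) <- families$family_id
  out
}

#' Split a family into sub-families at a stricter threshold
#'
#' Rebuilds the identity network over the family members at `min_identity`
#' (default 0.80) and returns its connected components.
#'
#' @param ids,sequences the family's peptides.
#' @param min_identity sub-family threshold.
#' @return data.frame as in [connected_components()].
#' @export
subfamily_split <- function(ids, sequences, min_identity = 0.80) {
  connected_components(build_network(ids, sequences, min_identity))
}

#' Export a network as GraphML and a TSV edge list
#'
#' Both formats load directly into Cytoscape; the families TSV carries the
#' component assignment.
#'
#' @param network a [build_network()] result.
#' @param graphml_path,edges_path,families_path output files (NULL skips).
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL,
                          families_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(.as_igraph(network), graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(families_path)) {
    fam <- connected_components(network)
    utils::write.table(fam, families_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(network)
}
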