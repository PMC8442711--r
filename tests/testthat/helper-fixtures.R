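# Shared fixture builders (all generated in code at test time).

# Wrap a raw nucleotide sequence in a mining window covering all of it,
# anchored on a tiny bait CDS at the left edge.
make_test_window <- function(seq) {
  g <- genome_record("testwin", seq, features = list(
    annotated_feature("CDS", 0, 3, 1L, qualifiers = list(product = "bait"))))
  b <- find_baits(g, product_keywords = "bait")
  extract_window(g, b[[1]], flank_nt = nchar(seq))
}

# A deterministic AmiA-like precursor: leader + HLSATH core + follower.
# The follower deliberately avoids tripeptides isobaric with the dehydrated
# cores (e.g. RAY == HLSA - H2O).
amia_like_parent <- function() {
  paste0("MTQETAAELLDAAELAELSEADGG", "HLSATH", "GGSDAEAVESFWDGELAED")
}
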