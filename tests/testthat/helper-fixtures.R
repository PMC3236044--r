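# Small hand-built records used across tests; the larger fixtures come
# from the seeded generator.

aa20 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

# a tiny replicon with one forward CDS encoding "MK" at positions 10..18
# (0-based half-open 9..18): ATG AAA TAA
tiny_replicon <- function(extra_features = list(), topology = "linear") {
  seqs <- paste0(strrep("C", 9), "ATGAAATAA", strrep("C", 12))
  cds <- gb_feature("CDS", gb_location(c(9, 18)),
                    list(locus_tag = "TST_0001", product = "demo protein"))
  gene <- gb_feature("gene", gb_location(c(9, 18)),
                     list(locus_tag = "TST_0001"))
  gb_replicon("chr1", seqs, topology = topology,
              features = c(list(gene, cds), extra_features))
}

tiny_record <- function(extra_features = list(), ...) {
  genome_record("Testus minimus", list(tiny_replicon(extra_features)),
                bioproject = "PRJNA999999",
                structured_comment = c("Annotation Provider" = "test"),
                ...)
}

# record with a chosen set of tRNA products / rRNA products
rna_record <- function(trna_products = character(0),
                       rrna_products = character(0),
                       trna_pseudo = logical(length(trna_products)),
                       rrna_pseudo = logical(length(rrna_products))) {
  feats <- list()
  pos <- 100
  for (i in seq_along(trna_products)) {
    q <- list(product = trna_products[i], locus_tag = sprintf("TST_%04d", 100 + i))
    if (trna_pseudo[i]) q$pseudo <- NA
    feats[[length(feats) + 1L]] <- gb_feature(
      "tRNA", gb_location(c(pos, pos + 75)), q)
    pos <- pos + 100
  }
  for (i in seq_along(rrna_products)) {
    q <- list(product = rrna_products[i], locus_tag = sprintf("TST_%04d", 200 + i))
    if (rrna_pseudo[i]) q$pseudo <- NA
    feats[[length(feats) + 1L]] <- gb_feature(
      "rRNA", gb_location(c(pos, pos + 120)), q)
    pos <- pos + 200
  }
  genome_record("Testus minimus",
                list(gb_replicon("chr1", strrep("ACGT", 2000),
                                 features = feats)),
                bioproject = "PRJNA999999",
                structured_comment = c(k = "v"))
}

# brute-force per-base extraction oracle (independent of extract_feature_seq)
oracle_extract <- function(sequence, segments, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(sequence, "")[[1]]
  picked <- character(0)
  for (i in seq_len(nrow(segments))) {
    picked <- c(picked, chars[(segments[i, 1] + 1):segments[i, 2]])
  }
  if (strand == "-") picked <- rev(unname(comp[picked]))
  paste(picked, collapse = "")
}

expect_metrics_equal_truth <- function(m, t) {
  for (f in c("replicon_count", "protein_count", "rna_count",
              "trna_aa_count", "hypothetical_count", "min_protein_len_aa")) {
    expect_identical(as.integer(m[[f]]), as.integer(t[[f]]), label = f)
  }
  for (f in c("total_length_mbp", "gc_percent", "coding_density",
              "avg_protein_len_aa", "short_protein_percent",
              "standard_start_percent", "hypothetical_ratio")) {
    if (is.na(t[[f]])) expect_true(is.na(m[[f]]), label = f)
    else expect_equal(m[[f]], t[[f]], tolerance = 1e-9, label = f)
  }
  expect_setequal(m$trna_aa_set, t$trna_aa_set)
}
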