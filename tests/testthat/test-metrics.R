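# Annotation-report measures.

test_that("coding density reproduces the published report arithmetic", {
  # protein counts / genome kbp from the published example report rows
  expect_equal(as.numeric(coding_density(4144, 4640)), 0.89)
  expect_equal(as.numeric(coding_density(1604, 3268)), 0.49)
  expect_equal(as.numeric(coding_density(0, 1000)), 0)
  expect_error(coding_density(10, 0), "positive")
  # identity: raw density * kbp = count exactly
  d <- coding_density(4144, 4640)
  expect_equal(attr(d, "raw") * 4640, 4144, tolerance = 1e-12)
})

test_that("every published density value is recovered from counts and lengths", {
  tab <- annotation_report_examples()
  recomputed <- vapply(seq_len(nrow(tab)), function(i) {
    as.numeric(coding_density(tab$protein_count[i],
                              tab$total_length_mbp[i] * 1000))
  }, 0)
  # lengths are printed to 3 decimals (Mbp), so the recomputed density can
  # differ by one unit in the last printed digit for very small genomes
  expect_true(all(abs(recomputed - tab$coding_density) <= 0.01 + 1e-12))
  exact <- tab$total_length_mbp > 0.5
  expect_equal(recomputed[exact], tab$coding_density[exact])
})

test_that("GC percent pools replicons and excludes ambiguity codes", {
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent(c("AT", "GC")), 50)
  expect_equal(gc_percent("GCNNNN"), 100)   # N excluded from both sides
  expect_error(gc_percent("NNN"), "zero unambiguous")
  set.seed(3)
  sq <- paste(sample(c("A", "C", "G", "T", "N"), 5000, TRUE), collapse = "")
  chars <- strsplit(sq, "")[[1]]
  oracle <- 100 * sum(chars %in% c("G", "C")) /
    sum(chars %in% c("A", "C", "G", "T"))
  expect_equal(gc_percent(sq), oracle, tolerance = 1e-12)
})

test_that("protein stats use /translation length, else span arithmetic", {
  # lengths {100, 200} at threshold 150 -> short 50%, avg 150
  r <- gb_replicon("c", strrep("A", 2000), features = list(
    gb_feature("CDS", gb_location(c(0, 303)),
               list(translation = strrep("K", 100))),
    gb_feature("CDS", gb_location(c(400, 1003)),
               list(translation = strrep("K", 200)))))
  rec <- genome_record("t", list(r))
  ps <- protein_stats(rec, 150L)
  expect_equal(ps$short_percent, 50)
  expect_equal(ps$avg_len, 150)
  # span 303 nt, complete, no /translation -> 100 aa
  r2 <- gb_replicon("c", strrep("A", 400), features = list(
    gb_feature("CDS", gb_location(c(0, 303)), list())))
  expect_equal(protein_stats(genome_record("t", list(r2)))$lengths, 100L)
  # 3'-partial: stop not annotated, no -1
  r3 <- gb_replicon("c", strrep("A", 400), features = list(
    gb_feature("CDS", gb_location(c(0, 300), partial3 = TRUE), list())))
  expect_equal(protein_stats(genome_record("t", list(r3)))$lengths, 100L)
  # no proteins: absent stats + WARN finding, not an error
  ps0 <- protein_stats(genome_record("t", list(gb_replicon("c", "ACGT"))))
  expect_equal(ps0$count, 0L)
  expect_true(is.na(ps0$avg_len))
  expect_equal(ps0$findings$rule_id, "METRIC003")
})

test_that("short-protein percentage is monotone in the threshold", {
  rec <- generate_genome(genome_spec(seed = 12, n_proteins = 20))$record
  expect_equal(protein_stats(rec, 0L)$short_percent, 0)
  expect_equal(protein_stats(rec, 100000L)$short_percent, 100)
  th <- c(50, 150, 300, 500)
  vals <- vapply(th, function(t) protein_stats(rec, t)$short_percent, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("tRNA amino-acid sets count functional tRNAs only", {
  r <- rna_record(c("tRNA-Ala", "tRNA-Gly", "tRNA-Ala"))
  aa <- amino_acids_with_trna(r)
  expect_equal(aa$count, 2)
  expect_setequal(aa$set, c("Ala", "Gly"))
  # full standard complement
  full <- rna_record(paste0("tRNA-", aa20))
  expect_equal(amino_acids_with_trna(full)$count, 20)
  # Sec adds to the count; pseudo-tRNAs excluded from the functional set
  r2 <- rna_record(c(paste0("tRNA-", aa20), "tRNA-Sec", "tRNA-Trp"),
                   trna_pseudo = c(rep(FALSE, 21), TRUE))
  aa2 <- amino_acids_with_trna(r2)
  expect_equal(aa2$count, 21)
  expect_equal(aa2$pseudo_count, 1)
  # unparseable product -> OTHER + WARN
  r3 <- rna_record("transfer RNA for alanine")
  aa3 <- amino_acids_with_trna(r3)
  expect_true("OTHER" %in% aa3$set)
  expect_true("METRIC002" %in% aa3$findings$rule_id)
})

test_that("hypothetical counting normalizes names and flags missing products", {
  r <- gb_replicon("c", strrep("A", 1000), features = list(
    gb_feature("CDS", gb_location(c(0, 30)),
               list(product = "hypothetical protein")),
    gb_feature("CDS", gb_location(c(50, 80)),
               list(product = "DNA gyrase subunit A")),
    gb_feature("CDS", gb_location(c(100, 130)),
               list(product = "  Hypothetical  Protein ")),
    gb_feature("CDS", gb_location(c(200, 230)), list())))
  rec <- genome_record("t", list(r))
  h <- hypothetical_count(rec)
  expect_equal(as.integer(h), 3L)   # normalized variant + missing product
  expect_true("METRIC001" %in% attr(h, "findings")$rule_id)
})

test_that("standard-start percentage is strand-aware and skips 5'-partials", {
  # ATG, GTG, ATG -> 66.67 (one on the minus strand)
  sq <- paste0("ATGAAATAA", "CC", "GTGAAATAA", "CC",
               revcomp <- as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGCCCTAA"))), "CC")
  r <- gb_replicon("c", sq, features = list(
    gb_feature("CDS", gb_location(c(0, 9)), list(product = "a")),
    gb_feature("CDS", gb_location(c(11, 20)), list(product = "b")),
    gb_feature("CDS", gb_location(c(22, 31), strand = "-"),
               list(product = "c")),
    gb_feature("CDS", gb_location(c(11, 20), partial5 = TRUE),
               list(product = "excluded"))))
  rec <- genome_record("t", list(r))
  expect_equal(round(standard_start_percent(rec), 2), 66.67)
  # all-ATG genome reaches the attainable maximum of 100
  rec2 <- generate_genome(genome_spec(seed = 2, n_proteins = 10,
                                      standard_start_fraction = 1))$record
  expect_equal(standard_start_percent(rec2), 100)
})

test_that("compute_metrics matches generator truth and handles empties", {
  g <- generate_genome(genome_spec(seed = 31))
  expect_metrics_equal_truth(compute_metrics(g$record), g$truth$metrics)
  # empty annotation: zero counts, absent stats, WARN findings
  empty <- genome_record("e", list(gb_replicon("r", strrep("ACGT", 100))))
  m <- compute_metrics(empty)
  expect_equal(m$protein_count, 0L)
  expect_equal(m$rna_count, 0L)
  expect_true(is.na(m$avg_protein_len_aa))
  expect_true("METRIC003" %in% attr(m, "findings")$rule_id)
  # two replicons: pooled length
  two <- genome_record("t", list(gb_replicon("a", strrep("ACGT", 250)),
                                 gb_replicon("b", strrep("ACGT", 250))))
  m2 <- compute_metrics(two)
  expect_equal(m2$replicon_count, 2L)
  expect_equal(m2$total_length_mbp, 2000 / 1e6)
})

test_that("hypothetical ratio stays within [0,1] and all-hypothetical hits 1", {
  g <- generate_genome(genome_spec(seed = 8, n_proteins = 15,
                                   hypothetical_fraction = 1))
  m <- compute_metrics(g$record)
  expect_equal(m$hypothetical_count, 15L)
  expect_equal(m$hypothetical_ratio, 1)
  for (s in 1:5) {
    mm <- compute_metrics(generate_genome(genome_spec(
      seed = s, hypothetical_fraction = runif(1)))$record)
    expect_gte(mm$hypothetical_ratio, 0)
    expect_lte(mm$hypothetical_ratio, 1)
  }
})

test_that("report rounding is half-away-from-zero at 2 decimals", {
  expect_equal(as.numeric(coding_density(182, 160)), 1.14)   # 1.1375
  expect_equal(as.numeric(coding_density(2662, 2232)), 1.19)
  expect_equal(as.numeric(coding_density(4177, 4216)), 0.99)
  m <- compute_metrics(generate_genome(genome_spec(seed = 1))$record)
  f <- format_metrics(m)
  expect_match(f[["coding_density"]], "^[0-9]+\\.[0-9]{2}$")
  expect_match(f[["avg_protein_len_aa"]], "^[0-9]+$")
})
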