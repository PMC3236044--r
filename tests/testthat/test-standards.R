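# Minimal annotation standards and the compliance report.

test_that("rRNA set check distinguishes present, pseudo-only and missing", {
  full <- rna_record(rrna_products = c("5S ribosomal RNA",
                                       "16S ribosomal RNA",
                                       "23S ribosomal RNA"))
  expect_equal(check_rrna_set(full)$status, "PASS")
  part <- rna_record(rrna_products = c("16S ribosomal RNA",
                                       "23S ribosomal RNA"))
  chk <- check_rrna_set(part)
  expect_equal(chk$status, "FAIL")
  expect_equal(chk$missing_items, "5S")
  ps <- rna_record(rrna_products = c("5S ribosomal RNA",
                                     "16S ribosomal RNA",
                                     "23S ribosomal RNA"),
                   rrna_pseudo = c(FALSE, FALSE, TRUE))
  expect_equal(check_rrna_set(ps)$status, "WARN")
  # subunit synonyms classify too; unclassifiable products count as none
  syn <- rna_record(rrna_products = c("5S ribosomal RNA",
                                      "small subunit ribosomal RNA",
                                      "large subunit ribosomal RNA"))
  expect_equal(check_rrna_set(syn)$status, "PASS")
  odd <- rna_record(rrna_products = "ribosomal something")
  chk2 <- check_rrna_set(odd)
  expect_equal(chk2$status, "FAIL")
  expect_true("RRNA001" %in% attr(chk2, "findings")$rule_id)
})

test_that("tRNA coverage check wants all 20 standard amino acids", {
  expect_equal(check_trna_set(rna_record(paste0("tRNA-", aa20)))$status,
               "PASS")
  few <- rna_record(paste0("tRNA-", setdiff(aa20, "Trp")))
  chk <- check_trna_set(few)
  expect_equal(chk$status, "FAIL")
  expect_equal(chk$missing_items, "Trp")
  # pseudo-tRNA covering the missing amino acid downgrades to WARN
  ps <- rna_record(paste0("tRNA-", aa20),
                   trna_pseudo = c(rep(FALSE, 19), TRUE))
  expect_equal(check_trna_set(ps)$status, "WARN")
})

test_that("core-function check finds, warns on pseudo-only, fails on absent", {
  catalog <- load_core_catalog()
  expect_equal(nrow(catalog), 12)
  rec <- gold_standard()
  chk <- check_core_functions(rec, catalog)
  expect_equal(chk$status, "PASS")
  # remove the elongation-factor-P product
  r <- rec$replicons[[1]]
  feats <- lapply(r$features, function(f) {
    if (identical(qual_value(f, "product"), "elongation factor P")) {
      f$qualifiers[["product"]] <- "ordinary enzyme"
    }
    f
  })
  rec2 <- genome_record(rec$organism,
                        list(gb_replicon(r$name, r$sequence, r$topology, feats)),
                        bioproject = rec$bioproject,
                        structured_comment = rec$structured_comment)
  chk2 <- check_core_functions(rec2, catalog)
  expect_equal(chk2$status, "FAIL")
  expect_true("efp" %in% chk2$missing_items)
  # the same function present only as pseudogene -> WARN
  feats3 <- lapply(r$features, function(f) {
    if (identical(qual_value(f, "product"), "elongation factor P")) {
      f$qualifiers[["pseudo"]] <- NA_character_
    }
    f
  })
  rec3 <- genome_record(rec$organism,
                        list(gb_replicon(r$name, r$sequence, r$topology, feats3)),
                        bioproject = rec$bioproject,
                        structured_comment = rec$structured_comment)
  chk3 <- check_core_functions(rec3, catalog)
  expect_equal(chk3$status, "WARN")
  expect_true("efp" %in% chk3$missing_items)
})

test_that("the shipped catalog records the historical additions per function", {
  catalog <- load_core_catalog()
  expect_equal(sum(catalog$additions), 42)
  ext <- load_core_catalog(extended = TRUE)
  expect_gt(nrow(ext), 12)
  expect_equal(sum(ext$additions, na.rm = TRUE), 42)
})

test_that("density and hypothetical-ratio checks use the configured bands", {
  cfg <- qc_config()
  mk <- function(density, ratio, n = 1000L) {
    structure(list(coding_density = density, protein_count = n,
                   hypothetical_ratio = ratio), class = "metrics_row")
  }
  both <- check_density_and_names(mk(0.89, 21 / 4144), cfg)
  expect_equal(both[[1]]$status, "PASS")
  expect_equal(both[[2]]$status, "PASS")
  expect_equal(check_density_and_names(mk(0.30, 0.1), cfg)[[1]]$status,
               "WARN")
  expect_equal(check_density_and_names(mk(0.9, 1.0), cfg)[[2]]$status,
               "FAIL")
  expect_equal(check_density_and_names(mk(0.9, 0.85), cfg)[[2]]$status,
               "WARN")
})

test_that("evaluate aggregates checks, findings and exemptions", {
  rep <- evaluate(gold_standard())
  expect_equal(rep$overall, "COMPLIANT")
  expect_true(all(vapply(rep$checks, `[[`, "", "status") == "PASS"))

  norr <- generate_genome(gold_spec(42, rrna_subset = character(0)))$record
  rep2 <- evaluate(norr)
  expect_equal(rep2$overall, "NONCOMPLIANT")
  expect_equal(rep2$checks$RRNA_SET$status, "FAIL")

  endo <- generate_genome(gold_spec(
    7, trna_aa_subset = setdiff(aa20, c("Trp", "His")),
    exemption_notes = c(TRNA_SET = "codon recoding in a reduced endosymbiont genome")))$record
  rep3 <- evaluate(endo)
  expect_equal(rep3$checks$TRNA_SET$status, "EXEMPT")
  expect_equal(rep3$overall, "COMPLIANT_WITH_EXEMPTIONS")
})

test_that("evaluate is pure and idempotent", {
  rec <- case_fixture("PSEUDO002")
  r1 <- evaluate(rec)
  r2 <- evaluate(rec)
  expect_identical(
    lapply(r1$checks, function(c) c[c("check_id", "status")]),
    lapply(r2$checks, function(c) c[c("check_id", "status")]))
  expect_identical(as.data.frame(r1$findings), as.data.frame(r2$findings))
  expect_identical(r1$overall, r2$overall)
})

test_that("adding features never breaks a coverage-based PASS", {
  base <- gold_standard()
  rep0 <- evaluate(base)
  coverage_checks <- c("RRNA_SET", "TRNA_SET", "CORE_FUNCS")
  r <- base$replicons[[1]]
  extra <- list(
    gb_feature("gene", gb_location(c(2, 40)), list(locus_tag = "SYN_8001")),
    gb_feature("tRNA", gb_location(c(2, 40)),
               list(locus_tag = "SYN_8001", product = "tRNA-Sec")),
    gb_feature("rRNA", gb_location(c(50, 95)),
               list(locus_tag = "SYN_8002", product = "5S ribosomal RNA")),
    gb_feature("gene", gb_location(c(50, 95)), list(locus_tag = "SYN_8002")))
  grown <- genome_record(base$organism,
                         list(gb_replicon(r$name, r$sequence, r$topology,
                                          c(r$features, extra))),
                         bioproject = base$bioproject,
                         structured_comment = base$structured_comment)
  rep1 <- evaluate(grown)
  for (id in coverage_checks) {
    if (rep0$checks[[id]]$status == "PASS") {
      expect_equal(rep1$checks[[id]]$status, "PASS", label = id)
    }
  }
})

test_that("every check has PASS, FAIL and (where defined) EXEMPT fixtures", {
  statuses <- function(rec) {
    vapply(evaluate(rec)$checks, `[[`, "", "status")
  }
  gold <- statuses(gold_standard())
  expect_true(all(gold == "PASS"))
  fails <- list(
    RRNA_SET = generate_genome(gold_spec(1, rrna_subset = "5S"))$record,
    TRNA_SET = generate_genome(gold_spec(1, trna_aa_subset = "Ala"))$record,
    CORE_FUNCS = generate_genome(genome_spec(seed = 1, include_core = FALSE))$record,
    HYPOTHETICAL_RATIO = generate_genome(genome_spec(
      seed = 1, hypothetical_fraction = 1))$record,
    LOCUS_TAGS = case_fixture("LT001"),
    PSEUDO_FORMAT = case_fixture("PSEUDO003"),
    VALIDATION_CLEAN = case_fixture("STRUCT002"))
  for (id in names(fails)) {
    expect_equal(statuses(fails[[id]])[[id]], "FAIL", label = id)
  }
  exempt <- generate_genome(gold_spec(
    1, rrna_subset = c("16S", "23S"),
    exemption_notes = c(RRNA_SET = "5S unresolvable in assembly")))$record
  expect_equal(statuses(exempt)[["RRNA_SET"]], "EXEMPT")
})
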