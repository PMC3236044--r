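# Lint rules: naming, structured evidence, pseudogenes, locus_tags,
# structure; plus the rule-engine invariants.

test_that("only the two accepted unknown-function names pass the naming rule", {
  f <- lint_protein_name("conserved hypothetical protein")
  expect_equal(f$rule_id, "NAME001")
  expect_equal(f$severity, "FAIL")
  expect_equal(f$suggestion, "hypothetical protein")
  expect_equal(nrow(lint_protein_name("hypothetical protein")), 0)
  expect_equal(nrow(lint_protein_name("uncharacterized protein")), 0)
  expect_equal(nrow(lint_protein_name("DNA gyrase subunit A")), 0)
  for (bad in c("novel protein", "protein of unknown function", "unknown")) {
    expect_true("NAME001" %in% lint_protein_name(bad)$rule_id, label = bad)
  }
})

test_that("style naming checks are off by default and on by configuration", {
  style <- naming_rules(style = TRUE)
  expect_equal(nrow(lint_protein_name("  spaced  name ")), 0)
  expect_true("NAME002" %in% lint_protein_name("  spaced  name ", style)$rule_id)
  expect_true("NAME003" %in% lint_protein_name("UPPERCASE PROTEIN", style)$rule_id)
  expect_true("NAME003" %in% lint_protein_name(
    "oxidase of Testus minimus", style, organism = "Testus minimus")$rule_id)
  expect_true("NAME004" %in% lint_protein_name("gyrase homolog", style)$rule_id)
  expect_true("NAME005" %in% lint_protein_name("ABC_0001", style)$rule_id)
  expect_true("NAME005" %in% lint_protein_name("ORF123", style)$rule_id)
  expect_equal(nrow(lint_protein_name("DNA gyrase subunit A", style)), 0)
})

test_that("inference parsing follows the structured-evidence grammar", {
  ev <- parse_inference("COORDINATES: similar to AA sequence:INSD:AAD51968.1")
  expect_equal(ev$category, "COORDINATES")
  expect_equal(ev$type, "similar to AA sequence")
  expect_equal(ev$basis, list(c(source = "INSD", version = "AAD51968.1")))
  expect_equal(nrow(ev$findings), 0)

  ev2 <- parse_inference("ab initio prediction:Genscan:2.0")
  expect_true(is.na(ev2$category))
  expect_equal(ev2$type, "ab initio prediction")
  expect_equal(ev2$basis, list(c(source = "Genscan", version = "2.0")))

  bad <- parse_inference("EXISTENCE: banana")
  expect_true("EV001" %in% bad$findings$rule_id)
  nobasis <- parse_inference("profile")
  expect_true("EV002" %in% nobasis$findings$rule_id)
  samesp <- parse_inference("similar to DNA sequence (same species):INSD:X1.1")
  expect_true(samesp$same_species)
})

test_that("render/parse of evidence qualifiers is a two-sided identity", {
  cases <- c("COORDINATES: similar to AA sequence:INSD:AAD51968.1",
             "ab initio prediction:Genscan:2.0",
             "EXISTENCE: non-experimental",
             "profile:HMMER:3.1",
             "similar to DNA sequence (same species):INSD:AE014075.1",
             "alignment:Splign:1.26")
  for (x in cases) {
    p <- parse_inference(x)
    expect_equal(render_inference(p), x)                    # canonical form
    p2 <- parse_inference(render_inference(p))
    expect_equal(p2[c("category", "type", "same_species", "basis")],
                 p[c("category", "type", "same_species", "basis")])
  }
  ecases <- c("EXISTENCE: N-terminal sequencing [PMID:1234567]",
              "COORDINATES: transcript mapping",
              "RT-PCR of the full-length transcript [doi:10.1000/x]")
  for (x in ecases) {
    p <- parse_experiment(x)
    expect_equal(render_experiment(p), x)
    p2 <- parse_experiment(render_experiment(p))
    expect_equal(p2[c("category", "description", "citation")],
                 p[c("category", "description", "citation")])
  }
})

test_that("experiment parsing extracts category and citation", {
  ev <- parse_experiment("EXISTENCE: N-terminal sequencing [PMID:1234567]")
  expect_equal(ev$category, "EXISTENCE")
  expect_equal(ev$description, "N-terminal sequencing")
  expect_equal(ev$citation, "PMID:1234567")
  ev2 <- parse_experiment("coordinates: transcript mapping")
  expect_equal(ev2$category, "COORDINATES")   # case-folded
  bad <- parse_experiment("DESCRIPTION:")
  expect_true("EV003" %in% bad$findings$rule_id)
})

test_that("pseudogene rules enforce the no-translated-product prohibition", {
  mk <- function(quals, key = "CDS") {
    genome_record("t", list(gb_replicon("c", strrep("A", 500), features =
      list(gb_feature(key, gb_location(c(0, 300)), quals)))))
  }
  f1 <- validate_pseudogenes(mk(list(pseudo = NA, translation = "MK")))
  expect_true(any(f1$rule_id == "PSEUDO001" & f1$severity == "ERROR"))
  # clean case: /pseudo with the product name in the note
  expect_equal(nrow(validate_pseudogenes(
    mk(list(pseudo = NA, note = "gyrA pseudogene")))), 0)
  f2 <- validate_pseudogenes(mk(list(pseudo = NA, product = "gyrA")))
  expect_true("PSEUDO002" %in% f2$rule_id)
  f3 <- validate_pseudogenes(mk(list(
    exception = "annotated by transcript or proteomic data")))
  expect_true(any(f3$rule_id == "PSEUDO003" & f3$severity == "FAIL"))
  expect_equal(nrow(validate_pseudogenes(mk(list(
    exception = "annotated by transcript or proteomic data",
    inference = "similar to AA sequence:INSD:X.1")))), 0)
  f4 <- validate_pseudogenes(mk(list(artificial_location = NA,
                                     product = "DNA gyrase")))
  expect_true("PSEUDO004" %in% f4$rule_id)
  expect_equal(f4$suggestion[f4$rule_id == "PSEUDO004"],
               "LOW-QUALITY PROTEIN: DNA gyrase")
  expect_equal(nrow(validate_pseudogenes(mk(list(
    artificial_location = NA,
    product = "LOW-QUALITY PROTEIN: DNA gyrase")))), 0)
  f5 <- validate_pseudogenes(mk(list(locus_tag = "TST_0009"),
                                key = "misc_feature"))
  expect_true("PSEUDO005" %in% f5$rule_id)
  f6 <- validate_pseudogenes(mk(list(pseudogene = "unprocessed")))
  expect_true("PSEUDO006" %in% f6$rule_id)
})

test_that("locus_tag rules cover duplication, prefixes, syntax and absence", {
  mk <- function(tags, keys = rep("gene", length(tags))) {
    feats <- lapply(seq_along(tags), function(i) {
      q <- if (is.na(tags[i])) list() else list(locus_tag = tags[i])
      gb_feature(keys[i], gb_location(c(10 * i, 10 * i + 6)), q)
    })
    genome_record("t", list(gb_replicon("c", strrep("A", 500),
                                        features = feats)))
  }
  expect_equal(nrow(validate_locus_tags(mk(c("ECK_0001", "ECK_0002")))), 0)
  d <- validate_locus_tags(mk(c("ECK_0001", "ECK_0001")))
  expect_true(any(d$rule_id == "LT001" & d$severity == "FAIL"))
  # a gene and its CDS legitimately share one tag
  expect_equal(nrow(validate_locus_tags(
    mk(c("ECK_0001", "ECK_0001"), keys = c("gene", "CDS")))), 0)
  p <- validate_locus_tags(mk(c("ECK_0001", "ABC_0002")))
  expect_true("LT002" %in% p$rule_id)
  s <- validate_locus_tags(mk(c("AB_0001", "1CK_0002", "ECK-0003")))
  expect_equal(sum(s$rule_id == "LT003"), 3)
  a <- validate_locus_tags(mk(c("ECK_0001", NA), keys = c("gene", "tRNA")))
  expect_true("LT004" %in% a$rule_id)
  # misc_feature may lack a tag silently
  expect_equal(nrow(validate_locus_tags(mk(NA, keys = "misc_feature"))), 0)
})

test_that("structural rules detect missing genes and translation conflicts", {
  sq <- paste0(strrep("C", 9), "ATGAAATAA", strrep("C", 12))
  cds_ok <- gb_feature("CDS", gb_location(c(9, 18)),
                       list(translation = "MK"))
  cds_bad <- gb_feature("CDS", gb_location(c(9, 18)),
                        list(translation = "MR"))
  gene <- gb_feature("gene", gb_location(c(9, 18)), list())
  rec1 <- genome_record("t", list(gb_replicon("c", sq,
                                              features = list(gene, cds_ok))),
                        bioproject = "P1", structured_comment = c(k = "v"))
  expect_equal(nrow(validate_structure(rec1)), 0)
  rec2 <- genome_record("t", list(gb_replicon("c", sq,
                                              features = list(gene, cds_bad))),
                        bioproject = "P1", structured_comment = c(k = "v"))
  f2 <- validate_structure(rec2)
  expect_true(any(f2$rule_id == "STRUCT002" & f2$severity == "ERROR"))
  rec3 <- genome_record("t", list(gb_replicon("c", sq,
                                              features = list(cds_ok))),
                        bioproject = "P1", structured_comment = c(k = "v"))
  expect_true("STRUCT001" %in% validate_structure(rec3)$rule_id)
  # span not divisible by 3 without partial/exception
  rec4 <- genome_record("t", list(gb_replicon("c", sq, features = list(
    gb_feature("gene", gb_location(c(9, 17)), list()),
    gb_feature("CDS", gb_location(c(9, 17)), list())))),
    bioproject = "P1", structured_comment = c(k = "v"))
  expect_true("STRUCT003" %in% validate_structure(rec4)$rule_id)
  # record-level metadata rules
  rec5 <- genome_record("t", list(gb_replicon("c", sq,
                                              features = list(gene, cds_ok))))
  ids <- validate_structure(rec5)$rule_id
  expect_true(all(c("STRUCT004", "STRUCT005") %in% ids))
})

test_that("the finding multiset is invariant under feature permutation", {
  rec <- case_fixture("LT003")
  r <- rec$replicons[[1]]
  set.seed(7)
  perm <- sample(length(r$features))
  rec2 <- genome_record(rec$organism,
                        list(gb_replicon(r$name, r$sequence, r$topology,
                                         r$features[perm])),
                        bioproject = rec$bioproject,
                        structured_comment = rec$structured_comment)
  f1 <- as.data.frame(lint_record(rec))
  f2 <- as.data.frame(lint_record(rec2))
  key <- function(d) sort(paste(d$rule_id, d$severity, d$feature))
  expect_equal(key(f1), key(f2))
})

test_that("each registered plantable rule fires on its fixture, none on gold", {
  gold_findings <- lint_record(gold_standard())
  expect_equal(nrow(gold_findings), 0)
  reg <- rule_catalog()
  for (rid in reg$rule_id[reg$plantable]) {
    f <- lint_record(case_fixture(rid))
    expect_gte(sum(f$rule_id == rid), 1)
    other_block <- f$severity[f$rule_id != rid] %in% c("ERROR", "FAIL")
    expect_false(any(other_block), label = rid)
  }
})
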