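# Deterministic generator of annotated genome records with known ground
# truth. Counts (hypothetical names, standard starts, short proteins) are
# constructed exactly rather than sampled, so truth equality is exact; GC
# is realized by assigning the exact number of G/C bases to intergenic
# positions, and the realized value is the recorded truth.

PRODUCT_POOL <- c(
  "DNA gyrase subunit A", "DNA polymerase III subunit alpha",
  "recombinase A", "chaperonin GroEL", "cell division protein FtsZ",
  "ATP synthase subunit beta", "preprotein translocase subunit SecA",
  "RNA polymerase sigma factor RpoD", "glutamine synthetase",
  "citrate synthase", "enolase", "pyruvate kinase",
  "phosphoglycerate kinase", "malate dehydrogenase",
  "succinate dehydrogenase flavoprotein subunit", "aconitate hydratase",
  "isocitrate dehydrogenase", "DNA ligase LigA",
  "single-stranded DNA-binding protein",
  "transcription termination factor Rho")

RRNA_LENGTHS <- c(`5S` = 120L, `16S` = 1542L, `23S` = 2904L)
TRNA_LENGTH <- 75L

PLANTABLE_RULES <- RULE_REGISTRY$rule_id[RULE_REGISTRY$plantable]

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codons <- function(transl_table = 11L) {
  code <- genetic_code_table(transl_table)
  names(code)[code != "*"]
}

#' Specification of a synthetic genome
#'
#' Defines the study conditions for one generated genome: size, GC target,
#' gene content, exact construction fractions, RNA complements, pseudogene
#' strategy cases, evidence coverage and planted rule violations. Defaults
#' describe a small, well-annotated bacterial chromosome.
#'
#' @param seed integer RNG seed; the same seed gives byte-identical output.
#' @param length_bp replicon length.
#' @param gc_target target GC percent; realized within the feasible range
#'   and recorded exactly in the truth.
#' @param n_proteins number of base protein-coding genes.
#' @param protein_len_mean,protein_len_sd,protein_len_min protein length
#'   distribution in amino acids (normal, truncated at the minimum).
#' @param hypothetical_fraction exact fraction of proteins named
#'   "hypothetical protein" (count, not expectation).
#' @param standard_start_fraction exact fraction of CDS starting with ATG
#'   (the rest start GTG).
#' @param trna_aa_subset amino acids receiving a functional tRNA.
#' @param rrna_subset subset of c("5S","16S","23S") present as functional
#'   rRNAs.
#' @param pseudo_trna_aas,pseudo_rrna_subset RNA features added as
#'   pseudogenes.
#' @param pseudo_cases pseudogene strategy cases to include, from
#'   c("case1","case3a","case3c","case3d","case4") (all clean forms).
#' @param evidence_profile exact fraction of CDS carrying /inference and
#'   /experiment qualifiers.
#' @param planted_violations rule ids (see [rule_catalog()]) each planted
#'   exactly once.
#' @param include_core give the first core-catalog functions as products so
#'   the core-function check passes.
#' @param organism,bioproject,structured_comment record-level fields.
#' @param exemption_notes named character: check id -> free text, emitted
#'   as "annotation-exception" structured-comment lines.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(seed = 1L, length_bp = 60000L, gc_target = 50,
                        n_proteins = 30L, protein_len_mean = 300,
                        protein_len_sd = 80, protein_len_min = 50L,
                        hypothetical_fraction = 0.2,
                        standard_start_fraction = 0.9,
                        trna_aa_subset = AA3,
                        rrna_subset = c("5S", "16S", "23S"),
                        pseudo_trna_aas = character(0),
                        pseudo_rrna_subset = character(0),
                        pseudo_cases = character(0),
                        evidence_profile = 0.3,
                        planted_violations = character(0),
                        include_core = FALSE,
                        organism = "Synthetica exempli",
                        bioproject = "PRJNA000001",
                        structured_comment = TRUE,
                        exemption_notes = NULL) {
  stopifnot(hypothetical_fraction >= 0, hypothetical_fraction <= 1,
            standard_start_fraction >= 0, standard_start_fraction <= 1,
            evidence_profile >= 0, evidence_profile <= 1,
            n_proteins >= 0, length_bp > 0,
            all(trna_aa_subset %in% AA3),
            all(rrna_subset %in% names(RRNA_LENGTHS)),
            all(pseudo_cases %in% c("case1", "case3a", "case3c", "case3d",
                                    "case4")))
  bad <- setdiff(planted_violations, PLANTABLE_RULES)
  if (length(bad)) stop("unregistered rule id(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "genome_spec")
}

# exact-count index selection: k of n, seeded
pick_exact <- function(n, frac) {
  k <- as.integer(round_half_up(frac * n, 0L))
  if (k > n) k <- n
  if (k == 0L) integer(0) else sample.int(n, k)
}

new_element <- function(kind, nt, key, strand = "+", quals = list(),
                        gene = TRUE, locus_tag = TRUE, extra = list()) {
  c(list(kind = kind, nt = nt, key = key, strand = strand, quals = quals,
         gene = gene, locus_tag = locus_tag), extra)
}

cds_nt <- function(aa_len, start_codon, codons) {
  paste0(start_codon,
         paste(sample(codons, aa_len - 1L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Generate a synthetic annotated genome with known truth
#'
#' Builds the record deterministically under the spec's seed. Protein
#' lengths are drawn once and recorded; hypothetical names, standard start
#' codons and evidence qualifiers are assigned to hit their fractions as
#' exact counts; each planted violation is introduced exactly once; GC is
#' realized by exact base assignment and the realized value recorded.
#'
#' @param spec a [genome_spec()].
#' @return List with elements `record` (a [genome_record()]) and `truth`
#'   (expected metrics, expected finding rule ids, expected check
#'   statuses).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(spec$seed)
  # planting the record-level rules means dropping the corresponding field
  if ("STRUCT004" %in% spec$planted_violations) spec$structured_comment <- FALSE
  if ("STRUCT005" %in% spec$planted_violations) spec$bioproject <- NULL
  codons <- sense_codons()
  n <- spec$n_proteins

  # base protein plan: exact-count construction
  lens <- pmax(spec$protein_len_min,
               as.integer(round(stats::rnorm(n, spec$protein_len_mean,
                                             spec$protein_len_sd))))
  idx_hyp <- pick_exact(n, spec$hypothetical_fraction)
  idx_std <- pick_exact(n, spec$standard_start_fraction)
  idx_ev <- pick_exact(n, spec$evidence_profile)
  catalog <- if (spec$include_core) load_core_catalog() else NULL
  products <- character(n)
  non_hyp <- setdiff(seq_len(n), idx_hyp)
  pool_i <- 0L
  core_used <- 0L
  for (i in seq_len(n)) {
    if (i %in% idx_hyp) {
      products[i] <- "hypothetical protein"
    } else if (!is.null(catalog) && core_used < nrow(catalog)) {
      core_used <- core_used + 1L
      products[i] <- catalog$display_name[core_used]
      el <- catalog$expected_len_aa[core_used]
      if (is.finite(el)) {
        lens[i] <- max(spec$protein_len_min, as.integer(round(el)))
      }
    } else {
      pool_i <- pool_i + 1L
      products[i] <- PRODUCT_POOL[(pool_i - 1L) %% length(PRODUCT_POOL) + 1L]
    }
  }
  if (!is.null(catalog) && core_used < nrow(catalog)) {
    stop("infeasible spec: not enough non-hypothetical proteins to cover the core catalog")
  }

  elements <- list()
  # element truth fields: protein (logical), aa_len, start, product,
  # hypothetical, pseudo
  for (i in seq_len(n)) {
    start_codon <- if (i %in% idx_std) "ATG" else "GTG"
    quals <- list()
    quals[["product"]] <- products[i]
    if (i %in% idx_ev) {
      quals[["inference"]] <- "ab initio prediction:Genscan:2.0"
      quals[["experiment"]] <- "EXISTENCE: N-terminal sequencing [PMID:1234567]"
    }
    elements[[length(elements) + 1L]] <- new_element(
      "protein", cds_nt(lens[i], start_codon, codons), "CDS",
      strand = sample(c("+", "-"), 1L), quals = quals,
      extra = list(protein = TRUE, aa_len = lens[i],
                   start = start_codon, hypothetical = i %in% idx_hyp))
  }
  for (aa in spec$trna_aa_subset) {
    elements[[length(elements) + 1L]] <- new_element(
      "trna", random_dna(TRNA_LENGTH), "tRNA",
      quals = list(product = paste0("tRNA-", aa)))
  }
  for (aa in spec$pseudo_trna_aas) {
    elements[[length(elements) + 1L]] <- new_element(
      "trna_pseudo", random_dna(TRNA_LENGTH), "tRNA",
      quals = list(product = paste0("tRNA-", aa), pseudo = NA))
  }
  for (cls in spec$rrna_subset) {
    elements[[length(elements) + 1L]] <- new_element(
      "rrna", random_dna(RRNA_LENGTHS[[cls]]), "rRNA",
      quals = list(product = paste0(cls, " ribosomal RNA")))
  }
  for (cls in spec$pseudo_rrna_subset) {
    elements[[length(elements) + 1L]] <- new_element(
      "rrna_pseudo", random_dna(RRNA_LENGTHS[[cls]]), "rRNA",
      quals = list(product = paste0(cls, " ribosomal RNA"), pseudo = NA))
  }
  elements <- c(elements, pseudo_case_elements(spec$pseudo_cases, codons,
                                               spec, lens))
  planted <- planted_elements(spec$planted_violations, codons, spec)
  elements <- c(elements, planted$elements)

  # shuffle genomic order, then lay out left to right
  elements <- elements[sample(length(elements))]
  total_gene_bp <- sum(vapply(elements, function(e) nchar(e$nt), 0L))
  m_int <- spec$length_bp - total_gene_bp
  n_gaps <- length(elements) + 1L
  if (m_int < 2L * n_gaps) {
    stop(sprintf("infeasible spec: %d bp of features exceed %d bp genome",
                 total_gene_bp, spec$length_bp))
  }

  # intergenic filler with exact GC assignment
  g0 <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(vapply(elements, `[[`, "", "nt")),
    letters = c("G", "C")))
  want_gc <- as.integer(round(spec$gc_target / 100 * spec$length_bp))
  need <- min(max(want_gc - g0, 0L), m_int)
  int_bases <- sample(c("A", "T"), m_int, replace = TRUE)
  if (need > 0L) {
    int_bases[sample.int(m_int, need)] <- sample(c("G", "C"), need,
                                                 replace = TRUE)
  }
  realized_gc <- 100 * (g0 + need) / spec$length_bp

  gaps <- rep(m_int %/% n_gaps, n_gaps)
  gaps[1L] <- gaps[1L] + m_int %% n_gaps
  int_str <- paste(int_bases, collapse = "")

  # realize sequence and features
  seq_parts <- character(0)
  features <- list()
  pos <- 0L; int_off <- 0L; tag_i <- 0L
  take_int <- function(k) {
    s <- substr(int_str, int_off + 1L, int_off + k)
    int_off <<- int_off + k
    s
  }
  for (ei in seq_along(elements)) {
    e <- elements[[ei]]
    g <- gaps[ei]
    seq_parts <- c(seq_parts, take_int(g))
    pos <- pos + g
    L <- nchar(e$nt)
    embedded <- if (e$strand == "-") revcomp(e$nt) else e$nt
    seq_parts <- c(seq_parts, embedded)
    loc <- gb_location(matrix(c(pos, pos + L), ncol = 2L),
                       strand = e$strand)
    quals <- e$quals
    tag <- NULL
    if (isTRUE(e$locus_tag)) {
      if (!is.null(e$fixed_tag)) {
        tag <- e$fixed_tag
      } else {
        tag_i <- tag_i + 1L
        tag <- sprintf("SYN_%04d", tag_i)
      }
    }
    if (isTRUE(e$gene)) {
      gq <- list()
      if (!is.null(tag) && !isTRUE(e$gene_untagged)) gq[["locus_tag"]] <- tag
      if (!is.null(e$gene_tag)) gq[["locus_tag"]] <- e$gene_tag
      features[[length(features) + 1L]] <- gb_feature("gene", loc, gq)
    }
    fq <- list()
    if (!is.null(tag) && !isTRUE(e$feature_untagged)) fq[["locus_tag"]] <- tag
    fq <- c(fq, quals)
    features[[length(features) + 1L]] <- gb_feature(e$key, loc, fq)
    pos <- pos + L
    elements[[ei]]$tag <- tag
  }
  seq_parts <- c(seq_parts, take_int(gaps[n_gaps]))
  genome_seq <- paste(seq_parts, collapse = "")
  stopifnot(nchar(genome_seq) == spec$length_bp)

  scomment <- NULL
  if (isTRUE(spec$structured_comment)) {
    scomment <- c("Annotation Provider" = "annoqc synthetic generator",
                  "Annotation Pipeline" = "annoqc::generate_genome",
                  "Annotation Software revision" =
                    as.character(utils::packageVersion("annoqc")))
    if (!is.null(spec$exemption_notes)) {
      for (id in names(spec$exemption_notes)) {
        scomment[[paste0("Exception ", id)]] <-
          paste0("annotation-exception: ", id, ": ",
                 spec$exemption_notes[[id]])
      }
    }
  }
  record <- genome_record(
    spec$organism,
    list(gb_replicon("synrep1", genome_seq, topology = "linear",
                     features = features)),
    bioproject = if (is.null(spec$bioproject) || is.na(spec$bioproject) ||
                     !nzchar(spec$bioproject)) NULL else spec$bioproject,
    structured_comment = scomment)

  truth <- build_truth(spec, elements, realized_gc)
  list(record = record, truth = truth)
}

# clean pseudogene-strategy cases (each introduces no finding beyond the
# advisory PSEUDO006-free forms)
pseudo_case_elements <- function(cases, codons, spec, lens) {
  out <- list()
  mean_len <- as.integer(spec$protein_len_mean)
  for (cs in cases) {
    if (cs == "case1") {
      out[[length(out) + 1L]] <- new_element(
        "pseudo_cds", cds_nt(mean_len, "ATG", codons), "CDS",
        quals = list(pseudo = NA, note = "gyrB pseudogene"),
        extra = list(pseudo = TRUE))
    } else if (cs == "case3a") {
      # frameshifted gene, sequence correct: intervals combined, /pseudo
      out[[length(out) + 1L]] <- new_element(
        "pseudo_cds", cds_nt(mean_len, "ATG", codons), "CDS",
        quals = list(pseudo = NA,
                     note = "frameshifted; intervals combined into a single gene"),
        extra = list(pseudo = TRUE))
    } else if (cs == "case3c") {
      # sequencing error: imported translation, exception + inference
      aa_len <- mean_len
      nt <- cds_nt(aa_len, "ATG", codons)
      nt_fs <- paste0(substr(nt, 1L, 30L), "A",
                      substr(nt, 31L, nchar(nt)))   # 1-base insertion
      tr <- paste0("M", paste(sample(setdiff(LETTERS, c("B", "J", "O", "U",
                                                        "X", "Z")),
                                     aa_len - 1L, replace = TRUE),
                              collapse = ""))
      out[[length(out) + 1L]] <- new_element(
        "exception_cds", nt_fs, "CDS",
        quals = list(product = "DNA topoisomerase IV subunit A",
                     exception = TRANSCRIPT_EXCEPTION,
                     inference = "similar to AA sequence:INSD:AAD51968.1",
                     translation = tr),
        extra = list(protein = TRUE, aa_len = aa_len, start = "ATG",
                     hypothetical = FALSE))
    } else if (cs == "case3d") {
      out[[length(out) + 1L]] <- new_element(
        "artificial_cds", cds_nt(mean_len, "ATG", codons), "CDS",
        quals = list(artificial_location = NA,
                     product = "LOW-QUALITY PROTEIN: DNA topoisomerase IV subunit B"),
        extra = list(protein = TRUE, aa_len = mean_len, start = "ATG",
                     hypothetical = FALSE))
    } else if (cs == "case4") {
      out[[length(out) + 1L]] <- new_element(
        "similarity_region", random_dna(240L), "misc_feature",
        quals = list(note = "region of similarity to DNA gyrase subunit B"),
        gene = FALSE, locus_tag = FALSE)
    }
  }
  out
}

# one element (or spec tweak) per planted rule violation
planted_elements <- function(rules, codons, spec) {
  out <- list()
  L <- 120L  # aa length of planted proteins
  add <- function(e) out[[length(out) + 1L]] <<- e
  for (rid in rules) {
    switch(rid,
      NAME001 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "conserved hypothetical protein"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = TRUE))),
      EV001 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "citrate lyase subunit beta",
                     inference = "EXISTENCE: banana"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      EV002 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "citrate lyase subunit alpha",
                     inference = "profile"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      EV003 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "citrate lyase subunit gamma",
                     experiment = "DESCRIPTION:"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      PSEUDO001 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(pseudo = NA, note = "degraded transporter pseudogene",
                     translation = "MKLVNT"),
        extra = list(pseudo = TRUE))),
      PSEUDO002 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(pseudo = NA, product = "degraded ABC transporter permease"),
        extra = list(pseudo = TRUE))),
      PSEUDO003 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "fumarate hydratase",
                     exception = TRANSCRIPT_EXCEPTION),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      PSEUDO004 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(artificial_location = NA,
                     product = "argininosuccinate synthase"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      PSEUDO005 = add(new_element(
        "planted", random_dna(200L), "misc_feature",
        quals = list(note = "region of similarity to recombinase A"),
        gene = FALSE, locus_tag = TRUE)),
      PSEUDO006 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(pseudogene = "unprocessed",
                     note = "unprocessed pseudogene"),
        extra = list(pseudo = TRUE))),
      LT001 = {
        add(new_element("planted_gene", random_dna(90L), "gene",
                        gene = FALSE, locus_tag = TRUE,
                        extra = list(fixed_tag = "SYN_9901")))
        add(new_element("planted_gene", random_dna(90L), "gene",
                        gene = FALSE, locus_tag = TRUE,
                        extra = list(fixed_tag = "SYN_9901")))
      },
      LT002 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "aspartate aminotransferase"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE, fixed_tag = "ZZZ_0001"))),
      LT003 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "serine hydroxymethyltransferase"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE, gene_tag = "AB_0001"))),
      LT004 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "adenylate kinase"),
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE, feature_untagged = TRUE))),
      STRUCT001 = add(new_element(
        "planted", cds_nt(L, "ATG", codons), "CDS",
        quals = list(product = "thymidylate synthase"),
        gene = FALSE,
        extra = list(protein = TRUE, aa_len = L, start = "ATG",
                     hypothetical = FALSE))),
      STRUCT002 = {
        nt <- cds_nt(L, "ATG", codons)
        good <- translate_cds(nt)
        bad <- paste0(substr(good, 1L, nchar(good) - 1L),
                      if (substr(good, nchar(good), nchar(good)) == "A") "G"
                      else "A")
        add(new_element(
          "planted", nt, "CDS",
          quals = list(product = "ribose-phosphate pyrophosphokinase",
                       translation = bad),
          extra = list(protein = TRUE, aa_len = nchar(bad), start = "ATG",
                       hypothetical = FALSE)))
      },
      STRUCT003 = {
        nt <- cds_nt(L, "ATG", codons)
        nt <- paste0(substr(nt, 1L, nchar(nt) - 3L), "G",
                     substr(nt, nchar(nt) - 2L, nchar(nt)))
        add(new_element(
          "planted", nt, "CDS",
          quals = list(product = "orotate phosphoribosyltransferase"),
          extra = list(protein = TRUE, aa_len = nchar(nt) %/% 3L - 1L,
                       start = "ATG", hypothetical = FALSE)))
      },
      STRUCT004 = NULL,  # realized by dropping the structured comment
      STRUCT005 = NULL,  # realized by dropping the bioproject
      stop("no injector for rule ", rid)
    )
  }
  list(elements = out)
}

# analytic truth from the construction plan (independent of the metrics
# pipeline, which re-derives everything from the realized record)
build_truth <- function(spec, elements, realized_gc) {
  is_protein <- vapply(elements, function(e) isTRUE(e$protein), FALSE)
  pe <- elements[is_protein]
  lens <- vapply(pe, function(e) as.integer(e$aa_len), 0L)
  hyp <- vapply(pe, function(e) isTRUE(e$hypothetical), FALSE)
  starts <- vapply(pe, function(e) e$start %||% "", "")
  keys <- vapply(elements, `[[`, "", "key")
  n_rna <- sum(keys %in% qc_config()$rna_keys)
  count <- length(lens)

  metrics <- list(
    organism = spec$organism,
    replicon_count = 1L,
    total_length_mbp = spec$length_bp / 1e6,
    gc_percent = realized_gc,
    protein_count = count,
    rna_count = n_rna,
    trna_aa_count = length(unique(spec$trna_aa_subset)),
    trna_aa_set = unique(spec$trna_aa_subset),
    hypothetical_count = sum(hyp),
    coding_density = count / (spec$length_bp / 1000),
    avg_protein_len_aa = if (count) mean(lens) else NA_real_,
    min_protein_len_aa = if (count) min(lens) else NA_integer_,
    short_protein_percent = if (count) 100 * sum(lens < 150L) / count
                            else NA_real_,
    standard_start_percent = if (count) 100 * sum(starts == "ATG") / count
                             else NA_real_,
    hypothetical_ratio = if (count) sum(hyp) / count else NA_real_
  )

  expected_rules <- spec$planted_violations
  if (!isTRUE(spec$structured_comment) &&
      !"STRUCT004" %in% expected_rules) {
    expected_rules <- c(expected_rules, "STRUCT004")
  }
  no_bp <- is.null(spec$bioproject) || is.na(spec$bioproject) ||
    !nzchar(spec$bioproject)
  if (no_bp && !"STRUCT005" %in% expected_rules) {
    expected_rules <- c(expected_rules, "STRUCT005")
  }
  cfg <- qc_config()
  sev <- RULE_REGISTRY$severity[match(expected_rules, RULE_REGISTRY$rule_id)]
  status_from <- function(prefix) {
    s <- sev[startsWith(expected_rules, prefix)]
    if (any(s %in% c("ERROR", "FAIL"))) "FAIL"
    else if (any(s == "WARN")) "WARN"
    else "PASS"
  }
  dens <- metrics$coding_density
  ratio <- metrics$hypothetical_ratio
  checks <- c(
    RRNA_SET = if (all(names(RRNA_LENGTHS) %in% spec$rrna_subset)) "PASS"
               else if (all(setdiff(names(RRNA_LENGTHS), spec$rrna_subset)
                            %in% spec$pseudo_rrna_subset)) "WARN" else "FAIL",
    TRNA_SET = if (all(AA3 %in% spec$trna_aa_subset)) "PASS"
               else if (all(setdiff(AA3, spec$trna_aa_subset)
                            %in% spec$pseudo_trna_aas)) "WARN" else "FAIL",
    CORE_FUNCS = if (isTRUE(spec$include_core)) "PASS" else "FAIL",
    DENSITY = if (!is.na(dens) && dens >= cfg$density_lo &&
                  dens <= cfg$density_hi) "PASS" else "WARN",
    HYPOTHETICAL_RATIO = if (is.na(ratio)) "WARN"
                         else if (ratio >= cfg$hypothetical_fail) "FAIL"
                         else if (ratio >= cfg$hypothetical_warn) "WARN"
                         else "PASS",
    LOCUS_TAGS = status_from("LT"),
    PSEUDO_FORMAT = status_from("PSEUDO"),
    VALIDATION_CLEAN = status_from("STRUCT")
  )
  if (!is.null(spec$exemption_notes)) {
    for (id in names(spec$exemption_notes)) {
      if (identical(checks[[id]], "FAIL")) checks[[id]] <- "EXEMPT"
    }
  }
  any_fail <- any(checks == "FAIL")
  any_error <- any(sev == "ERROR")
  overall <- if (any_fail || any_error) "NONCOMPLIANT"
  else if (any(checks == "EXEMPT")) "COMPLIANT_WITH_EXEMPTIONS"
  else "COMPLIANT"

  list(metrics = metrics, finding_rules = sort(expected_rules),
       checks = checks, overall = overall)
}

#' Gold-standard and rule-violation fixtures
#'
#' `gold_standard()` returns a record meeting every minimal standard
#' (full rRNA and tRNA complements, the full core catalog annotated,
#' bioproject + structured comment, clean locus_tags): it evaluates
#' COMPLIANT with no WARN-or-worse rule findings. `case_fixture(rule_id)`
#' returns the same genome with exactly one planted violation of that rule.
#'
#' @param seed RNG seed for the underlying spec.
#' @return A [genome_record()].
#' @export
gold_standard <- function(seed = 42L) {
  generate_genome(gold_spec(seed))$record
}

#' @rdname gold_standard
#' @param ... [genome_spec()] overrides applied on top of the
#'   gold-standard conditions.
#' @export
gold_spec <- function(seed = 42L, ...) {
  genome_spec(seed = seed, length_bp = 70000L, n_proteins = 40L,
              hypothetical_fraction = 0.1, standard_start_fraction = 0.9,
              evidence_profile = 0.25, include_core = TRUE, ...)
}

#' @rdname gold_standard
#' @param rule_id a plantable rule id from [rule_catalog()].
#' @export
case_fixture <- function(rule_id, seed = 42L) {
  if (!rule_id %in% PLANTABLE_RULES) {
    stop("unregistered or non-plantable rule id: ", rule_id)
  }
  generate_genome(gold_spec(seed, planted_violations = rule_id))$record
}
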