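# Per-feature INSDC convention lint: protein naming, structured evidence
# qualifiers, pseudogene strategies, locus_tags and feature structure.
# Every outcome is a finding; the rule engine never mutates a record.

# --- protein naming -------------------------------------------------------

#' Naming rule set
#'
#' The mandatory rule is the two-accepted-names rule: for proteins of
#' unknown function only "hypothetical protein" and "uncharacterized
#' protein" are acceptable; the older synonyms ("conserved hypothetical
#' protein", "novel protein", "protein of unknown function", ...) are
#' banned. Style checks beyond that (whitespace, case, vague qualifiers,
#' identifier-as-name) are off by default.
#'
#' @param style enable the optional style checks.
#' @param banned banned unknown-function synonyms.
#' @param vague_words vague qualifier words flagged by the style checks.
#' @return A list used by [lint_protein_name()].
#' @export
naming_rules <- function(style = FALSE,
                         banned = qc_config()$banned_names,
                         vague_words = qc_config()$vague_name_words) {
  list(style = isTRUE(style), banned = banned, vague_words = vague_words)
}

#' Lint one protein product name
#'
#' @param name product name (non-empty after trimming).
#' @param rules a [naming_rules()] set.
#' @param organism optional organism name, for the trailing-organism style
#'   check.
#' @param feature,replicon context strings copied into findings.
#' @return A findings table (empty when the name is acceptable).
#' @export
lint_protein_name <- function(name, rules = naming_rules(), organism = NULL,
                              feature = "", replicon = "") {
  findings <- empty_findings()
  norm <- normalize_product(name)
  if (norm %in% tolower(rules$banned)) {
    findings <- rbind_findings(findings, new_finding(
      "NAME001", "FAIL", replicon = replicon, feature = feature,
      message = sprintf("'%s' is no longer an acceptable unknown-function name", name),
      suggestion = "hypothetical protein"))
  }
  if (!rules$style) return(findings)
  if (grepl("^\\s|\\s$", name) || grepl("\\s{2,}", name)) {
    findings <- rbind_findings(findings, new_finding(
      "NAME002", "WARN", replicon = replicon, feature = feature,
      message = "leading/trailing/multiple whitespace in product name",
      suggestion = gsub("\\s+", " ", trimws(name))))
  }
  letters_only <- gsub("[^A-Za-z]", "", name)
  if (nchar(letters_only) > 3L && letters_only == toupper(letters_only)) {
    findings <- rbind_findings(findings, new_finding(
      "NAME003", "WARN", replicon = replicon, feature = feature,
      message = "product name is all-uppercase"))
  } else if (!is.null(organism) && nzchar(organism) &&
             grepl(paste0("\\Q", organism, "\\E$"), trimws(name))) {
    findings <- rbind_findings(findings, new_finding(
      "NAME003", "WARN", replicon = replicon, feature = feature,
      message = "product name ends with a bare organism name"))
  }
  pat <- paste0("\\b(", paste(rules$vague_words, collapse = "|"), ")\\b")
  if (grepl(pat, norm)) {
    findings <- rbind_findings(findings, new_finding(
      "NAME004", "WARN", replicon = replicon, feature = feature,
      message = "product name carries a vague qualifier (homolog/fragment/putative)"))
  }
  if (grepl("^(ORF\\d+|[A-Za-z][A-Za-z0-9]{2,}_\\d+)$", trimws(name))) {
    findings <- rbind_findings(findings, new_finding(
      "NAME005", "WARN", replicon = replicon, feature = feature,
      message = "product name is a bare locus_tag or ORF identifier",
      suggestion = "hypothetical protein"))
  }
  findings
}

# --- structured evidence qualifiers --------------------------------------

EVIDENCE_CATEGORIES <- c("EXISTENCE", "COORDINATES", "DESCRIPTION")
INFERENCE_TYPES <- c("non-experimental", "similar to sequence",
                     "similar to AA sequence", "similar to DNA sequence",
                     "similar to RNA sequence", "profile",
                     "ab initio prediction", "alignment")
BASIS_REQUIRED_TYPES <- c("similar to sequence", "similar to AA sequence",
                          "similar to DNA sequence",
                          "similar to RNA sequence", "profile", "alignment")

canon_inference_type <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  if (tolower(x) %in% c("non experimental", "non-experimental")) {
    return("non-experimental")
  }
  hit <- INFERENCE_TYPES[tolower(INFERENCE_TYPES) == tolower(x)]
  if (length(hit)) hit[[1L]] else NA_character_
}

#' Parse a structured /inference qualifier
#'
#' Grammar: optional category token (EXISTENCE / COORDINATES / DESCRIPTION)
#' and colon; an evidence-type phrase (non-experimental, similar to
#' AA/DNA/RNA sequence, profile, ab initio prediction, alignment);
#' optional "(same species)"; then a colon-separated evidence basis of
#' (source, version-or-accession) pairs — an algorithm with its version or
#' a database with an accession.version.
#'
#' @param raw qualifier value.
#' @param feature,replicon context for findings.
#' @return An `inference_evidence` object: `category`, `type`,
#'   `same_species`, `basis` (list of `c(source, version)`), `raw`, plus a
#'   `findings` element (EV001 for unknown tokens, EV002 for a missing
#'   required basis). `render_inference(parse_inference(x))` is the
#'   canonical form of `x`.
#' @export
parse_inference <- function(raw, feature = "", replicon = "") {
  stopifnot(nzchar(raw))
  findings <- empty_findings()
  s <- trimws(raw)
  category <- NA_character_
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*:\\s*(.*)$", s))[[1L]]
  if (length(m) && toupper(m[2L]) %in% EVIDENCE_CATEGORIES) {
    category <- toupper(m[2L])
    s <- m[3L]
  } else if (length(m) && is.na(canon_inference_type(m[2L])) &&
             !grepl(" ", m[2L]) &&
             is.na(canon_inference_type(strsplit(s, ":")[[1L]][1L]))) {
    # looks like a category token but is not one
    findings <- rbind_findings(findings, new_finding(
      "EV001", "FAIL", replicon = replicon, feature = feature,
      message = sprintf("unknown evidence category '%s'", m[2L])))
    s <- m[3L]
  }
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  type_raw <- if (length(parts)) parts[[1L]] else ""
  same_species <- grepl("\\(same species\\)", type_raw)
  type_raw <- trimws(sub("\\(same species\\)", "", type_raw))
  type <- canon_inference_type(type_raw)
  if (is.na(type)) {
    findings <- rbind_findings(findings, new_finding(
      "EV001", "FAIL", replicon = replicon, feature = feature,
      message = sprintf("unknown evidence type '%s'", type_raw)))
  }
  basis_parts <- if (length(parts) > 1L) trimws(parts[-1L]) else character(0)
  basis_parts <- basis_parts[nzchar(basis_parts)]
  basis <- list()
  i <- 1L
  while (i <= length(basis_parts)) {
    src <- basis_parts[[i]]
    ver <- if (i + 1L <= length(basis_parts)) basis_parts[[i + 1L]] else NA_character_
    basis[[length(basis) + 1L]] <- c(source = src, version = ver)
    i <- i + 2L
  }
  if (!is.na(type) && type %in% BASIS_REQUIRED_TYPES && !length(basis)) {
    findings <- rbind_findings(findings, new_finding(
      "EV002", "WARN", replicon = replicon, feature = feature,
      message = sprintf("evidence type '%s' requires a basis but none given", type)))
  }
  structure(list(category = category, type = type,
                 same_species = same_species, basis = basis, raw = raw,
                 findings = findings),
            class = "inference_evidence")
}

#' Render inference evidence in canonical form
#'
#' @param ev an `inference_evidence` (from [parse_inference()]).
#' @return Canonical qualifier string; `parse_inference(render_inference(p))`
#'   reproduces `p`.
#' @export
render_inference <- function(ev) {
  type <- if (is.na(ev$type)) "" else ev$type
  s <- paste0(type, if (ev$same_species) " (same species)" else "")
  if (length(ev$basis)) {
    bs <- vapply(ev$basis, function(b) {
      if (is.na(b[["version"]])) b[["source"]]
      else paste0(b[["source"]], ":", b[["version"]])
    }, "")
    s <- paste(c(s, bs), collapse = ":")
  }
  if (!is.na(ev$category)) s <- paste0(ev$category, ": ", s)
  s
}

#' Parse a structured /experiment qualifier
#'
#' Optional category prefix (EXISTENCE / COORDINATES / DESCRIPTION,
#' case-folded); a free-text description of the experiment; an optional
#' trailing bracketed citation `[PMID:nnn]` or `[doi:...]`.
#'
#' @param raw qualifier value.
#' @param feature,replicon context for findings.
#' @return An `experiment_evidence` object: `category`, `description`,
#'   `citation`, `raw`, `findings` (EV003 when a category token has an
#'   empty description).
#' @export
parse_experiment <- function(raw, feature = "", replicon = "") {
  stopifnot(nzchar(raw))
  findings <- empty_findings()
  s <- trimws(raw)
  category <- NA_character_
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*:(.*)$", s))[[1L]]
  if (length(m) && toupper(m[2L]) %in% EVIDENCE_CATEGORIES) {
    category <- toupper(m[2L])
    s <- trimws(m[3L])
  }
  citation <- NA_character_
  cm <- regmatches(s, regexec("\\[\\s*((PMID|pmid):[0-9]+|(doi|DOI):[^]]+)\\s*\\]\\s*$", s))[[1L]]
  if (length(cm)) {
    citation <- cm[2L]
    citation <- sub("^pmid:", "PMID:", citation)
    citation <- sub("^DOI:", "doi:", citation)
    s <- trimws(sub("\\[[^]]*\\]\\s*$", "", s))
  }
  if (!is.na(category) && !nzchar(s)) {
    findings <- rbind_findings(findings, new_finding(
      "EV003", "FAIL", replicon = replicon, feature = feature,
      message = "experiment category token with empty description"))
  }
  structure(list(category = category, description = s, citation = citation,
                 raw = raw, findings = findings),
            class = "experiment_evidence")
}

#' Render experiment evidence in canonical form
#'
#' @param ev an `experiment_evidence`.
#' @return Canonical qualifier string.
#' @export
render_experiment <- function(ev) {
  s <- ev$description
  if (!is.na(ev$citation)) s <- paste0(s, " [", ev$citation, "]")
  if (!is.na(ev$category)) s <- paste0(ev$category, ": ", s)
  s
}

# evidence lint over a whole record
lint_evidence <- function(record) {
  findings <- empty_findings()
  for (x in all_features(record)) {
    f <- x$feature
    for (v in qual_values(f, "inference")) {
      ev <- parse_inference(v, feature = feature_handle(f),
                            replicon = x$replicon)
      findings <- rbind_findings(findings, ev$findings)
    }
    for (v in qual_values(f, "experiment")) {
      ev <- parse_experiment(v, feature = feature_handle(f),
                             replicon = x$replicon)
      findings <- rbind_findings(findings, ev$findings)
    }
  }
  findings
}

# --- pseudogene strategies ------------------------------------------------

TRANSCRIPT_EXCEPTION <- "annotated by transcript or proteomic data"

#' Validate pseudogene annotation strategies
#'
#' INSDC does not allow a translated product to be derived from a feature
#' labeled as a pseudogene: a `/pseudo` feature carrying `/translation` or
#' `/protein_id` is an ERROR (PSEUDO001); a `/pseudo` CDS with `/product`
#' is a WARN (the product name belongs in `/note`; PSEUDO002). Frameshifts
#' rescued by the transcript/proteomic-data exception must carry
#' `/experiment` or `/inference` (PSEUDO003); `/artificial_location`
#' products must be prefaced "LOW-QUALITY PROTEIN:" (PSEUDO004);
#' similarity-region misc_features carry no gene or locus_tag (PSEUDO005).
#' A `/pseudogene` qualifier with a value is accepted as a synonym of
#' `/pseudo` with an INFO note (PSEUDO006).
#'
#' @param record a [genome_record()].
#' @return A findings table.
#' @export
validate_pseudogenes <- function(record) {
  findings <- empty_findings()
  for (x in all_features(record)) {
    f <- x$feature; h <- feature_handle(f); rn <- x$replicon
    if (has_qual(f, "pseudogene")) {
      findings <- rbind_findings(findings, new_finding(
        "PSEUDO006", "INFO", replicon = rn, feature = h,
        message = "/pseudogene accepted as synonym of /pseudo (INSDC proposal pending)"))
    }
    if (is_pseudo(f)) {
      if (has_qual(f, "translation") || has_qual(f, "protein_id")) {
        findings <- rbind_findings(findings, new_finding(
          "PSEUDO001", "ERROR", replicon = rn, feature = h,
          message = "pseudogene carries a translated product (/translation or /protein_id)"))
      }
      if (f$key == "CDS" && has_qual(f, "product")) {
        findings <- rbind_findings(findings, new_finding(
          "PSEUDO002", "WARN", replicon = rn, feature = h,
          message = "pseudo CDS carries /product; product name belongs in /note"))
      }
    }
    if (f$key == "CDS") {
      exc <- qual_values(f, "exception")
      if (TRANSCRIPT_EXCEPTION %in% exc &&
          !has_qual(f, "experiment") && !has_qual(f, "inference")) {
        findings <- rbind_findings(findings, new_finding(
          "PSEUDO003", "FAIL", replicon = rn, feature = h,
          message = sprintf("exception \"%s\" requires /experiment or /inference",
                            TRANSCRIPT_EXCEPTION)))
      }
      if (has_qual(f, "artificial_location")) {
        p <- qual_value(f, "product")
        if (!is.na(p) && !startsWith(p, "LOW-QUALITY PROTEIN:")) {
          findings <- rbind_findings(findings, new_finding(
            "PSEUDO004", "WARN", replicon = rn, feature = h,
            message = "artificial_location product must be prefaced \"LOW-QUALITY PROTEIN:\"",
            suggestion = paste0("LOW-QUALITY PROTEIN: ", p)))
        }
      }
    }
    if (f$key == "misc_feature" &&
        (has_qual(f, "locus_tag") || has_qual(f, "gene"))) {
      findings <- rbind_findings(findings, new_finding(
        "PSEUDO005", "INFO", replicon = rn, feature = h,
        message = "similarity-region misc_feature carries /locus_tag or /gene (expected: neither)"))
    }
  }
  findings
}

# --- locus tags -----------------------------------------------------------

LOCUS_TAG_KEYS <- c("gene", "CDS", "tRNA", "rRNA")
LOCUS_TAG_RE <- "^[A-Za-z][A-Za-z0-9]{2,}_[A-Za-z0-9]+$"

#' Validate locus_tag usage
#'
#' A genome uses one registered locus_tag prefix so every gene feature can
#' be uniquely identified. Rules: duplicate tags on features of the same
#' key (a gene and its CDS legitimately share one tag, so duplication is
#' judged per feature key; LT001 FAIL); more than one distinct prefix
#' (LT002 FAIL); tag not matching the registry syntax — letter start,
#' alphanumeric prefix of length >= 3, single underscore (LT003 WARN);
#' gene/CDS/tRNA/rRNA features lacking a tag (LT004 WARN).
#'
#' @param record a [genome_record()].
#' @return A findings table.
#' @export
validate_locus_tags <- function(record) {
  findings <- empty_findings()
  tags <- list()
  prefixes <- character(0)
  for (x in all_features(record)) {
    f <- x$feature
    lt <- qual_value(f, "locus_tag")
    if (is.na(lt)) {
      if (f$key %in% LOCUS_TAG_KEYS) {
        findings <- rbind_findings(findings, new_finding(
          "LT004", "WARN", replicon = x$replicon,
          feature = feature_handle(f),
          message = sprintf("%s feature lacking /locus_tag", f$key)))
      }
      next
    }
    tags[[length(tags) + 1L]] <- c(key = f$key, tag = lt,
                                   replicon = x$replicon)
    if (!grepl(LOCUS_TAG_RE, lt)) {
      findings <- rbind_findings(findings, new_finding(
        "LT003", "WARN", replicon = x$replicon, feature = feature_handle(f),
        message = sprintf("locus_tag '%s' does not match registry syntax", lt)))
    } else {
      prefixes <- c(prefixes, sub("_.*$", "", lt))
    }
  }
  if (length(tags)) {
    keyed <- vapply(tags, function(t) paste(t[["key"]], t[["tag"]]), "")
    dup <- unique(keyed[duplicated(keyed)])
    for (d in dup) {
      t <- tags[[match(d, keyed)]]
      findings <- rbind_findings(findings, new_finding(
        "LT001", "FAIL", replicon = t[["replicon"]],
        feature = paste(t[["key"]], t[["tag"]]),
        message = sprintf("duplicate locus_tag '%s' on multiple %s features",
                          t[["tag"]], t[["key"]])))
    }
  }
  upfx <- unique(prefixes)
  if (length(upfx) > 1L) {
    findings <- rbind_findings(findings, new_finding(
      "LT002", "FAIL",
      message = sprintf("multiple locus_tag prefixes in one genome: %s",
                        paste(sort(upfx), collapse = ", "))))
  }
  findings
}

# --- structural rules -----------------------------------------------------

span_signature <- function(loc) {
  paste(loc_min(loc), loc_max(loc), loc$strand)
}

#' Validate feature structure
#'
#' STRUCT001 WARN: CDS without a gene feature covering the same range;
#' STRUCT002 ERROR: translation computed from the sequence conflicts with
#' the archived /translation (skipped when an /exception explains the
#' conflict); STRUCT003 WARN: CDS span not divisible by 3 without partial
#' markers or /exception; STRUCT004 INFO: structured metadata comment block
#' absent; STRUCT005 WARN: BioProject identifier missing.
#'
#' @param record a [genome_record()].
#' @return A findings table.
#' @export
validate_structure <- function(record) {
  findings <- empty_findings()
  for (r in record$replicons) {
    gene_spans <- vapply(Filter(function(f) f$key == "gene", r$features),
                         function(f) span_signature(f$location), "")
    for (f in r$features) {
      if (f$key != "CDS") next
      h <- feature_handle(f)
      if (!span_signature(f$location) %in% gene_spans) {
        findings <- rbind_findings(findings, new_finding(
          "STRUCT001", "WARN", replicon = r$name, feature = h,
          message = "CDS without a same-range gene feature"))
      }
      partial <- f$location$partial5 || f$location$partial3
      if (!is_pseudo(f) && !has_qual(f, "exception") && !partial &&
          loc_span(f$location) %% 3L != 0L) {
        findings <- rbind_findings(findings, new_finding(
          "STRUCT003", "WARN", replicon = r$name, feature = h,
          message = sprintf("CDS span %d not divisible by 3", loc_span(f$location))))
      }
      tr <- qual_value(f, "translation")
      if (!is.na(tr) && !is_pseudo(f) && !has_qual(f, "exception") &&
          seq_available(r)) {
        computed <- tryCatch(translate_feature(r, f), error = function(e) NULL)
        if (is.null(computed) || computed != tr) {
          findings <- rbind_findings(findings, new_finding(
            "STRUCT002", "ERROR", replicon = r$name, feature = h,
            message = "computed translation conflicts with /translation"))
        }
      }
    }
  }
  if (is.null(record$structured_comment)) {
    findings <- rbind_findings(findings, new_finding(
      "STRUCT004", "INFO",
      message = "structured metadata comment block absent (SOP/provenance metadata expected)"))
  }
  if (is.null(record$bioproject)) {
    findings <- rbind_findings(findings, new_finding(
      "STRUCT005", "WARN",
      message = "BioProject identifier missing"))
  }
  findings
}

#' Run the full lint rule set over a record
#'
#' Concatenates parse-time findings, naming lint over non-pseudo CDS
#' products, evidence-qualifier lint, pseudogene rules, locus_tag rules and
#' structural rules. The finding multiset is invariant under feature
#' permutation.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()] (`naming_style_checks` switches the
#'   optional style rules).
#' @return A findings table.
#' @export
lint_record <- function(record, config = qc_config()) {
  findings <- attr(record, "findings") %||% empty_findings()
  rules <- naming_rules(style = config$naming_style_checks,
                        banned = config$banned_names,
                        vague_words = config$vague_name_words)
  for (x in protein_features(record)) {
    p <- qual_value(x$feature, "product")
    if (!is.na(p) && nzchar(trimws(p))) {
      findings <- rbind_findings(findings, lint_protein_name(
        p, rules, organism = record$organism,
        feature = feature_handle(x$feature), replicon = x$replicon))
    }
  }
  rbind_findings(findings,
                 lint_evidence(record),
                 validate_pseudogenes(record),
                 validate_locus_tags(record),
                 validate_structure(record))
}
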