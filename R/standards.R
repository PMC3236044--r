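# Minimal annotation standards for one genome: rRNA set, tRNA coverage,
# core conserved functions, expected coding density and naming, plus the
# lint-derived format checks, aggregated into a compliance report.

CHECK_IDS <- c("RRNA_SET", "TRNA_SET", "CORE_FUNCS", "DENSITY",
               "HYPOTHETICAL_RATIO", "LOCUS_TAGS", "PSEUDO_FORMAT",
               "VALIDATION_CLEAN")

standard_check <- function(check_id, status, detail = "",
                           missing_items = character(0)) {
  stopifnot(check_id %in% CHECK_IDS,
            status %in% c("PASS", "FAIL", "WARN", "EXEMPT"))
  structure(list(check_id = check_id, status = status, detail = detail,
                 missing_items = missing_items),
            class = "standard_check")
}

#' @export
print.standard_check <- function(x, ...) {
  cat(sprintf("%-18s %-6s %s\n", x$check_id, x$status, x$detail))
  if (length(x$missing_items)) {
    cat("    missing:", paste(x$missing_items, collapse = ", "), "\n")
  }
  invisible(x)
}

# --- core-function catalog ------------------------------------------------

#' Load the core-function catalog
#'
#' The default catalog ships with the package: the 12 core functional
#' groups that were historically found missing from submitted complete
#' genomes and added back to reference records (mostly small ribosomal
#' proteins), with their historical addition counts and expected average
#' protein lengths. A larger non-normative extension (more ribosomal
#' proteins and tRNA ligases) can be appended with `extended = TRUE`, and
#' any user table with the same columns can replace the catalog entirely.
#'
#' @param path optional user catalog TSV (columns: function_id,
#'   display_name, patterns ( `|`-separated, case-insensitive), additions,
#'   expected_len_aa, len_spread_aa).
#' @param extended append the shipped non-normative extension.
#' @return data.frame of core functions.
#' @export
load_core_catalog <- function(path = NULL, extended = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "core_functions.tsv", package = "annoqc")
  }
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (extended) {
    ext <- system.file("extdata", "core_functions_extended.tsv",
                       package = "annoqc")
    cat_df <- rbind(cat_df, utils::read.delim(ext, stringsAsFactors = FALSE))
  }
  stopifnot(!anyDuplicated(cat_df$function_id),
            all(nzchar(cat_df$patterns)))
  cat_df
}

# --- individual checks ----------------------------------------------------

RRNA_PATTERNS <- list(
  `5S` = "\\b5S\\b",
  `16S` = "\\b16S\\b|small subunit ribosomal|\\bSSU\\b",
  `23S` = "\\b23S\\b|large subunit ribosomal|\\bLSU\\b"
)

#' Check the ribosomal RNA set
#'
#' A complete genome needs at least one each of 5S, 16S and 23S rRNA as
#' functional (non-pseudo) features. A class present only as a pseudogene
#' gives WARN; a missing class gives FAIL with the missing classes listed;
#' an unclassifiable rRNA product is an INFO and counts as none.
#'
#' @param record a [genome_record()].
#' @return A `standard_check` (findings in `attr(,"findings")`).
#' @export
check_rrna_set <- function(record) {
  findings <- empty_findings()
  fun_classes <- character(0); pseudo_classes <- character(0)
  for (x in all_features(record)) {
    f <- x$feature
    if (f$key != "rRNA") next
    p <- qual_value(f, "product")
    cls <- NA_character_
    if (!is.na(p)) {
      for (nm in names(RRNA_PATTERNS)) {
        if (grepl(RRNA_PATTERNS[[nm]], p, ignore.case = TRUE)) {
          cls <- nm; break
        }
      }
    }
    if (is.na(cls)) {
      findings <- rbind_findings(findings, new_finding(
        "RRNA001", "INFO", replicon = x$replicon,
        feature = feature_handle(f),
        message = sprintf("unclassifiable rRNA product '%s'", p %||% "")))
      next
    }
    if (is_pseudo(f)) pseudo_classes <- union(pseudo_classes, cls)
    else fun_classes <- union(fun_classes, cls)
  }
  want <- names(RRNA_PATTERNS)
  missing <- setdiff(want, fun_classes)
  chk <- if (!length(missing)) {
    standard_check("RRNA_SET", "PASS", "5S, 16S and 23S rRNA all present")
  } else if (all(missing %in% pseudo_classes)) {
    standard_check("RRNA_SET", "WARN",
                   sprintf("rRNA class(es) present only as pseudogenes: %s",
                           paste(missing, collapse = ", ")),
                   missing_items = missing)
  } else {
    standard_check("RRNA_SET", "FAIL",
                   sprintf("missing rRNA class(es): %s",
                           paste(setdiff(missing, pseudo_classes), collapse = ", ")),
                   missing_items = setdiff(missing, pseudo_classes))
  }
  attr(chk, "findings") <- findings
  chk
}

#' Check tRNA amino-acid coverage
#'
#' PASS when functional tRNAs cover all 20 standard amino acids; FAIL lists
#' the missing amino acids. An amino acid covered only by a pseudo-tRNA is
#' downgraded to WARN rather than FAIL.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()].
#' @return A `standard_check`.
#' @export
check_trna_set <- function(record, config = qc_config()) {
  trna <- amino_acids_with_trna(record, config)
  missing <- setdiff(AA3, trna$set)
  if (!length(missing)) {
    return(standard_check("TRNA_SET", "PASS",
                          "functional tRNAs cover all 20 standard amino acids"))
  }
  only_pseudo <- missing[missing %in% trna$pseudo_set]
  truly_missing <- setdiff(missing, only_pseudo)
  if (!length(truly_missing)) {
    standard_check("TRNA_SET", "WARN",
                   sprintf("amino acid(s) covered only by pseudo-tRNAs: %s",
                           paste(only_pseudo, collapse = ", ")),
                   missing_items = only_pseudo)
  } else {
    standard_check("TRNA_SET", "FAIL",
                   sprintf("missing tRNA(s) for: %s",
                           paste(truly_missing, collapse = ", ")),
                   missing_items = truly_missing)
  }
}

#' Check presence of core conserved functions
#'
#' Searches non-pseudo CDS `/product` values against each catalog entry's
#' name patterns. FAIL when any core function is fully absent; a function
#' matched only by a pseudogene is a WARN item (an already-annotated
#' pseudogene/frameshift explains the missing protein); matched proteins
#' whose length is outside `expected_len_aa +/- 4 * len_spread_aa` are
#' reported as INFO detail.
#'
#' @param record a [genome_record()].
#' @param catalog a catalog from [load_core_catalog()].
#' @return A `standard_check`.
#' @export
check_core_functions <- function(record, catalog = load_core_catalog()) {
  stopifnot(nrow(catalog) > 0L)
  feats <- list()
  for (r in record$replicons) {
    for (f in r$features) {
      if (f$key == "CDS") feats[[length(feats) + 1L]] <- f
    }
  }
  products <- vapply(feats, function(f) qual_value(f, "product") %||% "", "")
  pseudo <- vapply(feats, is_pseudo, FALSE)
  found <- character(0); pseudo_only <- character(0); missing <- character(0)
  len_notes <- character(0)
  for (i in seq_len(nrow(catalog))) {
    pats <- strsplit(catalog$patterns[i], "|", fixed = TRUE)[[1L]]
    hit <- rep(FALSE, length(products))
    for (p in pats) {
      hit <- hit | grepl(p, products, ignore.case = TRUE, fixed = FALSE)
    }
    id <- catalog$function_id[i]
    if (any(hit & !pseudo)) {
      found <- c(found, id)
      el <- catalog$expected_len_aa[i]; sp <- catalog$len_spread_aa[i]
      if (is.finite(el) && is.finite(sp)) {
        for (j in which(hit & !pseudo)) {
          len <- protein_length_aa(feats[[j]])
          if (abs(len - el) > 4 * sp) {
            len_notes <- c(len_notes, sprintf(
              "%s: matched protein length %d aa outside expected %.1f +/- 4*%.1f",
              id, len, el, sp))
          }
        }
      }
    } else if (any(hit & pseudo)) {
      pseudo_only <- c(pseudo_only, id)
    } else {
      missing <- c(missing, id)
    }
  }
  detail <- sprintf("%d/%d core functions found", length(found), nrow(catalog))
  if (length(len_notes)) {
    detail <- paste(c(detail, len_notes), collapse = "; ")
  }
  if (length(missing)) {
    standard_check("CORE_FUNCS", "FAIL",
                   paste0(detail, "; absent: ", paste(missing, collapse = ", ")),
                   missing_items = missing)
  } else if (length(pseudo_only)) {
    standard_check("CORE_FUNCS", "WARN",
                   paste0(detail, "; present only as pseudogene: ",
                          paste(pseudo_only, collapse = ", ")),
                   missing_items = pseudo_only)
  } else {
    standard_check("CORE_FUNCS", "PASS", detail)
  }
}

#' Check coding density and hypothetical-name ratio
#'
#' DENSITY: WARN when the coding density falls outside the configured
#' expected band. HYPOTHETICAL_RATIO: FAIL when the ratio of hypothetical
#' to total proteins reaches the fail threshold (a genome where every
#' protein is effectively unnamed falls below the minimal standards), WARN
#' at the warn threshold.
#'
#' @param metrics a `metrics_row` from [compute_metrics()].
#' @param config a [qc_config()].
#' @return List of two `standard_check`s.
#' @export
check_density_and_names <- function(metrics, config = qc_config()) {
  d <- metrics$coding_density
  density <- if (is.na(d) || metrics$protein_count == 0L) {
    standard_check("DENSITY", "WARN", "no proteins; density not assessable")
  } else if (d < config$density_lo || d > config$density_hi) {
    standard_check("DENSITY", "WARN",
                   sprintf("coding density %.2f outside expected [%.2f, %.2f]",
                           d, config$density_lo, config$density_hi))
  } else {
    standard_check("DENSITY", "PASS",
                   sprintf("coding density %.2f within expected [%.2f, %.2f]",
                           d, config$density_lo, config$density_hi))
  }
  r <- metrics$hypothetical_ratio
  hyp <- if (is.na(r)) {
    standard_check("HYPOTHETICAL_RATIO", "WARN", "no proteins; ratio not assessable")
  } else if (r >= config$hypothetical_fail) {
    standard_check("HYPOTHETICAL_RATIO", "FAIL",
                   sprintf("hypothetical ratio %.3f >= %.2f: effectively no functional annotation",
                           r, config$hypothetical_fail))
  } else if (r >= config$hypothetical_warn) {
    standard_check("HYPOTHETICAL_RATIO", "WARN",
                   sprintf("hypothetical ratio %.3f >= %.2f", r,
                           config$hypothetical_warn))
  } else {
    standard_check("HYPOTHETICAL_RATIO", "PASS",
                   sprintf("hypothetical ratio %.3f", r))
  }
  list(density, hyp)
}

# --- exemptions -----------------------------------------------------------

EXEMPTION_RE <- "^\\s*annotation-exception:\\s*([A-Z_]+)\\s*:\\s*(.*)$"

# documented exceptions: "annotation-exception: <CHECK_ID>: <free text>" in
# a /note or a structured-comment line
collect_exemptions <- function(record) {
  out <- list()
  texts <- character(0)
  if (!is.null(record$structured_comment)) {
    texts <- c(texts, paste0(names(record$structured_comment), " :: ",
                             record$structured_comment),
               unname(record$structured_comment))
  }
  for (x in all_features(record)) {
    texts <- c(texts, qual_values(x$feature, "note"))
  }
  for (t in texts) {
    m <- regmatches(t, regexec(EXEMPTION_RE, t))[[1L]]
    if (length(m) == 3L && m[2L] %in% CHECK_IDS) {
      out[[m[2L]]] <- m[3L]
    }
  }
  out
}

# --- evaluation -----------------------------------------------------------

findings_to_check <- function(check_id, findings, rule_prefix, detail_ok) {
  sel <- findings[startsWith(findings$rule_id, rule_prefix), , drop = FALSE]
  if (any(sel$severity %in% c("ERROR", "FAIL"))) {
    standard_check(check_id, "FAIL",
                   sprintf("%d blocking finding(s): %s",
                           sum(sel$severity %in% c("ERROR", "FAIL")),
                           paste(unique(sel$rule_id[sel$severity %in%
                                                      c("ERROR", "FAIL")]),
                                 collapse = ", ")))
  } else if (any(sel$severity == "WARN")) {
    standard_check(check_id, "WARN",
                   sprintf("%d warning finding(s): %s", sum(sel$severity == "WARN"),
                           paste(unique(sel$rule_id[sel$severity == "WARN"]),
                                 collapse = ", ")))
  } else {
    standard_check(check_id, "PASS", detail_ok)
  }
}

#' Evaluate a genome against the minimal annotation standards
#'
#' Computes the measure vector, runs every standard check and the full lint
#' rule set, applies documented exceptions (an `annotation-exception:
#' <CHECK_ID>: <text>` note flips a FAIL on that check to EXEMPT), and
#' aggregates the overall status: COMPLIANT when no check FAILs and no
#' ERROR-severity finding exists; COMPLIANT_WITH_EXEMPTIONS when the only
#' FAILs were exempted; NONCOMPLIANT otherwise. Deterministic and pure.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()].
#' @param catalog core-function catalog.
#' @return An object of class `compliance_report`.
#' @export
evaluate <- function(record, config = qc_config(),
                     catalog = load_core_catalog()) {
  metrics <- compute_metrics(record, config)
  findings <- rbind_findings(attr(metrics, "findings"),
                             lint_record(record, config))
  rrna <- check_rrna_set(record)
  findings <- rbind_findings(findings, attr(rrna, "findings"))
  attr(rrna, "findings") <- NULL
  checks <- c(list(rrna,
                   check_trna_set(record, config),
                   check_core_functions(record, catalog)),
              check_density_and_names(metrics, config),
              list(findings_to_check("LOCUS_TAGS", findings, "LT",
                                     "locus_tags present, unique, single prefix"),
                   findings_to_check("PSEUDO_FORMAT", findings, "PSEUDO",
                                     "pseudogene annotations follow accepted formats"),
                   findings_to_check("VALIDATION_CLEAN", findings, "STRUCT",
                                     "feature table structurally valid")))
  names(checks) <- vapply(checks, `[[`, "", "check_id")

  exemptions <- collect_exemptions(record)
  applied <- character(0)
  for (id in names(exemptions)) {
    if (!is.null(checks[[id]]) && checks[[id]]$status == "FAIL") {
      checks[[id]] <- standard_check(
        id, "EXEMPT",
        paste0(checks[[id]]$detail, " [documented exception: ",
               exemptions[[id]], "]"),
        missing_items = checks[[id]]$missing_items)
      applied <- c(applied, id)
    }
  }

  any_fail <- any(vapply(checks, `[[`, "", "status") == "FAIL")
  any_error <- any(findings$severity == "ERROR")
  overall <- if (any_fail || any_error) "NONCOMPLIANT"
  else if (length(applied)) "COMPLIANT_WITH_EXEMPTIONS"
  else "COMPLIANT"

  structure(list(genome = list(organism = record$organism,
                               bioproject = record$bioproject),
                 metrics = metrics, checks = checks, findings = findings,
                 exemptions = exemptions[applied], overall = overall),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("Compliance report:", x$genome$organism, "\n")
  cat("Overall:", x$overall, "\n")
  for (chk in x$checks) print(chk)
  ner <- sum(x$findings$severity == "ERROR")
  cat(sprintf("%d finding(s), %d ERROR\n", nrow(x$findings), ner))
  invisible(x)
}

#' Exit code of a compliance report
#'
#' 0 = COMPLIANT, 1 = COMPLIANT_WITH_EXEMPTIONS, 2 = NONCOMPLIANT.
#'
#' @param report a `compliance_report`.
#' @return Integer.
#' @export
report_exit_code <- function(report) {
  match(report$overall,
        c("COMPLIANT", "COMPLIANT_WITH_EXEMPTIONS", "NONCOMPLIANT")) - 1L
}

report_to_json <- function(report, path = NULL) {
  obj <- list(
    genome = report$genome,
    overall = report$overall,
    checks = lapply(unname(report$checks), function(chk) {
      list(check_id = chk$check_id, status = chk$status,
           detail = chk$detail, missing_items = chk$missing_items)
    }),
    findings = as.data.frame(report$findings),
    metrics = as.list(format_metrics(report$metrics)),
    tool = list(package = "annoqc",
                version = as.character(utils::packageVersion("annoqc")))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}
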