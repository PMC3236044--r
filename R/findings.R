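# Validation findings: one row per rule hit, with a registered rule id and
# a fixed severity scale.
#
# Severity scale: ERROR = violates an INSDC prohibition (record
# unsubmittable); FAIL = violates an accepted minimal standard; WARN =
# outside guideline; INFO = advisory.

SEVERITY_LEVELS <- c("ERROR", "FAIL", "WARN", "INFO")

# rule registry: id, default severity, short description, and whether the
# synthetic-fixture generator can plant a dedicated violation for it.
RULE_REGISTRY <- local({
  df <- read.table(text = '
rule_id|severity|plantable|description
PARSE001|INFO|FALSE|unknown feature key retained verbatim
NAME001|FAIL|TRUE|banned unknown-function product name (only "hypothetical protein" / "uncharacterized protein" are acceptable)
NAME002|WARN|FALSE|leading/trailing/multiple whitespace in product name (style)
NAME003|WARN|FALSE|product name all-uppercase or ends with a bare organism name (style)
NAME004|WARN|FALSE|product name carries vague qualifiers such as homolog/fragment/putative (style)
NAME005|WARN|FALSE|product name is a bare locus_tag or ORF identifier (style)
EV001|FAIL|TRUE|/inference with unknown category or evidence type
EV002|WARN|TRUE|/inference evidence type requires a basis but none given
EV003|FAIL|TRUE|/experiment category token with empty description
PSEUDO001|ERROR|TRUE|/pseudo feature carries /translation or /protein_id (translated products are not allowed on pseudogenes)
PSEUDO002|WARN|TRUE|/pseudo CDS carries /product (product name belongs in /note)
PSEUDO003|FAIL|TRUE|CDS with exception "annotated by transcript or proteomic data" lacking both /experiment and /inference
PSEUDO004|WARN|TRUE|/artificial_location CDS product lacks "LOW-QUALITY PROTEIN:" prefix
PSEUDO005|INFO|TRUE|misc_feature similarity region carries /locus_tag or /gene
PSEUDO006|INFO|TRUE|/pseudogene qualifier accepted as synonym of /pseudo (INSDC proposal pending)
LT001|FAIL|TRUE|duplicate locus_tag on features of the same key
LT002|FAIL|TRUE|more than one locus_tag prefix in one genome
LT003|WARN|TRUE|locus_tag does not match registry syntax (letter start, alphanumeric prefix of length >= 3, single underscore)
LT004|WARN|TRUE|gene/CDS/tRNA/rRNA feature lacking /locus_tag
STRUCT001|WARN|TRUE|CDS without a same-range gene feature
STRUCT002|ERROR|TRUE|computed translation conflicts with /translation
STRUCT003|WARN|TRUE|CDS span not divisible by 3 without partial markers or /exception
STRUCT004|INFO|TRUE|structured metadata comment block absent
STRUCT005|WARN|TRUE|BioProject identifier missing
METRIC001|WARN|FALSE|CDS without /product counted as hypothetical
METRIC002|WARN|FALSE|unparseable tRNA product; amino-acid token set to OTHER
METRIC003|WARN|FALSE|no protein-coding features; protein statistics absent
RRNA001|INFO|FALSE|rRNA with unclassifiable product
OUTLIER001|WARN|FALSE|measure beyond z-score threshold in cohort comparison
', sep = "|", header = TRUE, stringsAsFactors = FALSE, quote = "")
  df
})

#' Catalog of validation rules
#'
#' Every rule id that can appear in a finding, its default severity and a
#' one-line description.
#'
#' @return data.frame with columns rule_id, severity, plantable, description.
#' @export
rule_catalog <- function() RULE_REGISTRY

empty_findings <- function() {
  structure(
    data.frame(rule_id = character(0), severity = character(0),
               replicon = character(0), feature = character(0),
               message = character(0), suggestion = character(0),
               stringsAsFactors = FALSE),
    class = c("qc_findings", "data.frame"))
}

new_finding <- function(rule_id, severity, replicon = "", feature = "",
                        message = "", suggestion = NA_character_) {
  stopifnot(rule_id %in% RULE_REGISTRY$rule_id,
            severity %in% SEVERITY_LEVELS)
  structure(
    data.frame(rule_id = rule_id, severity = severity, replicon = replicon,
               feature = feature, message = message, suggestion = suggestion,
               stringsAsFactors = FALSE),
    class = c("qc_findings", "data.frame"))
}

rbind_findings <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(parts)) return(empty_findings())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, class = c("qc_findings", "data.frame"))
}

#' @export
print.qc_findings <- function(x, ...) {
  if (!nrow(x)) {
    cat("no findings\n")
    return(invisible(x))
  }
  cat(nrow(x), "finding(s):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s %s: %s\n", x$severity[i], x$rule_id[i],
                x$feature[i], x$message[i]))
    if (!is.na(x$suggestion[i])) {
      cat(sprintf("        suggestion: %s\n", x$suggestion[i]))
    }
  }
  invisible(x)
}

#' Write findings as TSV
#'
#' @param findings a findings table.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_findings_tsv <- function(findings, path) {
  utils::write.table(as.data.frame(findings), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
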