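# Annotation-report measures for one genome record: coding density, GC,
# protein length statistics, hypothetical and standard-start ratios, RNA
# counts and tRNA amino-acid coverage.

normalize_product <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

seq_available <- function(replicon) {
  !isFALSE(attr(replicon, "sequence_known"))
}

#' Coding density
#'
#' Annotated protein-coding genes per kilobase of genome. Reported rounded
#' to 2 decimals (half away from zero); the raw value is the return value's
#' `raw` attribute.
#'
#' @param protein_count number of protein-coding genes.
#' @param total_length_kbp genome length in kilobases.
#' @return Density in proteins per kbp (2-decimal), with attribute `raw`.
#' @export
coding_density <- function(protein_count, total_length_kbp) {
  if (total_length_kbp <= 0) stop("total length must be positive")
  raw <- protein_count / total_length_kbp
  structure(round_half_up(raw, 2L), raw = raw)
}

#' Pooled GC percentage
#'
#' `100 * (G + C) / (A + C + G + T)` over all supplied sequences; ambiguity
#' characters are excluded from numerator and denominator.
#'
#' @param seqs character vector (or list) of nucleotide strings.
#' @return GC percent (raw, not rounded).
#' @export
gc_percent <- function(seqs) {
  seqs <- unlist(seqs, use.names = FALSE)
  if (!length(seqs)) stop("no sequences supplied")
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(seqs)), letters = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) stop("sequence with zero unambiguous bases")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

# protein-coding CDS features (non-pseudo; /exception and
# /artificial_location cases still yield products and count as proteins)
protein_features <- function(record) {
  out <- list()
  for (r in record$replicons) {
    for (f in r$features) {
      if (f$key == "CDS" && !is_pseudo(f)) {
        out[[length(out) + 1L]] <- list(replicon = r$name, feature = f)
      }
    }
  }
  out
}

# protein length in amino acids: /translation length when present, else
# span/3 - 1 (stop codon excluded; no -1 when 3'-partial)
protein_length_aa <- function(feature) {
  tr <- qual_value(feature, "translation")
  if (!is.na(tr)) return(nchar(tr))
  span <- loc_span(feature$location)
  len <- span %/% 3L
  if (!feature$location$partial3) len <- len - 1L
  max(len, 0L)
}

#' Protein count and length statistics
#'
#' @param record a [genome_record()].
#' @param short_threshold_aa proteins shorter than this are "short".
#' @return List with `count`, `avg_len` (raw), `min_len`, `short_percent`
#'   (raw), `lengths`, and a `findings` table. With no proteins the
#'   statistics are `NA` and a WARN finding is emitted.
#' @export
protein_stats <- function(record, short_threshold_aa = 150L) {
  pf <- protein_features(record)
  findings <- empty_findings()
  if (!length(pf)) {
    findings <- new_finding("METRIC003", "WARN",
                            message = "no protein-coding features; protein statistics absent")
    return(list(count = 0L, avg_len = NA_real_, min_len = NA_integer_,
                short_percent = NA_real_, lengths = integer(0),
                findings = findings))
  }
  lens <- vapply(pf, function(x) protein_length_aa(x$feature), 0L)
  list(count = length(lens),
       avg_len = mean(lens),
       min_len = min(lens),
       short_percent = 100 * sum(lens < short_threshold_aa) / length(lens),
       lengths = lens,
       findings = findings)
}

#' RNA feature count
#'
#' Counts features whose key is in the configured RNA set (transfer,
#' ribosomal, non-coding, tmRNA by default).
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()].
#' @return Integer count.
#' @export
rna_count <- function(record, config = qc_config()) {
  sum(vapply(all_features(record),
             function(x) x$feature$key %in% config$rna_keys, FALSE))
}

parse_trna_token <- function(product, tokens) {
  m <- regmatches(product, regexec("tRNA-([A-Za-z0-9]+)", product))[[1L]]
  if (length(m) == 2L) {
    hit <- tokens[tolower(tokens) == tolower(m[2L])]
    if (length(hit)) return(hit[[1L]])
  }
  NA_character_
}

#' Amino acids covered by functional tRNAs
#'
#' Parses amino-acid tokens from tRNA `/product` values of the form
#' `tRNA-Xxx`. Pseudo-tRNAs are counted separately and excluded from the
#' functional set; an unparseable product maps to token OTHER with a WARN.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()].
#' @return List: `count`, `set` (functional tokens), `pseudo_set`,
#'   `pseudo_count`, `findings`.
#' @export
amino_acids_with_trna <- function(record, config = qc_config()) {
  findings <- empty_findings()
  fun_set <- character(0); pseudo_set <- character(0); pseudo_n <- 0L
  for (x in all_features(record)) {
    f <- x$feature
    if (f$key != "tRNA") next
    tok <- parse_trna_token(qual_value(f, "product") %||% "", config$trna_tokens)
    if (is.na(tok)) {
      tok <- "OTHER"
      findings <- rbind_findings(findings, new_finding(
        "METRIC002", "WARN", replicon = x$replicon,
        feature = feature_handle(f),
        message = sprintf("unparseable tRNA product '%s'; counted as OTHER",
                          qual_value(f, "product"))))
    }
    if (is_pseudo(f)) {
      pseudo_n <- pseudo_n + 1L
      pseudo_set <- union(pseudo_set, tok)
    } else {
      fun_set <- union(fun_set, tok)
    }
  }
  list(count = length(fun_set), set = fun_set,
       pseudo_set = pseudo_set, pseudo_count = pseudo_n,
       findings = findings)
}

#' Count of hypothetical proteins
#'
#' Non-pseudo CDS whose normalized `/product` (case-folded, trimmed, inner
#' whitespace collapsed) is in the configured hypothetical-name set. A CDS
#' without `/product` counts as hypothetical with a WARN finding.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()] (uses `hypothetical_names`).
#' @return Integer count, with the findings table as attribute `findings`.
#' @export
hypothetical_count <- function(record, config = qc_config()) {
  findings <- empty_findings()
  n <- 0L
  for (x in protein_features(record)) {
    p <- qual_value(x$feature, "product")
    if (is.na(p)) {
      n <- n + 1L
      findings <- rbind_findings(findings, new_finding(
        "METRIC001", "WARN", replicon = x$replicon,
        feature = feature_handle(x$feature),
        message = "CDS without /product counted as hypothetical"))
    } else if (normalize_product(p) %in% config$hypothetical_names) {
      n <- n + 1L
    }
  }
  structure(n, findings = findings)
}

#' Percentage of standard (ATG) start codons
#'
#' Over non-pseudo CDS with a complete 5' end, the fraction whose first
#' strand-aware codon is ATG, times 100. 5'-partial CDS are excluded from
#' numerator and denominator.
#'
#' @param record a [genome_record()].
#' @return Percent (raw); `NA` when no eligible CDS.
#' @export
standard_start_percent <- function(record) {
  n <- 0L; atg <- 0L
  for (r in record$replicons) {
    cds <- Filter(function(f) f$key == "CDS" && !is_pseudo(f), r$features)
    if (length(cds) && !seq_available(r)) {
      stop("sequence unavailable for replicon ", r$name)
    }
    for (f in cds) {
      if (f$location$partial5) next
      nt <- extract_feature_seq(r, f$location)
      if (nchar(nt) < 3L) next
      n <- n + 1L
      if (substr(nt, 1L, 3L) == "ATG") atg <- atg + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  100 * atg / n
}

#' Compute the full annotation-report measure vector
#'
#' Assembles all per-genome measures into a `metrics_row`. Values are kept
#' raw (pre-rounding); [format_metrics()] / [write_metrics_tsv()] apply the
#' report rounding (2 decimals for percents and density, integer average
#' length, half away from zero). Deterministic given record and config.
#'
#' @param record a [genome_record()].
#' @param config a [qc_config()].
#' @return An object of class `metrics_row`; findings in
#'   `attr(,"findings")`.
#' @export
compute_metrics <- function(record, config = qc_config()) {
  findings <- empty_findings()
  seqs <- vapply(record$replicons, `[[`, "", "sequence")
  total_bp <- sum(nchar(seqs))
  seq_ok <- all(vapply(record$replicons, seq_available, TRUE))

  ps <- protein_stats(record, config$short_protein_aa)
  findings <- rbind_findings(findings, ps$findings)
  hyp <- hypothetical_count(record, config)
  findings <- rbind_findings(findings, attr(hyp, "findings"))
  trna <- amino_acids_with_trna(record, config)
  findings <- rbind_findings(findings, trna$findings)

  gc <- if (seq_ok) gc_percent(seqs) else NA_real_
  ssp <- if (seq_ok) standard_start_percent(record) else NA_real_
  if (!seq_ok) {
    # sequence-dependent fields absent; everything else still filled
    gc <- NA_real_
  }

  dens <- coding_density(ps$count, total_bp / 1000)
  row <- list(
    organism = record$organism,
    bioproject = record$bioproject %||% NA_character_,
    replicon_count = length(record$replicons),
    total_length_mbp = total_bp / 1e6,
    gc_percent = gc,
    protein_count = ps$count,
    rna_count = rna_count(record, config),
    trna_aa_count = trna$count,
    trna_aa_set = trna$set,
    hypothetical_count = as.integer(hyp),
    coding_density = attr(dens, "raw"),
    avg_protein_len_aa = ps$avg_len,
    min_protein_len_aa = ps$min_len,
    short_protein_percent = ps$short_percent,
    standard_start_percent = ssp,
    hypothetical_ratio = if (ps$count > 0) as.integer(hyp) / ps$count
                         else NA_real_
  )
  structure(row, class = "metrics_row", findings = findings)
}

#' @export
print.metrics_row <- function(x, ...) {
  cat("<metrics_row> ", x$organism, "\n", sep = "")
  f <- format_metrics(x)
  for (nm in names(f)) cat(sprintf("  %-24s %s\n", nm, f[[nm]]))
  invisible(x)
}

METRICS_COLUMNS <- c("bioproject", "organism", "replicon_count",
                     "total_length_mbp", "gc_percent", "protein_count",
                     "rna_count", "trna_aa_count", "hypothetical_count",
                     "coding_density", "avg_protein_len_aa",
                     "min_protein_len_aa", "short_protein_percent",
                     "standard_start_percent")

#' Report-rounded view of a metrics row
#'
#' @param row a `metrics_row`.
#' @return Named character vector in annotation-report column order.
#' @export
format_metrics <- function(row) {
  fmt2 <- function(v) if (is.na(v)) "" else sprintf("%.2f", round_half_up(v, 2L))
  c(bioproject = if (is.na(row$bioproject)) "" else row$bioproject,
    organism = row$organism,
    replicon_count = as.character(row$replicon_count),
    total_length_mbp = sprintf("%.3f", round_half_up(row$total_length_mbp, 3L)),
    gc_percent = fmt2(row$gc_percent),
    protein_count = as.character(row$protein_count),
    rna_count = as.character(row$rna_count),
    trna_aa_count = as.character(row$trna_aa_count),
    hypothetical_count = as.character(row$hypothetical_count),
    coding_density = fmt2(row$coding_density),
    avg_protein_len_aa = if (is.na(row$avg_protein_len_aa)) "" else
      as.character(round_half_up(row$avg_protein_len_aa, 0L)),
    min_protein_len_aa = if (is.na(row$min_protein_len_aa)) "" else
      as.character(row$min_protein_len_aa),
    short_protein_percent = fmt2(row$short_protein_percent),
    standard_start_percent = fmt2(row$standard_start_percent))
}

#' Write metrics rows as a TSV table
#'
#' One row per genome, in the annotation-report column order.
#'
#' @param rows list of `metrics_row` objects (or a single one).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_metrics_tsv <- function(rows, path) {
  if (inherits(rows, "metrics_row")) rows <- list(rows)
  mat <- do.call(rbind, lapply(rows, format_metrics))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  utils::write.table(df[, METRICS_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
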