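# Run configuration: every threshold used by any metric or check lives
# here, so that no check depends on a hidden constant.

#' Quality-control configuration
#'
#' All tunable thresholds and name sets, with the package defaults:
#'
#' * `short_protein_aa` (150): proteins shorter than this count as "short".
#' * `hypothetical_warn` (0.8) / `hypothetical_fail` (0.95): thresholds on
#'   the hypothetical-protein ratio; a ratio at or above the fail threshold
#'   (every protein effectively unnamed) falls below the minimal standards.
#' * `density_lo` (0.5) / `density_hi` (1.25): expected coding-density band
#'   in proteins per kbp, bracketing the extremes observed in real complete
#'   genomes (0.49 in a degraded intracellular pathogen, 1.19 in a dense
#'   neisserial genome); outside the band is a WARN, not a FAIL, because
#'   real biology produces both ends.
#' * `z_threshold` (3.0): absolute z-score beyond which a cohort measure is
#'   flagged as an outlier.
#' * `hypothetical_names`: normalized product names counted as hypothetical.
#' * `rna_keys`: feature keys counted as RNAs (transfer, ribosomal,
#'   non-coding; `misc_RNA`/`precursor_RNA` excluded by default).
#' * `trna_tokens`: recognized amino-acid tokens in `tRNA-Xxx` products —
#'   the 20 standard amino acids plus Sec, Pyl, fMet, Ile2 and OTHER;
#'   completeness of the functional set is judged on the standard 20.
#'
#' @param ... overrides of any default by name.
#' @return An object of class `qc_config` (a named list).
#' @export
qc_config <- function(...) {
  defaults <- list(
    short_protein_aa = 150L,
    hypothetical_warn = 0.8,
    hypothetical_fail = 0.95,
    density_lo = 0.5,
    density_hi = 1.25,
    z_threshold = 3.0,
    hypothetical_names = c(
      "hypothetical protein", "uncharacterized protein",
      "conserved hypothetical protein", "protein of unknown function",
      "unknown", "unnamed protein product"),
    banned_names = c(
      "conserved hypothetical protein", "novel protein",
      "protein of unknown function", "unknown", "unknown protein",
      "unnamed protein product"),
    vague_name_words = c("homolog", "homologue", "fragment", "putative?"),
    rna_keys = c("tRNA", "rRNA", "ncRNA", "tmRNA"),
    trna_tokens = c(AA3, "Sec", "Pyl", "fMet", "Ile2", "OTHER"),
    naming_style_checks = FALSE,
    transl_table = 11L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  cfg <- defaults
  stopifnot(cfg$short_protein_aa >= 0,
            cfg$hypothetical_warn >= 0, cfg$hypothetical_warn <= 1,
            cfg$hypothetical_fail >= 0, cfg$hypothetical_fail <= 1,
            cfg$density_lo >= 0, cfg$density_hi > cfg$density_lo,
            cfg$z_threshold > 0)
  structure(cfg, class = "qc_config")
}

# the 20 standard amino acids, three-letter tokens as used in tRNA products
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' Read a configuration file
#'
#' Accepts YAML (`.yml`/`.yaml`) or plain `key = value` lines; values parse
#' as numbers where possible, comma-separated lists become vectors.
#'
#' @param path config file.
#' @return A [qc_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    out <- list()
    for (ln in lines) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0L) next
      k <- trimws(substr(ln, 1L, eq - 1L))
      v <- trimws(substr(ln, eq + 1L, nchar(ln)))
      if (grepl(",", v, fixed = TRUE)) {
        v <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
      }
      num <- suppressWarnings(as.numeric(v))
      if (length(num) && !anyNA(num)) v <- num
      out[[k]] <- v
    }
    out
  }
  do.call(qc_config, vals)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[order(names(config))], f)
  unname(tools::md5sum(f))
}

# report rounding: half away from zero, matching the annotation-report
# presentation (e.g. 182 proteins / 160 kbp -> 1.14)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
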