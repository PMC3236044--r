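# Data model for annotated prokaryotic genome records.
#
# Internal coordinates are 0-based half-open throughout; GenBank/GFF3/tbl
# I/O converts to 1-based inclusive at the boundary.

KNOWN_FEATURE_KEYS <- c(
  "source", "gene", "CDS", "tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA",
  "precursor_RNA", "misc_feature", "repeat_region", "mobile_element",
  "regulatory", "operon", "rep_origin"
)

#' Feature location
#'
#' A located span on a replicon: one or more ordered segments (0-based,
#' half-open), a strand, partialness flags and a multi-segment operator.
#' Multi-segment locations arise from interrupted genes, e.g. a frameshifted
#' pseudogene annotated by combining intervals into a single gene.
#'
#' @param segments two-column integer matrix (start, end), 0-based half-open,
#'   in location (biological reading) order along the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param partial5,partial3 logical; TRUE when the corresponding biological
#'   end of the feature extends beyond the annotated span (`<`/`>` markers).
#' @param operator `"single"`, `"join"` or `"order"`.
#' @return An object of class `gb_location`.
#' @export
gb_location <- function(segments, strand = "+", partial5 = FALSE,
                        partial3 = FALSE, operator = NULL) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(segments, ncol = 2, byrow = TRUE)
  }
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) < 1L) stop("location must have at least one segment")
  if (any(segments[, 1] >= segments[, 2])) {
    stop("location segment with start >= end (half-open convention)")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.null(operator)) operator <- if (nrow(segments) > 1L) "join" else "single"
  if (!operator %in% c("single", "join", "order")) {
    stop("operator must be single, join or order")
  }
  structure(
    list(segments = segments, strand = strand,
         partial5 = isTRUE(partial5), partial3 = isTRUE(partial3),
         operator = operator),
    class = "gb_location"
  )
}

loc_span <- function(loc) sum(loc$segments[, 2] - loc$segments[, 1])
loc_min <- function(loc) min(loc$segments[, 1])
loc_max <- function(loc) max(loc$segments[, 2])

#' @export
print.gb_location <- function(x, ...) {
  cat(location_to_text(x), "\n")
  invisible(x)
}

#' Annotated feature
#'
#' A typed annotation (CDS, gene, tRNA, rRNA, ...) with a location and a
#' qualifier multimap. Qualifier names may repeat; flag qualifiers such as
#' `/pseudo` carry `NA` as their value.
#'
#' @param key feature-key token.
#' @param location a [gb_location()].
#' @param qualifiers named list; names are qualifier names (may repeat),
#'   values single strings or `NA` for flags.
#' @return An object of class `gb_feature`.
#' @export
gb_feature <- function(key, location, qualifiers = list()) {
  if (!nzchar(key)) stop("feature key must be non-empty")
  if (!inherits(location, "gb_location")) stop("location must be a gb_location")
  if (length(qualifiers) && is.null(names(qualifiers))) {
    stop("qualifiers must be named")
  }
  qualifiers <- lapply(qualifiers, function(v) {
    if (length(v) == 0L || (length(v) == 1L && is.na(v))) NA_character_
    else as.character(v)
  })
  structure(list(key = key, location = location, qualifiers = qualifiers),
            class = "gb_feature")
}

# qualifier accessors ------------------------------------------------------

#' Qualifier values of a feature
#'
#' @param feature a [gb_feature()].
#' @param name qualifier name.
#' @return `qual_values()`: character vector of all values (empty if absent);
#'   `qual_value()`: first value or `NA`; `has_qual()`: logical.
#' @export
qual_values <- function(feature, name) {
  v <- feature$qualifiers[names(feature$qualifiers) == name]
  if (!length(v)) return(character(0))
  unlist(v, use.names = FALSE)
}

#' @rdname qual_values
#' @export
qual_value <- function(feature, name) {
  v <- qual_values(feature, name)
  if (length(v)) v[[1L]] else NA_character_
}

#' @rdname qual_values
#' @export
has_qual <- function(feature, name) name %in% names(feature$qualifiers)

# /pseudo, accepting /pseudogene (with value) as a synonym
is_pseudo <- function(feature) {
  has_qual(feature, "pseudo") || has_qual(feature, "pseudogene")
}

feature_handle <- function(feature) {
  lt <- qual_value(feature, "locus_tag")
  h <- paste0(feature$key, " ", location_to_text(feature$location))
  if (!is.na(lt)) h <- paste0(h, " [", lt, "]")
  h
}

#' @export
print.gb_feature <- function(x, ...) {
  cat(feature_handle(x), "\n")
  for (i in seq_along(x$qualifiers)) {
    v <- x$qualifiers[[i]]
    cat("  /", names(x$qualifiers)[i],
        if (!is.na(v)) paste0("=\"", v, "\"") else "", "\n", sep = "")
  }
  invisible(x)
}

#' Replicon
#'
#' One chromosome or plasmid: a nucleotide sequence (IUPAC alphabet), a
#' topology and its annotated features.
#'
#' @param name replicon identifier (unique within a record).
#' @param sequence nucleotide string; stored uppercased.
#' @param topology `"linear"` or `"circular"`.
#' @param features list of [gb_feature()].
#' @return An object of class `gb_replicon`.
#' @export
gb_replicon <- function(name, sequence, topology = "linear", features = list()) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("replicon sequence must be non-empty")
  if (!topology %in% c("linear", "circular")) {
    stop("topology must be linear or circular")
  }
  len <- nchar(sequence)
  for (f in features) {
    check_location_bounds(f$location, len, topology,
                          context = feature_handle(f))
  }
  structure(list(name = name, sequence = sequence, topology = topology,
                 features = features),
            class = "gb_replicon")
}

# Origin-spanning locations (first segment start > last segment end) are
# allowed on circular replicons only.
check_location_bounds <- function(loc, len, topology, context = "") {
  if (loc_max(loc) > len) {
    stop(sprintf("feature beyond sequence bounds (%s): %s",
                 topology, context))
  }
  n <- nrow(loc$segments)
  if (n > 1L && loc$segments[1L, 1L] > loc$segments[n, 2L] &&
      topology != "circular") {
    stop(sprintf("origin-spanning location on a linear replicon: %s", context))
  }
  invisible(TRUE)
}

#' Genome record
#'
#' One annotated genome: organism, optional BioProject identifier, one or
#' more replicons, and an optional structured metadata comment block (the
#' key-value block used to record annotation provenance and SOPs).
#'
#' @param organism organism name.
#' @param replicons list of [gb_replicon()]; names must be unique.
#' @param bioproject optional BioProject identifier.
#' @param structured_comment optional named character vector.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(organism, replicons, bioproject = NULL,
                          structured_comment = NULL) {
  if (!length(replicons)) stop("a genome record needs at least one replicon")
  nms <- vapply(replicons, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("replicon names must be unique")
  names(replicons) <- nms
  structure(list(organism = organism, bioproject = bioproject,
                 replicons = replicons,
                 structured_comment = structured_comment),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$organism, "\n", sep = "")
  if (!is.null(x$bioproject)) cat("  BioProject: ", x$bioproject, "\n", sep = "")
  for (r in x$replicons) {
    cat(sprintf("  %s: %d bp (%s), %d features\n",
                r$name, nchar(r$sequence), r$topology, length(r$features)))
  }
  invisible(x)
}

all_features <- function(record) {
  out <- list()
  for (r in record$replicons) {
    for (f in r$features) {
      out[[length(out) + 1L]] <- list(replicon = r$name, feature = f)
    }
  }
  out
}

# sequence operations ------------------------------------------------------

revcomp <- function(nt) {
  if (!nchar(nt)) return(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Extract the nucleotide sequence of a location
#'
#' Segments are concatenated in location order, then the whole concatenation
#' is reverse-complemented when the strand is reverse. Origin-spanning
#' locations on circular replicons are supported (as multi-segment joins).
#'
#' @param replicon a [gb_replicon()].
#' @param location a [gb_location()].
#' @return Nucleotide string.
#' @export
extract_feature_seq <- function(replicon, location) {
  check_location_bounds(location, nchar(replicon$sequence),
                        replicon$topology)
  parts <- apply(location$segments, 1L, function(seg) {
    substr(replicon$sequence, seg[1L] + 1L, seg[2L])
  })
  nt <- paste(parts, collapse = "")
  if (location$strand == "-") nt <- revcomp(nt) else nt
}

genetic_code_table <- function(transl_table = 11L) {
  Biostrings::getGeneticCode(as.character(transl_table))
}

#' Translate a CDS nucleotide sequence
#'
#' Codon-by-codon translation under an NCBI genetic-code table (default 11,
#' the bacterial/archaeal/plastid code). The initial codon is rendered "M"
#' unless the CDS is 5'-partial; a trailing stop codon is dropped; codons
#' containing ambiguity characters translate to "X". An internal stop codon
#' is an error (condition class `annoqc_internal_stop`, carrying the codon
#' index as `codon_index`), never silently translated.
#'
#' @param nt nucleotide string (coding strand).
#' @param transl_table NCBI genetic-code table number.
#' @param partial5 TRUE when the CDS lacks its true start codon.
#' @param partial3 TRUE when the CDS lacks its stop codon.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nt, transl_table = 11L, partial5 = FALSE,
                          partial3 = FALSE) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L && !partial5 && !partial3) {
    stop("length not multiple of 3")
  }
  code <- genetic_code_table(transl_table)
  ncod <- n %/% 3L
  if (ncod < 1L) stop("sequence shorter than one codon")
  codons <- substring(nt, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"   # ambiguity codes
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (!length(aa)) stop("nothing to translate after removing trailing stop")
  internal <- which(aa == "*")
  if (length(internal)) {
    cond <- structure(
      class = c("annoqc_internal_stop", "error", "condition"),
      list(message = sprintf("internal stop codon at codon %d", internal[1L]),
           call = sys.call(-1L), codon_index = internal[1L]))
    stop(cond)
  }
  if (!partial5) aa[1L] <- "M"
  paste(aa, collapse = "")
}

# translation of a located CDS feature on its replicon
translate_feature <- function(replicon, feature) {
  tt <- qual_value(feature, "transl_table")
  tt <- if (is.na(tt)) 11L else as.integer(tt)
  nt <- extract_feature_seq(replicon, feature$location)
  translate_cds(nt, transl_table = tt,
                partial5 = feature$location$partial5,
                partial3 = feature$location$partial3)
}

# structural equality used by the round-trip oracles ----------------------

location_equal <- function(a, b) {
  identical(unname(a$segments), unname(b$segments)) &&
    a$strand == b$strand && a$partial5 == b$partial5 &&
    a$partial3 == b$partial3 && a$operator == b$operator
}

feature_equal <- function(a, b) {
  if (a$key != b$key || !location_equal(a$location, b$location)) return(FALSE)
  qa <- a$qualifiers; qb <- b$qualifiers
  if (length(qa) != length(qb)) return(FALSE)
  if (!identical(names(qa), names(qb))) return(FALSE)
  all(mapply(function(x, y) identical(is.na(x), is.na(y)) &&
               (is.na(x) || x == y), qa, qb))
}

#' Field-by-field equality of two genome records
#'
#' Used by the parse/write round-trip oracles: organism, bioproject,
#' structured comment, replicon names/sequences/topologies and every
#' feature (key, location, qualifier multimap) must agree.
#'
#' @param a,b [genome_record()] objects.
#' @return Logical.
#' @export
record_equal <- function(a, b) {
  if (!identical(a$organism, b$organism)) return(FALSE)
  if (!identical(a$bioproject, b$bioproject)) return(FALSE)
  sa <- a$structured_comment; sb <- b$structured_comment
  if (is.null(sa) != is.null(sb)) return(FALSE)
  if (!is.null(sa) && !identical(sa[order(names(sa))], sb[order(names(sb))])) {
    return(FALSE)
  }
  if (length(a$replicons) != length(b$replicons)) return(FALSE)
  for (i in seq_along(a$replicons)) {
    ra <- a$replicons[[i]]; rb <- b$replicons[[i]]
    if (ra$name != rb$name || ra$sequence != rb$sequence ||
        ra$topology != rb$topology) return(FALSE)
    if (length(ra$features) != length(rb$features)) return(FALSE)
    for (j in seq_along(ra$features)) {
      if (!feature_equal(ra$features[[j]], rb$features[[j]])) return(FALSE)
    }
  }
  TRUE
}
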