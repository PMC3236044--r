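# GFF3 (+ FASTA) reader and writer.
#
# CDS parts sharing an ID merge into one multi-segment feature; pseudo=true
# (or a pseudogene attribute) maps to the /pseudo flag; product, locus_tag,
# inference, experiment and other attributes map to qualifiers of the same
# name. Record-level fields travel as pragmas (##organism, ##bioproject,
# ##genome-topology, ##annotation-comment) so that a record written as GFF3
# reparses to an equivalent record.

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

gff_unescape <- function(x) utils::URLdecode(x)

#' Write a genome record as GFF3 (+ embedded FASTA)
#'
#' @param record a [genome_record()].
#' @param path optional output file.
#' @param fasta include a `##FASTA` section with the replicon sequences.
#' @return GFF3 text (invisibly when `path` given).
#' @export
write_gff3 <- function(record, path = NULL, fasta = TRUE) {
  out <- "##gff-version 3"
  out <- c(out, paste0("##organism ", record$organism))
  if (!is.null(record$bioproject)) {
    out <- c(out, paste0("##bioproject ", record$bioproject))
  }
  if (!is.null(record$structured_comment)) {
    sc <- record$structured_comment
    for (k in names(sc)) {
      out <- c(out, paste0("##annotation-comment ", k, " :: ", sc[[k]]))
    }
  }
  for (r in record$replicons) {
    out <- c(out, sprintf("##sequence-region %s 1 %d", r$name,
                          nchar(r$sequence)))
    if (r$topology == "circular") {
      out <- c(out, paste0("##genome-topology ", r$name, " circular"))
    }
  }
  fid <- 0L
  for (r in record$replicons) {
    for (f in r$features) {
      fid <- fid + 1L
      loc <- f$location
      attrs <- c(sprintf("ID=f%06d", fid))
      if (loc$partial5) attrs <- c(attrs, "partial5=true")
      if (loc$partial3) attrs <- c(attrs, "partial3=true")
      if (loc$operator == "order") attrs <- c(attrs, "part_operator=order")
      for (qi in seq_along(f$qualifiers)) {
        nm <- names(f$qualifiers)[qi]
        v <- f$qualifiers[[qi]]
        if (nm %in% c("pseudo", "pseudogene") && is.na(v)) {
          attrs <- c(attrs, paste0(nm, "=true"))
        } else if (is.na(v)) {
          attrs <- c(attrs, paste0(nm, "=true"))
        } else {
          attrs <- c(attrs, paste0(nm, "=", gff_escape(v)))
        }
      }
      attr_str <- paste(attrs, collapse = ";")
      segs <- loc$segments
      phase_base <- 0L
      for (i in seq_len(nrow(segs))) {
        phase <- if (f$key == "CDS") {
          as.character(phase_base %% 3L)
        } else "."
        out <- c(out, paste(r$name, "annoqc", f$key,
                            segs[i, 1L] + 1L, segs[i, 2L], ".",
                            loc$strand, phase, attr_str, sep = "\t"))
        phase_base <- (3L - ((segs[i, 2L] - segs[i, 1L] - phase_base) %% 3L)) %% 3L
      }
    }
  }
  if (fasta) {
    out <- c(out, "##FASTA")
    for (r in record$replicons) {
      out <- c(out, paste0(">", r$name))
      len <- nchar(r$sequence)
      starts <- seq(1L, len, by = 60L)
      out <- c(out, substring(r$sequence, starts, pmin(starts + 59L, len)))
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

parse_fasta_text <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) return(list())
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[i]])
    body <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    out[[nm]] <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  out
}

#' Read GFF3 into a genome record
#'
#' Sequences come from the embedded `##FASTA` section or from `fasta`. A
#' record parsed without sequence still supports sequence-independent
#' metrics; sequence-dependent operations raise a "sequence unavailable"
#' error when they are actually requested.
#'
#' @param x GFF3 file path, string or lines.
#' @param fasta optional FASTA file path, string or lines.
#' @return A [genome_record()].
#' @export
read_gff3 <- function(x, fasta = NULL) {
  lines <- as_lines(x)
  if (!length(grep("^##gff-version", lines))) {
    stop("missing ##gff-version directive")
  }
  fasta_i <- grep("^##FASTA", lines)
  seqs <- list()
  if (length(fasta_i)) {
    seqs <- parse_fasta_text(lines[(fasta_i[1L] + 1L):length(lines)])
    lines <- lines[seq_len(fasta_i[1L] - 1L)]
  }
  if (!is.null(fasta)) seqs <- parse_fasta_text(as_lines(fasta))

  organism <- "unknown organism"; bioproject <- NULL
  scomment <- character(0)
  region_len <- integer(0)
  topo <- character(0)
  for (ln in grep("^##", lines, value = TRUE)) {
    if (startsWith(ln, "##organism ")) organism <- trimws(sub("^##organism ", "", ln))
    if (startsWith(ln, "##bioproject ")) bioproject <- trimws(sub("^##bioproject ", "", ln))
    if (startsWith(ln, "##annotation-comment ")) {
      p <- strsplit(sub("^##annotation-comment ", "", ln), " :: ", fixed = TRUE)[[1L]]
      if (length(p) == 2L) scomment[p[1L]] <- p[2L]
    }
    if (startsWith(ln, "##sequence-region ")) {
      p <- strsplit(trimws(ln), "\\s+")[[1L]]
      region_len[p[2L]] <- as.integer(p[4L])
    }
    if (startsWith(ln, "##genome-topology ")) {
      p <- strsplit(trimws(ln), "\\s+")[[1L]]
      topo[p[2L]] <- p[3L]
    }
  }

  rows <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  anon <- 0L
  feats_by_rep <- list()   # replicon -> list of feature build states keyed by ID
  order_by_rep <- list()
  for (ln in rows) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(p) < 9L) stop("malformed GFF3 row: ", ln)
    seqid <- p[1L]; type <- p[3L]
    start <- as.integer(p[4L]); end <- as.integer(p[5L])
    strand <- if (p[7L] %in% c("+", "-")) p[7L] else "+"
    if (!is.na(region_len[seqid]) && length(region_len) &&
        seqid %in% names(region_len) && end > region_len[[seqid]]) {
      stop(sprintf("coordinate %d outside region bounds of %s", end, seqid))
    }
    attrs <- strsplit(p[9L], ";", fixed = TRUE)[[1L]]
    kv <- list()
    for (a in attrs) {
      if (!nzchar(a)) next
      eq <- regexpr("=", a, fixed = TRUE)
      if (eq < 0L) next
      kv[[length(kv) + 1L]] <- c(substr(a, 1L, eq - 1L),
                                 gff_unescape(substr(a, eq + 1L, nchar(a))))
    }
    nm <- vapply(kv, `[[`, "", 1L)
    anon <- anon + 1L
    id <- if ("ID" %in% nm) kv[[which(nm == "ID")[1L]]][2L] else
      sprintf(".anon%06d", anon)
    key <- paste0(seqid, "\r", type, "\r", id)
    if (is.null(feats_by_rep[[seqid]])) {
      feats_by_rep[[seqid]] <- list()
      order_by_rep[[seqid]] <- character(0)
    }
    st <- feats_by_rep[[seqid]][[key]]
    if (is.null(st)) {
      quals <- list()
      partial5 <- FALSE; partial3 <- FALSE; op <- NULL
      for (pair in kv) {
        k <- pair[1L]; v <- pair[2L]
        if (k %in% c("ID", "Parent")) next
        if (k == "partial5") { partial5 <- identical(v, "true"); next }
        if (k == "partial3") { partial3 <- identical(v, "true"); next }
        if (k == "part_operator") { op <- v; next }
        if (k %in% c("pseudo", "pseudogene") &&
            tolower(v) %in% c("true", "1", "yes")) {
          quals[[length(quals) + 1L]] <- NA_character_
          names(quals)[length(quals)] <- "pseudo"
          next
        }
        if (identical(v, "true") &&
            k %in% c("artificial_location", "ribosomal_slippage")) {
          quals[[length(quals) + 1L]] <- NA_character_
          names(quals)[length(quals)] <- k
          next
        }
        quals[[length(quals) + 1L]] <- v
        names(quals)[length(quals)] <- k
      }
      st <- list(type = type, strand = strand, segs = list(),
                 quals = quals, partial5 = partial5, partial3 = partial3,
                 operator = op)
      order_by_rep[[seqid]] <- c(order_by_rep[[seqid]], key)
    }
    st$segs[[length(st$segs) + 1L]] <- c(start - 1L, end)
    feats_by_rep[[seqid]][[key]] <- st
  }

  rep_names <- unique(c(names(region_len), names(feats_by_rep), names(seqs)))
  if (!length(rep_names)) stop("no sequence regions or features found")
  replicons <- list()
  for (rn in rep_names) {
    sq <- seqs[[rn]]
    if (is.null(sq)) {
      # sequence unavailable: placeholder of Ns so the record is still usable
      # for sequence-independent metrics
      ln <- region_len[[rn]]
      if (is.null(ln) || is.na(ln)) {
        ln <- max(vapply(feats_by_rep[[rn]],
                         function(s) max(vapply(s$segs, `[[`, 0L, 2L)), 0L))
      }
      sq <- strrep("N", ln)
      seq_known <- FALSE
    } else seq_known <- TRUE
    feats <- list()
    for (key in order_by_rep[[rn]]) {
      st <- feats_by_rep[[rn]][[key]]
      segs <- do.call(rbind, st$segs)
      segs <- segs[order(segs[, 1L]), , drop = FALSE]
      loc <- gb_location(segs, strand = st$strand,
                         partial5 = st$partial5, partial3 = st$partial3,
                         operator = st$operator %||%
                           if (nrow(segs) > 1L) "join" else "single")
      feats[[length(feats) + 1L]] <- gb_feature(st$type, loc, st$quals)
    }
    rep <- gb_replicon(rn, sq,
                       topology = if (identical(topo[rn][[1L]] %||% "linear",
                                                "circular")) "circular" else "linear",
                       features = feats)
    attr(rep, "sequence_known") <- seq_known
    replicons[[length(replicons) + 1L]] <- rep
  }
  genome_record(organism, replicons, bioproject = bioproject,
                structured_comment = if (length(scomment)) scomment else NULL)
}
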