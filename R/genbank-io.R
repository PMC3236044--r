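# GenBank flat-file dialect: reader, writer, and the INSDC 5-column
# feature table (.tbl) writer used by submission tooling.

as_lines <- function(x) {
  if (length(x) == 1L && (grepl("\n", x, fixed = TRUE) || !file.exists(x))) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  if (length(x) == 1L && file.exists(x)) return(readLines(x, warn = FALSE))
  x
}

# location text <-> gb_location -------------------------------------------

#' Parse an INSDC location string
#'
#' Handles `complement()`, `join()`, `order()`, single bases, and the
#' `<`/`>` partialness markers. External coordinates are 1-based inclusive;
#' the returned [gb_location()] is 0-based half-open.
#'
#' @param txt location string, e.g. `"complement(join(10..30,40..60))"`.
#' @return A [gb_location()].
#' @export
parse_location_text <- function(txt) {
  raw <- gsub("[[:space:]]", "", txt)
  s <- raw
  strand <- "+"
  if (grepl("^complement\\(", s)) {
    if (!endsWith(s, ")")) stop("malformed location: ", txt)
    s <- substr(s, nchar("complement(") + 1L, nchar(s) - 1L)
    strand <- "-"
  }
  operator <- "single"
  for (op in c("join", "order")) {
    pre <- paste0(op, "(")
    if (startsWith(s, pre)) {
      if (!endsWith(s, ")")) stop("malformed location: ", txt)
      s <- substr(s, nchar(pre) + 1L, nchar(s) - 1L)
      operator <- op
      break
    }
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("malformed location: ", txt)
  partial5 <- FALSE; partial3 <- FALSE
  segs <- matrix(0L, nrow = length(parts), ncol = 2L)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    lt <- grepl("<", p, fixed = TRUE)
    gt <- grepl(">", p, fixed = TRUE)
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1L]]
    if (!length(m)) stop("malformed location: ", txt)
    a <- as.integer(m[2L])
    b <- if (nzchar(m[4L] %||% "")) as.integer(m[4L]) else a
    if (a > b) stop("malformed location (start > end): ", txt)
    segs[i, ] <- c(a - 1L, b)   # to 0-based half-open
    # < marks the lower coordinate, > the upper; map to biological 5'/3'
    if (lt) { if (strand == "+") partial5 <- TRUE else partial3 <- TRUE }
    if (gt) { if (strand == "+") partial3 <- TRUE else partial5 <- TRUE }
  }
  if (length(parts) == 1L && operator == "single") operator <- "single"
  gb_location(segs, strand = strand, partial5 = partial5,
              partial3 = partial3,
              operator = if (nrow(segs) > 1L && operator == "single") "join"
                         else operator)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Render a location as INSDC location text
#'
#' @param loc a [gb_location()].
#' @return Location string (1-based inclusive coordinates).
#' @export
location_to_text <- function(loc) {
  segs <- loc$segments
  n <- nrow(segs)
  lt_i <- gt_i <- 0L
  if (loc$strand == "+") {
    if (loc$partial5) lt_i <- 1L
    if (loc$partial3) gt_i <- n
  } else {
    if (loc$partial3) lt_i <- 1L
    if (loc$partial5) gt_i <- n
  }
  parts <- vapply(seq_len(n), function(i) {
    a <- segs[i, 1L] + 1L; b <- segs[i, 2L]
    lo <- paste0(if (i == lt_i) "<" else "", a)
    hi <- paste0(if (i == gt_i) ">" else "", b)
    if (a == b && !loc$partial5 && !loc$partial3) as.character(a)
    else paste0(lo, "..", hi)
  }, "")
  s <- if (n > 1L) {
    paste0(if (loc$operator == "order") "order(" else "join(",
           paste(parts, collapse = ","), ")")
  } else parts
  if (loc$strand == "-") paste0("complement(", s, ")") else s
}

# reader -------------------------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses one or more LOCUS...// blocks into a single [genome_record()] with
#' one replicon per block. Feature keys, locations (complement/join/order,
#' partial markers) and qualifiers are preserved verbatim; the ORIGIN
#' sequence is uppercased. Unknown feature keys are retained and reported as
#' INFO findings (attached as `attr(record, "findings")`) — the validator
#' must not destroy evidence.
#'
#' @param x file path, single string, or character vector of lines.
#' @return A [genome_record()]; parse-time findings in `attr(,"findings")`.
#' @export
read_genbank <- function(x) {
  lines <- as_lines(x)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS block found")
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts)) stop("unterminated LOCUS block")
  organism <- NULL; bioproject <- NULL; scomment <- NULL
  replicons <- list()
  findings <- empty_findings()
  for (bi in seq_along(starts)) {
    block <- lines[starts[bi]:ends[bi]]
    parsed <- parse_genbank_block(block, first_line = starts[bi])
    if (bi == 1L) {
      organism <- parsed$organism
      bioproject <- parsed$bioproject
      scomment <- parsed$structured_comment
    }
    replicons[[length(replicons) + 1L]] <- parsed$replicon
    findings <- rbind_findings(findings, parsed$findings)
  }
  rec <- genome_record(organism %||% "unknown organism", replicons,
                       bioproject = bioproject,
                       structured_comment = scomment)
  attr(rec, "findings") <- findings
  rec
}

parse_genbank_block <- function(block, first_line = 1L) {
  locus <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
  name <- locus[2L]
  topology <- if ("circular" %in% locus) "circular" else "linear"
  organism <- NULL; bioproject <- NULL
  org_i <- grep("^  ORGANISM", block)
  if (length(org_i)) organism <- trimws(sub("^  ORGANISM", "", block[org_i[1L]]))
  if (is.null(organism)) {
    def_i <- grep("^DEFINITION", block)
    if (length(def_i)) {
      organism <- sub("\\.$", "", trimws(sub("^DEFINITION", "", block[def_i[1L]])))
    }
  }
  db_i <- grep("^DBLINK", block)
  if (length(db_i)) {
    m <- regmatches(block[db_i[1L]],
                    regexec("BioProject:\\s*(\\S+)", block[db_i[1L]]))[[1L]]
    if (length(m) == 2L) bioproject <- m[2L]
  }
  scomment <- parse_structured_comment(block)

  feat_i <- grep("^FEATURES", block)
  orig_i <- grep("^ORIGIN", block)
  seq_str <- ""
  if (length(orig_i)) {
    seq_lines <- block[(orig_i[1L] + 1L):(length(block) - 1L)]
    seq_str <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  features <- list()
  findings <- empty_findings()
  if (length(feat_i)) {
    stop_i <- if (length(orig_i)) orig_i[1L] else length(block)
    if (stop_i - feat_i[1L] > 1L) {
      flines <- block[(feat_i[1L] + 1L):(stop_i - 1L)]
      parsed <- parse_feature_lines(flines, name,
                                    line_offset = first_line + feat_i[1L])
      features <- parsed$features
      findings <- parsed$findings
    }
  }
  replicon <- gb_replicon(name, seq_str, topology = topology,
                          features = features)
  list(replicon = replicon, organism = organism, bioproject = bioproject,
       structured_comment = scomment, findings = findings)
}

parse_structured_comment <- function(block) {
  s_i <- grep("-START##", block, fixed = TRUE)
  e_i <- grep("-END##", block, fixed = TRUE)
  if (!length(s_i) || !length(e_i)) return(NULL)
  body <- block[(s_i[1L] + 1L):(e_i[1L] - 1L)]
  out <- character(0)
  for (ln in body) {
    p <- strsplit(trimws(ln), " :: ", fixed = TRUE)[[1L]]
    if (length(p) == 2L) out[p[1L]] <- p[2L]
  }
  if (length(out)) out else NULL
}

parse_feature_lines <- function(flines, replicon_name, line_offset = 0L) {
  features <- list()
  findings <- empty_findings()
  cur_key <- NULL; cur_loctxt <- NULL; cur_quals <- list()
  cur_qual_name <- NULL; cur_qual_val <- NULL; in_quote <- FALSE
  loc_open <- FALSE

  flush_qual <- function() {
    if (!is.null(cur_qual_name)) {
      cur_quals[[length(cur_quals) + 1L]] <<- cur_qual_val
      names(cur_quals)[length(cur_quals)] <<- cur_qual_name
      cur_qual_name <<- NULL; cur_qual_val <<- NULL; in_quote <<- FALSE
    }
  }
  flush_feature <- function() {
    flush_qual()
    if (!is.null(cur_key)) {
      loc <- parse_location_text(cur_loctxt)
      features[[length(features) + 1L]] <<-
        gb_feature(cur_key, loc, cur_quals)
      if (!cur_key %in% KNOWN_FEATURE_KEYS) {
        findings <<- rbind_findings(findings, new_finding(
          "PARSE001", "INFO", replicon = replicon_name,
          feature = paste(cur_key, cur_loctxt),
          message = sprintf("unknown feature key '%s' retained", cur_key)))
      }
      cur_key <<- NULL; cur_loctxt <<- NULL; cur_quals <<- list()
      loc_open <<- FALSE
    }
  }
  start_qual <- function(text) {
    flush_qual()
    m <- regmatches(text, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", text))[[1L]]
    if (!length(m)) stop("malformed qualifier line: ", text)
    cur_qual_name <<- m[2L]
    if (!nzchar(m[3L])) {           # flag qualifier
      cur_qual_val <<- NA_character_
    } else {
      v <- m[4L]
      if (startsWith(v, "\"")) {
        if (nchar(v) > 1L && endsWith(v, "\"")) {
          cur_qual_val <<- substr(v, 2L, nchar(v) - 1L)
        } else {
          cur_qual_val <<- substr(v, 2L, nchar(v))
          in_quote <<- TRUE
        }
      } else cur_qual_val <<- v
    }
  }

  for (i in seq_along(flines)) {
    line <- flines[i]
    if (!nzchar(trimws(line))) next
    key_field <- substr(line, 6L, 20L)
    content <- trimws(substr(line, 21L, nchar(line)))
    if (nzchar(trimws(key_field)) && substr(line, 1L, 5L) == "     ") {
      flush_feature()
      cur_key <- trimws(key_field)
      cur_loctxt <- content
      loc_open <- TRUE
    } else if (startsWith(content, "/") && !in_quote) {
      loc_open <- FALSE
      start_qual(content)
    } else if (in_quote) {
      joiner <- if (identical(cur_qual_name, "translation")) "" else " "
      if (endsWith(content, "\"")) {
        cur_qual_val <- paste0(cur_qual_val, joiner,
                               substr(content, 1L, nchar(content) - 1L))
        in_quote <- FALSE
      } else {
        cur_qual_val <- paste0(cur_qual_val, joiner, content)
      }
    } else if (loc_open) {
      cur_loctxt <- paste0(cur_loctxt, content)
    } else if (!is.null(cur_qual_name)) {
      cur_qual_val <- paste0(cur_qual_val, " ", content)
    } else {
      stop(sprintf("malformed feature table near line %d: %s",
                   line_offset + i, line))
    }
  }
  flush_feature()
  list(features = features, findings = findings)
}

# writer -------------------------------------------------------------------

wrap_qualifier <- function(name, value, width = 79L, indent = 21L) {
  pad <- strrep(" ", indent)
  if (is.na(value)) return(paste0(pad, "/", name))
  first <- paste0(pad, "/", name, "=\"")
  avail1 <- width - nchar(first)
  avail <- width - indent
  if (name == "translation") {
    # hard wrap; parse rejoins translation continuations without a space
    out <- character(0)
    rem <- paste0(value, "\"")
    take <- min(avail1, nchar(rem))
    out <- paste0(first, substr(rem, 1L, take))
    rem <- substr(rem, take + 1L, nchar(rem))
    while (nchar(rem)) {
      take <- min(avail, nchar(rem))
      out <- c(out, paste0(pad, substr(rem, 1L, take)))
      rem <- substr(rem, take + 1L, nchar(rem))
    }
    return(out)
  }
  if (!grepl(" ", value, fixed = TRUE) || grepl("  ", value, fixed = TRUE)) {
    # unwrappable without loss: emit on one (possibly long) line
    return(paste0(first, value, "\""))
  }
  # word wrap, rejoined with a single space on parse
  words <- strsplit(paste0(value, "\""), " ", fixed = TRUE)[[1L]]
  lines <- character(0)
  cur <- paste0(first, words[1L])
  for (w in words[-1L]) {
    if (nchar(cur) + 1L + nchar(w) <= width) {
      cur <- paste0(cur, " ", w)
    } else {
      lines <- c(lines, cur)
      cur <- paste0(pad, w)
    }
  }
  c(lines, cur)
}

#' Write a genome record as a GenBank flat file
#'
#' Output is deterministic (fixed LOCUS date) and reparses to an equal
#' record: `record_equal(read_genbank(write_genbank(x)), x)` holds for all
#' records produced by the package.
#'
#' @param record a [genome_record()].
#' @param path optional output file; when `NULL` the text is returned.
#' @return Character scalar of flat-file text (invisibly when `path` given).
#' @export
write_genbank <- function(record, path = NULL) {
  out <- character(0)
  first <- TRUE
  for (r in record$replicons) {
    len <- nchar(r$sequence)
    out <- c(out, sprintf("LOCUS       %-16s %10d bp    DNA     %-8s BCT 01-JAN-2011",
                          r$name, len, r$topology))
    out <- c(out, paste0("DEFINITION  ", record$organism, "."))
    if (first && !is.null(record$bioproject)) {
      out <- c(out, paste0("DBLINK      BioProject: ", record$bioproject))
    }
    out <- c(out, paste0("SOURCE      ", record$organism),
             paste0("  ORGANISM  ", record$organism))
    if (first && !is.null(record$structured_comment)) {
      sc <- record$structured_comment
      out <- c(out, "COMMENT     ##Genome-Annotation-Data-START##")
      for (k in names(sc)) {
        out <- c(out, paste0("            ", k, " :: ", sc[[k]]))
      }
      out <- c(out, "            ##Genome-Annotation-Data-END##")
    }
    out <- c(out, "FEATURES             Location/Qualifiers")
    for (f in r$features) {
      out <- c(out, sprintf("     %-16s%s", f$key,
                            location_to_text(f$location)))
      for (qi in seq_along(f$qualifiers)) {
        out <- c(out, wrap_qualifier(names(f$qualifiers)[qi],
                                     f$qualifiers[[qi]]))
      }
    }
    out <- c(out, "ORIGIN")
    seq_lc <- tolower(r$sequence)
    starts <- seq(1L, len, by = 60L)
    for (s in starts) {
      chunk <- substr(seq_lc, s, min(s + 59L, len))
      tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
      out <- c(out, paste0(formatC(s, width = 9L), " ",
                           paste(tens, collapse = " ")))
    }
    out <- c(out, "//")
    first <- FALSE
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Write an INSDC 5-column feature table (.tbl)
#'
#' Coordinates are 1-based inclusive; on the minus strand intervals are
#' written in translation order with start > end; `<`/`>` mark partial 5'/3'
#' ends on the first/last written coordinate.
#'
#' @param record a [genome_record()].
#' @param path optional output file.
#' @return Character scalar of .tbl text (invisibly when `path` given).
#' @export
write_feature_table <- function(record, path = NULL) {
  out <- character(0)
  for (r in record$replicons) {
    out <- c(out, paste0(">Feature ", r$name))
    for (f in r$features) {
      loc <- f$location
      segs <- loc$segments
      ivs <- lapply(seq_len(nrow(segs)), function(i) {
        c(segs[i, 1L] + 1L, segs[i, 2L])
      })
      if (loc$strand == "-") {
        ivs <- rev(lapply(ivs, function(v) c(v[2L], v[1L])))
      }
      for (i in seq_along(ivs)) {
        a <- as.character(ivs[[i]][1L]); b <- as.character(ivs[[i]][2L])
        if (i == 1L && loc$partial5) a <- paste0("<", a)
        if (i == length(ivs) && loc$partial3) b <- paste0(">", b)
        out <- c(out, if (i == 1L) paste(a, b, f$key, sep = "\t")
                 else paste(a, b, sep = "\t"))
      }
      for (qi in seq_along(f$qualifiers)) {
        v <- f$qualifiers[[qi]]
        nm <- names(f$qualifiers)[qi]
        out <- c(out, if (is.na(v)) paste0("\t\t\t", nm)
                 else paste0("\t\t\t", nm, "\t", v))
      }
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
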