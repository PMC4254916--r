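# Minimal GenBank flat-file (GBFF) record reader and writer.
#
# Only what voucher extraction needs: record boundaries ("//"), the LOCUS
# and ACCESSION lines, and the qualifiers of the FEATURES source feature
# with continuation-line unwrapping. Reads plain-text GBFF only.

# Parse a GBFF file into a list of records:
# list(accession, locus, voucher = character vector of /specimen_voucher
# values, n_qualifiers_seen)
read_gbff_records <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) return(list())
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) {
    stop("malformed GenBank flat file (no record terminator '//'): ", path,
         call. = FALSE)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:(ends[k] - 1L)]
    rec <- rec[nzchar(trimws(rec))]
    if (length(rec) == 0L) next
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (length(locus_line) == 0L) {
      stop(sprintf(
        "malformed GenBank flat file: record %d (line %d) has no LOCUS line",
        k, starts[k]), call. = FALSE)
    }
    locus <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]
    acc_line <- grep("^ACCESSION", rec, value = TRUE)
    accession <- if (length(acc_line) > 0L) {
      strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
    } else {
      locus
    }
    quals <- gbff_source_qualifiers(rec)
    vouchers <- quals$value[quals$name == "specimen_voucher"]
    out[[k]] <- list(accession = accession, locus = locus,
                     vouchers = vouchers)
  }
  out[!vapply(out, is.null, logical(1))]
}

# Extract qualifiers of the first "source" feature in a record's FEATURES
# block, unwrapping continuation lines and stripping surrounding quotes.
gbff_source_qualifiers <- function(rec) {
  none <- data.frame(name = character(), value = character())
  fstart <- grep("^FEATURES", rec)
  if (length(fstart) == 0L) return(none)
  # FEATURES block ends at the next top-level (column-1) keyword
  body <- rec[-seq_len(fstart[1])]
  top <- grep("^[A-Z]", body)
  if (length(top) > 0L) body <- body[seq_len(top[1] - 1L)]
  # feature keys sit at column 6 (5 spaces); qualifiers deeper, with "/"
  keys <- grep("^ {5}\\S", body)
  if (length(keys) == 0L) return(none)
  src <- which(grepl("^ {5}source\\s", body[keys]) |
                 grepl("^ {5}source$", body[keys]))
  if (length(src) == 0L) return(none)
  from <- keys[src[1]]
  to <- if (src[1] < length(keys)) keys[src[1] + 1L] - 1L else length(body)
  block <- body[seq(from, to)]
  qstart <- grep("^\\s+/", block)
  if (length(qstart) == 0L) return(none)
  qend <- c(qstart[-1L] - 1L, length(block))
  name <- character(length(qstart))
  value <- character(length(qstart))
  for (i in seq_along(qstart)) {
    txt <- paste(trimws(block[qstart[i]:qend[i]]), collapse = " ")
    txt <- sub("^/", "", txt)
    eq <- regexpr("=", txt, fixed = TRUE)
    if (eq == -1L) {
      name[i] <- txt
      value[i] <- ""
    } else {
      name[i] <- substr(txt, 1L, eq - 1L)
      v <- substring(txt, eq + 1L)
      value[i] <- gsub('^"|"$', "", v)
    }
  }
  data.frame(name = name, value = value)
}

# Serialize minimal GBFF records. `records` is a data.frame with columns
# accession, organism, voucher (NA = omit the qualifier).
write_gbff <- function(records, path) {
  wrap_qualifier <- function(text) {
    # GBFF wraps feature-table lines at 79 columns with a 21-column indent;
    # wrapping happens at spaces only, so unwrapping can rejoin with a space
    indent <- strrep(" ", 21)
    width <- 79L - 21L
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    lines <- character(0)
    cur <- words[1]
    for (w in words[-1]) {
      if (nchar(cur) + 1L + nchar(w) <= width) {
        cur <- paste(cur, w)
      } else {
        lines <- c(lines, cur)
        cur <- w
      }
    }
    paste0(indent, c(lines, cur))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[i]
    org <- records$organism[i]
    lines <- c(
      sprintf("LOCUS       %s                 60 bp    DNA     linear   VRT", acc),
      sprintf("DEFINITION  %s voucher study sequence.", org),
      sprintf("ACCESSION   %s", acc),
      "FEATURES             Location/Qualifiers",
      "     source          1..60",
      wrap_qualifier(sprintf('/organism="%s"', org)),
      wrap_qualifier('/mol_type="genomic DNA"')
    )
    if (!is.na(records$voucher[i])) {
      lines <- c(lines,
                 wrap_qualifier(sprintf('/specimen_voucher="%s"',
                                        records$voucher[i])))
    }
    lines <- c(lines,
               "ORIGIN",
               paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
               "//")
    writeLines(lines, con)
  }
  invisible(path)
}
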