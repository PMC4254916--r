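# Adapters turning repository exports into identifier corpora:
# Darwin Core occurrence tables, GenBank flat files, BOLD specimen TSVs,
# and Linkout URL lists.

read_delim_auto <- function(path) {
  readr::read_delim(
    path,
    delim = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    col_types = readr::cols(.default = "c"),
    na = character(), progress = FALSE, show_col_types = FALSE,
    skip_empty_rows = FALSE
  )
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop("input ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a Darwin Core occurrence table
#'
#' Reads a delimited occurrence file (a Darwin Core Archive core file
#' pre-extracted to its occurrence table) and reconstitutes one triplet per
#' row by joining the record-level terms `institutionCode` and
#' `collectionCode` with the occurrence-level term `catalogNumber`.
#' Non-empty cells become the identifier's parts verbatim; the colon-joined
#' form is additionally evaluated against the canonical grammar and the
#' outcome recorded in `rule_fired`. Rows with all three cells empty yield
#' a record with no identifiers.
#'
#' @param path CSV (`.csv`) or TSV occurrence file with a header row.
#' @param column_map Named character vector mapping the roles
#'   `institution_code`, `collection_code`, `catalog_number`, and optionally
#'   `record_id`, to column names in the file. When no `record_id` column is
#'   mapped, row numbers are used.
#' @param allowlist Optional character vector of accepted institution codes
#'   (a reproducible stand-in for expert vetting of codes): identifiers
#'   whose IC is absent from the list are dropped. `NULL` disables
#'   filtering.
#' @return An [identifier_corpus()] with `repository = "SPECIMEN"`.
#' @export
read_dwc_occurrences <- function(path,
                                 column_map = c(
                                   institution_code = "institutionCode",
                                   collection_code = "collectionCode",
                                   catalog_number = "catalogNumber"
                                 ),
                                 allowlist = NULL) {
  tab <- read_delim_auto(path)
  require_columns(tab, unname(column_map[c("institution_code",
                                           "collection_code",
                                           "catalog_number")]), path)
  ic <- blank_to_na(tab[[column_map[["institution_code"]]]])
  cc <- blank_to_na(tab[[column_map[["collection_code"]]]])
  cn <- blank_to_na(tab[[column_map[["catalog_number"]]]])
  ids <- if ("record_id" %in% names(column_map)) {
    as.character(tab[[column_map[["record_id"]]]])
  } else {
    as.character(seq_len(nrow(tab)))
  }
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    present <- c(ic[i], cc[i], cn[i])
    present <- present[!is.na(present)]
    if (length(present) == 0L) return(parsed_empty())
    joined <- paste(present, collapse = ":")
    row <- parse_field(joined)
    if (nrow(row) != 1L) row <- row[1, , drop = FALSE]
    # the structured cells are authoritative for the parts; the parse of
    # the joined form only supplies the rule provenance
    row$ic <- ic[i]; row$cc <- cc[i]; row$cn <- cn[i]
    row$raw <- joined
    row
  })
  corpus <- build_corpus(parsed, ids, rep("occurrence", nrow(tab)),
                         "SPECIMEN")
  apply_allowlist(corpus, allowlist)
}

#' Extract specimen vouchers from a GenBank flat file
#'
#' Scans a plain-text GenBank flat file (GBFF) and, for every sequence
#' record whose `source` feature carries one or more `/specimen_voucher`
#' qualifiers, parses each qualifier value with [parse_field()] into an
#' identifier record keyed by accession. Qualifier values are used after
#' unwrapping continuation lines and stripping surrounding quotes; no other
#' qualifier (isolate, db_xref, note, ...) is read. Records without the
#' qualifier are counted but contribute no identifiers.
#'
#' @param path GBFF file.
#' @param allowlist Optional institution-code allowlist (see
#'   [read_dwc_occurrences()]).
#' @param strip_urn Passed to [parse_field()].
#' @return An [identifier_corpus()] with `repository = "GENBANK"`.
#' @export
extract_genbank_vouchers <- function(path, allowlist = NULL,
                                     strip_urn = FALSE) {
  recs <- read_gbff_records(path)
  ids <- vapply(recs, `[[`, character(1), "accession")
  parsed <- lapply(recs, function(r) {
    if (length(r$vouchers) == 0L) return(parsed_empty())
    bind_rows(lapply(r$vouchers, parse_field, strip_urn = strip_urn))
  })
  has_voucher <- vapply(recs, function(r) length(r$vouchers) > 0L, logical(1))
  corpus <- build_corpus(parsed, ids, rep("specimen_voucher", length(recs)),
                         "GENBANK", has_info = has_voucher)
  apply_allowlist(corpus, allowlist)
}

#' Reconcile the two BOLD identifier fields
#'
#' BOLD allocates the `catalognum` field (MuseumID) for the specimen
#' identifier, but `sampleid` may also carry a triplet, so both are
#' checked. When only one field is populated it is used; when both agree
#' byte-for-byte the single shared text is used; when they disagree both
#' texts are kept (catalognum first) as candidate identifiers.
#'
#' @param catalognum,sampleid Single field values (may be empty/`NA`).
#' @return List with `texts` (character vector of candidate identifier
#'   texts, possibly empty), `fields` (which field each text came from) and
#'   `agreement` (one of `"ONLY_ONE"`, `"EXACT_MATCH"`, `"DISAGREE"`,
#'   `"BOTH_EMPTY"`).
#' @examples
#' reconcile_bold_fields("ROM:Birds:12", "")
#' reconcile_bold_fields("A:Bc:1", "XYZ 2")
#' @export
reconcile_bold_fields <- function(catalognum, sampleid) {
  cat_ <- blank_to_na(catalognum)
  samp <- blank_to_na(sampleid)
  if (is.na(cat_) && is.na(samp)) {
    return(list(texts = character(0), fields = character(0),
                agreement = "BOTH_EMPTY"))
  }
  if (is.na(cat_) || is.na(samp)) {
    txt <- if (is.na(cat_)) samp else cat_
    fld <- if (is.na(cat_)) "sampleid" else "catalognum"
    return(list(texts = txt, fields = fld, agreement = "ONLY_ONE"))
  }
  if (identical(cat_, samp)) {
    return(list(texts = cat_, fields = "catalognum",
                agreement = "EXACT_MATCH"))
  }
  list(texts = c(cat_, samp), fields = c("catalognum", "sampleid"),
       agreement = "DISAGREE")
}

#' Read a BOLD specimen export
#'
#' Reads a BOLD-style specimen TSV, reconciles the `catalognum` and
#' `sampleid` fields per row ([reconcile_bold_fields()]), and parses each
#' resulting candidate text with [parse_field()]. The per-row
#' reconciliation outcome is retained in the corpus under
#' `$extra$bold_reconciliation` so disagreeing rows can be reported
#' separately.
#'
#' @param path BOLD TSV with `catalognum` and `sampleid` columns (names
#'   remappable through `column_map`; an optional `record_id` entry maps a
#'   process/record id column).
#' @param column_map Named character vector as in [read_dwc_occurrences()].
#' @param allowlist Optional institution-code allowlist.
#' @return An [identifier_corpus()] with `repository = "BOLD"`.
#' @export
read_bold_table <- function(path,
                            column_map = c(catalognum = "catalognum",
                                           sampleid = "sampleid"),
                            allowlist = NULL) {
  tab <- read_delim_auto(path)
  require_columns(tab, unname(column_map[c("catalognum", "sampleid")]), path)
  cat_ <- tab[[column_map[["catalognum"]]]]
  samp <- tab[[column_map[["sampleid"]]]]
  ids <- if ("record_id" %in% names(column_map)) {
    as.character(tab[[column_map[["record_id"]]]])
  } else {
    as.character(seq_len(nrow(tab)))
  }
  recon <- lapply(seq_len(nrow(tab)),
                  function(i) reconcile_bold_fields(cat_[i], samp[i]))
  parsed <- lapply(recon, function(r) {
    if (length(r$texts) == 0L) return(parsed_empty())
    bind_rows(lapply(r$texts, parse_field))
  })
  fields <- lapply(seq_along(recon), function(i) {
    r <- recon[[i]]
    if (length(r$texts) == 0L) return(character(0))
    # one source_field label per parsed identifier row
    rep(r$fields, vapply(r$texts,
                         function(t) nrow(parse_field(t)), integer(1)))
  })
  recon_tab <- tibble(
    record_id = ids,
    catalognum_raw = blank_to_na(cat_),
    sampleid_raw = blank_to_na(samp),
    agreement = vapply(recon, `[[`, character(1), "agreement")
  )
  corpus <- build_corpus(parsed, ids, fields, "BOLD",
                         extra = list(bold_reconciliation = recon_tab))
  apply_allowlist(corpus, allowlist)
}

#' Extract the candidate identifier from a Linkout URL
#'
#' NCBI Linkout URLs sometimes encode a specimen identifier in their tail.
#' The candidate is whatever follows the final `"/"`, and then, if that
#' substring contains `"="`, whatever follows the final `"="`. The split is
#' deliberately literal; URLs are not normalized first.
#'
#' @param url Character vector of URLs.
#' @return Character vector of candidate texts (possibly `""`).
#' @examples
#' linkout_tail("http://arctos.database.museum/guid/MVZ:Mamm:12345")
#' linkout_tail("http://x.org/fetch?id=KU:Fish:99")
#' @export
linkout_tail <- function(url) {
  stopifnot(all(nzchar(url)))
  tail_ <- sub(".*/", "", url)
  has_eq <- grepl("=", tail_, fixed = TRUE)
  tail_[has_eq] <- sub(".*=", "", tail_[has_eq])
  tail_
}

#' Read a Linkout URL list
#'
#' Reads a plain-text list of Linkout URLs, one `accession<TAB>url` pair
#' per line (no header), extracts each URL tail with [linkout_tail()] and
#' parses it with [parse_field()].
#'
#' @param path Tab-separated accession/URL file.
#' @param allowlist Optional institution-code allowlist.
#' @return An [identifier_corpus()] with `repository = "GENBANK"` and
#'   `source_field = "linkout"`.
#' @export
read_linkout_urls <- function(path, allowlist = NULL) {
  tab <- readr::read_tsv(path, col_names = c("accession", "url"),
                         col_types = "cc", progress = FALSE)
  tails <- linkout_tail(tab$url)
  parsed <- lapply(tails, parse_field)
  corpus <- build_corpus(parsed, tab$accession,
                         rep("linkout", nrow(tab)), "GENBANK")
  apply_allowlist(corpus, allowlist)
}

# drop identifiers whose IC is not on the allowlist (identifiers without an
# IC are kept: the list vets codes, it does not require them)
apply_allowlist <- function(corpus, allowlist) {
  if (is.null(allowlist)) return(corpus)
  keep <- is.na(corpus$identifiers$ic) | corpus$identifiers$ic %in% allowlist
  corpus$identifiers <- corpus$identifiers[keep, , drop = FALSE]
  corpus
}
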