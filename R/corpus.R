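# The identifier_corpus container: one repository's records with their
# parsed identifiers in a tidy one-row-per-identifier tibble, plus a
# record-level table so records that yielded no identifier still count.

corpus_identifier_cols <- c(
  "repository", "record_id", "source_field", "raw", "ic", "cc", "cn",
  "rule_fired", "used_default_ic", "used_default_cn"
)

#' Build an identifier corpus
#'
#' Bundles the parsed identifiers of one repository with its record-level
#' bookkeeping. Adapters construct these; most users will not call the
#' constructor directly.
#'
#' @param identifiers Tibble with one row per parsed identifier (columns
#'   `repository`, `record_id`, `source_field`, `raw`, `ic`, `cc`, `cn`,
#'   `rule_fired`, `used_default_ic`, `used_default_cn`).
#' @param records Tibble with one row per source record (`record_id`,
#'   `n_identifiers`, `has_specimen_info`).
#' @param repository One of `"SPECIMEN"`, `"GENBANK"`, `"BOLD"`.
#' @param extra Optional named list of adapter-specific side tables (e.g.
#'   the BOLD field reconciliation).
#' @return Object of class `identifier_corpus`.
#' @export
identifier_corpus <- function(identifiers, records, repository,
                              extra = list()) {
  repository <- match.arg(repository, c("SPECIMEN", "GENBANK", "BOLD"))
  stopifnot(all(corpus_identifier_cols %in% names(identifiers)))
  if (anyDuplicated(records$record_id)) {
    stop("record_id must be unique within a corpus", call. = FALSE)
  }
  structure(
    list(identifiers = as_tibble(identifiers), records = as_tibble(records),
         repository = repository, extra = extra),
    class = "identifier_corpus"
  )
}

#' @export
print.identifier_corpus <- function(x, ...) {
  cat(sprintf(
    "<identifier_corpus> %s: %d records, %d with specimen info, %d identifiers\n",
    x$repository, nrow(x$records), sum(x$records$has_specimen_info),
    nrow(x$identifiers)
  ))
  if (nrow(x$identifiers) > 0L) print(head(x$identifiers, 5))
  invisible(x)
}

# assemble a corpus from per-record lists of parsed identifiers, applying
# record-level IC propagation
build_corpus <- function(parsed_by_record, record_ids, source_fields,
                         repository, has_info = NULL, extra = list()) {
  stopifnot(length(parsed_by_record) == length(record_ids))
  n_ids <- vapply(parsed_by_record, nrow, integer(1))
  if (is.null(has_info)) has_info <- n_ids > 0L
  rows <- lapply(seq_along(parsed_by_record), function(i) {
    ids <- propagate_record_ic(parsed_by_record[[i]])
    if (nrow(ids) == 0L) return(NULL)
    sf <- source_fields[[i]]
    if (length(sf) == 1L) sf <- rep(sf, nrow(ids))
    dplyr::bind_cols(
      tibble(repository = rep(repository, nrow(ids)),
             record_id = rep(record_ids[i], nrow(ids)),
             source_field = sf),
      ids
    )
  })
  identifiers <- bind_rows(rows)
  if (nrow(identifiers) == 0L) {
    identifiers <- dplyr::bind_cols(
      tibble(repository = character(), record_id = character(),
             source_field = character()),
      parsed_empty()
    )
  }
  records <- tibble(record_id = record_ids, n_identifiers = n_ids,
                    has_specimen_info = has_info)
  identifier_corpus(identifiers, records, repository, extra)
}

#' Write / read a normalized corpus file
#'
#' The normalized corpus format is a UTF-8 TSV with a header row and one
#' identifier per line:
#' `repository, record_id, source_field, raw, IC, CC, CN, rule_fired`.
#'
#' @param corpus An `identifier_corpus`.
#' @param path File path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()`
#'   returns a tibble of identifiers (the record-level table is not round-
#'   tripped).
#' @export
write_corpus <- function(corpus, path) {
  out <- corpus$identifiers %>%
    select("repository", "record_id", "source_field", "raw",
           IC = "ic", CC = "cc", CN = "cn", "rule_fired")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  tab[] <- lapply(tab, blank_to_na)
  rename(tab, ic = "IC", cc = "CC", cn = "CN")
}
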