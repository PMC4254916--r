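# The audit taxonomy: canonical vs coerced identifiers, and among coerced
# ones the three irregularity classes (syntactic-only, missing-data-only,
# both kinds of problems).

#' Classify parsed identifiers into the audit taxonomy
#'
#' Every parsed identifier receives exactly one label:
#'
#' * `CANONICAL` -- recognized whole by the canonical grammar.
#' * `SYNTACTIC_ONLY` -- all three parts recovered, but the source text did
#'   not follow canonical structure (wrong delimiters, reordered parts).
#' * `MISSING_ONLY` -- at least one part absent (typically the collection
#'   code, giving a doublet) while the raw text used only colon delimiters
#'   between the recovered parts, as structured sources with empty cells
#'   produce.
#' * `BOTH` -- both kinds of problems; a bare catalog number falls here.
#' * `NO_IDENTIFIER` -- nothing recoverable (`UNPARSEABLE`).
#'
#' @param parsed Tibble of parsed identifiers (from [parse_field()] or a
#'   corpus), or a single one-row tibble.
#' @return Character vector of labels, one per row.
#' @examples
#' classify_identifier(parse_field("MVZ:Mamm:12345")) # CANONICAL
#' classify_identifier(parse_field("MVZ Mamm 12345")) # SYNTACTIC_ONLY
#' classify_identifier(parse_field("MVZ:12345"))      # MISSING_ONLY
#' classify_identifier(parse_field("12345"))          # BOTH
#' @export
classify_identifier <- function(parsed) {
  if (nrow(parsed) == 0L) return(character(0))
  n_parts <- (!is.na(parsed$ic)) + (!is.na(parsed$cc)) + (!is.na(parsed$cn))
  # delimiters other than ":" present anywhere in the raw text
  other_delim <- grepl("[. _#-]", parsed$raw)
  colon_joined <- grepl(":", parsed$raw, fixed = TRUE) & !other_delim
  out <- rep("BOTH", nrow(parsed))
  out[n_parts >= 2L & n_parts < 3L & colon_joined] <- "MISSING_ONLY"
  out[n_parts == 3L] <- "SYNTACTIC_ONLY"
  out[parsed$rule_fired == "CANONICAL_REGEX"] <- "CANONICAL"
  out[parsed$rule_fired == "UNPARSEABLE"] <- "NO_IDENTIFIER"
  out
}

#' Attach class labels to a corpus
#'
#' Adds a `class_label` column to the corpus identifier table.
#'
#' @param corpus An [identifier_corpus()].
#' @return The corpus with `identifiers$class_label` populated.
#' @export
classify_corpus <- function(corpus) {
  corpus$identifiers$class_label <- classify_identifier(corpus$identifiers)
  corpus
}

#' Summarize a repository's identifiers
#'
#' Produces the per-repository audit summary: total records examined,
#' records bearing specimen information, and identifier counts in the
#' canonical/coerced breakdown with the coerced identifiers split into the
#' three irregularity classes. Identifiers (not records) are the counting
#' unit when a record carries several; records with zero identifiers are
#' counted only in the totals.
#'
#' @param corpus An [identifier_corpus()] (classified automatically if
#'   needed).
#' @return One-row tibble with columns `repository`, `total_records`,
#'   `records_with_specimen_info`, `canonical`, `coerced`,
#'   `syntactic_only`, `missing_only`, `both_problems`, `no_identifier`.
#'   `canonical + coerced` equals the number of classified identifiers and
#'   `coerced = syntactic_only + missing_only + both_problems`.
#' @export
summarize_repository <- function(corpus) {
  if (!"class_label" %in% names(corpus$identifiers)) {
    corpus <- classify_corpus(corpus)
  }
  lab <- corpus$identifiers$class_label
  tab <- function(x) sum(lab == x)
  out <- tibble(
    repository = corpus$repository,
    total_records = nrow(corpus$records),
    records_with_specimen_info = sum(corpus$records$has_specimen_info),
    canonical = tab("CANONICAL"),
    syntactic_only = tab("SYNTACTIC_ONLY"),
    missing_only = tab("MISSING_ONLY"),
    both_problems = tab("BOTH"),
    no_identifier = tab("NO_IDENTIFIER")
  )
  out$coerced <- out$syntactic_only + out$missing_only + out$both_problems
  stopifnot(out$canonical + out$coerced == sum(lab != "NO_IDENTIFIER"))
  out[, c("repository", "total_records", "records_with_specimen_info",
          "canonical", "coerced", "syntactic_only", "missing_only",
          "both_problems", "no_identifier")]
}
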