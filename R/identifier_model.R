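#' dwcaudit: audit Darwin Core Triplet specimen identifiers
#'
#' The Darwin Core (DwC) Triplet --
#' `institutionCode:collectionCode:catalogNumber` -- is the de facto
#' identifier used to link biocollection specimen records to downstream
#' derivatives such as GenBank sequences and BOLD barcode records. In
#' practice the triplet is deployed with wildly varying fidelity: wrong
#' delimiters, missing collection codes (doublets), bare catalog numbers,
#' several identifiers crammed into one field. dwcaudit provides a strict
#' canonical recognizer, a heuristic coercion parser that reconstructs
#' structured parts from messy voucher text, adapters for the three
#' repository formats, a classification of every identifier by completeness
#' and syntax, tiered cross-repository matching, and a seeded synthetic
#' corpus generator with ground-truth links for offline evaluation.
#'
#' @section Main entry points:
#' * [parse_field()] -- voucher text to structured identifiers.
#' * [read_dwc_occurrences()], [extract_genbank_vouchers()],
#'   [read_bold_table()], [read_linkout_urls()] -- repository adapters.
#' * [classify_corpus()], [summarize_repository()] -- audit taxonomy.
#' * [match_corpora()], [effective_matches()] -- cross-repository linkage.
#' * [generate_linked_corpora()] -- synthetic three-repository test data.
#' * [run_audit()] -- end-to-end pipeline with report files.
#'
#' @importFrom dplyr %>% .data arrange bind_cols bind_rows distinct filter
#'   group_by inner_join left_join mutate n n_distinct pull rename row_number
#'   select summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
#' @importFrom utils head modifyList
#' @keywords internal
"_PACKAGE"

#' Canonical Darwin Core Triplet grammar
#'
#' Constants defining the canonical triplet grammar and the tokenization
#' alphabet used by the coercion parser.
#'
#' `dwc_canonical_regex` accepts a canonical triplet:
#' 2--8 capital letters for the institution code, a colon, a word with a
#' leading capital for the collection code, a colon, and any string
#' containing at least one digit for the catalog number. [is_canonical()]
#' applies it with full-match (anchored) semantics.
#'
#' `dwc_fragment_separators` split a field that holds several identifiers
#' into fragments; `dwc_token_delimiters` split a fragment into tokens.
#'
#' @format `dwc_canonical_regex` is a length-one character string;
#'   the separator/delimiter sets are character vectors.
#' @examples
#' grepl(paste0("^(?:", dwc_canonical_regex, ")$"), "MVZ:Mamm:12345")
#' @export
dwc_canonical_regex <- "[A-Z]{2,8}\\:[A-Z][a-z]+\\:.*[0-9]+.*"

#' @rdname dwc_canonical_regex
#' @export
dwc_fragment_separators <- c(";", "(")

#' @rdname dwc_canonical_regex
#' @export
dwc_token_delimiters <- c(":", ".", "-", "_", "#", " ")

# enum levels shared across the package
parse_rules <- c(
  "CANONICAL_REGEX", "FIRST_THREE", "IC_CN", "IC_CC_DEFAULT_CN",
  "CC_CN_DEFAULT_IC", "CN_DEFAULT_IC", "UNPARSEABLE"
)
class_labels <- c(
  "CANONICAL", "SYNTACTIC_ONLY", "MISSING_ONLY", "BOTH", "NO_IDENTIFIER"
)
match_tiers <- c(
  "CANONICAL", "TRIPLET_TRIPLET", "TRIPLET_DOUBLET", "DOUBLET_DOUBLET"
)

# empty-string cells and all-whitespace cells are indistinguishable from
# absent in CSV exports; treat both as NA
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Construct triplet parts
#'
#' Builds the (IC, CC, CN) value object at the heart of every parsing and
#' matching rule: institution code, collection code, catalog number. Values
#' are stored verbatim (no case folding, no zero stripping); empty strings
#' are treated as absent. At least one part must be present.
#'
#' @param ic,cc,cn Institution code, collection code, catalog number.
#'   `NA` or `""` mean absent.
#' @return An object of class `triplet_parts`: a named list with elements
#'   `ic`, `cc`, `cn` (`NA_character_` for absent parts).
#' @examples
#' triplet_parts("MVZ", "Mamm", "12345")
#' triplet_parts("MVZ", cn = "12345") # a doublet
#' @export
triplet_parts <- function(ic = NA_character_, cc = NA_character_,
                          cn = NA_character_) {
  one <- function(x, what) {
    if (length(x) != 1L) stop(what, " must be a single value", call. = FALSE)
    blank_to_na(x)
  }
  out <- list(ic = one(ic, "ic"), cc = one(cc, "cc"), cn = one(cn, "cn"))
  if (all(is.na(unlist(out)))) {
    stop("at least one of ic, cc, cn must be present", call. = FALSE)
  }
  structure(out, class = "triplet_parts")
}

#' @export
print.triplet_parts <- function(x, ...) {
  show <- function(v) if (is.na(v)) "-" else v
  cat("<triplet_parts> ", show(x$ic), ":", show(x$cc), ":", show(x$cn), "\n",
      sep = "")
  invisible(x)
}

#' @export
`==.triplet_parts` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

#' Completeness of an identifier
#'
#' Classifies the presence pattern of triplet parts. A `TRIPLET` has all
#' three parts; a `DOUBLET` has institution code and catalog number but no
#' collection code (the ambiguity-prone `IC:CN` form); `CN_ONLY` is a bare
#' catalog number; every other partial pattern is `OTHER_PARTIAL`.
#'
#' @param ic,cc,cn Character vectors of parts (`NA` = absent), or pass a
#'   `triplet_parts` object as `ic`.
#' @return Character vector over
#'   `c("TRIPLET", "DOUBLET", "CN_ONLY", "OTHER_PARTIAL")`.
#' @examples
#' completeness("MVZ", "Mamm", "12345")
#' completeness("MVZ", NA, "12345")
#' completeness(triplet_parts(cn = "12345"))
#' @export
completeness <- function(ic, cc = NA_character_, cn = NA_character_) {
  if (inherits(ic, "triplet_parts")) {
    parts <- ic
    ic <- parts$ic; cc <- parts$cc; cn <- parts$cn
  }
  ic <- !is.na(blank_to_na(ic))
  cc <- !is.na(blank_to_na(cc))
  cn <- !is.na(blank_to_na(cn))
  out <- rep("OTHER_PARTIAL", max(length(ic), length(cc), length(cn)))
  out[ic & cc & cn] <- "TRIPLET"
  out[ic & !cc & cn] <- "DOUBLET"
  out[!ic & !cc & cn] <- "CN_ONLY"
  out
}
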