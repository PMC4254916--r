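# The canonical recognizer and the heuristic coercion algorithm.
#
# The coercion algorithm operates in three stages:
#   1. split a field into fragments on ";" and "(" (multiple identifiers
#      are commonly packed into one field that way);
#   2. tokenize each fragment on [":", ".", "-", "_", "#", " "], scan the
#      final token for a default IC (all-caps word) or CN (multi-digit
#      number), then apply five ordered coercion rules to the leading
#      tokens;
#   3. within a record, donate the first available IC to identifiers that
#      lack one.
# Everything here is deterministic and free of I/O.

anchored <- function(rx) paste0("^(?:", rx, ")$")

# role tests for single tokens (vectorized)
token_is_ic <- function(x) grepl("^[A-Z]{2,8}$", x)
token_is_cc <- function(x) grepl("^[A-Z][a-z]+$", x)
token_is_cn <- function(x) grepl("[0-9]", x)

# zero-row template for parsed-identifier tibbles
parsed_empty <- function() {
  tibble(
    raw = character(), ic = character(), cc = character(), cn = character(),
    rule_fired = character(), used_default_ic = logical(),
    used_default_cn = logical()
  )
}

parsed_row <- function(raw, ic, cc, cn, rule, def_ic = FALSE, def_cn = FALSE) {
  tibble(
    raw = raw, ic = ic, cc = cc, cn = cn, rule_fired = rule,
    used_default_ic = def_ic, used_default_cn = def_cn
  )
}

#' Test whether text is a canonical Darwin Core Triplet
#'
#' A canonical triplet is `IC:CC:CN` where the institution code is 2--8
#' capital letters, the collection code is a word with a leading capital,
#' and the catalog number is any string containing a digit. The grammar is
#' the regular expression [dwc_canonical_regex], applied with full-match
#' semantics to the whitespace-trimmed text.
#'
#' @param text Character vector of candidate identifier texts.
#' @param strip_urn If `TRUE`, a leading `"urn:catalog:"` prefix (the Darwin
#'   Core `occurrenceID` recommendation) is removed before evaluation.
#' @return Logical vector.
#' @examples
#' is_canonical("MVZ:Mamm:12345")   # TRUE
#' is_canonical("M:Mamm:12345")     # FALSE: IC needs 2-8 capitals
#' is_canonical("MVZ:Mamm:ABCD")    # FALSE: CN needs a digit
#' is_canonical("MVZ Mamm 12345")   # FALSE: colons required
#' @export
is_canonical <- function(text, strip_urn = FALSE) {
  if (length(text) == 0L) return(logical(0))
  if (any(is.na(text)) || any(!nzchar(trimws(text)))) {
    stop("is_canonical() requires non-empty text", call. = FALSE)
  }
  x <- trimws(text)
  if (strip_urn) x <- sub("^urn:catalog:", "", x)
  grepl(anchored(dwc_canonical_regex), x, perl = TRUE)
}

#' Split a field into identifier fragments
#'
#' Breaks a text value suspected of containing one or more triplets into
#' fragments on semicolons and open parentheses, the separators most
#' commonly used to pack several identifiers into one field. Fragments are
#' whitespace-trimmed; empty fragments are dropped.
#'
#' @param text A single field value.
#' @return Character vector of fragments (possibly empty).
#' @examples
#' split_fragments("MVZ:Mamm:1; MVZ:Mamm:2")
#' split_fragments("KU 123 (also KU 124)")
#' @export
split_fragments <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) return(character(0))
  frags <- strsplit(text, "[;(]")[[1]]
  frags <- trimws(frags)
  frags[nzchar(frags)]
}

#' Tokenize an identifier fragment
#'
#' Partitions a fragment into tokens on the six delimiters
#' `":", ".", "-", "_", "#", " "`. Runs of consecutive delimiters do not
#' produce empty tokens.
#'
#' @param fragment A single fragment.
#' @return Character vector of tokens.
#' @examples
#' tokenize("MVZ:Mamm:12345")
#' tokenize("UAM_Fish_100")
#' @export
tokenize <- function(fragment) {
  stopifnot(length(fragment) == 1L, !is.na(fragment), nzchar(fragment))
  toks <- strsplit(fragment, "[:. _#-]")[[1]]
  toks[nzchar(toks)]
}

#' Which triplet roles can a token fill?
#'
#' A token can serve as an institution code if it is 2--8 capital letters,
#' as a collection code if it is a leading-capital lowercase word, and as a
#' catalog number if it contains at least one digit. A token may qualify
#' for several roles or none.
#'
#' @param token A single token.
#' @return Character vector, a subset of `c("IC", "CC", "CN")`.
#' @examples
#' token_roles("MVZ")    # "IC"
#' token_roles("Mamm")   # "CC"
#' token_roles("B1978")  # "CN"
#' token_roles("tissue") # character(0)
#' @export
token_roles <- function(token) {
  stopifnot(length(token) == 1L, !is.na(token), nzchar(token))
  c("IC", "CC", "CN")[c(token_is_ic(token), token_is_cc(token),
                        token_is_cn(token))]
}

#' Scan a token list for default IC / CN donors
#'
#' Inspects only the final token of a fragment: an all-caps word (two or
#' more letters, letters only) becomes the default institution code; a
#' multi-digit number (two or more digits, digits only) becomes the default
#' catalog number. The defaults are consumed by the coercion rules only
#' when the leading tokens do not supply that part themselves.
#'
#' @param tokens Character vector of tokens from one fragment.
#' @return List with `default_ic` and `default_cn` (each `NA` if absent).
#' @examples
#' scan_defaults(c("Fish", "12345", "UWFC")) # default_ic = "UWFC"
#' scan_defaults(c("MVZ", "Mamm", "4567"))   # default_cn = "4567"
#' @export
scan_defaults <- function(tokens) {
  stopifnot(length(tokens) >= 1L)
  last <- tokens[length(tokens)]
  list(
    default_ic = if (grepl("^[A-Z]{2,}$", last)) last else NA_character_,
    default_cn = if (grepl("^[0-9]{2,}$", last)) last else NA_character_
  )
}

#' Coerce a token list into identifier parts
#'
#' Applies the five ordered coercion rules to the leading tokens of a
#' fragment; the first rule whose role conditions hold wins, and any
#' trailing tokens are ignored:
#'
#' 1. `FIRST_THREE` -- tokens 1--3 match IC, CC, CN.
#' 2. `IC_CN` -- tokens 1--2 match IC and CN; no CC assigned.
#' 3. `IC_CC_DEFAULT_CN` -- tokens 1--2 match IC and CC; the default CN
#'    (from [scan_defaults()]) is used if available.
#' 4. `CC_CN_DEFAULT_IC` -- tokens 1--2 match CC and CN; the default IC is
#'    used if available.
#' 5. `CN_DEFAULT_IC` -- token 1 matches CN; the default IC is used if
#'    available.
#'
#' If no rule fires the result is `UNPARSEABLE` with no parts recovered.
#'
#' @param tokens Character vector of tokens.
#' @param defaults Defaults from [scan_defaults()] on the same tokens.
#' @param raw The original fragment text to record as provenance.
#' @return One-row tibble with columns `raw`, `ic`, `cc`, `cn`,
#'   `rule_fired`, `used_default_ic`, `used_default_cn`.
#' @examples
#' toks <- tokenize("Fish 12345 UWFC")
#' coerce_tokens(toks, scan_defaults(toks), "Fish 12345 UWFC")
#' @export
coerce_tokens <- function(tokens, defaults = scan_defaults(tokens),
                          raw = paste(tokens, collapse = " ")) {
  stopifnot(length(tokens) >= 1L)
  n <- length(tokens)
  t1 <- tokens[1]
  t2 <- if (n >= 2L) tokens[2] else NA_character_
  t3 <- if (n >= 3L) tokens[3] else NA_character_
  has2 <- n >= 2L
  has3 <- n >= 3L

  if (has3 && token_is_ic(t1) && token_is_cc(t2) && token_is_cn(t3)) {
    return(parsed_row(raw, t1, t2, t3, "FIRST_THREE"))
  }
  if (has2 && token_is_ic(t1) && token_is_cn(t2)) {
    return(parsed_row(raw, t1, NA_character_, t2, "IC_CN"))
  }
  if (has2 && token_is_ic(t1) && token_is_cc(t2)) {
    return(parsed_row(raw, t1, t2, defaults$default_cn, "IC_CC_DEFAULT_CN",
                      def_cn = !is.na(defaults$default_cn)))
  }
  if (has2 && token_is_cc(t1) && token_is_cn(t2)) {
    return(parsed_row(raw, defaults$default_ic, t1, t2, "CC_CN_DEFAULT_IC",
                      def_ic = !is.na(defaults$default_ic)))
  }
  if (token_is_cn(t1)) {
    return(parsed_row(raw, defaults$default_ic, NA_character_, t1,
                      "CN_DEFAULT_IC", def_ic = !is.na(defaults$default_ic)))
  }
  parsed_row(raw, NA_character_, NA_character_, NA_character_, "UNPARSEABLE")
}

# split a canonical string into its three parts; the CN may itself contain
# colons, so only the first two colons delimit
split_canonical <- function(x) {
  pieces <- strsplit(x, ":", fixed = TRUE)[[1]]
  list(ic = pieces[1], cc = pieces[2],
       cn = paste(pieces[-(1:2)], collapse = ":"))
}

#' Parse a voucher field into structured identifiers
#'
#' The full recognition pipeline for one field value. The text is first
#' split into fragments ([split_fragments()]); a fragment that is itself
#' canonical ([is_canonical()]) is split on colons and short-circuits to a
#' `CANONICAL_REGEX` identifier, and the rest are tokenized and coerced
#' ([tokenize()], [scan_defaults()], [coerce_tokens()]). Splitting comes
#' first because the catalog-number slot of the canonical grammar (`.*`)
#' would otherwise swallow a second packed identifier. A stray closing
#' parenthesis left at a fragment end by the splitting step is stripped
#' before tokenization (only `"("` is a separator, so its partner would
#' otherwise pollute the final token's role test).
#'
#' @param text A single field value; `NA` or empty yields zero rows.
#' @param strip_urn Passed to [is_canonical()].
#' @return Tibble with one row per identifier found (columns as in
#'   [coerce_tokens()]); fragments where no rule fires are retained with
#'   `rule_fired = "UNPARSEABLE"`.
#' @examples
#' parse_field("MVZ:Mamm:12345")
#' parse_field("MVZ:Mamm:1; 2345")
#' parse_field("UAM_Fish_100")
#' @export
parse_field <- function(text, strip_urn = FALSE) {
  stopifnot(length(text) <= 1L)
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(parsed_empty())
  }
  x <- trimws(text)
  if (strip_urn) x <- sub("^urn:catalog:", "", x)
  frags <- split_fragments(x)
  out <- lapply(frags, function(fr) {
    if (is_canonical(fr)) {
      p <- split_canonical(fr)
      return(parsed_row(fr, p$ic, p$cc, p$cn, "CANONICAL_REGEX"))
    }
    fr2 <- trimws(sub("\\)+$", "", fr))
    if (!nzchar(fr2)) {
      return(parsed_row(fr, NA_character_, NA_character_, NA_character_,
                        "UNPARSEABLE"))
    }
    toks <- tokenize(fr2)
    if (length(toks) == 0L) {
      return(parsed_row(fr, NA_character_, NA_character_, NA_character_,
                        "UNPARSEABLE"))
    }
    coerce_tokens(toks, scan_defaults(toks), raw = fr)
  })
  if (length(out) == 0L) parsed_empty() else bind_rows(out)
}

#' Donate a record-level default institution code
#'
#' Within one record, if any identifier carries an institution code, that
#' code (the first in document order when several disagree) becomes the
#' default for every identifier lacking one. Identifiers that already have
#' an IC are never modified; the operation is idempotent.
#'
#' @param identifiers Tibble of parsed identifiers from one record.
#' @return The tibble with missing `ic` filled and `used_default_ic` set on
#'   the rows that received the donor code.
#' @examples
#' ids <- parse_field("MVZ:Mamm:1; 2345")
#' propagate_record_ic(ids)
#' @export
propagate_record_ic <- function(identifiers) {
  if (nrow(identifiers) == 0L) return(identifiers)
  donors <- identifiers$ic[!is.na(identifiers$ic)]
  if (length(donors) == 0L) return(identifiers)
  fill <- is.na(identifiers$ic) & identifiers$rule_fired != "UNPARSEABLE"
  identifiers$ic[fill] <- donors[1]
  identifiers$used_default_ic[fill] <- TRUE
  identifiers
}

#' Render parts in canonical (colon-joined) form
#'
#' A complete triplet renders as `"IC:CC:CN"`; a doublet renders in the
#' doublet key dialect `"IC:CN"`. The institution code and catalog number
#' must both be present.
#'
#' @param ic,cc,cn Character vectors of parts, or a `triplet_parts` object
#'   as `ic`.
#' @return Character vector of colon-joined identifiers.
#' @examples
#' canonical_form("MVZ", "Mamm", "12345")
#' canonical_form("MVZ", NA, "12345")
#' @export
canonical_form <- function(ic, cc = NA_character_, cn = NA_character_) {
  if (inherits(ic, "triplet_parts")) {
    parts <- ic
    ic <- parts$ic; cc <- parts$cc; cn <- parts$cn
  }
  ic <- blank_to_na(ic); cc <- blank_to_na(cc); cn <- blank_to_na(cn)
  if (any(is.na(ic)) || any(is.na(cn))) {
    stop("canonical_form() requires ic and cn to be present", call. = FALSE)
  }
  ifelse(is.na(cc), paste(ic, cn, sep = ":"), paste(ic, cc, cn, sep = ":"))
}
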