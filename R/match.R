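# Cross-repository matching at tiered precision.
#
# Tier precedence (highest first): CANONICAL > TRIPLET_TRIPLET >
# TRIPLET_DOUBLET > DOUBLET_DOUBLET. Each cross-corpus identifier pair is
# counted in at most one tier:
#   CANONICAL        both sides canonical, identical full keys
#   TRIPLET_TRIPLET  both sides complete triplets, identical full keys,
#                    at least one side non-canonical
#   TRIPLET_DOUBLET  exactly one side has a collection code, identical
#                    doublet (IC:CN) keys
#   DOUBLET_DOUBLET  both sides lack the collection code, identical
#                    doublet keys
# Two complete triplets that share a doublet key but carry different
# collection codes match in no tier.

#' Matching key for an identifier at a tier
#'
#' Canonical and triplet-triplet tiers compare full `"IC:CC:CN"` keys
#' (all three parts required); triplet-doublet and doublet-doublet tiers
#' compare `"IC:CN"` doublet keys (IC and CN required). Keys compare
#' byte-exactly by default.
#'
#' @param parsed Tibble of parsed identifiers.
#' @param tier One of `"CANONICAL"`, `"TRIPLET_TRIPLET"`,
#'   `"TRIPLET_DOUBLET"`, `"DOUBLET_DOUBLET"`.
#' @param case_insensitive Fold keys to upper case before comparison
#'   (sensitivity analysis; default off).
#' @return Character vector of keys, `NA` where the required parts are
#'   absent.
#' @examples
#' match_key(parse_field("MVZ:Mamm:12345"), "TRIPLET_DOUBLET") # "MVZ:12345"
#' match_key(parse_field("12345"), "DOUBLET_DOUBLET")          # NA
#' @export
match_key <- function(parsed, tier, case_insensitive = FALSE) {
  tier <- match.arg(tier, match_tiers)
  full <- tier %in% c("CANONICAL", "TRIPLET_TRIPLET")
  key <- rep(NA_character_, nrow(parsed))
  if (full) {
    ok <- !is.na(parsed$ic) & !is.na(parsed$cc) & !is.na(parsed$cn)
    key[ok] <- paste(parsed$ic[ok], parsed$cc[ok], parsed$cn[ok], sep = ":")
  } else {
    ok <- !is.na(parsed$ic) & !is.na(parsed$cn)
    key[ok] <- paste(parsed$ic[ok], parsed$cn[ok], sep = ":")
  }
  if (case_insensitive) key <- toupper(key)
  key
}

# identifier table of a corpus with key and flag columns precomputed
match_side <- function(corpus, case_insensitive) {
  ids <- if (inherits(corpus, "identifier_corpus")) {
    classify_corpus(corpus)$identifiers
  } else {
    corpus
  }
  if (!"class_label" %in% names(ids)) {
    ids$class_label <- classify_identifier(ids)
  }
  ids$.row <- seq_len(nrow(ids))
  ids$canonical <- ids$rule_fired == "CANONICAL_REGEX"
  ids$has_cc <- !is.na(ids$cc)
  ids$full_key <- match_key(ids, "TRIPLET_TRIPLET", case_insensitive)
  ids$doub_key <- match_key(ids, "DOUBLET_DOUBLET", case_insensitive)
  ids
}

# doublet keys that resolve to more than one collection within a corpus
ambiguous_doublet_keys <- function(ids) {
  with_key <- ids[!is.na(ids$doub_key), c("doub_key", "cc")]
  if (nrow(with_key) == 0L) return(character(0))
  cc_per_key <- tapply(with_key$cc, with_key$doub_key,
                       function(x) length(unique(x)))
  names(cc_per_key)[cc_per_key > 1L]
}

#' Match two identifier corpora
#'
#' Pairs every identifier in corpus A with every identifier in corpus B
#' that shares its key and assigns each pair the single highest applicable
#' tier. Totals count identifier pairs (so one specimen voucher matching
#' three sequence records contributes three matches); distinct counts are
#' unique keys per tier. For the doublet tiers, a matched key is flagged
#' ambiguous when it resolves to more than one collection code within
#' either corpus -- the doublet is then not even locally unique.
#'
#' @param corpus_a,corpus_b [identifier_corpus()] objects (or bare
#'   identifier tibbles).
#' @param case_insensitive Fold keys before comparison; default off
#'   (byte-exact).
#' @return Object of class `match_summary`: list with
#'   * `tiers` -- tibble of `tier`, `total_matches`, `distinct_keys`, and
#'     `distinct_triplet_keys` (for the triplet-doublet tier, the unique
#'     full keys on the triplet side; `NA` elsewhere);
#'   * `pairs` -- tibble of matched pairs (`tier`, `key`, `record_a`,
#'     `record_b`, `ambiguous`);
#'   * `ambiguous_keys` -- number of distinct matched doublet keys flagged
#'     ambiguous;
#'   * `matched_keys` -- character vector of distinct keys over all tiers.
#' @export
match_corpora <- function(corpus_a, corpus_b, case_insensitive = FALSE) {
  a <- match_side(corpus_a, case_insensitive)
  b <- match_side(corpus_b, case_insensitive)

  slim <- function(x) x[, c(".row", "record_id", "canonical", "has_cc",
                            "full_key", "doub_key")]
  a_ <- slim(a); b_ <- slim(b)

  # full-key tiers: both sides complete triplets
  fa <- a_[!is.na(a_$full_key), ]
  fb <- b_[!is.na(b_$full_key), ]
  full <- inner_join(fa, fb, by = "full_key", suffix = c("_a", "_b"),
                     relationship = "many-to-many")
  full$tier <- as.character(ifelse(full$canonical_a & full$canonical_b,
                                   "CANONICAL", "TRIPLET_TRIPLET"))
  full$key <- full$full_key

  # doublet-key tiers: at most one side may carry a collection code
  da <- a_[!is.na(a_$doub_key), ]
  db <- b_[!is.na(b_$doub_key), ]
  doub <- inner_join(da, db, by = "doub_key", suffix = c("_a", "_b"),
                     relationship = "many-to-many")
  doub <- doub[!(doub$has_cc_a & doub$has_cc_b), , drop = FALSE]
  doub$tier <- as.character(ifelse(doub$has_cc_a | doub$has_cc_b,
                                   "TRIPLET_DOUBLET", "DOUBLET_DOUBLET"))
  doub$key <- doub$doub_key

  amb_keys <- union(ambiguous_doublet_keys(a), ambiguous_doublet_keys(b))
  doub$ambiguous <- doub$key %in% amb_keys
  full$ambiguous <- FALSE

  cols <- c("tier", "key", "record_id_a", "record_id_b", "ambiguous")
  pairs <- bind_rows(full[, cols], doub[, cols]) %>%
    rename(record_a = "record_id_a", record_b = "record_id_b")

  # triplet-side full keys for the triplet-doublet tier
  td <- doub[doub$tier == "TRIPLET_DOUBLET", , drop = FALSE]
  td_full <- c(td$full_key_a[td$has_cc_a], td$full_key_b[td$has_cc_b])

  tiers <- tibble(tier = match_tiers) %>%
    left_join(
      pairs %>% group_by(.data$tier) %>%
        summarise(total_matches = n(),
                  distinct_keys = n_distinct(.data$key)),
      by = "tier"
    ) %>%
    mutate(
      total_matches = ifelse(is.na(.data$total_matches), 0L,
                             .data$total_matches),
      distinct_keys = ifelse(is.na(.data$distinct_keys), 0L,
                             .data$distinct_keys),
      distinct_triplet_keys = ifelse(
        .data$tier == "TRIPLET_DOUBLET", length(unique(td_full)), NA_integer_
      )
    )
  stopifnot(all(tiers$distinct_keys <= tiers$total_matches))

  structure(
    list(
      tiers = tiers,
      pairs = pairs,
      ambiguous_keys = length(unique(doub$key[doub$ambiguous])),
      matched_keys = unique(pairs$key)
    ),
    class = "match_summary"
  )
}

#' @export
print.match_summary <- function(x, ...) {
  cat("<match_summary>\n")
  print(x$tiers)
  cat("ambiguous matched doublet keys:", x$ambiguous_keys, "\n")
  invisible(x)
}

#' Effective matches across three repositories
#'
#' Counts identifier keys participating in at least one cross-repository
#' match. The default definition takes the union of the distinct matched
#' keys over the three pairwise comparisons; alternatives are the
#' intersection (keys matched in all three) and the plain sum of pairwise
#' distinct counts.
#'
#' @param summaries List of (usually three) [match_corpora()] results.
#' @param method `"union"` (default), `"intersection"`, or `"sum"`.
#' @return Integer count.
#' @export
effective_matches <- function(summaries,
                              method = c("union", "intersection", "sum")) {
  method <- match.arg(method)
  key_sets <- lapply(summaries, `[[`, "matched_keys")
  switch(
    method,
    union = length(unique(unlist(key_sets))),
    intersection = length(Reduce(intersect, key_sets)),
    sum = sum(vapply(key_sets, length, integer(1)))
  )
}

#' Records holding a given doublet key
#'
#' Lists every identifier in a corpus whose doublet reduction (`"IC:CN"`)
#' equals the queried key. More than one hit means the doublet is
#' ambiguous: within that institution the catalog number occurs in several
#' collections (or several records), so the doublet cannot pinpoint a
#' specimen.
#'
#' @param doublet_key Key text `"IC:CN"`.
#' @param corpus An [identifier_corpus()] or identifier tibble.
#' @param case_insensitive Fold keys before comparison.
#' @return Tibble of matching identifier rows.
#' @export
doublet_candidates <- function(doublet_key, corpus,
                               case_insensitive = FALSE) {
  ids <- match_side(corpus, case_insensitive)
  key <- if (case_insensitive) toupper(doublet_key) else doublet_key
  hit <- !is.na(ids$doub_key) & ids$doub_key == key
  ids[hit, setdiff(names(ids),
                   c(".row", "canonical", "has_cc", "full_key", "doub_key"))]
}
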