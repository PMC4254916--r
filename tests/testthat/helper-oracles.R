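# Independent oracles used to cross-check the implementation.

# Structural canonical-triplet checker: a character walk with no regular
# expressions at all. The grammar's three sections are all deterministic
# under greedy matching (a colon is neither an upper- nor a lower-case
# letter), so a single left-to-right pass is exact.
oracle_is_canonical <- function(text) {
  x <- trimws(text)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_upper <- function(c) c %in% LETTERS
  is_lower <- function(c) c %in% letters
  i <- 1L
  while (i <= n && is_upper(ch[i])) i <- i + 1L
  ic_len <- i - 1L
  if (ic_len < 2L || ic_len > 8L) return(FALSE)
  if (i > n || ch[i] != ":") return(FALSE)
  i <- i + 1L
  if (i > n || !is_upper(ch[i])) return(FALSE)
  i <- i + 1L
  lo <- 0L
  while (i <= n && is_lower(ch[i])) { i <- i + 1L; lo <- lo + 1L }
  if (lo < 1L) return(FALSE)
  if (i > n || ch[i] != ":") return(FALSE)
  rest <- ch[-seq_len(i)]
  any(rest %in% as.character(0:9))
}

# Second, engine-based oracle: the same printed expression evaluated by
# R's TRE engine (the implementation uses PCRE).
tre_is_canonical <- function(text) {
  grepl(paste0("^(?:", dwc_canonical_regex, ")$"), trimws(text),
        perl = FALSE)
}

# Adversarial string generator: random concatenations of grammar-adjacent
# pieces (near-miss institution codes, wrong delimiters, digit-free tails,
# packed fields ...), plus mutations of valid triplets.
adversarial_strings <- function(n) {
  pieces <- c(
    "M", "MV", "MVZ", "ABCDEFGH", "ABCDEFGHI", "mvz", "Mvz", "M1Z",
    "Mamm", "MAMM", "mamm", "M", "Fish", "F", "Fo",
    "12345", "1", "ABCD", "B1978", "tissue", "",
    ":", "::", ".", "-", "_", "#", " ", ";", "(", ")", "/", "=", "urn:catalog:"
  )
  base <- vapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    paste(sample(pieces, k, replace = TRUE), collapse = "")
  }, character(1))
  valid <- vapply(seq_len(min(n, 500)), function(i) {
    paste(
      paste(sample(LETTERS, sample(2:8, 1), replace = TRUE), collapse = ""),
      paste0(sample(LETTERS, 1),
             paste(sample(letters, sample(1:6, 1), replace = TRUE),
                   collapse = "")),
      paste(sample(c(0:9, "A", "b"), sample(1:6, 1), replace = TRUE),
            collapse = ""),
      sep = ":"
    )
  }, character(1))
  mutate_one <- function(s) {
    pos <- sample(nchar(s), 1)
    paste0(substr(s, 1, pos - 1), sample(c(":", "a", "Z", "9", " ", ""), 1),
           substring(s, pos + 1))
  }
  out <- c(base, valid, vapply(valid, mutate_one, character(1)))
  out[nzchar(trimws(out))]
}

# O(n^2) all-pairs reference matcher, written directly from the tier
# definitions (no joins, no shared code with match_corpora).
oracle_match_corpora <- function(ids_a, ids_b) {
  tiers <- c("CANONICAL", "TRIPLET_TRIPLET", "TRIPLET_DOUBLET",
             "DOUBLET_DOUBLET")
  totals <- setNames(integer(4), tiers)
  keys <- setNames(list(character(0), character(0), character(0),
                        character(0)), tiers)
  pair_tier <- function(a, b) {
    complete_a <- !is.na(a$ic) && !is.na(a$cc) && !is.na(a$cn)
    complete_b <- !is.na(b$ic) && !is.na(b$cc) && !is.na(b$cn)
    doub_a <- !is.na(a$ic) && !is.na(a$cn)
    doub_b <- !is.na(b$ic) && !is.na(b$cn)
    if (complete_a && complete_b &&
          a$ic == b$ic && a$cc == b$cc && a$cn == b$cn) {
      if (a$rule_fired == "CANONICAL_REGEX" &&
            b$rule_fired == "CANONICAL_REGEX") {
        return(list(tier = "CANONICAL",
                    key = paste(a$ic, a$cc, a$cn, sep = ":")))
      }
      return(list(tier = "TRIPLET_TRIPLET",
                  key = paste(a$ic, a$cc, a$cn, sep = ":")))
    }
    if (doub_a && doub_b && a$ic == b$ic && a$cn == b$cn) {
      has_cc <- c(!is.na(a$cc), !is.na(b$cc))
      if (sum(has_cc) == 1L) {
        return(list(tier = "TRIPLET_DOUBLET",
                    key = paste(a$ic, a$cn, sep = ":")))
      }
      if (sum(has_cc) == 0L) {
        return(list(tier = "DOUBLET_DOUBLET",
                    key = paste(a$ic, a$cn, sep = ":")))
      }
    }
    NULL
  }
  for (i in seq_len(nrow(ids_a))) {
    for (j in seq_len(nrow(ids_b))) {
      hit <- pair_tier(ids_a[i, ], ids_b[j, ])
      if (!is.null(hit)) {
        totals[hit$tier] <- totals[hit$tier] + 1L
        keys[[hit$tier]] <- c(keys[[hit$tier]], hit$key)
      }
    }
  }
  data.frame(
    tier = tiers,
    total_matches = as.integer(totals),
    distinct_keys = vapply(keys, function(k) length(unique(k)), integer(1)),
    row.names = NULL
  )
}

# Random identifier tibble (not via the package generator): draws parts
# with controlled sparsity from a narrow vocabulary so cross-corpus key
# collisions are frequent.
random_identifier_tibble <- function(n, ic_pool = c("MVZ", "KU", "UAM"),
                                     cc_pool = c("Mamm", "Fish"),
                                     cn_pool = as.character(1:25)) {
  ic <- sample(ic_pool, n, replace = TRUE)
  cc <- sample(cc_pool, n, replace = TRUE)
  cn <- sample(cn_pool, n, replace = TRUE)
  drop_cc <- runif(n) < 0.35
  drop_ic <- runif(n) < 0.10
  cc[drop_cc] <- NA_character_
  ic[drop_ic] <- NA_character_
  raw <- ifelse(is.na(ic), cn,
                ifelse(is.na(cc), paste(ic, cn, sep = ":"),
                       paste(ic, cc, cn, sep = ":")))
  canonical <- !is.na(ic) & !is.na(cc) & runif(n) < 0.6
  tibble::tibble(
    repository = "SPECIMEN",
    record_id = sprintf("r%04d", seq_len(n)),
    source_field = "test",
    raw = raw,
    ic = ic, cc = cc, cn = cn,
    rule_fired = ifelse(canonical, "CANONICAL_REGEX",
                        ifelse(is.na(ic), "CN_DEFAULT_IC",
                               ifelse(is.na(cc), "IC_CN", "FIRST_THREE"))),
    used_default_ic = FALSE,
    used_default_cn = FALSE
  )
}

# all token-role presence patterns for exhaustive rule-exclusivity checks:
# representative tokens for each achievable role subset
role_pattern_tokens <- list(
  ic_only = "MVZ",        # {IC}
  cc_only = "Mamm",       # {CC}
  cn_only = "B1978",      # {CN}
  ic_cn = "AB1",          # impossible: IC excludes digits; kept as CN
  none = "tissue",        # {}
  cn_digits = "12345"     # {CN}, also a multi-digit default donor
)
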