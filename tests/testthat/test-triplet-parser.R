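test_that("is_canonical enforces the full canonical grammar", {
  expect_true(is_canonical("MVZ:Mamm:12345"))
  expect_false(is_canonical("M:Mamm:12345"))     # IC needs 2-8 capitals
  expect_false(is_canonical("MVZ:Mamm:ABCD"))    # CN needs a digit
  expect_false(is_canonical("MVZ Mamm 12345"))   # colons required
  expect_false(is_canonical("ABCDEFGHI:Mamm:1")) # 9-letter IC too long
  expect_false(is_canonical("MVZ:MAMM:1"))       # CC needs lowercase tail
  expect_false(is_canonical("xMVZ:Mamm:1"))      # anchored at both ends
  expect_true(is_canonical("  MVZ:Mamm:1  "))    # trimmed first
  expect_true(is_canonical("MVZ:Mamm:a1b"))      # CN is any digit-bearing text
  expect_error(is_canonical(""), "non-empty")
})

test_that("is_canonical optionally strips the urn:catalog: prefix", {
  expect_false(is_canonical("urn:catalog:MVZ:Mamm:12345"))
  expect_true(is_canonical("urn:catalog:MVZ:Mamm:12345", strip_urn = TRUE))
  expect_true(is_canonical("MVZ:Mamm:12345", strip_urn = TRUE))
})

test_that("is_canonical agrees with the structural and TRE oracles", {
  withr::with_seed(101, {
    strings <- adversarial_strings(2000)
    got <- is_canonical(strings)
    expect_equal(got, vapply(strings, oracle_is_canonical, logical(1),
                             USE.NAMES = FALSE))
    expect_equal(got, tre_is_canonical(strings))
    expect_gt(sum(got), 0)  # the set must actually exercise both outcomes
    expect_gt(sum(!got), 0)
  })
})

test_that("split_fragments breaks on semicolons and open parentheses", {
  expect_equal(split_fragments("MVZ:Mamm:1; MVZ:Mamm:2"),
               c("MVZ:Mamm:1", "MVZ:Mamm:2"))
  expect_equal(split_fragments("KU 123 (also KU 124)"),
               c("KU 123", "also KU 124)"))
  expect_equal(split_fragments("ABC:De:9"), "ABC:De:9")
  expect_equal(split_fragments(";;"), character(0))
})

test_that("tokenize splits on the six delimiters and drops empty tokens", {
  expect_equal(tokenize("MVZ:Mamm:12345"), c("MVZ", "Mamm", "12345"))
  expect_equal(tokenize("UAM_Fish_100"), c("UAM", "Fish", "100"))
  expect_equal(tokenize("12345"), "12345")
  expect_equal(tokenize("A::B..C--D__E##F  G"),
               c("A", "B", "C", "D", "E", "F", "G"))
})

test_that("token_roles applies the three role rules", {
  expect_equal(token_roles("MVZ"), "IC")
  expect_equal(token_roles("Mamm"), "CC")
  expect_equal(token_roles("B1978"), "CN")
  expect_equal(token_roles("tissue"), character(0))
  expect_equal(token_roles("M"), character(0))      # single capital: no role
  expect_equal(token_roles("ABCDEFGHI"), character(0)) # too long for IC
  expect_equal(token_roles("12345"), "CN")
})

test_that("scan_defaults inspects only the final token", {
  expect_equal(scan_defaults(c("Fish", "12345", "UWFC")),
               list(default_ic = "UWFC", default_cn = NA_character_))
  expect_equal(scan_defaults(c("MVZ", "Mamm", "4567")),
               list(default_ic = NA_character_, default_cn = "4567"))
  expect_equal(scan_defaults("only"),
               list(default_ic = NA_character_, default_cn = NA_character_))
  # single digit is not a multi-digit number; a donor mid-list is ignored
  expect_true(is.na(scan_defaults(c("UWFC", "7"))$default_cn))
  expect_true(is.na(scan_defaults(c("UWFC", "7"))$default_ic))
})

test_that("coerce_tokens applies the five rules in printed order", {
  run <- function(toks) coerce_tokens(toks, scan_defaults(toks))

  r <- run(c("MVZ", "Mamm", "12345"))
  expect_equal(r$rule_fired, "FIRST_THREE")
  expect_equal(c(r$ic, r$cc, r$cn), c("MVZ", "Mamm", "12345"))

  r <- run(c("MVZ", "12345"))
  expect_equal(r$rule_fired, "IC_CN")
  expect_equal(c(r$ic, r$cn), c("MVZ", "12345"))
  expect_true(is.na(r$cc))

  r <- run(c("MVZ", "Mamm", "tissue", "4567"))
  expect_equal(r$rule_fired, "IC_CC_DEFAULT_CN")
  expect_equal(c(r$ic, r$cc, r$cn), c("MVZ", "Mamm", "4567"))
  expect_true(r$used_default_cn)

  r <- run(c("Fish", "12345", "UWFC"))
  expect_equal(r$rule_fired, "CC_CN_DEFAULT_IC")
  expect_equal(c(r$ic, r$cc, r$cn), c("UWFC", "Fish", "12345"))
  expect_true(r$used_default_ic)

  r <- run("12345")
  expect_equal(r$rule_fired, "CN_DEFAULT_IC")
  expect_true(is.na(r$ic))
  expect_equal(r$cn, "12345")

  r <- run("tissue")
  expect_equal(r$rule_fired, "UNPARSEABLE")
  expect_true(all(is.na(c(r$ic, r$cc, r$cn))))
})

test_that("exactly one rule fires for every token-role pattern", {
  # roles are mutually exclusive per token, so six representatives cover
  # every achievable pattern (incl. both default-donor subtypes of the
  # final token) for lists of up to 4 tokens
  reps <- c("MVZ", "Mamm", "B1978", "12345", "tissue", "M")
  for (k in 1:4) {
    grids <- do.call(expand.grid,
                     c(rep(list(reps), k), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grids))) {
      toks <- as.character(grids[i, ])
      r <- coerce_tokens(toks, scan_defaults(toks))
      expect_length(r$rule_fired, 1L)
      expect_true(r$rule_fired %in% c(
        "FIRST_THREE", "IC_CN", "IC_CC_DEFAULT_CN", "CC_CN_DEFAULT_IC",
        "CN_DEFAULT_IC", "UNPARSEABLE"
      ))
      if (r$rule_fired == "UNPARSEABLE") {
        expect_true(all(is.na(c(r$ic, r$cc, r$cn))))
      } else {
        expect_false(all(is.na(c(r$ic, r$cc, r$cn))))
      }
    }
  }
})

test_that("parse_field recognizes canonical text and coerces the rest", {
  r <- parse_field("MVZ:Mamm:12345")
  expect_equal(r$rule_fired, "CANONICAL_REGEX")
  expect_equal(c(r$ic, r$cc, r$cn), c("MVZ", "Mamm", "12345"))

  r <- parse_field("MVZ:Mamm:1; 2345")
  expect_equal(nrow(r), 2L)
  expect_equal(r$rule_fired, c("CANONICAL_REGEX", "CN_DEFAULT_IC"))
  expect_equal(r$cn, c("1", "2345"))
  expect_true(is.na(r$ic[2]))  # CN-only before record-level propagation

  expect_equal(nrow(parse_field("")), 0L)
  expect_equal(nrow(parse_field(NA_character_)), 0L)

  # stray ")" from fragment splitting is stripped before tokenization
  r <- parse_field("KU 123 (KU 124)")
  expect_equal(r$rule_fired, c("IC_CN", "IC_CN"))
  expect_equal(r$cn, c("123", "124"))
})

test_that("canonical fragments inside a multi-identifier field short-circuit", {
  r <- parse_field("USNM 54321; MVZ:Mamm:12345")
  expect_equal(r$rule_fired, c("IC_CN", "CANONICAL_REGEX"))
})

test_that("propagate_record_ic donates the first IC and is idempotent", {
  ids <- parse_field("MVZ:Mamm:1; 2345")
  out <- propagate_record_ic(ids)
  expect_equal(out$ic, c("MVZ", "MVZ"))
  expect_true(out$used_default_ic[2])
  expect_false(out$used_default_ic[1])
  expect_identical(propagate_record_ic(out), out)

  # no donor: unchanged
  solo <- parse_field("2345")
  expect_identical(propagate_record_ic(solo), solo)

  # identifiers that already have an IC are never modified; first IC in
  # document order is the donor when several disagree
  two <- dplyr::bind_rows(parse_field("KU 1"), parse_field("MVZ 2"),
                          parse_field("345"))
  out <- propagate_record_ic(two)
  expect_equal(out$ic, c("KU", "MVZ", "KU"))
})

test_that("canonical_form renders triplets and doublet keys", {
  expect_equal(canonical_form("MVZ", "Mamm", "12345"), "MVZ:Mamm:12345")
  expect_equal(canonical_form("MVZ", NA, "12345"), "MVZ:12345")
  expect_equal(canonical_form(triplet_parts("MVZ", NA, "1")), "MVZ:1")
  expect_error(canonical_form(NA, NA, "12345"), "ic and cn")
  expect_error(canonical_form("MVZ", "Mamm", NA), "ic and cn")
})

test_that("parse_field inverts canonical_form on role-valid triplets", {
  withr::with_seed(77, {
    for (i in 1:200) {
      ic <- paste(sample(LETTERS, sample(2:8, 1), replace = TRUE),
                  collapse = "")
      cc <- paste0(sample(LETTERS, 1),
                   paste(sample(letters, sample(1:7, 1), replace = TRUE),
                         collapse = ""))
      cn <- paste(sample(c(0:9, "A", "b"), sample(1:6, 1), replace = TRUE),
                  collapse = "")
      if (!grepl("[0-9]", cn)) cn <- paste0(cn, "1")
      r <- parse_field(canonical_form(ic, cc, cn))
      expect_equal(r$rule_fired, "CANONICAL_REGEX")
      expect_equal(c(r$ic, r$cc, r$cn), c(ic, cc, cn))
    }
  })
})

test_that("canonical text coerces to the same parts as the regex split", {
  withr::with_seed(78, {
    for (i in 1:100) {
      ic <- paste(sample(LETTERS, sample(2:8, 1), replace = TRUE),
                  collapse = "")
      cc <- paste0(sample(LETTERS, 1),
                   paste(sample(letters, sample(1:7, 1), replace = TRUE),
                         collapse = ""))
      cn <- paste(sample(0:9, sample(1:6, 1), replace = TRUE), collapse = "")
      text <- paste(ic, cc, cn, sep = ":")
      toks <- tokenize(text)
      r <- coerce_tokens(toks, scan_defaults(toks))
      expect_equal(r$rule_fired, "FIRST_THREE")
      expect_equal(c(r$ic, r$cc, r$cn), c(ic, cc, cn))
    }
  })
})
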