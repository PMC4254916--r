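# fixtures are built in code and written to tempfiles

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

dwc_fixture <- function() {
  write_tmp(c(
    "institutionCode\tcollectionCode\tcatalogNumber",
    "MVZ\tMamm\t12345",
    "MVZ\t\t12345",
    "\t\t",
    "KU\tFish\tno-digit",
    "\t\t999"
  ), ext = ".tsv")
}

test_that("read_dwc_occurrences joins the three mapped columns", {
  corpus <- read_dwc_occurrences(dwc_fixture())
  expect_s3_class(corpus, "identifier_corpus")
  expect_equal(nrow(corpus$records), 5L)
  ids <- corpus$identifiers
  expect_equal(nrow(ids), 4L)  # the all-empty row yields no identifier

  expect_equal(ids$raw[1], "MVZ:Mamm:12345")
  expect_equal(ids$rule_fired[1], "CANONICAL_REGEX")
  # doublet row: parts come from the cells, collection code absent
  expect_equal(ids$raw[2], "MVZ:12345")
  expect_true(is.na(ids$cc[2]))
  expect_equal(completeness(ids$ic[2], ids$cc[2], ids$cn[2]), "DOUBLET")
  # catalogNumber without a digit is kept verbatim as a cell value
  expect_equal(ids$cn[3], "no-digit")
  # bare catalog number row
  expect_equal(ids$cn[4], "999")
  expect_true(is.na(ids$ic[4]))
})

test_that("read_dwc_occurrences honors column maps and flags missing ones", {
  path <- write_tmp(c("inst,coll,cat", "MVZ,Mamm,1"), ext = ".csv")
  corpus <- read_dwc_occurrences(
    path, column_map = c(institution_code = "inst", collection_code = "coll",
                         catalog_number = "cat"))
  expect_equal(corpus$identifiers$raw, "MVZ:Mamm:1")
  expect_error(read_dwc_occurrences(path), "institutionCode")
})

gbff_fixture <- function() {
  recs <- data.frame(
    accession = c("AY00001", "AY00002", "AY00003", "AY00004"),
    organism = "Synthetica exempli",
    voucher = c("MVZ:Mamm:12345", "USNM 54321", NA,
                paste0("a rather long free text voucher note mentioning ",
                       "MVZ:Mamm:99999 somewhere near its end")),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".gbff")
  dwcaudit:::write_gbff(recs, path)
  path
}

test_that("extract_genbank_vouchers parses specimen_voucher per accession", {
  corpus <- extract_genbank_vouchers(gbff_fixture())
  expect_equal(corpus$repository, "GENBANK")
  expect_equal(nrow(corpus$records), 4L)
  # the voucher-less record is counted but contributes nothing
  expect_equal(sum(corpus$records$has_specimen_info), 3L)
  ids <- corpus$identifiers
  expect_equal(ids$record_id[1:2], c("AY00001", "AY00002"))
  expect_equal(ids$rule_fired[1], "CANONICAL_REGEX")
  # INSDC-style "USNM 54321" coerces to a doublet
  expect_equal(ids$rule_fired[2], "IC_CN")
  expect_equal(c(ids$ic[2], ids$cn[2]), c("USNM", "54321"))
})

test_that("continuation-line unwrapping restores wrapped voucher values", {
  corpus <- extract_genbank_vouchers(gbff_fixture())
  long <- corpus$identifiers[corpus$identifiers$record_id == "AY00004", ]
  expect_equal(long$raw, paste0(
    "a rather long free text voucher note mentioning ",
    "MVZ:Mamm:99999 somewhere near its end"))
})

test_that("qualifiers other than specimen_voucher are never read", {
  lines <- c(
    "LOCUS       XX00001                 60 bp    DNA     linear   VRT",
    "ACCESSION   XX00001",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"Synthetica exempli\"",
    "                     /isolate=\"MVZ:Mamm:11111\"",
    "                     /db_xref=\"taxon:9999\"",
    "                     /note=\"voucher MVZ:Mamm:22222\"",
    "     gene            1..60",
    "                     /specimen_voucher=\"NOT:A:source feature\"",
    "//"
  )
  corpus <- extract_genbank_vouchers(write_tmp(lines, ".gbff"))
  expect_equal(nrow(corpus$identifiers), 0L)
  expect_equal(sum(corpus$records$has_specimen_info), 0L)
})

test_that("multiple specimen_voucher qualifiers share record-level IC", {
  lines <- c(
    "LOCUS       XX00002                 60 bp    DNA     linear   VRT",
    "ACCESSION   XX00002",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /specimen_voucher=\"MVZ:Mamm:1\"",
    "                     /specimen_voucher=\"2345\"",
    "//"
  )
  corpus <- extract_genbank_vouchers(write_tmp(lines, ".gbff"))
  expect_equal(nrow(corpus$identifiers), 2L)
  expect_equal(corpus$identifiers$ic, c("MVZ", "MVZ"))
  expect_true(corpus$identifiers$used_default_ic[2])
})

test_that("malformed flat files raise a format error with the offset", {
  expect_error(extract_genbank_vouchers(write_tmp(c("junk", "lines"))),
               "no record terminator")
  expect_error(
    extract_genbank_vouchers(write_tmp(c("not a locus", "//"))),
    "record 1"
  )
})

test_that("reconcile_bold_fields covers the four agreement cases", {
  r <- reconcile_bold_fields("A:Bc:1", "")
  expect_equal(r$agreement, "ONLY_ONE")
  expect_equal(r$texts, "A:Bc:1")

  r <- reconcile_bold_fields("", "A:Bc:1")
  expect_equal(r$agreement, "ONLY_ONE")
  expect_equal(r$fields, "sampleid")

  r <- reconcile_bold_fields("A:Bc:1", "A:Bc:1")
  expect_equal(r$agreement, "EXACT_MATCH")
  expect_equal(r$texts, "A:Bc:1")

  r <- reconcile_bold_fields("A:Bc:1", "XYZ 2")
  expect_equal(r$agreement, "DISAGREE")
  expect_equal(r$texts, c("A:Bc:1", "XYZ 2"))  # catalognum first

  expect_equal(reconcile_bold_fields("", "")$agreement, "BOTH_EMPTY")
})

test_that("read_bold_table parses both fields and keeps reconciliation", {
  path <- write_tmp(c(
    "processid\tcatalognum\tsampleid",
    "P1\tROM:Birds:12\t",
    "P2\tMVZ:Mamm:1\tMVZ:Mamm:1",
    "P3\tKU:Fish:9\tUAM 77",
    "P4\t\t"
  ), ext = ".tsv")
  corpus <- read_bold_table(
    path, column_map = c(catalognum = "catalognum", sampleid = "sampleid",
                         record_id = "processid"))
  expect_equal(corpus$repository, "BOLD")
  recon <- corpus$extra$bold_reconciliation
  expect_equal(recon$agreement,
               c("ONLY_ONE", "EXACT_MATCH", "DISAGREE", "BOTH_EMPTY"))
  ids <- corpus$identifiers
  # DISAGREE contributes two candidate identifiers, others at most one
  expect_equal(sum(ids$record_id == "P3"), 2L)
  expect_equal(ids$source_field[ids$record_id == "P3"],
               c("catalognum", "sampleid"))
  expect_equal(sum(ids$record_id == "P2"), 1L)
  expect_equal(nrow(ids[ids$record_id == "P4", ]), 0L)
})

test_that("linkout_tail isolates the URL tail after '/' then '='", {
  expect_equal(linkout_tail("http://arctos.database.museum/guid/MVZ:Mamm:12345"),
               "MVZ:Mamm:12345")
  expect_equal(linkout_tail("http://x.org/fetch?id=KU:Fish:99"), "KU:Fish:99")
  expect_equal(linkout_tail("http://x.org/"), "")
  expect_equal(linkout_tail("http://x.org/a=1=KU:Fish:2"), "KU:Fish:2")
})

test_that("read_linkout_urls builds a GenBank-side corpus", {
  path <- write_tmp(c(
    "AY1\thttp://arctos.database.museum/guid/MVZ:Mamm:12345",
    "AY2\thttp://x.org/"
  ), ext = ".tsv")
  corpus <- read_linkout_urls(path)
  expect_equal(corpus$repository, "GENBANK")
  expect_equal(nrow(corpus$identifiers), 1L)
  expect_equal(corpus$identifiers$source_field, "linkout")
  expect_equal(corpus$identifiers$rule_fired, "CANONICAL_REGEX")
})

test_that("corpus conservation: emitted + voucherless = records read", {
  spec <- synthetic_spec(n_records = 150, seed = 9)
  paths <- generate_linked_corpora(spec, tempfile())
  for (corpus in list(read_dwc_occurrences(paths$specimen),
                      extract_genbank_vouchers(paths$genbank),
                      read_bold_table(paths$bold))) {
    n_with <- sum(corpus$records$has_specimen_info)
    n_without <- sum(!corpus$records$has_specimen_info)
    expect_equal(n_with + n_without, nrow(corpus$records))
    expect_setequal(unique(corpus$identifiers$record_id),
                    corpus$records$record_id[corpus$records$n_identifiers > 0])
  }
})

test_that("adapters are order-stable: same file, identical corpus", {
  spec <- synthetic_spec(n_records = 60, seed = 10)
  paths <- generate_linked_corpora(spec, tempfile())
  a <- extract_genbank_vouchers(paths$genbank)
  b <- extract_genbank_vouchers(paths$genbank)
  expect_identical(a$identifiers, b$identifiers)
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(a, f1); write_corpus(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the institution-code allowlist filters identifiers", {
  corpus <- read_dwc_occurrences(dwc_fixture(), allowlist = c("MVZ"))
  expect_true(all(is.na(corpus$identifiers$ic) |
                    corpus$identifiers$ic == "MVZ"))
  full <- read_dwc_occurrences(dwc_fixture())
  expect_gt(nrow(full$identifiers), nrow(corpus$identifiers) - 1)
})

test_that("write_corpus/read_corpus round-trip the identifier table", {
  corpus <- read_dwc_occurrences(dwc_fixture())
  path <- tempfile(fileext = ".tsv")
  write_corpus(corpus, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(c("repository", "record_id", "source_field",
                               "raw", "IC", "CC", "CN", "rule_fired"),
                             collapse = "\t"))
  back <- read_corpus(path)
  expect_equal(back$ic, corpus$identifiers$ic)
  expect_equal(back$raw, corpus$identifiers$raw)
})
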