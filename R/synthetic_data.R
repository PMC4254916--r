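# Seeded generator for offline three-repository test corpora: a structured
# specimen occurrence table, a GenBank-style flat file whose
# /specimen_voucher values are corrupted renderings of specimen
# identifiers, and a BOLD-style TSV with catalognum/sampleid agreement
# cases -- all with ground truth for every planted identifier and link.

corruption_labels <- c("CANONICAL", "DELIMITER_SWAP", "MISSING_CC",
                       "BARE_CN", "MULTI")

#' Specification for synthetic identifier corpora
#'
#' Collects the sizes, corruption rates and linkage parameters that drive
#' the generator. Corruption outcomes are mutually exclusive per
#' identifier: each identifier draws one label from a categorical
#' distribution over canonical rendering, delimiter substitution, dropped
#' collection code (doublet), bare catalog number, and multi-identifier
#' packing; any residual probability mass goes to the canonical outcome.
#'
#' Defaults emulate a messy sequence-repository profile: half the vouchers
#' canonical, the rest corrupted, 80% of sequence records lacking a
#' voucher qualifier altogether, and half the sequence/barcode records
#' genuinely referring to a specimen record.
#'
#' @param n_records Records per corpus.
#' @param seed Integer seed; the three corpora draw from deterministic
#'   per-corpus substreams of it.
#' @param rate_canonical,rate_delimiter_swap,rate_missing_cc,rate_bare_cn,rate_multi_identifier
#'   Corruption-outcome probabilities (must sum to at most 1).
#' @param rate_no_voucher Probability a GenBank-style record carries no
#'   `specimen_voucher` qualifier.
#' @param linked_fraction Probability a sequence/barcode record references
#'   a specimen record (the planted ground-truth links).
#' @param bold_exact,bold_disagree Among voucher-bearing BOLD rows, the
#'   probability that `sampleid` repeats `catalognum` exactly, and that it
#'   holds a conflicting local sample code; the residual leaves `sampleid`
#'   empty.
#' @param ic_vocab,cc_vocab Institution and collection code vocabularies.
#' @param cn_range Integer interval catalog numbers are drawn from; narrow
#'   it to force catalog-number collisions across collections and exercise
#'   doublet ambiguity.
#' @param avoid_cross_collisions Draw unlinked sequence-side identifiers so
#'   that their (IC, CN) pairs never collide with specimen identifiers,
#'   making planted links the only true matches (set `FALSE` to allow
#'   chance collisions).
#' @return Object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(n_records = 1000L,
                           seed = 20140101L,
                           rate_canonical = 0.50,
                           rate_delimiter_swap = 0.15,
                           rate_missing_cc = 0.20,
                           rate_bare_cn = 0.10,
                           rate_multi_identifier = 0.05,
                           rate_no_voucher = 0.80,
                           linked_fraction = 0.50,
                           bold_exact = 0.45,
                           bold_disagree = 0.35,
                           ic_vocab = c("MVZ", "KU", "UAM", "USNM", "UWFC",
                                        "ROM", "FMNH", "ANSP"),
                           cc_vocab = c("Mamm", "Fish", "Herp", "Bird",
                                        "Ornith", "Ento"),
                           cn_range = c(1L, 99999L),
                           avoid_cross_collisions = TRUE) {
  rates <- c(rate_canonical, rate_delimiter_swap, rate_missing_cc,
             rate_bare_cn, rate_multi_identifier)
  probs <- c(rates, rate_no_voucher, linked_fraction, bold_exact,
             bold_disagree)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (sum(rates) > 1 + 1e-9) {
    stop("corruption-outcome rates must sum to at most 1", call. = FALSE)
  }
  if (bold_exact + bold_disagree > 1 + 1e-9) {
    stop("bold_exact + bold_disagree must be at most 1", call. = FALSE)
  }
  stopifnot(n_records >= 1L, length(cn_range) == 2L,
            cn_range[1] <= cn_range[2])
  structure(
    list(
      n_records = as.integer(n_records), seed = as.integer(seed),
      rate_canonical = rate_canonical + (1 - sum(rates)),
      rate_delimiter_swap = rate_delimiter_swap,
      rate_missing_cc = rate_missing_cc, rate_bare_cn = rate_bare_cn,
      rate_multi_identifier = rate_multi_identifier,
      rate_no_voucher = rate_no_voucher, linked_fraction = linked_fraction,
      bold_exact = bold_exact, bold_disagree = bold_disagree,
      ic_vocab = ic_vocab, cc_vocab = cc_vocab,
      cn_range = as.integer(cn_range),
      avoid_cross_collisions = avoid_cross_collisions
    ),
    class = "synthetic_spec"
  )
}

corruption_probs <- function(spec) {
  setNames(
    c(spec$rate_canonical, spec$rate_delimiter_swap, spec$rate_missing_cc,
      spec$rate_bare_cn, spec$rate_multi_identifier),
    corruption_labels
  )
}

# deterministic per-corpus substream of the global seed (kept below 2^31)
sub_seed <- function(seed, k) (seed %% 1000000L) * 1000L + k

draw_parts <- function(n, spec) {
  tibble(
    ic = sample(spec$ic_vocab, n, replace = TRUE),
    cc = sample(spec$cc_vocab, n, replace = TRUE),
    cn = as.character(sample(seq(spec$cn_range[1], spec$cn_range[2]),
                             n, replace = TRUE))
  )
}

#' Render a corrupted identifier text
#'
#' Renders complete triplet parts as raw text under one corruption label:
#' `CANONICAL` joins with colons; `DELIMITER_SWAP` joins with a random
#' non-colon delimiter from the tokenization alphabet; `MISSING_CC` drops
#' the collection code (`"IC:CN"`); `BARE_CN` keeps only the catalog
#' number; `MULTI` packs the canonical rendering and a second bare catalog
#' number behind `"; "`.
#'
#' @param ic,cc,cn Complete triplet parts (single values).
#' @param corruption One of
#'   `"CANONICAL"`, `"DELIMITER_SWAP"`, `"MISSING_CC"`, `"BARE_CN"`,
#'   `"MULTI"`.
#' @param extra_cn Secondary catalog number used by `MULTI` (defaults to
#'   `cn` with a suffix digit).
#' @return Raw identifier text. Uses the session RNG for the random
#'   delimiter; seed externally for reproducibility.
#' @examples
#' corrupt_identifier("MVZ", "Mamm", "1", "MISSING_CC") # "MVZ:1"
#' @export
corrupt_identifier <- function(ic, cc, cn, corruption,
                               extra_cn = paste0(cn, "9")) {
  corruption <- match.arg(corruption, corruption_labels)
  stopifnot(!is.na(ic), !is.na(cc), !is.na(cn))
  switch(
    corruption,
    CANONICAL = paste(ic, cc, cn, sep = ":"),
    DELIMITER_SWAP = {
      d <- sample(setdiff(dwc_token_delimiters, ":"), 1L)
      paste(ic, cc, cn, sep = d)
    },
    MISSING_CC = paste(ic, cn, sep = ":"),
    BARE_CN = cn,
    MULTI = paste0(paste(ic, cc, cn, sep = ":"), "; ", extra_cn)
  )
}

# class label the audit taxonomy should assign to the primary identifier
# rendered under each corruption label
implied_class <- c(
  CANONICAL = "CANONICAL", DELIMITER_SWAP = "SYNTACTIC_ONLY",
  MISSING_CC = "MISSING_ONLY", BARE_CN = "BOTH", MULTI = "CANONICAL"
)

#' Generate a synthetic specimen occurrence table
#'
#' Emulates a curated occurrence dataset: a delimited table with
#' `institutionCode`, `collectionCode` and `catalogNumber` columns. The
#' structured format can only express missing data, so `MISSING_CC` empties
#' the `collectionCode` cell, `BARE_CN` empties both code cells, and every
#' other corruption outcome leaves the row fully populated.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (occurrence tibble, including an
#'   `occurrenceID` row key) and `truth` (ground-truth tibble: record id,
#'   true parts, corruption label).
#' @export
generate_specimen_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(sub_seed(spec$seed, 1L), {
    n <- spec$n_records
    parts <- draw_parts(n, spec)
    # occurrence rows must be unique specimens: no duplicate (ic, cc, cn)
    dup <- duplicated(parts)
    tries <- 0L
    while (any(dup)) {
      parts[dup, ] <- draw_parts(sum(dup), spec)
      dup <- duplicated(parts)
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("cannot draw ", n, " distinct specimens from the configured ",
             "ic/cc vocabularies and cn_range", call. = FALSE)
      }
    }
    corruption <- sample(corruption_labels, n, replace = TRUE,
                         prob = corruption_probs(spec))
    tab <- tibble(
      occurrenceID = sprintf("occ%06d", seq_len(n)),
      institutionCode = parts$ic,
      collectionCode = ifelse(corruption %in% c("MISSING_CC", "BARE_CN"),
                              "", parts$cc),
      catalogNumber = parts$cn
    )
    tab$institutionCode[corruption == "BARE_CN"] <- ""
    truth <- tibble(
      repository = "SPECIMEN", record_id = tab$occurrenceID,
      true_ic = parts$ic, true_cc = parts$cc, true_cn = parts$cn,
      corruption = corruption, link_target = NA_character_,
      has_voucher = TRUE
    )
    list(table = tab, truth = truth)
  })
}

# draw sequence-side identifiers: linked rows copy specimen parts,
# unlinked rows draw fresh parts (optionally avoiding IC:CN collisions
# with the specimen corpus)
draw_sequence_parts <- function(n, spec, specimen_truth) {
  linked <- stats::runif(n) < spec$linked_fraction
  target_idx <- sample(nrow(specimen_truth), n, replace = TRUE)
  parts <- tibble(
    ic = specimen_truth$true_ic[target_idx],
    cc = specimen_truth$true_cc[target_idx],
    cn = specimen_truth$true_cn[target_idx],
    link_target = specimen_truth$record_id[target_idx]
  )
  n_un <- sum(!linked)
  if (n_un > 0L) {
    fresh <- draw_parts(n_un, spec)
    if (spec$avoid_cross_collisions) {
      taken <- paste(specimen_truth$true_ic, specimen_truth$true_cn)
      for (tries in 1:50) {
        clash <- paste(fresh$ic, fresh$cn) %in% taken
        if (!any(clash)) break
        fresh[clash, ] <- draw_parts(sum(clash), spec)
      }
    }
    parts$ic[!linked] <- fresh$ic
    parts$cc[!linked] <- fresh$cc
    parts$cn[!linked] <- fresh$cn
    parts$link_target[!linked] <- NA_character_
  }
  parts
}

#' Generate linked three-repository corpora
#'
#' Produces a specimen occurrence table, a GenBank-style flat file whose
#' `/specimen_voucher` qualifiers are corrupted renderings of (mostly)
#' specimen identifiers, and a BOLD-style TSV whose `catalognum` /
#' `sampleid` fields exercise the agreement cases -- together with a
#' ground-truth table recording every planted identifier and link. With
#' probability `rate_no_voucher` a sequence record omits the voucher
#' qualifier entirely.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Directory to write the corpus files into (created if
#'   needed).
#' @return List with the file paths (`specimen`, `genbank`, `bold`,
#'   `ground_truth`) and the combined `truth` tibble.
#' @export
generate_linked_corpora <- function(spec, dir = tempfile("synth")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- generate_specimen_corpus(spec)

  gb <- withr::with_seed(sub_seed(spec$seed, 2L), {
    n <- spec$n_records
    acc <- sprintf("SY%06d", seq_len(n))
    has_voucher <- stats::runif(n) >= spec$rate_no_voucher
    parts <- draw_sequence_parts(n, spec, sp$truth)
    corruption <- sample(corruption_labels, n, replace = TRUE,
                         prob = corruption_probs(spec))
    voucher <- rep(NA_character_, n)
    for (i in which(has_voucher)) {
      voucher[i] <- corrupt_identifier(parts$ic[i], parts$cc[i],
                                       parts$cn[i], corruption[i])
    }
    list(
      records = tibble(accession = acc, organism = "Synthetica exempli",
                       voucher = voucher),
      truth = tibble(
        repository = "GENBANK", record_id = acc,
        true_ic = parts$ic, true_cc = parts$cc, true_cn = parts$cn,
        corruption = corruption,
        link_target = ifelse(has_voucher, parts$link_target, NA_character_),
        has_voucher = has_voucher
      )
    )
  })

  bold <- withr::with_seed(sub_seed(spec$seed, 3L), {
    n <- spec$n_records
    pid <- sprintf("SYNB%05d", seq_len(n))
    parts <- draw_sequence_parts(n, spec, sp$truth)
    corruption <- sample(corruption_labels, n, replace = TRUE,
                         prob = corruption_probs(spec))
    catalognum <- vapply(seq_len(n), function(i) {
      corrupt_identifier(parts$ic[i], parts$cc[i], parts$cn[i],
                         corruption[i])
    }, character(1))
    u <- stats::runif(n)
    sampleid <- ifelse(
      u < spec$bold_exact, catalognum,
      ifelse(u < spec$bold_exact + spec$bold_disagree,
             sprintf("BIOUG%05d", sample(99999L, n, replace = TRUE)), "")
    )
    list(
      table = tibble(processid = pid, catalognum = catalognum,
                     sampleid = sampleid),
      truth = tibble(
        repository = "BOLD", record_id = pid,
        true_ic = parts$ic, true_cc = parts$cc, true_cn = parts$cn,
        corruption = corruption, link_target = parts$link_target,
        has_voucher = TRUE
      )
    )
  })

  truth <- bind_rows(sp$truth, gb$truth, bold$truth)
  paths <- list(
    specimen = file.path(dir, "specimen_occurrences.tsv"),
    genbank = file.path(dir, "sequences.gbff"),
    bold = file.path(dir, "bold_specimens.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  readr::write_tsv(sp$table, paths$specimen, na = "")
  write_gbff(as.data.frame(gb$records), paths$genbank)
  readr::write_tsv(bold$table, paths$bold, na = "")
  readr::write_tsv(truth, paths$ground_truth, na = "")
  c(paths, list(truth = truth))
}
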