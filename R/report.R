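# End-to-end pipeline: ingest -> parse -> classify -> match -> report.
# Produces the three audit tables (per-repository triplet summary,
# irregularity breakdown, cross-repository match tiers), a machine-readable
# summary JSON, a match detail file and a run log.

#' Run the full identifier audit
#'
#' Ingests up to three repository corpora, classifies every identifier,
#' matches each pair of corpora at tiered precision, counts effective
#' matches across all pairs, and writes the report files (see
#' [render_tables()]) plus a run log with per-stage counts. All processing
#' on fixed inputs is deterministic.
#'
#' @param specimen,genbank,bold Paths to a Darwin Core occurrence table, a
#'   GenBank flat file and a BOLD specimen TSV; any may be `NULL` to skip
#'   that corpus.
#' @param linkout Optional accession/URL list; its identifiers are appended
#'   to the GenBank corpus records.
#' @param out_dir Output directory for report files (created; `NULL`
#'   disables writing).
#' @param allowlist Optional institution-code allowlist file (one code per
#'   line) or character vector.
#' @param column_maps Optional list with elements `specimen` and/or `bold`
#'   overriding the adapter column maps.
#' @param strip_urn,case_insensitive Normalization switches (see
#'   [is_canonical()] and [match_corpora()]).
#' @param effective_method Effective-match definition (see
#'   [effective_matches()]).
#' @return List of class `dwc_audit`: `corpora` (named list of classified
#'   corpora), `audit` (per-repository summaries), `irregularities`, `matches`
#'   (named list of `match_summary` objects), `effective_matches`,
#'   `overlap_pct`, and `files` (paths written).
#' @export
run_audit <- function(specimen = NULL, genbank = NULL, bold = NULL,
                      linkout = NULL, out_dir = NULL, allowlist = NULL,
                      column_maps = list(), strip_urn = FALSE,
                      case_insensitive = FALSE,
                      effective_method = c("union", "intersection", "sum")) {
  effective_method <- match.arg(effective_method)
  inputs <- c(specimen = specimen, genbank = genbank, bold = bold,
              linkout = linkout)
  missing_in <- inputs[!vapply(inputs, file.exists, logical(1))]
  if (length(missing_in) > 0L) {
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing_in, names(missing_in)),
               collapse = ", "), call. = FALSE)
  }
  if (is.character(allowlist) && length(allowlist) == 1L &&
        file.exists(allowlist)) {
    allowlist <- readr::read_lines(allowlist)
    allowlist <- trimws(allowlist[nzchar(trimws(allowlist))])
  }

  corpora <- list()
  if (!is.null(specimen)) {
    args <- list(path = specimen, allowlist = allowlist)
    if (!is.null(column_maps$specimen)) args$column_map <- column_maps$specimen
    corpora$specimen <- classify_corpus(do.call(read_dwc_occurrences, args))
  }
  if (!is.null(genbank)) {
    gb <- extract_genbank_vouchers(genbank, allowlist = allowlist,
                                   strip_urn = strip_urn)
    if (!is.null(linkout)) {
      lo <- read_linkout_urls(linkout, allowlist = allowlist)
      gb <- merge_genbank_linkout(gb, lo)
    }
    corpora$genbank <- classify_corpus(gb)
  }
  if (!is.null(bold)) {
    args <- list(path = bold, allowlist = allowlist)
    if (!is.null(column_maps$bold)) args$column_map <- column_maps$bold
    corpora$bold <- classify_corpus(do.call(read_bold_table, args))
  }

  audit <- bind_rows(lapply(corpora, summarize_repository))

  pair_names <- list(c("specimen", "bold"), c("specimen", "genbank"),
                     c("bold", "genbank"))
  pair_names <- Filter(function(p) all(p %in% names(corpora)), pair_names)
  matches <- lapply(pair_names, function(p) {
    match_corpora(corpora[[p[1]]], corpora[[p[2]]],
                  case_insensitive = case_insensitive)
  })
  names(matches) <- vapply(pair_names, paste, character(1), collapse = "-")

  eff <- if (length(matches) > 0L) {
    effective_matches(matches, method = effective_method)
  } else {
    0L
  }
  overlap <- vapply(seq_along(matches), function(i) {
    p <- pair_names[[i]]
    overlap_pct(matches[[i]], corpora[[p[1]]], corpora[[p[2]]])
  }, numeric(1))
  names(overlap) <- names(matches)

  res <- structure(
    list(corpora = corpora, audit = audit,
         matches = matches, effective_matches = eff, overlap_pct = overlap,
         config = list(strip_urn = strip_urn,
                       case_insensitive = case_insensitive,
                       effective_method = effective_method),
         files = character(0)),
    class = "dwc_audit"
  )
  if (!is.null(out_dir)) {
    res$files <- render_tables(res, out_dir)
    write_run_log(res, inputs, file.path(out_dir, "run_log.txt"))
  }
  res
}

# fold linkout-derived identifiers into the GenBank corpus (same accession
# space); records present in both keep all identifiers
merge_genbank_linkout <- function(gb, lo) {
  ids <- bind_rows(gb$identifiers, lo$identifiers)
  extra_rec <- lo$records[!(lo$records$record_id %in% gb$records$record_id), ]
  recs <- bind_rows(gb$records, extra_rec)
  n_by_rec <- table(ids$record_id)
  recs$n_identifiers <- as.integer(n_by_rec[recs$record_id])
  recs$n_identifiers[is.na(recs$n_identifiers)] <- 0L
  recs$has_specimen_info <- recs$has_specimen_info | recs$n_identifiers > 0L
  identifier_corpus(ids, recs, "GENBANK", extra = gb$extra)
}

# share of the smaller corpus's distinct keys that found a cross-corpus
# match, as a percentage
overlap_pct <- function(ms, corpus_a, corpus_b) {
  n_keys <- function(corpus) {
    ids <- match_side(corpus, case_insensitive = FALSE)
    # each identifier contributes its most specific key
    key <- ifelse(is.na(ids$full_key), ids$doub_key, ids$full_key)
    length(unique(key[!is.na(key)]))
  }
  smaller <- min(n_keys(corpus_a), n_keys(corpus_b))
  if (smaller == 0L) return(0)
  100 * length(ms$matched_keys) / smaller
}

#' @export
print.dwc_audit <- function(x, ...) {
  cat("<dwc_audit>\n\nPer-repository summary:\n")
  print(x$audit)
  for (nm in names(x$matches)) {
    cat("\nMatches", nm, ":\n")
    print(x$matches[[nm]]$tiers)
  }
  cat("\nEffective matches across repositories:", x$effective_matches, "\n")
  invisible(x)
}

#' Write audit report files
#'
#' Writes the audit tables in both machine-readable and human-readable
#' form:
#'
#' * `table1.tsv` -- per-repository totals and canonical vs coerced counts;
#' * `table2.tsv` -- coerced identifiers by irregularity class;
#' * `table3.tsv` -- cross-repository match tiers with separate
#'   total/distinct columns; `table3_human.tsv` renders each cell as
#'   `"total (distinct)"`;
#' * `matches.tsv` -- one row per matched pair
#'   (`tier, key, repoA_record, repoB_record, ambiguous`);
#' * `summary.json` -- everything above plus effective matches and the
#'   pairwise overlap percentages (distinct matched keys over the distinct
#'   keys of the smaller corpus).
#'
#' @param audit A `dwc_audit` result from [run_audit()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of file paths written (invisibly).
#' @export
render_tables <- function(audit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table1 = file.path(out_dir, "table1.tsv"),
    table2 = file.path(out_dir, "table2.tsv"),
    table3 = file.path(out_dir, "table3.tsv"),
    table3_human = file.path(out_dir, "table3_human.tsv"),
    matches = file.path(out_dir, "matches.tsv"),
    summary = file.path(out_dir, "summary.json")
  )

  t1 <- audit$audit[, c("repository", "total_records",
                        "records_with_specimen_info", "canonical", "coerced")]
  t2 <- audit$audit[, c("repository", "syntactic_only", "missing_only",
                        "both_problems")]
  readr::write_tsv(t1, paths[["table1"]])
  readr::write_tsv(t2, paths[["table2"]])

  t3 <- bind_rows(lapply(names(audit$matches), function(nm) {
    tiers <- audit$matches[[nm]]$tiers
    tibble(
      pair = nm,
      tier = tiers$tier,
      total_matches = tiers$total_matches,
      distinct_keys = tiers$distinct_keys,
      distinct_triplet_keys = tiers$distinct_triplet_keys,
      ambiguous_keys = audit$matches[[nm]]$ambiguous_keys
    )
  }))
  readr::write_tsv(t3, paths[["table3"]])

  if (nrow(t3) > 0L) {
    human <- t3 %>%
      mutate(cell = sprintf("%d (%d)", .data$total_matches,
                            .data$distinct_keys)) %>%
      select("pair", "tier", "cell") %>%
      tidyr::pivot_wider(names_from = "tier", values_from = "cell")
  } else {
    human <- tibble(pair = character(0))
  }
  readr::write_tsv(human, paths[["table3_human"]])

  pairs <- bind_rows(lapply(names(audit$matches), function(nm) {
    p <- audit$matches[[nm]]$pairs
    if (nrow(p) == 0L) return(NULL)
    dplyr::bind_cols(tibble(pair = rep(nm, nrow(p))), p)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- tibble(pair = character(0), tier = character(0),
                    key = character(0), record_a = character(0),
                    record_b = character(0), ambiguous = logical(0))
  }
  readr::write_tsv(pairs, paths[["matches"]])

  summary <- list(
    audit = audit$audit,
    match_tiers = t3,
    effective_matches = audit$effective_matches,
    overlap_pct = as.list(audit$overlap_pct),
    config = audit$config
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}

write_run_log <- function(res, inputs, path) {
  lines <- c(
    sprintf("dwcaudit run log (%s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("canonical grammar: %s", dwc_canonical_regex),
    "",
    "inputs:",
    sprintf("  %s: %s (md5 %s)", names(inputs), inputs,
            vapply(inputs, function(f) unname(tools::md5sum(f)),
                   character(1))),
    "",
    "config:",
    sprintf("  %s = %s", names(res$config),
            vapply(res$config, as.character, character(1))),
    "",
    "stage counts:"
  )
  for (nm in names(res$corpora)) {
    co <- res$corpora[[nm]]
    lines <- c(lines, sprintf(
      "  %s: %d records read, %d with specimen info, %d identifiers parsed",
      nm, nrow(co$records), sum(co$records$has_specimen_info),
      nrow(co$identifiers)
    ))
  }
  for (nm in names(res$matches)) {
    tiers <- res$matches[[nm]]$tiers
    lines <- c(lines, sprintf("  match %s: %d pairs, %d distinct keys",
                              nm, sum(tiers$total_matches),
                              length(res$matches[[nm]]$matched_keys)))
  }
  lines <- c(lines, sprintf("  effective matches: %d",
                            res$effective_matches))
  writeLines(lines, path)
  invisible(path)
}
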