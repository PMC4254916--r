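# dwcaudit

Audit and cross-matching of Darwin Core Triplet specimen identifiers.

## The problem

Natural-history specimens are cited across biodiversity repositories by the
*Darwin Core Triplet*, the concatenation

```
institutionCode:collectionCode:catalogNumber      e.g.  MVZ:Mamm:12345
```

Occurrence datasets publish it in structured fields; sequence repositories
carry it as free text in the GenBank `/specimen_voucher` qualifier or the
BOLD `catalognum`/`sampleid` fields. In the wild the triplet is deployed
with wildly varying fidelity — wrong delimiters (`UAM_Fish_100`), missing
collection codes ("doublets" such as `MVZ:12345`), bare catalog numbers,
or several identifiers packed into one field — which cripples its use for
relinking specimens to their sequence and barcode derivatives. dwcaudit is
for biodiversity informaticians and collection-data managers who want to
quantify that mess and measure how much cross-repository linkage the
identifiers actually support.

## What it implements

* **Canonical recognizer.** A triplet is canonical iff it fully matches
  the grammar `[A-Z]{2,8}\:[A-Z][a-z]+\:.*[0-9]+.*` — a 2–8 capital-letter
  institution code (IC), a leading-capital collection code (CC), and a
  digit-bearing catalog number (CN), colon-separated.
* **Coercion parser.** Non-canonical text is split into fragments on `;`
  and `(`, tokenized on `: . - _ # ␣`, scanned for a default IC (trailing
  all-caps word) or CN (trailing multi-digit number), and coerced through
  five ordered rules (IC+CC+CN, IC+CN, IC+CC with default CN, CC+CN with
  default IC, CN with default IC). Records holding several identifiers
  donate their first IC to identifiers lacking one.
* **Audit taxonomy.** Every identifier is canonical or coerced; coerced
  ones split into syntactic-only, missing-data-only, and
  both-kinds-of-problems classes.
* **Tiered matching.** Cross-repository pairs match at canonical >
  triplet–triplet > triplet–doublet > doublet–doublet precedence, with
  total and distinct-key counts per tier and explicit flagging of doublet
  keys that resolve to more than one collection.
* **Synthetic corpora.** A seeded generator emits a specimen occurrence
  table, a GenBank-style flat file and a BOLD-style TSV with configurable
  corruption rates and ground-truth links, so the whole pipeline is
  testable offline.

## Worked example

```r
library(dwcaudit)

parse_field("MVZ:Mamm:12345")
#>   raw            ic    cc    cn    rule_fired      used_default_ic ...
#> 1 MVZ:Mamm:12345 MVZ   Mamm  12345 CANONICAL_REGEX FALSE

propagate_record_ic(parse_field("UAM Fish 100; 2345"))
#>   raw          ic    cc    cn    rule_fired    used_default_ic
#> 1 UAM Fish 100 UAM   Fish  100   FIRST_THREE   FALSE
#> 2 2345         UAM   <NA>  2345  CN_DEFAULT_IC TRUE
```

The first value is recognized whole by the grammar. The second field holds
two identifiers: the space-delimited one coerces via the first-three-tokens
rule, and the bare catalog number inherits the record's institution code,
leaving a doublet.

A full audit over synthetic linked corpora (500 records per repository,
seeded):

```r
spec  <- synthetic_spec(n_records = 500, seed = 11)
paths <- generate_linked_corpora(spec, tempfile())
res   <- run_audit(specimen = paths$specimen, genbank = paths$genbank,
                   bold = paths$bold, out_dir = "report")
res$audit
#>   repository total_records records_with_specimen_info canonical coerced
#> 1 SPECIMEN             500                        500       340     160
#> 2 GENBANK              500                        109        62      52
#> 3 BOLD                 500                        500       276     432

res$matches[["specimen-genbank"]]$tiers
#>   tier            total_matches distinct_keys distinct_triplet_keys
#> 1 CANONICAL                  18            17                    NA
#> 2 TRIPLET_TRIPLET             6             6                    NA
#> 3 TRIPLET_DOUBLET            21            20                    20
#> 4 DOUBLET_DOUBLET             1             1                    NA

res$effective_matches
#> [1] 211
```

Reading: of 500 GenBank-style records only 109 carry any voucher (the
generator omits the qualifier at the configured 80% rate); 62 of their
identifiers are canonical. Between the specimen and GenBank corpora, 18
identifier pairs agree as perfectly formed triplets, 21 only match after
dropping the collection code, and 211 distinct keys participate in at
least one match across all three repository pairs. `run_audit()` also
writes `table1.tsv`–`table3.tsv`, a human-readable `table3_human.tsv`
(`"21 (20)"` cells), `matches.tsv`, `summary.json` and a run log under
`report/`.

A thin command-line front end with `parse`, `ingest`, `audit`, `match`,
`simulate` and `run` subcommands lives at
`system.file("cli", "dwcaudit.R", package = "dwcaudit")`.

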