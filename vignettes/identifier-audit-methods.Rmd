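---
title: "Auditing Darwin Core Triplet identifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Darwin Core Triplet identifiers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwcaudit)
```

## The identifier model

A Darwin Core Triplet names a specimen by three parts: an institution code
(IC), a collection code (CC) and a catalog number (CN), conventionally
joined with colons. dwcaudit treats the triplet as a value object
(`triplet_parts()`) whose parts are stored exactly as extracted — no case
folding, no leading-zero stripping — because the package's job is to audit
curatorial practice, and normalizing on ingest would destroy the evidence.
Empty strings are treated as absent, since delimited exports cannot
distinguish the two. `completeness()` maps the presence pattern to
`TRIPLET`, `DOUBLET` (IC and CN, no CC), `CN_ONLY`, or `OTHER_PARTIAL`.

A triplet is **canonical** when the whole trimmed text matches the grammar

```
[A-Z]{2,8}\:[A-Z][a-z]+\:.*[0-9]+.*
```

i.e. 2–8 capitals, a colon, a leading-capital lowercase word, a colon, and
any digit-bearing remainder. `is_canonical()` applies this with anchored
(full-match) semantics: the grammar describes the entire value, not a
substring. An optional switch strips the recommended `urn:catalog:`
occurrenceID prefix first; it is off by default because the prefix is an
occurrenceID convention, not part of the voucher fields we audit. The CN
slot deliberately accepts any digit-bearing text — the model places no
bound on catalog-number length or alphabet, which mirrors real catalog
numbers like `B1978` or `a1b`.

## The coercion algorithm

Free-text vouchers that are not canonical go through a deterministic
three-stage heuristic:

1. **Fragmenting.** The field is split on `;` and `(`, the separators most
   commonly used to pack several identifiers into one value. A closing
   `)` orphaned by this split is stripped from fragment ends before
   tokenization: only the opening parenthesis is a separator, and a
   residual `)` glued to the final token would corrupt its role test.
2. **Tokenizing and coercion.** Each fragment splits into tokens on the
   six delimiters `: . - _ # ␣`; empty tokens from delimiter runs are
   dropped (the set includes the space, so runs of spaces must not
   manufacture tokens). The final token is scanned for default donors —
   an all-caps word becomes a default IC, a multi-digit number a default
   CN — and five ordered rules then try the leading tokens:
   IC+CC+CN; IC+CN; IC+CC (+default CN); CC+CN (+default IC);
   CN (+default IC). The first rule whose role tests pass wins; trailing
   tokens are ignored; if none fires the fragment is `UNPARSEABLE` and no
   parts are recovered. Token roles are mutually exclusive (an IC is
   capitals-only, a CC needs a lowercase tail, a CN needs a digit), which
   is what makes exhaustive enumeration of rule behavior feasible in the
   tests.
3. **Record-level IC propagation.** If any identifier in a record carries
   an IC, identifiers lacking one inherit it. When several identifiers
   carry different ICs the first in document order donates — the rule's
   source text says only "that IC", and document order is the
   deterministic reading.

Two readings here were genuinely open and are fixed as package policy:
"all-caps word" means *two or more* capitals, letters only (mirroring the
IC rule's letters-only form — a single capital is also rejected as an IC),
and "multi-digit number" means two or more digits, digits only. Likewise,
a fragment whose leading tokens fit no rule (e.g. leading prose such as
`also KU 124`) is recorded as `UNPARSEABLE` rather than scanning interior
token windows; interior scanning would invent matches the rule set never
licensed.

Fragmenting runs *before* the canonical shortcut. Because the CN slot of
the grammar is `.*[0-9]+.*`, a packed value like `MVZ:Mamm:1; 2345` would
otherwise match the grammar whole, swallowing the second identifier into
the catalog number. Per-fragment canonical recognition is equivalent for
every value without `;`/`(` — including everything `canonical_form()` can
emit, so the parse/render round trip is unaffected.

## Source adapters

* **Occurrence tables.** Structured rows are authoritative: the three
  cells become the parts verbatim, and the colon-joined form is evaluated
  by the recognizer only to record rule provenance. A row with
  institutionCode alone coerces to `UNPARSEABLE` (a lone IC identifies
  nothing) but the row still counts as a record.
* **GenBank flat files.** Only `/specimen_voucher` qualifiers on the
  `source` feature are read — `DEFINITION`, `isolate`, `db_xref` and
  `note` are documented dead ends — with continuation lines unwrapped and
  quotes stripped, since line wrapping is a format property, not data.
  Several voucher qualifiers on one record become several identifiers on
  one record, which is what lets IC propagation act. The GBFF reader is
  purpose-built for this extraction (record boundaries, accession, source
  qualifiers) rather than general flat-file parsing.
* **BOLD exports.** `catalognum` is the designated MuseumID field but
  `sampleid` may also carry a triplet, so both are reconciled per row:
  one populated field, exact agreement, or disagreement (both parsed,
  catalognum first, the row flagged for separate reporting).
* **Linkout URLs.** The candidate is the text after the final `/`, then
  after the final `=` if one is present — implemented exactly as stated
  and knowingly brittle; URL normalization is out of scope.
* **Allowlist.** Expert vetting of institution codes is replaced by an
  optional user-supplied code list; identifiers whose IC is absent from
  the list are dropped, identifiers without an IC are kept (the list vets
  codes, it does not require them).

## Classification and matching

Each identifier gets exactly one label. `CANONICAL` and `NO_IDENTIFIER`
follow directly from the parse rule. Among the rest, all three parts
present means `SYNTACTIC_ONLY`; at least two parts recovered from a raw
text whose only delimiter is the colon means `MISSING_ONLY`; everything
else — including a bare catalog number — is `BOTH`. The `MISSING_ONLY`
boundary is chosen so that doublets arising from structured sources with
empty collection-code cells (colon-joined, nothing else wrong) land there,
while free-text mess lands in `BOTH`; a curated occurrence corpus then
shows irregularities only in the missing-data column, which is the
empirically observed profile for curated aggregators.

Matching compares keys byte-exactly by default (a case-insensitive switch
exists for sensitivity analysis): full `IC:CC:CN` keys for the canonical
and triplet–triplet tiers, `IC:CN` doublet keys for the triplet–doublet
and doublet–doublet tiers. Tier precedence (canonical highest) makes the
tiers disjoint; a pair of complete triplets sharing a doublet key but
disagreeing on CC matches in *no* tier — it is evidence of ambiguity, not
of identity. Totals count identifier pairs (one voucher against three
sequence records is three matches); distinct counts are unique keys per
tier. For the triplet–doublet tier the distinct count is reported both
over doublet keys and over the triplet side's full keys, since either
convention is defensible. A matched doublet key is *ambiguous* when either
corpus resolves it to more than one collection code; `doublet_candidates()`
exposes the holders.

"Effective matches" across three repositories is not given a precise
published definition; the package's default is the union of distinct
matched keys over the three pairwise comparisons, with intersection and
plain-sum alternatives selectable, so the reading is explicit and
swappable. Pairwise overlap percentages divide the distinct matched keys
by the distinct identifier keys of the smaller corpus.

## The synthetic generator

`generate_linked_corpora()` emulates the three-repository study design:
a specimen occurrence table, a GenBank-style flat file, a BOLD-style TSV,
plus a ground-truth table. Each identifier draws one corruption outcome
from a categorical distribution — canonical, delimiter swap, dropped CC,
bare CN, multi-identifier packing — because the irregularity classes are
disjoint and one-label corruption is directly verifiable. Defaults are
fixed once as a plausible messy-repository profile: 50% canonical, 15%
delimiter swap, 20% missing CC, 10% bare CN, 5% multi-identifier; 80% of
sequence records lack the voucher qualifier (the observed magnitude for
vertebrate sequence records); half of the sequence/barcode records
genuinely reference a specimen. BOLD `sampleid` agreement (45% exact
repeat, 35% conflicting local sample code, 20% empty) echoes the
observation that just under half of doubly-populated rows disagree. The
structured specimen table can only express missing data, so delimiter and
multi-identifier outcomes leave its rows fully populated there.

Unlinked sequence-side identifiers are drawn to avoid IC×CN collisions
with the specimen corpus by default, so planted links are the only true
matches and matcher precision is measurable; narrowing `cn_range` (and the
vocabularies) deliberately forces catalog-number collisions across
collections to exercise doublet ambiguity. A single global seed drives
deterministic per-corpus sub-seeds, so each corpus is independently
reproducible and identical spec+seed yields byte-identical files.

What the generator does *not* model: real sequence content, taxonomy,
geography, institution-code typos, transposed part order, or non-triplet
identifier schemes. Passing tests therefore demonstrate that the rules are
implemented faithfully and recover planted structure — not that the rules
capture every failure mode of real repository data.

## Numerical and degenerate-input choices

Everything outside the generator is deterministic; the generator is the
only consumer of randomness. Empty fields parse to zero identifiers;
empty corpora produce all-zero tables and empty match summaries; an
all-absent `triplet_parts()` and a `canonical_form()` without IC or CN are
errors, while `UNPARSEABLE` is a value, not an error. Records without any
voucher text count in totals but nowhere else.

Test and acceptance problem sizes are chosen to keep the full suite at
desk scale while leaving the checks sharp: ≥10⁴ adversarial strings for
the dual-oracle grammar check (a regex-free structural walker plus a
second regex engine), exhaustive token-role enumeration to 4 tokens
(6⁴ + … + 6 = 1,554 patterns), brute-force O(n²) matcher cross-checks at
200 identifiers per side, and linked corpora of 1,000 records per
repository for frequency (3σ binomial), link-recovery and ambiguity
checks.

## Known limitations

* The coercion rules never scan interior token windows, so identifiers
  buried after leading prose are not recovered (by design, see above).
* Reordered parts (`12345:Mamm:MVZ`) are not repaired beyond what the
  CC+CN/default rules happen to catch; there is no fuzzy or edit-distance
  matching of institution codes against registries.
* The Linkout tail split assumes the identifier sits after the last
  `/`/`=`, which real submitters do not guarantee.
* Full-scale reproduction of published repository-wide counts requires
  the archived multi-million-record harvests; this package reproduces the
  method and verifies it on generated corpora with known ground truth.
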