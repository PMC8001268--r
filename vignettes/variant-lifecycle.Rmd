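---
title: "Managing clinical variants across annotation updates with varledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing clinical variants across annotation updates with varledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varledger)
```

## The problem

A clinical genomics laboratory accumulates variant calls from several
sequencing pipelines over many years. The evidence behind a variant's
interpretation — ClinVar assertions, locus-specific databases, in-house
curation — keeps moving, so a variant reported as *uncertain significance*
in 2019 may be *pathogenic* today. Reinterpretation has two practical
prerequisites: the laboratory must be able to re-annotate everything it has
ever seen without re-touching per-patient files, and it must be able to ask
"which variants changed in a clinically meaningful way, and which patients
carry them?" `varledger` implements the data-management core of that
workflow: a deduplicated variant store with historically tracked attribute
values, dialect-driven ingestion, virtual-panel (consent) filtering,
chunked export for external re-annotation, and change-detection queries.

## Variant identity and the history rule

A variant is identified by the exact tuple (chromosome, position, ref
allele, alt allele) after two canonicalizations: the chromosome label gets
a `chr` prefix if it lacks one, and alleles are uppercased. The canonical
text form is `chrom|pos|ref|alt`, e.g. `chr13|32936829|A|G`. Multiallelic
VCF records are split into one record per alt allele before keying. No
left-alignment or parsimony normalization is applied — the same indel
written two ways is two records. We chose exact-string identity because
every input here is VCF from a known caller, and silent normalization
would make provenance ("which file said this?") ambiguous; the cost, that
differently-represented indels are distinct, is documented rather than
hidden.

Attribute writes follow one rule, applied uniformly to variant attributes
(gene, ClinVar assertion, mutation type, classification tier) and to
per-sample observation attributes (genotype, allele-frequency percent):

* first value → history of length 1;
* identical value re-imported → history unchanged, but the current entry's
  timestamp and source are refreshed, so "last confirmed" is recoverable;
* differing value → appended, prior value preserved.

Values are compared as whitespace-trimmed, case-sensitive strings:
annotations are free text, and `Pathogenic` vs `pathogenic` may be a
deliberate change upstream. A case-insensitive mode exists at query time
instead, where it belongs. Histories never contain empty strings — empty
annotation cells simply write nothing.

## Dialects

Input formats differ by vendor, so ingestion is driven by declarative
dialect specs rather than code. A VCF dialect names the FORMAT subfields
that become sample attributes, the INFO subfields that become variant
attributes, derived attributes, an optional row filter, and the INFO
subfield that resolves the gene symbol. Two presets cover the dialects the
package is designed around:

* `dialect_preset("tss-hotspot")` — VCF 4.1 from a hotspot caller that
  reports every hotspot position even when the sample is reference, so
  most rows have genotype `0/0` and allele frequency 0. The preset maps
  `GT` and `AF` to sample attributes and carries the row filter
  *exclude where GT equals 0/0*.
* `dialect_preset("ddm")` — a commercial VCF 4.2 with FORMAT `GT:AD:DP`
  and no AF subfield. The allele frequency is derived as
  `100 * AD / DP` (alt-allele depth over read depth, in percent); INFO
  `SGVEP`, `DBXREF` and `TYPE` map to the gene symbol, database
  cross-references and mutation type.

The filter grammar is deliberately small: one field, equality or set
membership, exclude or include-only. That covers every filter this
workflow needs, and a richer expression language would have to be
versioned, escaped and audited — poor trades for a clinical tool. One
semantic decision deserves emphasis: *a filter never matches a record that
lacks its field*. Excluding on absence would silently drop whole dialects
that simply do not emit the field (the commercial dialect has no `AF`),
which is the wrong failure mode for consent- and QC-critical filtering.

Derived attributes are undefined (omitted, with a warning counted in the
ingest report) when the denominator is zero or a field is absent; for a
comma-separated per-allele `AD`, the entry belonging to the record's alt
allele after multiallelic splitting is used. Derived values are stored at
full precision; rounding is a display concern.

Annotation dialects describe delimited text files: tab or comma, key
columns (either four chrom/pos/ref/alt columns or a single combined
`chrom|pos|ref|alt` column — both occur in practice), a column→attribute
map, leading rows to skip, an optional row filter and an optional *break
condition* that stops processing just before its first matching row (for
trailing summary blocks). Dialect specs round-trip through YAML or JSON
configs and revalidate identically on load.

Attribute names are deliberately shared across dialects: when two
pipelines both produce a `ClinVar` column mapped to the same attribute
name, collision *is* the mechanism that makes histories comparable across
sources. The package therefore enforces name uniqueness within a spec but
no global registry.

## Panels and consent filtering

A gene panel is a named set of uppercased symbols; a virtual panel is a
named subset of a parent panel used to restrict an import to the genes a
patient consented to. We require the subset relation at creation time — a
consent filter wider than the assay is meaningless. Virtual-panel
filtering needs a gene symbol per record, so it demands a dialect with
`gene_symbol_source`; records whose symbol cannot be resolved are dropped
and attributed to the panel filter in the ingest report (the conservative
consent reading). Filtering is by gene symbol, not coordinates — panels
are defined as gene lists here, and coordinate-based filtering would
require transcript models this package intentionally does not own.

## Storage and transactions

The store lives in memory as hashed environments (variants, attribute
histories, observations) and persists as a single deterministic JSON file:
equal stores serialize to identical bytes, so a save/load round-trip is
exact and replay tests can compare files literally. Every import runs
inside a snapshot/rollback transaction — an import either fully applies or
leaves the store untouched — which is the contract a laboratory needs when
a half-read file would otherwise leave half-written histories. The
single-file, single-writer design matches the package's scope (a library
and CLI, not a server); multi-user concurrency and at-rest encryption are
explicitly out of scope.

## Re-annotation

`export_unique_variants()` writes every distinct variant as minimal
site-only VCF 4.2 (ID, QUAL, FILTER and INFO all `.`), sorted in natural
chromosome order (`chr1`..`chr22`, `chrX`, `chrY`, `chrM`, others
lexicographically) then position — determinism makes chunk contents
reproducible — in files of at most `chunk_size` records (default 10,000)
inside one ZIP archive. Genotype columns are omitted: re-annotation needs
sites, not carriers. The archive is written by a small built-in ZIP writer
(deflate entries, fixed timestamps) so archives are byte-reproducible.
The loop closes by running any external annotator over the exported files
and re-importing its output through an annotation dialect; the round-trip
touches exactly the exported variant set.

## Change detection

`search_changes()` answers the reinterpretation question: variants whose
attribute currently equals one of `current_equals` and previously held one
of `previous_in`. "Previously" defaults to *any strictly-prior value*, not
only the immediate predecessor: the clinical question is "was this variant
ever reported benign or VUS to a patient?", and an intermediate value must
not hide a transition. A `strict_previous` flag restricts matching to the
immediate predecessor for audit-style queries, and `since` restricts to
changes imported after a date. `samples_with_variant()` then lists the
distinct carriers for recontact.

The classification workflow uses the five-tier IARC system (C1 Benign …
C5 Pathogenic) stored in the reserved attribute `classification`, batch
uploaded from TSV or set per-variant with `classify()`.
`classification_summary()` reports per-tier counts and percentages of the
classified total, rounded half-up to one decimal (base R's banker's
rounding would not reproduce conventionally printed percentages); the
percentages can therefore sum to 100 ± 0.2.

## Synthetic data

The generators in this package are first-class, tested code, because the
package's correctness claims are all fixture-truth claims:

* `generate_tss_vcf(n_rows, n_nonref, seed)` emulates the hotspot
  dialect: exactly `n_nonref` rows are non-reference (GT `0/1`/`1/1`, AF
  in (0, 100]), the rest GT `0/0` with AF 0. The defaults used in the
  acceptance checks — 5,000 rows of which 15 are non-reference — are the
  typical per-file profile this workflow is designed around.
* `generate_ddm_vcf(gene_pool, n_records, seed)` emulates the commercial
  dialect, with exact per-gene record counts when the pool is a named
  integer vector (so panel-filter truth is fixed by construction), AD/DP
  drawn with AD ≤ DP, and a `DBXREF` of `ClinVar:<x>,dbsnp:rs<n>` per
  record. An explicit `duplicate_keys` parameter injects key collisions
  for deduplication tests; otherwise positions are drawn without
  replacement per gene window so collisions cannot occur by accident.
* `generate_annotation_file()` simulates the external annotator, changing
  a designated attribute for a seeded subset of `round(fraction * n)`
  variants and returning the truth list.
* `build_reclassification_scenario()` builds a store with one designated
  BRCA2 variant (`chr13|32936829|A|G`) whose ClinVar history is
  [uncertain significance → pathogenic] and classification history
  [C3 → C5], three carriers, and decoys covering every non-matching
  history shape.

All generators are pure functions of (parameters, seed) — identical calls
produce byte-identical files (R's Mersenne-Twister via `set.seed`, with
the caller's RNG state restored). What they do *not* emulate: realistic
allele-frequency spectra, reference-consistent REF alleles, indels and
structural variants, multi-sample VCFs, or annotator disagreement beyond a
single designated transition. Passing tests therefore demonstrate the
bookkeeping — identity, history, filtering, conservation — not robustness
to the full messiness of production VCF headers.

## Numerical and degenerate-input choices

* Positions are VCF-native (1-based); no coordinate conversion anywhere.
* Phased separators are normalized (`0|0` → `0/0`) before filter
  comparison, so phasing cannot defeat the reference-row filter.
* Symbolic alts (`<DEL>`, breakends) cannot form a key and are skipped
  with a counted warning.
* Per-file conservation is assertable from every ingest report:
  `rows_read = dropped_by_row_filter + dropped_by_virtual_panel +
  rows_loaded + rows_skipped`.
* An empty store exports a valid empty ZIP (0 entries); `chunk_count(0,
  k) = 0`.
* Timestamps are ISO-8601 UTC strings, so `since` comparisons are
  lexicographic and serialization is locale-independent.

## Problem sizes in the test suite

The suite exercises the ingest paths on files of tens to a few thousand
rows, the history property on 1,200 random writes, the change-search
oracle on 1,000 random stores plus the built scenario, and the export
path on a 22,569-variant store (three 10,000-record chunks). These sizes
were chosen as the smallest that still pin down every counting invariant
exactly; the store comfortably handles them in seconds.

## Known limitations

* Exact-string identity means differently-normalized indels do not
  deduplicate.
* Single-sample VCFs only; multi-sample files are a hard error by design
  (the sample identifier is caller-supplied, since vendor header
  conventions are unreliable).
* The `DBXREF` grammar (comma-separated `source:token` pairs) is an
  assumption isolated in `split_dbxref()`, to be re-specified if a vendor
  documents otherwise; colon-less tokens are preserved under
  `dbxref_raw`.
* Gene resolution exists only for dialects with a gene INFO subfield; a
  region-map fallback for gene-less dialects is out of scope.
* The store is single-writer; there is no server, web UI, or encryption
  at rest, and annotation pipelines themselves (ClinVar/LOVD queries) are
  external by design.
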