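# varledger

Lifecycle management of clinical sequence variants across annotation
updates, for clinical genomics laboratories that accumulate VCF and
annotation files from heterogeneous pipelines over years and must answer:
*which variants have been reclassified since we reported them, and which
patients carry them?*

The package provides:

* **A deduplicated variant store.** Variant identity is the exact tuple
  (chrom, pos, ref, alt) after canonicalization, written
  `chrom|pos|ref|alt`. Multiallelic records are split before keying, so
  the same variant arriving from any number of files or callers is one
  record.
* **Historically tracked attributes.** Every attribute write follows one
  rule: an identical value is overwritten in place (provenance refreshed),
  a differing value is appended with the prior value preserved. The full
  history — value, timestamp, source file — is queryable per variant and
  per sample observation.
* **Dialect-driven ingestion.** Declarative specs map FORMAT/INFO
  subfields (VCF) or columns (TSV/CSV) to attributes, with row filters
  (e.g. *exclude where GT is 0/0* for hotspot callers), break conditions,
  and derived attributes. The commercial-dialect preset derives the
  allele-frequency percent from allelic and read depth,

  AF = 100 · AD / DP,

  where AD is the alt-allele depth — the dialect carries no AF subfield.
* **Virtual gene panels.** Imports can be restricted to a consented gene
  subset of the sequencing panel; records off-panel (or with no resolvable
  gene symbol) are dropped and counted.
* **Re-annotation export.** All unique variants export as chunked,
  site-only VCF files (≤ 10,000 records each by default) in a single ZIP
  archive, ready for any external annotation pipeline; re-importing the
  annotator's output closes the loop.
* **Change detection.** `search_changes()` finds variants whose attribute
  moved from any prior value in one set to a current value in another —
  e.g. ClinVar from "benign"/"uncertain significance" to "pathogenic" —
  and `samples_with_variant()` lists carriers for recontact. Pathogenicity
  is managed on the five-tier IARC scale (C1 Benign … C5 Pathogenic).
* **Deterministic synthetic generators** for both VCF dialects,
  annotation/classification files, and a pre-built reclassification
  scenario, so everything is testable without any external data.

## Worked example

```r
library(varledger)
store <- variant_store()

# 1. a hotspot-caller VCF: 5,000 rows, 15 of them real variant calls
generate_tss_vcf("patient1.vcf", n_rows = 5000, n_nonref = 15, seed = 7)
ingest_vcf(store, "patient1.vcf", dialect_preset("tss-hotspot"),
           sample_id = "P001")
#> <ingest_report> vcf import of patient1.vcf
#>   rows read: 5000  dropped by row filter: 4985  dropped by virtual panel: 0
#>   rows loaded: 15  rows skipped: 0
#>   variants created: 15  matched existing: 0
#>   attributes created/unchanged/updated: 30/0/0
```

The hotspot caller reports every hotspot position even when the sample is
reference, so 4,985 rows with genotype 0/0 are dropped by the dialect's
row filter and exactly the 15 non-reference variants are loaded (the 30
attributes are each variant's genotype and allele frequency for P001).

```r
# 2. a commercial VCF for the same patient, consent-filtered to BRCA1/2
panel <- gene_panel("hereditary_cancer",
                    c("BRCA1", "BRCA2", "TP53", "ATM", "CHEK2"))
vp    <- virtual_panel("brca_consent", panel, c("BRCA1", "BRCA2"))
generate_ddm_vcf("patient1_ddm.vcf",
                 c(BRCA1 = 20L, BRCA2 = 25L, TP53 = 15L), 60, seed = 8)
ingest_vcf(store, "patient1_ddm.vcf", dialect_preset("ddm"),
           sample_id = "P001", panel = panel, virtual_panel = vp)
#> <ingest_report> vcf import of patient1_ddm.vcf
#>   rows read: 60  dropped by row filter: 0  dropped by virtual panel: 15
#>   rows loaded: 45  rows skipped: 0
#>   variants created: 45  matched existing: 0
#>   attributes created/unchanged/updated: 270/0/0
```

The 15 TP53 records are outside the patient's consent and are dropped by
the virtual panel; the 45 loaded records each get a gene symbol, mutation
type and database cross-references from INFO, plus a genotype and an
allele frequency derived from AD/DP.

```r
# 3. export everything for external re-annotation
export_unique_variants(store, "reannotation.zip", chunk_size = 25)
#> $files     "reannotation_0001.vcf" "reannotation_0002.vcf" "reannotation_0003.vcf"
#> $n_variants 60

# 4. after re-annotation: who was reclassified, and who carries it?
sc <- build_reclassification_scenario(seed = 1)
search_changes(sc$store, change_query(
  "ClinVar", previous_in = c("benign", "uncertain significance"),
  current_equals = "pathogenic"))
#>              variant         previous_value current_value              changed_at
#> 1 chr13|32936829|A|G uncertain significance    pathogenic 2021-02-01T00:00:00.000
samples_with_variant(sc$store, "chr13|32936829|A|G")
#> [1] "S001" "S002" "S003"
```

The scenario's designated BRCA2 variant, once reported as uncertain
significance (tier C3), is now pathogenic (C5); the three carriers are the
patients to recontact.

## Command-line interface

A thin wrapper at `inst/cli/varledger` exposes the same operations as
subcommands (`init-store`, `define-dialect`, `create-panel`,
`create-virtual-panel`, `import-vcf`, `import-annotation`,
`import-classification`, `classify`, `export-reannotation`, `search`,
`search-changes`, `summary`, `samples-with-variant`, `stats`,
`make-fixtures`), each emitting JSON on stdout; see `?run_cli`.

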