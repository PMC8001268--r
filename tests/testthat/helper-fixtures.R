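# Shared fixture helpers: tiny in-code stores and files.

# A store holding the given variant ids (canonical "chrom|pos|ref|alt").
store_with_variants <- function(ids) {
  st <- variant_store()
  for (id in ids) upsert_variant(st, id)
  st
}

# Write a small hand-built VCF; lines are data rows (already tab-joined
# CHROM..sample columns), header declares FORMAT via `format_ids`.
write_mini_vcf <- function(path, data_lines, sample = "S1",
                           version = "4.2") {
  writeLines(c(
    paste0("##fileformat=VCFv", version),
    "##INFO=<ID=SGVEP,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=DBXREF,Number=1,Type=String,Description=\"x\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample),
    data_lines
  ), path)
  path
}

# Independent brute-force oracle for search_changes: a plain scan over
# attribute_history() of every variant, re-deriving the predicate from
# first principles.
brute_force_changes <- function(store, q) {
  hits <- character(0)
  norm <- function(x) {
    x <- trimws(x)
    if (q$ignore_case) tolower(x) else x
  }
  for (id in variant_ids(store)) {
    h <- attribute_history(store, id, q$attribute)
    n <- nrow(h)
    if (n == 0L) next
    if (!is.null(q$current_equals) &&
        !(norm(h$value[n]) %in% norm(q$current_equals))) next
    if (!is.null(q$previous_in)) {
      if (n < 2L) next
      prior <- if (q$strict_previous) h$value[n - 1L] else
        h$value[seq_len(n - 1L)]
      if (!any(norm(prior) %in% norm(q$previous_in))) next
    }
    if (!is.null(q$since) && h$imported_at[n] < q$since) next
    hits <- c(hits, id)
  }
  hits
}

# A random store of small ClinVar histories for oracle testing; values and
# history lengths drawn from a fixed pool.
random_history_store <- function(n_variants = 4L) {
  st <- variant_store()
  pool <- c("benign", "likely benign", "uncertain significance",
            "likely pathogenic", "pathogenic")
  for (i in seq_len(n_variants)) {
    key <- variant_key(sample(c("chr1", "chr2", "chrX"), 1L),
                       sample.int(1e7, 1L), "A", "G")
    if (has_variant(st, key$id)) next
    upsert_variant(st, key)
    len <- sample.int(4L, 1L)
    vals <- sample(pool, len, replace = TRUE)
    for (j in seq_along(vals)) {
      record_attribute(st, key, "ClinVar", vals[j],
                       source = sprintf("f%d.tsv", j),
                       imported_at = sprintf("2021-0%d-01T00:00:00", j))
    }
  }
  st
}
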