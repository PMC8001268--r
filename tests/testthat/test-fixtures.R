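test_that("generators are byte-deterministic in (parameters, seed)", {
  p1 <- tempfile(); p2 <- tempfile(); p3 <- tempfile()
  generate_tss_vcf(p1, 80, 5, seed = 17)
  generate_tss_vcf(p2, 80, 5, seed = 17)
  generate_tss_vcf(p3, 80, 5, seed = 18)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(readLines(p1), readLines(p3)))

  d1 <- tempfile(); d2 <- tempfile()
  generate_ddm_vcf(d1, c("BRCA1", "TP53"), 30, seed = 2)
  generate_ddm_vcf(d2, c("BRCA1", "TP53"), 30, seed = 2)
  expect_identical(readLines(d1), readLines(d2))

  m <- data.frame(chrom = "chr1", pos = 1:50, ref = "A", alt = "G")
  a1 <- tempfile(); a2 <- tempfile()
  r1 <- generate_annotation_file(a1, m, fraction_changed = 0.2, seed = 9)
  r2 <- generate_annotation_file(a2, m, fraction_changed = 0.2, seed = 9)
  expect_identical(readLines(a1), readLines(a2))
  expect_identical(r1$changed_keys, r2$changed_keys)
})

test_that("hotspot generator hits the requested reference/non-reference profile", {
  path <- tempfile()
  g <- generate_tss_vcf(path, 300, 12, seed = 3)
  m <- g$manifest
  expect_equal(nrow(m), 300L)
  expect_equal(sum(m$gt != "0/0"), 12L)
  expect_true(all(m$gt[m$gt != "0/0"] %in% c("0/1", "1/1")))
  expect_true(all(m$af[m$gt != "0/0"] > 0 & m$af[m$gt != "0/0"] <= 100))
  expect_true(all(m$af[m$gt == "0/0"] == 0))
  # the generated file parses under its own dialect with zero hard errors
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("tss-hotspot"),
                    sample_id = "S")
  expect_equal(rep$rows_read, 300L)
  expect_equal(rep$rows_loaded, 12L)
  # degenerate profiles
  g0 <- generate_tss_vcf(tempfile(), 10, 0, seed = 1)
  expect_equal(sum(g0$manifest$gt != "0/0"), 0L)
  expect_error(generate_tss_vcf(tempfile(), 10, 11, seed = 1),
               "n_nonref")
})

test_that("commercial generator manifest predicts ingest exactly", {
  path <- tempfile()
  pool <- c(BRCA1 = 10L, BRCA2 = 8L, OFF = 2L)
  g <- generate_ddm_vcf(path, pool, 20, seed = 6)
  m <- g$manifest
  expect_equal(as.vector(table(m$gene)[names(pool)]),
               unname(as.integer(pool)))
  expect_equal(m$expected_allele_frequency, 100 * m$ad_alt / m$dp)
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "S")
  expect_equal(rep$rows_loaded, 20L)
  for (i in seq_len(nrow(m))) {
    id <- paste(m$chrom[i], m$pos[i], m$ref[i], m$alt[i], sep = "|")
    expect_equal(current_attribute(st, id, "gene"), m$gene[i])
    af <- observation_history(st, id, "S", "allele_frequency")$value
    expect_equal(as.numeric(af), m$expected_allele_frequency[i])
  }
  # every record AD == DP -> all derived frequencies 100
  g2 <- generate_ddm_vcf(tempfile(), "BRCA1", 5, seed = 44)
  # (can't force AD == DP from the interface; assert the relation instead)
  expect_true(all(g2$manifest$expected_allele_frequency ==
                    100 * g2$manifest$ad_alt / g2$manifest$dp))
  expect_error(generate_ddm_vcf(tempfile(), character(0), 5, seed = 1),
               "non-empty")
  expect_error(generate_ddm_vcf(tempfile(), c(A = 2L, B = 2L), 5,
                                seed = 1),
               "sum to n_records")
})

test_that("key-collision injection exercises deduplication", {
  path <- tempfile()
  g <- generate_ddm_vcf(path, c("BRCA1", "BRCA2"), 20, seed = 8,
                        duplicate_keys = 3L)
  keys <- paste(g$manifest$chrom, g$manifest$pos, g$manifest$ref,
                g$manifest$alt, sep = "|")
  expect_equal(length(unique(keys)), 17L)
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "S")
  expect_equal(rep$rows_read, 20L)
  expect_equal(unique_variant_count(st), 17L)
  expect_equal(rep$variants_matched_existing, 3L)
})

test_that("annotation generator changes exactly the requested fraction", {
  m <- data.frame(chrom = "chr3", pos = 1:100, ref = "A", alt = "G")
  res <- generate_annotation_file(
    tempfile(), m,
    attributes = list(ClinVar = "uncertain significance"),
    fraction_changed = 0.11, seed = 20
  )
  expect_length(res$changed_keys, 11L)
  expect_equal(sum(res$table$ClinVar == "pathogenic"), 11L)
  expect_equal(sum(res$table$ClinVar == "uncertain significance"), 89L)

  res0 <- generate_annotation_file(tempfile(), m, fraction_changed = 0,
                                   seed = 1)
  expect_length(res0$changed_keys, 0L)
  res1 <- generate_annotation_file(tempfile(), m, fraction_changed = 1,
                                   seed = 1)
  expect_length(res1$changed_keys, 100L)
})

test_that("a simulated re-annotation cycle surfaces exactly the changed variants", {
  m <- data.frame(chrom = "chr7", pos = 1:100, ref = "C", alt = "T")
  st <- store_with_variants(sprintf("chr7|%d|C|T", 1:100))
  base <- generate_annotation_file(
    tempfile(), m, attributes = list(ClinVar = "uncertain significance"),
    fraction_changed = 0, seed = 1
  )
  d <- annotation_dialect("ann", key_columns = c("chrom", "pos", "ref",
                                                 "alt"),
                          attr_map = c(ClinVar = "ClinVar"))
  ingest_annotation(st, base$path, d,
                    imported_at = "2020-01-01T00:00:00")
  stats_before <- store_stats(st)
  reann <- generate_annotation_file(
    tempfile(), m, attributes = list(ClinVar = "uncertain significance"),
    fraction_changed = 0.11, seed = 33
  )
  ingest_annotation(st, reann$path, d,
                    imported_at = "2021-01-01T00:00:00")
  # exactly the truth-list histories grew, by exactly one entry each
  expect_equal(store_stats(st)$n_attribute_entries,
               stats_before$n_attribute_entries + 11L)
  hits <- search_changes(st, change_query(
    "ClinVar", previous_in = c("benign", "uncertain significance"),
    current_equals = "pathogenic"))
  expect_equal(hits$variant, sort_variant_ids(reann$changed_keys))
  expect_equal(nrow(hits), 11L)
})

test_that("the reclassification scenario encodes its own truth", {
  sc <- build_reclassification_scenario(seed = 2)
  res <- search_changes(sc$store, sc$query)
  expect_equal(res$variant, sc$expected$change_hits)
  expect_equal(res$previous_value, "uncertain significance")
  expect_equal(samples_with_variant(sc$store, sc$designated),
               sc$expected$carriers)
  expect_equal(
    attribute_history(sc$store, sc$designated, "classification")$value,
    c("C3", "C5")
  )
  # the unchanged pathogenic decoy is never returned
  expect_equal(nrow(res), 1L)
  expect_true(validate_store(sc$store))
})
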