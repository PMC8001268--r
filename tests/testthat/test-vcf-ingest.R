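test_that("INFO subfield extraction handles pairs, flags and absence", {
  expect_equal(parse_info_subfield("SGVEP=BRCA2;TYPE=SNV", "SGVEP"),
               "BRCA2")
  expect_equal(parse_info_subfield("SGVEP=BRCA2;TYPE=SNV", "TYPE"), "SNV")
  expect_true(is.na(parse_info_subfield("DP=100", "SGVEP")))
  expect_equal(parse_info_subfield("DP=100;HS", "HS"), "")  # flag sentinel
  expect_equal(
    parse_info_subfield("DBXREF=ClinVar:pathogenic,dbsnp:rs1", "DBXREF"),
    "ClinVar:pathogenic,dbsnp:rs1"
  )
  expect_true(is.na(parse_info_subfield(".", "DP")))
})

test_that("database cross-references split into per-source attributes", {
  expect_equal(
    split_dbxref("ClinVar:pathogenic,dbsnp:rs1"),
    c(dbxref_ClinVar = "pathogenic", dbxref_dbsnp = "rs1")
  )
  expect_length(split_dbxref(""), 0L)
  expect_equal(split_dbxref("oddtoken"), c(dbxref_raw = "oddtoken"))
  # mixed pairs and raw tokens
  expect_equal(
    split_dbxref("ClinVar:benign,odd,LOVD:BRCA2_x"),
    c(dbxref_ClinVar = "benign", dbxref_LOVD = "BRCA2_x",
      dbxref_raw = "odd")
  )
})

test_that("hotspot-dialect ingest drops reference rows and keeps the truth set", {
  path <- tempfile(fileext = ".vcf")
  g <- generate_tss_vcf(path, n_rows = 120, n_nonref = 9, seed = 21)
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("tss-hotspot"),
                    sample_id = "P1")
  expect_equal(rep$rows_read, 120L)
  expect_equal(rep$rows_dropped_by_row_filter, 111L)
  expect_equal(rep$rows_loaded, 9L)
  expect_equal(rep$variants_created, 9L)
  expect_equal(unique_variant_count(st), 9L)
  # conservation: every row accounted for
  expect_equal(rep$rows_read,
               rep$rows_dropped_by_row_filter +
                 rep$rows_dropped_by_virtual_panel +
                 rep$rows_loaded + rep$rows_skipped)
  # no stored observation from this import has genotype 0/0
  for (id in variant_ids(st)) {
    h <- observation_history(st, id, "P1", "genotype")
    expect_false(any(h$value == "0/0"))
  }
  # loaded set matches the manifest truth exactly
  m <- g$manifest[g$manifest$gt != "0/0", ]
  truth <- sort_variant_ids(paste(m$chrom, m$pos, m$ref, m$alt,
                                  sep = "|"))
  expect_equal(variant_ids(st), truth)
})

test_that("commercial-dialect ingest derives allele frequency from depths", {
  path <- tempfile(fileext = ".vcf")
  write_mini_vcf(path, paste(
    "chr13", "32936829", ".", "A", "G", "100", "PASS",
    "SGVEP=BRCA2;DBXREF=ClinVar:pathogenic,dbsnp:rs81002830;TYPE=SNV",
    "GT:AD:DP", "0/1:39,13:52", sep = "\t"))
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "P2")
  expect_equal(rep$rows_loaded, 1L)
  k <- "chr13|32936829|A|G"
  expect_equal(observation_history(st, k, "P2", "allele_frequency")$value,
               "25")
  expect_equal(current_attribute(st, k, "gene"), "BRCA2")
  expect_equal(current_attribute(st, k, "mutation_type"), "SNV")
  expect_equal(current_attribute(st, k, "dbxref_ClinVar"), "pathogenic")
  expect_equal(current_attribute(st, k, "dbxref_dbsnp"), "rs81002830")
})

test_that("virtual panel filtering drops off-panel and unresolvable records", {
  path <- tempfile(fileext = ".vcf")
  pool <- c(BRCA1 = 25L, BRCA2 = 25L, TP53 = 4L, OFFGENE1 = 4L,
            OFFGENE2 = 2L)
  generate_ddm_vcf(path, pool, n_records = 60, seed = 9)
  parent <- gene_panel("assay", names(pool))
  vp <- virtual_panel("consent", parent, c("BRCA1", "BRCA2", "TP53"))
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "P3",
                    panel = parent, virtual_panel = vp)
  expect_equal(rep$rows_read, 60L)
  expect_equal(rep$rows_dropped_by_virtual_panel, 6L)
  expect_equal(rep$rows_loaded, 54L)
  # every imported variant's gene symbol is inside the virtual panel
  for (id in variant_ids(st)) {
    expect_true(current_attribute(st, id, "gene") %in% vp$genes)
  }
  # virtual panel without a gene source is a hard error
  expect_error(
    ingest_vcf(st, path, dialect_preset("tss-hotspot"), sample_id = "P3",
               virtual_panel = vp),
    "no gene_symbol_source"
  )
})

test_that("re-importing the same file is a no-op on the store", {
  path <- tempfile(fileext = ".vcf")
  generate_ddm_vcf(path, c("BRCA1", "BRCA2"), n_records = 30, seed = 4)
  st <- variant_store()
  rep1 <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "P1",
                     imported_at = "2021-01-01T00:00:00")
  stats1 <- store_stats(st)
  hist1 <- lapply(variant_ids(st), function(id)
    attribute_history(st, id, "gene"))
  rep2 <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "P1",
                     imported_at = "2021-02-01T00:00:00")
  expect_equal(rep2$variants_created, 0L)
  expect_equal(rep2$variants_matched_existing, rep1$variants_created)
  expect_equal(rep2$attributes_updated, 0L)
  expect_equal(rep2$attributes_created, 0L)
  expect_equal(rep2$attributes_unchanged,
               rep1$attributes_created + rep1$attributes_unchanged)
  expect_equal(unique_variant_count(st), stats1$n_variants)
  stats2 <- store_stats(st)
  expect_equal(stats2$n_attribute_entries, stats1$n_attribute_entries)
  expect_equal(stats2$n_observation_entries, stats1$n_observation_entries)
  hist2 <- lapply(variant_ids(st), function(id)
    attribute_history(st, id, "gene"))
  expect_equal(lapply(hist2, `[[`, "value"),
               lapply(hist1, `[[`, "value"))
})

test_that("the same variant from both dialects yields one record with tracked attributes", {
  tss <- tempfile(fileext = ".vcf")
  write_mini_vcf(tss, paste("chr13", "32936829", ".", "A", "G", "100",
                            "PASS", "HS", "GT:AF", "0/1:47.30",
                            sep = "\t"), version = "4.1")
  ddm <- tempfile(fileext = ".vcf")
  write_mini_vcf(ddm, paste("13", "32936829", ".", "a", "g", "90", "PASS",
                            "SGVEP=BRCA2;TYPE=SNV", "GT:AD:DP",
                            "0/1:39,13:52", sep = "\t"))
  st <- variant_store()
  ingest_vcf(st, tss, dialect_preset("tss-hotspot"), sample_id = "P1")
  rep <- ingest_vcf(st, ddm, dialect_preset("ddm"), sample_id = "P1")
  expect_equal(unique_variant_count(st), 1L)
  expect_equal(rep$variants_matched_existing, 1L)
  # common attribute (genotype, same name in both dialects) unchanged;
  # allele_frequency differs (47.3 vs 25) so its history grew
  k <- "chr13|32936829|A|G"
  expect_equal(nrow(observation_history(st, k, "P1", "genotype")), 1L)
  expect_equal(observation_history(st, k, "P1", "allele_frequency")$value,
               c("47.30", "25"))
})

test_that("multiallelic records split into one keyed record per alt", {
  path <- tempfile(fileext = ".vcf")
  write_mini_vcf(path, paste("chr2", "1000", ".", "A", "G,T", "50",
                             "PASS", "SGVEP=MSH2;TYPE=SNV", "GT:AD:DP",
                             "1/2:26,13,13:52", sep = "\t"))
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("ddm"), sample_id = "P1")
  expect_equal(unique_variant_count(st), 2L)
  expect_equal(rep$records_loaded, 2L)
  expect_equal(rep$rows_loaded, 1L)
  # each split record uses its own alt depth
  expect_equal(
    observation_history(st, "chr2|1000|A|G", "P1",
                        "allele_frequency")$value, "25")
  expect_equal(
    observation_history(st, "chr2|1000|A|T", "P1",
                        "allele_frequency")$value, "25")
})

test_that("phased genotypes, symbolic alts and malformed files are handled", {
  # 0|0 normalized to 0/0 and excluded by the hotspot filter
  path <- tempfile(fileext = ".vcf")
  write_mini_vcf(path, c(
    paste("chr1", "100", ".", "A", "G", ".", ".", ".", "GT:AF",
          "0|0:0.00", sep = "\t"),
    paste("chr1", "200", ".", "C", "T", ".", ".", ".", "GT:AF",
          "0|1:12.00", sep = "\t"),
    paste("chr1", "300", ".", "G", "<DEL>", ".", ".", ".", "GT:AF",
          "0/1:40.00", sep = "\t")
  ))
  st <- variant_store()
  rep <- ingest_vcf(st, path, dialect_preset("tss-hotspot"),
                    sample_id = "P1")
  expect_equal(rep$rows_dropped_by_row_filter, 1L)
  expect_equal(rep$rows_loaded, 1L)
  expect_equal(rep$records_skipped_symbolic, 1L)
  expect_equal(variant_ids(st), "chr1|200|C|T")

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\t1\t.\tA\tG"), bad)
  expect_error(ingest_vcf(variant_store(), bad, dialect_preset("ddm"),
                          sample_id = "P1"),
               "malformed VCF")

  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t1\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/1"
  ), multi)
  expect_error(ingest_vcf(variant_store(), multi, dialect_preset("ddm"),
                          sample_id = "P1"),
               "multi-sample")
})
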