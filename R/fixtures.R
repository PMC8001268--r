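# Deterministic synthetic-data generators: both VCF dialects, annotation
# and classification files, and a pre-built reclassification scenario.
# Every generator is a pure function of (parameters, seed): identical
# inputs produce byte-identical files, and each returns a manifest of
# ground truth sufficient to predict the ingest report exactly.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

# Positions drawn without replacement within each chromosome so keys never
# collide by accident; collisions for dedup tests are injected explicitly.
draw_positions <- function(chroms) {
  pos <- integer(length(chroms))
  for (cn in unique(chroms)) {
    idx <- which(chroms == cn)
    pos[idx] <- sample.int(100000000L, length(idx), replace = FALSE)
  }
  pos
}

order_vcf <- function(df) {
  df[order(chrom_rank(df$chrom), df$chrom, df$pos, df$ref, df$alt), ,
     drop = FALSE]
}

#' Generate a hotspot-caller style VCF (TSS dialect)
#'
#' Emulates a hotspot caller that reports every position in its hotspot
#' list even when the sample is reference: a single-sample VCF 4.1 with
#' FORMAT `GT:AF` in which exactly `n_nonref` records carry GT 0/1 or 1/1
#' with AF in (0, 100], and the remaining rows are reference calls with
#' GT 0/0 and AF 0. Ingesting under the GT=0/0 exclude filter therefore
#' loads exactly `n_nonref` variants.
#'
#' @param path output VCF path.
#' @param n_rows total data rows.
#' @param n_nonref number of non-reference rows (0 <= n_nonref <= n_rows).
#' @param seed integer seed; identical (seed, parameters) give
#'   byte-identical files.
#' @param sample_id sample column name.
#' @return list with `path` and `manifest` (data.frame of every row's
#'   chrom, pos, ref, alt, gt, af plus a `params` attribute recording the
#'   generator identity), invisibly.
#' @export
generate_tss_vcf <- function(path, n_rows, n_nonref, seed,
                             sample_id = "SAMPLE01") {
  n_rows <- as.integer(n_rows)
  n_nonref <- as.integer(n_nonref)
  if (n_nonref < 0L || n_nonref > n_rows) {
    stop("n_nonref must satisfy 0 <= n_nonref <= n_rows", call. = FALSE)
  }
  manifest <- with_seed(seed, {
    chrom_pool <- paste0("chr", c(1, 2, 13, 17))
    chroms <- sample(chrom_pool, n_rows, replace = TRUE)
    pos <- draw_positions(chroms)
    al <- random_snv_alleles(n_rows)
    df <- order_vcf(data.frame(chrom = chroms, pos = pos, ref = al$ref,
                               alt = al$alt, stringsAsFactors = FALSE))
    df$gt <- "0/0"
    df$af <- 0
    if (n_nonref > 0L) {
      idx <- sort(sample.int(n_rows, n_nonref))
      df$gt[idx] <- sample(c("0/1", "1/1"), n_nonref, replace = TRUE)
      df$af[idx] <- round(stats::runif(n_nonref, min = 1, max = 100), 2)
    }
    df
  })
  meta <- c(
    "##fileformat=VCFv4.1",
    "##source=varledger synthetic hotspot-caller emulation",
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Genotype\">"),
    paste0("##FORMAT=<ID=AF,Number=A,Type=Float,",
           "Description=\"Allele frequency\">"),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  body <- paste(manifest$chrom, manifest$pos, ".", manifest$ref,
                manifest$alt, "100", "PASS", "HS", "GT:AF",
                paste0(manifest$gt, ":", sprintf("%.2f", manifest$af)),
                sep = "\t")
  writeLines(c(meta, body), path)
  attr(manifest, "params") <- list(
    generator = "generate_tss_vcf", seed = as.integer(seed),
    n_rows = n_rows, n_nonref = n_nonref, sample_id = sample_id,
    rng = "R Mersenne-Twister via set.seed"
  )
  invisible(list(path = path, manifest = manifest))
}

#' Generate a commercial-style VCF (DDM dialect)
#'
#' A single-sample VCF 4.2 with FORMAT `GT:AD:DP` (no AF subfield) and
#' INFO subfields `SGVEP` (gene symbol), `DBXREF` (database
#' cross-references) and `TYPE` per record. The manifest records each
#' record's gene and the expected derived allele frequency 100*AD/DP,
#' where AD is the alt-allele depth.
#'
#' @param path output VCF path.
#' @param gene_pool genes to draw from: either a character vector (drawn
#'   uniformly) or a named integer vector of exact per-gene record counts
#'   summing to `n_records`.
#' @param n_records number of data rows.
#' @param seed integer seed.
#' @param sample_id sample column name.
#' @param duplicate_keys number of records (taken from the end) whose keys
#'   are overwritten with copies of the first records' keys, to exercise
#'   deduplication. Default 0.
#' @return list with `path` and `manifest` (chrom, pos, ref, alt, gene,
#'   gt, ad_ref, ad_alt, dp, expected_allele_frequency, clinvar),
#'   invisibly.
#' @export
generate_ddm_vcf <- function(path, gene_pool, n_records, seed,
                             sample_id = "SAMPLE01", duplicate_keys = 0L) {
  n_records <- as.integer(n_records)
  if (length(gene_pool) == 0L) {
    stop("gene_pool must be non-empty", call. = FALSE)
  }
  exact <- !is.null(names(gene_pool)) && all(nzchar(names(gene_pool)))
  if (exact && sum(as.integer(gene_pool)) != n_records) {
    stop("named gene_pool counts must sum to n_records", call. = FALSE)
  }
  manifest <- with_seed(seed, {
    genes <- if (exact) {
      sample(rep(names(gene_pool), times = as.integer(gene_pool)))
    } else {
      sample(as.character(gene_pool), n_records, replace = TRUE)
    }
    gene_levels <- sort(unique(genes))
    chrom_pool <- paste0("chr", c(1:22, "X"))
    gene_chrom <- stats::setNames(
      chrom_pool[(seq_along(gene_levels) - 1L) %% length(chrom_pool) + 1L],
      gene_levels
    )
    chroms <- unname(gene_chrom[genes])
    # window each gene's positions so genes never share a locus
    pos <- integer(n_records)
    for (g in gene_levels) {
      idx <- which(genes == g)
      base <- (match(g, gene_levels) - 1L) * 1000000L
      pos[idx] <- base + sample.int(999999L, length(idx),
                                    replace = FALSE)
    }
    al <- random_snv_alleles(n_records)
    dp <- sample(30:200, n_records, replace = TRUE)
    ad_alt <- vapply(dp, function(d) sample.int(d, 1L), integer(1))
    clinvar <- sample(c("benign", "likely_benign",
                        "uncertain_significance", "pathogenic"),
                      n_records, replace = TRUE)
    rsid <- sample.int(99999999L, n_records, replace = FALSE)
    df <- data.frame(
      chrom = chroms, pos = pos, ref = al$ref, alt = al$alt, gene = genes,
      gt = ifelse(ad_alt == dp, "1/1", "0/1"),
      ad_ref = dp - ad_alt, ad_alt = ad_alt, dp = dp,
      clinvar = clinvar, rsid = rsid, stringsAsFactors = FALSE
    )
    df$expected_allele_frequency <- 100 * df$ad_alt / df$dp
    df <- order_vcf(df)
    dk <- as.integer(duplicate_keys)
    if (dk > 0L) {
      if (2L * dk > n_records) {
        stop("duplicate_keys too large for n_records", call. = FALSE)
      }
      tail_idx <- (n_records - dk + 1L):n_records
      df[tail_idx, c("chrom", "pos", "ref", "alt", "gene")] <-
        df[seq_len(dk), c("chrom", "pos", "ref", "alt", "gene")]
      df <- order_vcf(df)
    }
    df
  })
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=varledger synthetic commercial-caller emulation",
    "##INFO=<ID=SGVEP,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=DBXREF,Number=1,Type=String,",
           "Description=\"Database cross-references\">"),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Mutation type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  info <- paste0("SGVEP=", manifest$gene,
                 ";DBXREF=ClinVar:", manifest$clinvar,
                 ",dbsnp:rs", manifest$rsid,
                 ";TYPE=SNV")
  body <- paste(manifest$chrom, manifest$pos, ".", manifest$ref,
                manifest$alt, "100", "PASS", info, "GT:AD:DP",
                paste0(manifest$gt, ":", manifest$ad_ref, ",",
                       manifest$ad_alt, ":", manifest$dp),
                sep = "\t")
  writeLines(c(meta, body), path)
  attr(manifest, "params") <- list(
    generator = "generate_ddm_vcf", seed = as.integer(seed),
    n_records = n_records, sample_id = sample_id,
    duplicate_keys = as.integer(duplicate_keys),
    rng = "R Mersenne-Twister via set.seed"
  )
  invisible(list(path = path, manifest = manifest))
}

#' Generate an annotation file from a manifest
#'
#' Simulates the external annotator: one tab-delimited row per distinct
#' variant in the manifest, with constant (or pooled) attribute values; a
#' seeded subset of size `round(fraction_changed * n)` receives
#' `changed_value` for `changed_attr` instead. The returned truth list of
#' changed keys predicts exactly which histories grow on re-import.
#'
#' @param path output TSV path.
#' @param manifest data.frame with columns chrom, pos, ref, alt (e.g. from
#'   a VCF generator or [export_unique_variants()] input).
#' @param attributes named list of attribute values; a length-1 value is
#'   constant, a longer vector is sampled per row.
#' @param fraction_changed proportion of variants (0..1) whose
#'   `changed_attr` is set to `changed_value`.
#' @param changed_attr attribute receiving the change (must appear in
#'   `attributes`).
#' @param changed_value the new value for changed rows.
#' @param seed integer seed.
#' @return list with `path`, `changed_keys` (canonical ids) and the
#'   written `table`, invisibly.
#' @export
generate_annotation_file <- function(path, manifest,
                                     attributes =
                                       list(ClinVar =
                                              "uncertain significance"),
                                     fraction_changed = 0,
                                     changed_attr = "ClinVar",
                                     changed_value = "pathogenic",
                                     seed = 1L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0L,
            fraction_changed >= 0, fraction_changed <= 1)
  keys <- paste(canonical_chrom(manifest$chrom), manifest$pos,
                toupper(manifest$ref), toupper(manifest$alt), sep = "|")
  dedup <- !duplicated(keys)
  df <- manifest[dedup, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  keys <- keys[dedup]
  n <- nrow(df)
  out <- with_seed(seed, {
    for (nm in names(attributes)) {
      pool <- as.character(attributes[[nm]])
      df[[nm]] <- if (length(pool) == 1L) pool else
        sample(pool, n, replace = TRUE)
    }
    n_changed <- round(fraction_changed * n)
    changed <- if (n_changed > 0L) sort(sample.int(n, n_changed)) else
      integer(0)
    if (length(changed)) {
      if (!changed_attr %in% names(df)) {
        stop("changed_attr must be one of the attributes", call. = FALSE)
      }
      df[[changed_attr]][changed] <- changed_value
    }
    list(df = df, changed = changed)
  })
  utils::write.table(out$df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(path = path, changed_keys = keys[out$changed],
                 table = out$df))
}

#' Generate a batch-classification file from a manifest
#'
#' @param path output TSV path.
#' @param manifest data.frame with chrom, pos, ref, alt.
#' @param tiers either a single tier for all rows, a vector of length
#'   `nrow(manifest)`, or a named integer vector of per-tier counts
#'   summing to the number of distinct variants (assigned in manifest
#'   order).
#' @return list with `path` and the written `table`, invisibly.
#' @export
generate_classification_file <- function(path, manifest, tiers = "C3") {
  keys <- paste(canonical_chrom(manifest$chrom), manifest$pos,
                toupper(manifest$ref), toupper(manifest$alt), sep = "|")
  df <- manifest[!duplicated(keys), c("chrom", "pos", "ref", "alt"),
                 drop = FALSE]
  n <- nrow(df)
  tier_col <- if (!is.null(names(tiers))) {
    if (sum(as.integer(tiers)) != n) {
      stop("per-tier counts must sum to the number of distinct variants",
           call. = FALSE)
    }
    rep(names(tiers), times = as.integer(tiers))
  } else if (length(tiers) == 1L) {
    rep(as.character(tiers), n)
  } else {
    stopifnot(length(tiers) == n)
    as.character(tiers)
  }
  df$tier <- tier_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(path = path, table = df))
}

#' Build a populated reclassification scenario
#'
#' Constructs a store containing, among decoys, one designated BRCA2
#' variant (key `chr13|32936829|A|G`) whose ClinVar history is
#' ["uncertain significance" -> "pathogenic"] and whose classification
#' history is [C3 -> C5], carried by three samples. Decoy histories cover
#' the non-matching cases: unchanged pathogenic, benign -> likely benign,
#' single-entry VUS, pathogenic -> uncertain significance (reverse), and
#' an unclassified variant.
#'
#' @param seed integer seed used for decoy keys.
#' @param store optionally, an existing store to populate.
#' @return list with `store`, `designated` (the canonical id), `query`
#'   (the benign/VUS -> pathogenic [change_query()]), and `expected`
#'   (list with `change_hits` and `carriers`).
#' @export
build_reclassification_scenario <- function(seed = 1L,
                                            store = variant_store()) {
  t1 <- "2020-06-01T00:00:00.000"
  t2 <- "2021-02-01T00:00:00.000"
  designated <- variant_key("chr13", 32936829, "A", "G")
  upsert_variant(store, designated)
  record_attribute(store, designated, "ClinVar", "uncertain significance",
                   source = "annotation_2020.tsv", imported_at = t1)
  record_attribute(store, designated, "ClinVar", "pathogenic",
                   source = "reannotation_2021.tsv", imported_at = t2)
  record_attribute(store, designated, "classification", "C3",
                   source = "classification_2020.tsv", imported_at = t1)
  record_attribute(store, designated, "classification", "C5",
                   source = "classification_2021.tsv", imported_at = t2)
  carriers <- c("S001", "S002", "S003")
  for (smp in carriers) {
    record_observation(store, designated, smp,
                       list(genotype = "0/1", allele_frequency = 48.7),
                       source = paste0(smp, ".vcf"), imported_at = t1)
  }
  decoy_histories <- list(
    list("pathogenic", "pathogenic"),              # unchanged (no growth)
    list("benign", "likely benign"),               # wrong current value
    list("uncertain significance"),                # no prior entry
    list("pathogenic", "uncertain significance"),  # reverse transition
    list("likely pathogenic", "pathogenic")        # prior not in set
  )
  decoys <- with_seed(seed, {
    chroms <- sample(paste0("chr", c(2, 7, 11, 17, 19)))
    pos <- sample.int(100000000L, length(decoy_histories))
    al <- random_snv_alleles(length(decoy_histories))
    data.frame(chrom = chroms, pos = pos, ref = al$ref, alt = al$alt,
               stringsAsFactors = FALSE)
  })
  for (i in seq_len(nrow(decoys))) {
    key <- variant_key(decoys$chrom[i], decoys$pos[i], decoys$ref[i],
                       decoys$alt[i])
    upsert_variant(store, key)
    hist <- decoy_histories[[i]]
    for (j in seq_along(hist)) {
      record_attribute(store, key, "ClinVar", hist[[j]],
                       source = if (j == 1L) "annotation_2020.tsv" else
                         "reannotation_2021.tsv",
                       imported_at = if (j == 1L) t1 else t2)
    }
  }
  # one unannotated decoy
  extra <- variant_key("chr5", 1234567, "G", "T")
  upsert_variant(store, extra)
  q <- change_query("ClinVar",
                    previous_in = c("benign", "uncertain significance"),
                    current_equals = "pathogenic")
  list(store = store, designated = designated$id, query = q,
       expected = list(change_hits = designated$id, carriers = carriers))
}
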