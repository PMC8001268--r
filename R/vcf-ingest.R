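# VCF ingestion: parse a file under a VCF dialect spec, apply row and
# virtual-panel filters, split multiallelic records, and load variants,
# variant attributes and sample observations into the store.

new_ingest_report <- function(kind, source) {
  structure(
    list(kind = kind, source = source,
         rows_read = 0L,
         rows_dropped_by_row_filter = 0L,
         rows_dropped_by_virtual_panel = 0L,
         rows_loaded = 0L,
         rows_skipped = 0L,
         records_loaded = 0L,
         records_skipped_symbolic = 0L,
         variants_created = 0L,
         variants_matched_existing = 0L,
         attributes_created = 0L,
         attributes_unchanged = 0L,
         attributes_updated = 0L,
         rows_stopped_by_break = 0L,
         rows_rejected = 0L,
         warnings = integer(0)),
    class = "ingest_report"
  )
}

tally_outcomes <- function(report, outcomes) {
  report$attributes_created <- report$attributes_created +
    sum(outcomes == "created")
  report$attributes_unchanged <- report$attributes_unchanged +
    sum(outcomes == "unchanged")
  report$attributes_updated <- report$attributes_updated +
    sum(outcomes == "updated")
  report
}

add_warning <- function(report, what) {
  cur <- report$warnings[what]
  report$warnings[what] <- if (is.na(cur)) 1L else cur + 1L
  report
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("<ingest_report> ", x$kind, " import of ", x$source, "\n", sep = "")
  cat("  rows read: ", x$rows_read,
      "  dropped by row filter: ", x$rows_dropped_by_row_filter,
      "  dropped by virtual panel: ", x$rows_dropped_by_virtual_panel, "\n",
      sep = "")
  cat("  rows loaded: ", x$rows_loaded,
      "  rows skipped: ", x$rows_skipped, "\n", sep = "")
  cat("  variants created: ", x$variants_created,
      "  matched existing: ", x$variants_matched_existing, "\n", sep = "")
  cat("  attributes created/unchanged/updated: ", x$attributes_created,
      "/", x$attributes_unchanged, "/", x$attributes_updated, "\n",
      sep = "")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (nm in names(x$warnings)) {
      cat("    ", nm, ": ", x$warnings[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Extract one INFO subfield
#'
#' Parses the semicolon-delimited `key=value` pairs and flags of a VCF INFO
#' column. Flags (keys with no `=`) return an empty-string sentinel;
#' absent keys return `NA_character_`.
#'
#' @param info_column the INFO column text of one record.
#' @param key the subfield key to extract.
#' @return the value, `""` for a flag, or `NA_character_` if absent.
#' @examples
#' parse_info_subfield("SGVEP=BRCA2;TYPE=SNV", "SGVEP")  # "BRCA2"
#' parse_info_subfield("DP=100", "SGVEP")                # NA
#' @export
parse_info_subfield <- function(info_column, key) {
  if (is.null(info_column) || is.na(info_column) ||
      identical(info_column, ".")) {
    return(NA_character_)
  }
  tokens <- strsplit(as.character(info_column), ";", fixed = TRUE)[[1]]
  for (tok in tokens) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq == -1L) {
      if (identical(tok, key)) return("")
    } else if (identical(substr(tok, 1L, eq - 1L), key)) {
      return(substr(tok, eq + 1L, nchar(tok)))
    }
  }
  NA_character_
}

#' Split a database cross-reference list into per-source attributes
#'
#' Cross-reference values are comma-delimited `source:token` pairs (for
#' example `"ClinVar:pathogenic,dbsnp:rs1"`); each becomes one attribute
#' named `dbxref_<source>`. Tokens without a colon are collected whole
#' under `dbxref_raw`.
#'
#' @param value the cross-reference string.
#' @return named character vector of attributes; empty for an empty value.
#' @examples
#' split_dbxref("ClinVar:pathogenic,dbsnp:rs1")
#' @export
split_dbxref <- function(value) {
  if (is.null(value) || is.na(value) || !nzchar(trimws(value))) {
    return(stats::setNames(character(0), character(0)))
  }
  out <- character(0)
  raw <- character(0)
  for (tok in strsplit(trimws(value), ",", fixed = TRUE)[[1]]) {
    tok <- trimws(tok)
    if (!nzchar(tok)) next
    colon <- regexpr(":", tok, fixed = TRUE)
    if (colon == -1L) {
      raw <- c(raw, tok)
    } else {
      src <- substr(tok, 1L, colon - 1L)
      out[paste0("dbxref_", src)] <- substr(tok, colon + 1L, nchar(tok))
    }
  }
  if (length(raw)) out["dbxref_raw"] <- paste(raw, collapse = ",")
  out
}

# Symbolic alts (<DEL>, <NON_REF>) and breakend notation cannot form a
# variant key (allele alphabet is A,C,G,T,N).
is_symbolic_alt <- function(alt) {
  grepl("[<>\\[\\]]", alt) || identical(alt, "*") ||
    grepl("[^ACGTNacgtn]", alt)
}

vcf_open <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Pre-check for a #CHROM header line so a malformed file gets a clear
# diagnostic before the parser runs.
check_vcf_header <- function(path) {
  con <- vcf_open(path)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (startsWith(line, "#CHROM")) return(invisible(TRUE))
    if (!startsWith(line, "#")) break
  }
  stop("malformed VCF (no #CHROM header line): ", path, call. = FALSE)
}

#' Ingest a VCF file under a dialect spec
#'
#' For each surviving data line (after the dialect's row filter, the
#' virtual-panel filter, and multiallelic splitting): the variant is
#' upserted, INFO-mapped attributes are written with history semantics, and
#' FORMAT-mapped plus derived sample attributes are written as the sample's
#' observation. Every row's fate is tallied in the report. The import is
#' transactional — on error the store is left unchanged.
#'
#' Only single-sample VCFs are supported; `sample_id` is caller-supplied.
#' Phased genotype separators (`|`) are normalized to `/` before filter
#' comparison, so `0|0` is excluded by a `0/0` filter. FILTER and QUAL
#' columns are ignored. Records with symbolic alts or breakends are skipped
#' with a warning. Per-record warnings are aggregated as counts in the
#' report.
#'
#' @param store a `variant_store`.
#' @param path VCF file (plain or gzip).
#' @param dialect a [vcf_dialect()].
#' @param sample_id identifier of the file's sample.
#' @param panel optional [gene_panel()] associated with the file.
#' @param virtual_panel optional [virtual_panel()]; requires the dialect to
#'   have `gene_symbol_source` (hard error otherwise).
#' @param source provenance label recorded on every write; defaults to the
#'   file name.
#' @param imported_at ISO-8601 timestamp for the import.
#' @return an `ingest_report`.
#' @export
ingest_vcf <- function(store, path, dialect, sample_id,
                       panel = NULL, virtual_panel = NULL,
                       source = basename(path),
                       imported_at = store_now()) {
  stopifnot(inherits(store, "variant_store"),
            inherits(dialect, "vcf_dialect"))
  if (!is.null(virtual_panel) && is.null(dialect$gene_symbol_source)) {
    stop("dialect '", dialect$name, "' has no gene_symbol_source; ",
         "virtual-panel filtering is impossible", call. = FALSE)
  }
  if (missing(sample_id) && length(dialect$sample_attr_map) +
      length(dialect$derived_attrs) > 0L) {
    stop("sample_id is required", call. = FALSE)
  }
  check_vcf_header(path)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) {
      stop("malformed VCF: ", path, " (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  fix <- vcf@fix
  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) > 2L) {
    stop("multi-sample VCF not supported (", ncol(gt) - 1L,
         " sample columns): ", path, call. = FALSE)
  }
  report <- new_ingest_report("vcf", source)
  with_store_transaction(store, {
    for (i in seq_len(nrow(fix))) {
      report$rows_read <- report$rows_read + 1L
      info <- fix[i, "INFO"]

      fmt_rec <- list()
      if (!is.null(gt) && ncol(gt) == 2L && !is.na(gt[i, 1])) {
        keys <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
        vals <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
        length(vals) <- length(keys)
        fmt_rec <- as.list(vals)
        names(fmt_rec) <- keys
        if (!is.null(fmt_rec$GT) && !is.na(fmt_rec$GT)) {
          fmt_rec$GT <- gsub("|", "/", fmt_rec$GT, fixed = TRUE)
        }
      }

      if (!is.null(dialect$row_filter)) {
        f <- dialect$row_filter
        rec <- fmt_rec
        if (is.null(rec[[f$field]])) {
          v <- parse_info_subfield(info, f$field)
          if (!is.na(v)) rec[[f$field]] <- v
        }
        if (evaluate_row_filter(f, rec)) {
          report$rows_dropped_by_row_filter <-
            report$rows_dropped_by_row_filter + 1L
          next
        }
      }

      if (!is.null(virtual_panel)) {
        gene <- parse_info_subfield(info, dialect$gene_symbol_source)
        if (!passes_virtual_panel(gene, virtual_panel)) {
          report$rows_dropped_by_virtual_panel <-
            report$rows_dropped_by_virtual_panel + 1L
          next
        }
      }

      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      loaded_any <- FALSE
      for (j in seq_along(alts)) {
        if (is_symbolic_alt(alts[j])) {
          report$records_skipped_symbolic <-
            report$records_skipped_symbolic + 1L
          report <- add_warning(report, "symbolic or non-ACGTN alt skipped")
          next
        }
        key <- tryCatch(
          variant_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                      alts[j]),
          error = function(e) NULL
        )
        if (is.null(key)) {
          report <- add_warning(report, "invalid variant key skipped")
          next
        }
        up <- upsert_variant(store, key)
        if (up$created) {
          report$variants_created <- report$variants_created + 1L
        } else {
          report$variants_matched_existing <-
            report$variants_matched_existing + 1L
        }

        for (k in names(dialect$variant_attr_map)) {
          v <- parse_info_subfield(info, k)
          if (is.na(v) || !nzchar(trimws(v))) next
          if (k %in% dialect$split_keys) {
            xrefs <- split_dbxref(v)
            for (nm in names(xrefs)) {
              out <- record_attribute(store, key, nm, xrefs[[nm]],
                                      source, imported_at)
              report <- tally_outcomes(report, out)
            }
          } else {
            out <- record_attribute(store, key,
                                    dialect$variant_attr_map[[k]], v,
                                    source, imported_at)
            report <- tally_outcomes(report, out)
          }
        }

        sattrs <- list()
        for (k in names(dialect$sample_attr_map)) {
          v <- fmt_rec[[k]]
          if (is.null(v) || is.na(v) || identical(v, ".")) {
            report <- add_warning(
              report, paste0("FORMAT subfield '", k, "' absent"))
            next
          }
          sattrs[[dialect$sample_attr_map[[k]]]] <- v
        }
        for (d in dialect$derived_attrs) {
          v <- withCallingHandlers(
            evaluate_derived(d, fmt_rec, alt_index = j),
            warning = function(w) {
              invokeRestart("muffleWarning")
            }
          )
          if (is.na(v)) {
            report <- add_warning(
              report, paste0("derived attribute '", d$target_attr,
                             "' undefined"))
          } else {
            sattrs[[d$target_attr]] <- v
          }
        }
        if (length(sattrs)) {
          out <- record_observation(store, key, sample_id, sattrs,
                                    source, imported_at)
          report <- tally_outcomes(report, out)
        }
        report$records_loaded <- report$records_loaded + 1L
        loaded_any <- TRUE
      }
      if (loaded_any) {
        report$rows_loaded <- report$rows_loaded + 1L
      } else {
        report$rows_skipped <- report$rows_skipped + 1L
      }
    }
    report
  })
}
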