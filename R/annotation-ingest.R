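# Delimited annotation and batch-classification ingestion, writing variant
# attributes (including the pathogenicity tier) with history semantics.

#' The five-tier IARC pathogenicity classification
#'
#' Codes C1..C5 in one-to-one correspondence with the labels Benign,
#' Likely Benign, Uncertain Significance, Likely Pathogenic, Pathogenic.
#'
#' @return data.frame with columns `code` and `label`.
#' @export
classification_tiers <- function() {
  data.frame(
    code = paste0("C", 1:5),
    label = c("Benign", "Likely Benign", "Uncertain Significance",
              "Likely Pathogenic", "Pathogenic"),
    stringsAsFactors = FALSE
  )
}

#' Label for a tier code (and vice versa)
#' @param code a tier code `"C1"`..`"C5"`.
#' @return the label; error for an unknown code.
#' @export
tier_label <- function(code) {
  tiers <- classification_tiers()
  i <- match(code, tiers$code)
  if (any(is.na(i))) {
    stop("unknown classification tier: ",
         paste(code[is.na(i)], collapse = ", "), call. = FALSE)
  }
  tiers$label[i]
}

read_delimited <- function(path, delimiter, skip = 0L) {
  utils::read.delim(path, sep = delimiter, skip = skip, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), quote = "\"",
                    comment.char = "", blank.lines.skip = FALSE,
                    stringsAsFactors = FALSE)
}

row_key <- function(row, key_columns) {
  if (length(key_columns) == 4L) {
    variant_key(row[[key_columns[1]]], row[[key_columns[2]]],
                row[[key_columns[3]]], row[[key_columns[4]]])
  } else {
    parse_variant_key(row[[key_columns[1]]])
  }
}

#' Ingest a delimited annotation file under an annotation dialect
#'
#' Rows are processed in order. Processing stops just before the first row
#' matching the dialect's break condition; the row filter drops individual
#' rows. For each surviving row the variant is located by its key (skipped
#' with a warning when absent, unless `create_missing`) and every non-empty
#' mapped column is written via [record_attribute()] — empty cells never
#' create history entries. Transactional like all imports.
#'
#' @param store a `variant_store`.
#' @param path annotation file path.
#' @param dialect an [annotation_dialect()].
#' @param create_missing create variants not yet present in the store?
#' @param source provenance label; defaults to the file name.
#' @param imported_at ISO-8601 timestamp for the import.
#' @return an `ingest_report`.
#' @export
ingest_annotation <- function(store, path, dialect, create_missing = FALSE,
                              source = basename(path),
                              imported_at = store_now()) {
  stopifnot(inherits(store, "variant_store"),
            inherits(dialect, "annotation_dialect"))
  df <- read_delimited(path, dialect$delimiter, skip = dialect$header_rows)
  missing_keys <- setdiff(dialect$key_columns, names(df))
  if (length(missing_keys)) {
    stop("annotation file ", path, " lacks key column(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  report <- new_ingest_report("annotation", source)
  with_store_transaction(store, {
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      if (!is.null(dialect$break_condition) &&
          row_filter_matches(dialect$break_condition, row)) {
        report$rows_stopped_by_break <- nrow(df) - i + 1L
        break
      }
      report$rows_read <- report$rows_read + 1L
      if (!is.null(dialect$row_filter) &&
          evaluate_row_filter(dialect$row_filter, row)) {
        report$rows_dropped_by_row_filter <-
          report$rows_dropped_by_row_filter + 1L
        next
      }
      key <- tryCatch(row_key(row, dialect$key_columns),
                      error = function(e) NULL)
      if (is.null(key)) {
        report$rows_skipped <- report$rows_skipped + 1L
        report <- add_warning(report, "unparseable variant key")
        next
      }
      if (!has_variant(store, key$id)) {
        if (create_missing) {
          upsert_variant(store, key)
          report$variants_created <- report$variants_created + 1L
        } else {
          report$rows_skipped <- report$rows_skipped + 1L
          report <- add_warning(report, "variant not in store, row skipped")
          next
        }
      } else {
        report$variants_matched_existing <-
          report$variants_matched_existing + 1L
      }
      wrote <- FALSE
      for (col in names(dialect$attr_map)) {
        v <- row[[col]]
        if (is.null(v) || is.na(v)) next
        v <- trimws(v)
        if (!nzchar(v)) next
        out <- record_attribute(store, key, dialect$attr_map[[col]], v,
                                source, imported_at)
        report <- tally_outcomes(report, out)
        wrote <- TRUE
      }
      report$rows_loaded <- report$rows_loaded + 1L
      report$records_loaded <- report$records_loaded + 1L
    }
    report
  })
}

#' Batch-upload pathogenicity classifications
#'
#' Reads a tab-delimited file with columns `chrom`, `pos`, `ref`, `alt`,
#' `tier` (codes C1..C5) and stores the tier as the reserved attribute
#' `"classification"` with full history semantics, so reclassifications
#' (e.g. C3 to C5) are tracked. Rows with an unknown tier code are
#' rejected and counted.
#'
#' @param store a `variant_store`.
#' @param path TSV file path.
#' @param create_missing create variants not yet present? Default `TRUE`:
#'   a classification batch is authoritative for the variants it names.
#' @param source provenance label.
#' @param imported_at ISO-8601 timestamp.
#' @return an `ingest_report`.
#' @export
ingest_classification <- function(store, path, create_missing = TRUE,
                                  source = basename(path),
                                  imported_at = store_now()) {
  df <- read_delimited(path, "\t")
  needed <- c("chrom", "pos", "ref", "alt", "tier")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("classification file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  report <- new_ingest_report("classification", source)
  valid_tiers <- classification_tiers()$code
  with_store_transaction(store, {
    for (i in seq_len(nrow(df))) {
      report$rows_read <- report$rows_read + 1L
      tier <- trimws(df$tier[i])
      if (!tier %in% valid_tiers) {
        report$rows_rejected <- report$rows_rejected + 1L
        report <- add_warning(report, "unknown classification tier")
        next
      }
      key <- tryCatch(
        variant_key(df$chrom[i], df$pos[i], df$ref[i], df$alt[i]),
        error = function(e) NULL
      )
      if (is.null(key)) {
        report$rows_skipped <- report$rows_skipped + 1L
        report <- add_warning(report, "unparseable variant key")
        next
      }
      if (!has_variant(store, key$id)) {
        if (create_missing) {
          upsert_variant(store, key)
          report$variants_created <- report$variants_created + 1L
        } else {
          report$rows_skipped <- report$rows_skipped + 1L
          report <- add_warning(report, "variant not in store, row skipped")
          next
        }
      } else {
        report$variants_matched_existing <-
          report$variants_matched_existing + 1L
      }
      out <- record_attribute(store, key, "classification", tier, source,
                              imported_at)
      report <- tally_outcomes(report, out)
      report$rows_loaded <- report$rows_loaded + 1L
    }
    report
  })
}

#' Classify a single variant
#'
#' The direct equivalent of setting the tier interactively: writes the
#' reserved `"classification"` attribute with history semantics.
#'
#' @param store a `variant_store`.
#' @param chrom,pos,ref,alt the variant's key components.
#' @param tier a tier code `"C1"`..`"C5"`.
#' @param create_missing create the variant if absent (default `TRUE`).
#' @param source provenance label.
#' @param imported_at ISO-8601 timestamp.
#' @return the write outcome (`"created"`, `"unchanged"`, `"updated"`),
#'   invisibly.
#' @export
classify <- function(store, chrom, pos, ref, alt, tier,
                     create_missing = TRUE, source = "manual",
                     imported_at = store_now()) {
  tier <- trimws(as.character(tier))
  if (!tier %in% classification_tiers()$code) {
    stop("unknown classification tier: ", tier, call. = FALSE)
  }
  key <- variant_key(chrom, pos, ref, alt)
  if (!has_variant(store, key$id)) {
    if (!create_missing) stop("unknown variant: ", key$id, call. = FALSE)
    upsert_variant(store, key)
  }
  record_attribute(store, key, "classification", tier, source, imported_at)
}
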