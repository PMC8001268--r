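# -- variant identity ---------------------------------------------------------

CHROM_ORDER <- paste0("chr", c(1:22, "X", "Y", "M", "MT"))

#' Canonicalize a chromosome label
#'
#' Bare chromosome names are mapped to their "chr"-prefixed form; an existing
#' prefix is preserved (case-normalized to lowercase "chr"). No other
#' renaming is performed, so "chrMT" and "chrM" remain distinct labels.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @export
canonical_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  has_prefix <- grepl("^[Cc][Hh][Rr]", chrom)
  chrom[has_prefix] <- sub("^[Cc][Hh][Rr]", "chr", chrom[has_prefix])
  chrom[!has_prefix] <- paste0("chr", chrom[!has_prefix])
  chrom
}

#' Construct a validated variant key
#'
#' Variant identity is the exact tuple (chrom, pos, ref, alt) after
#' canonicalization: chromosome prefix normalization and allele uppercasing.
#' No left-alignment or parsimony normalization is applied, so
#' differently-represented indels are distinct records. The canonical text
#' form is `"chrom|pos|ref|alt"`.
#'
#' @param chrom chromosome label.
#' @param pos 1-based VCF position (integer >= 1).
#' @param ref reference allele over A,C,G,T,N.
#' @param alt single alternate allele over A,C,G,T,N.
#' @return an object of class `variant_key` with fields `chrom`, `pos`,
#'   `ref`, `alt` and the canonical `id`.
#' @examples
#' variant_key("13", 32936829, "A", "G")$id  # "chr13|32936829|A|G"
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- canonical_chrom(chrom)
  pos <- suppressWarnings(as.integer(pos))
  ref <- toupper(trimws(as.character(ref)))
  alt <- toupper(trimws(as.character(alt)))
  if (length(chrom) != 1L || !nzchar(chrom)) {
    stop("variant key: 'chrom' must be a single non-empty label", call. = FALSE)
  }
  if (length(pos) != 1L || is.na(pos) || pos < 1L) {
    stop("variant key: 'pos' must be a 1-based integer coordinate >= 1",
         call. = FALSE)
  }
  for (al in list(ref = ref, alt = alt)) {
    if (length(al) != 1L || !nzchar(al) || grepl("[^ACGTN]", al)) {
      stop("variant key: alleles must be non-empty strings over A,C,G,T,N",
           call. = FALSE)
    }
  }
  if (identical(ref, alt)) {
    stop("variant key: ref and alt must differ", call. = FALSE)
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         id = paste(chrom, pos, ref, alt, sep = "|")),
    class = "variant_key"
  )
}

#' Parse the canonical text form of a variant key
#'
#' @param id a string `"chrom|pos|ref|alt"`.
#' @return a `variant_key`.
#' @export
parse_variant_key <- function(id) {
  parts <- strsplit(as.character(id), "|", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("variant key text form must have four |-separated fields: ", id,
         call. = FALSE)
  }
  variant_key(parts[1], parts[2], parts[3], parts[4])
}

#' @export
print.variant_key <- function(x, ...) {
  cat("<variant>", x$id, "\n")
  invisible(x)
}

as_variant_key <- function(x) {
  if (inherits(x, "variant_key")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_variant_key(x))
  stop("expected a variant_key or its canonical 'chrom|pos|ref|alt' form",
       call. = FALSE)
}

# Rank used for deterministic ordering: chr1..chr22, chrX, chrY, chrM/chrMT,
# then any other label lexicographically.
chrom_rank <- function(chrom) {
  r <- match(chrom, CHROM_ORDER)
  r[is.na(r)] <- length(CHROM_ORDER) + 1L
  r
}

#' Order variant ids canonically
#'
#' Natural chromosome order (chr1..chr22, chrX, chrY, chrM, then others
#' lexicographically), then position, ref, alt.
#'
#' @param ids character vector of canonical variant ids.
#' @return the ids, sorted.
#' @export
sort_variant_ids <- function(ids) {
  if (length(ids) == 0L) return(character(0))
  parts <- do.call(rbind, strsplit(ids, "|", fixed = TRUE))
  ord <- order(chrom_rank(parts[, 1]), parts[, 1],
               as.integer(parts[, 2]), parts[, 3], parts[, 4])
  ids[ord]
}

# -- the store ----------------------------------------------------------------

#' Create an empty variant store
#'
#' The store holds unique variants, per-variant attribute histories,
#' per-sample observations, and the registered dialects and panels. It is
#' held in memory as hashed environments and persisted as a single JSON
#' file via [save_store()] / [load_store()]. Imports are transactional: a
#' failed import rolls the store back to its prior state.
#'
#' @return an object of class `variant_store`.
#' @export
variant_store <- function() {
  s <- new.env(parent = emptyenv())
  s$variants <- new.env(hash = TRUE, parent = emptyenv())
  s$attrs <- new.env(hash = TRUE, parent = emptyenv())
  s$obs <- new.env(hash = TRUE, parent = emptyenv())
  s$dialects <- list()
  s$panels <- list()
  s$virtual_panels <- list()
  s$seq <- 0L
  class(s) <- "variant_store"
  s
}

store_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

next_seq <- function(store) {
  store$seq <- store$seq + 1L
  store$seq
}

#' Insert a variant if absent
#'
#' Idempotent: a second call with an equal key returns the same handle with
#' `created = FALSE`. This is the deduplication point — the same variant
#' arriving from different file types maps to one record.
#'
#' @param store a `variant_store`.
#' @param key a [variant_key()] or its canonical text form.
#' @return list with the canonical `id`, the `key`, and logical `created`.
#' @export
upsert_variant <- function(store, key) {
  key <- as_variant_key(key)
  created <- !exists(key$id, envir = store$variants, inherits = FALSE)
  if (created) {
    assign(key$id, key, envir = store$variants)
  }
  list(id = key$id, key = key, created = created)
}

#' Number of distinct variants in the store
#' @param store a `variant_store`.
#' @return integer count.
#' @export
unique_variant_count <- function(store) {
  length(ls(store$variants, all.names = TRUE))
}

#' All variant ids, canonically ordered
#' @param store a `variant_store`.
#' @return character vector of canonical ids.
#' @export
variant_ids <- function(store) {
  sort_variant_ids(ls(store$variants, all.names = TRUE))
}

has_variant <- function(store, id) {
  exists(id, envir = store$variants, inherits = FALSE)
}

new_entry <- function(store, value, source, imported_at) {
  list(value = value, imported_at = imported_at, source = source,
       seq = next_seq(store))
}

# Core overwrite-vs-track semantics shared by variant attributes and sample
# observations: identical values refresh provenance without growing history,
# differing values append, preserving the prior value.
apply_entry <- function(store, entries, value, source, imported_at) {
  n <- length(entries)
  if (n == 0L) {
    return(list(entries = list(new_entry(store, value, source, imported_at)),
                outcome = "created"))
  }
  cur <- entries[[n]]
  if (identical(cur$value, value)) {
    cur$imported_at <- imported_at
    cur$source <- source
    entries[[n]] <- cur
    return(list(entries = entries, outcome = "unchanged"))
  }
  entries[[n + 1L]] <- new_entry(store, value, source, imported_at)
  list(entries = entries, outcome = "updated")
}

#' Record a variant attribute value with history semantics
#'
#' First write creates the attribute (history length 1). A value identical
#' to the current one leaves history untouched but refreshes the current
#' entry's timestamp and source ("last confirmed" stays recoverable). A
#' differing value appends a new entry, preserving the prior value — this is
#' the overwritten-if-identical, tracked-historically-if-different rule.
#' Values are compared as whitespace-trimmed, case-sensitive strings.
#'
#' @param store a `variant_store`.
#' @param variant a `variant_key`, its text form, or the id of a stored
#'   variant.
#' @param name attribute name.
#' @param value attribute value (coerced to character, trimmed; empty values
#'   are rejected — histories never contain the empty string).
#' @param source file identifier or other provenance label.
#' @param imported_at ISO-8601 timestamp; defaults to now (UTC).
#' @return one of `"created"`, `"unchanged"`, `"updated"` (invisibly).
#' @export
record_attribute <- function(store, variant, name, value,
                             source = "manual", imported_at = store_now()) {
  key <- as_variant_key(variant)
  if (!has_variant(store, key$id)) {
    stop("unknown variant: ", key$id, call. = FALSE)
  }
  value <- trimws(as.character(value))
  if (length(value) != 1L || is.na(value) || !nzchar(value)) {
    stop("attribute value must be a single non-empty string", call. = FALSE)
  }
  name <- as.character(name)
  hist <- if (exists(key$id, envir = store$attrs, inherits = FALSE)) {
    get(key$id, envir = store$attrs)
  } else {
    list()
  }
  res <- apply_entry(store, hist[[name]] %||% list(), value, source,
                     imported_at)
  hist[[name]] <- res$entries
  assign(key$id, hist, envir = store$attrs)
  invisible(res$outcome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full history of a variant attribute
#'
#' @inheritParams record_attribute
#' @return data.frame with columns `value`, `imported_at`, `source`, `seq`
#'   in write order (current value last); zero rows if never set.
#' @export
attribute_history <- function(store, variant, name) {
  key <- as_variant_key(variant)
  if (!has_variant(store, key$id)) {
    stop("unknown variant: ", key$id, call. = FALSE)
  }
  entries <- if (exists(key$id, envir = store$attrs, inherits = FALSE)) {
    get(key$id, envir = store$attrs)[[name]] %||% list()
  } else {
    list()
  }
  entries_df(entries)
}

entries_df <- function(entries) {
  data.frame(
    value = vapply(entries, `[[`, "", "value"),
    imported_at = vapply(entries, `[[`, "", "imported_at"),
    source = vapply(entries, `[[`, "", "source"),
    seq = vapply(entries, `[[`, 0L, "seq"),
    stringsAsFactors = FALSE
  )
}

#' Current value of a variant attribute
#' @inheritParams record_attribute
#' @return the current value, or `NA_character_` if never set.
#' @export
current_attribute <- function(store, variant, name) {
  h <- attribute_history(store, variant, name)
  if (nrow(h) == 0L) NA_character_ else h$value[nrow(h)]
}

#' Record one sample's observation of a variant
#'
#' Sample-linked attributes (genotype, allele-frequency percent, ...) follow
#' the same overwrite-vs-track rule as variant attributes, keyed by
#' (sample, variant, attribute).
#'
#' @inheritParams record_attribute
#' @param sample_id sample (patient) identifier.
#' @param sample_attrs named list/vector of attribute values; empty values
#'   are skipped.
#' @return named character vector of outcomes per attribute (invisibly).
#' @export
record_observation <- function(store, variant, sample_id, sample_attrs,
                               source = "manual", imported_at = store_now()) {
  key <- as_variant_key(variant)
  if (!has_variant(store, key$id)) {
    stop("unknown variant: ", key$id, call. = FALSE)
  }
  sample_id <- as.character(sample_id)
  stopifnot(length(sample_id) == 1L, nzchar(sample_id))
  per_var <- if (exists(key$id, envir = store$obs, inherits = FALSE)) {
    get(key$id, envir = store$obs)
  } else {
    list()
  }
  per_sample <- per_var[[sample_id]] %||% list()
  outcomes <- character(0)
  for (nm in names(sample_attrs)) {
    value <- trimws(format_attr_value(sample_attrs[[nm]]))
    if (is.na(value) || !nzchar(value)) next
    res <- apply_entry(store, per_sample[[nm]] %||% list(), value, source,
                       imported_at)
    per_sample[[nm]] <- res$entries
    outcomes[nm] <- res$outcome
  }
  per_var[[sample_id]] <- per_sample
  assign(key$id, per_var, envir = store$obs)
  invisible(outcomes)
}

# Numeric sample attributes (derived allele frequencies) are stored at full
# precision as their shortest round-tripping decimal form.
format_attr_value <- function(x) {
  if (is.numeric(x)) {
    format(x, digits = 15, trim = TRUE, scientific = FALSE)
  } else {
    as.character(x)
  }
}

#' Observation history for one sample attribute of a variant
#' @inheritParams record_observation
#' @param name attribute name.
#' @return data.frame as in [attribute_history()].
#' @export
observation_history <- function(store, variant, sample_id, name) {
  key <- as_variant_key(variant)
  per_var <- if (exists(key$id, envir = store$obs, inherits = FALSE)) {
    get(key$id, envir = store$obs)
  } else {
    list()
  }
  entries_df((per_var[[as.character(sample_id)]] %||% list())[[name]] %||%
               list())
}

#' Samples carrying a variant
#'
#' The recontact lookup: every sample with at least one observation of the
#' variant, each listed once regardless of how many source files reported
#' it.
#'
#' @inheritParams record_attribute
#' @return sorted character vector of distinct sample identifiers.
#' @export
samples_with_variant <- function(store, variant) {
  key <- as_variant_key(variant)
  if (!exists(key$id, envir = store$obs, inherits = FALSE)) {
    return(character(0))
  }
  sort(unique(names(get(key$id, envir = store$obs))))
}

#' Store summary counts
#' @param store a `variant_store`.
#' @return list with `n_variants`, `n_samples`, `n_attribute_entries`,
#'   `n_observation_entries`.
#' @export
store_stats <- function(store) {
  n_attr <- 0L
  for (id in ls(store$attrs, all.names = TRUE)) {
    n_attr <- n_attr + sum(lengths(get(id, envir = store$attrs)))
  }
  samples <- character(0)
  n_obs <- 0L
  for (id in ls(store$obs, all.names = TRUE)) {
    per_var <- get(id, envir = store$obs)
    samples <- union(samples, names(per_var))
    n_obs <- n_obs + sum(vapply(per_var, function(s) sum(lengths(s)),
                                integer(1)))
  }
  list(n_variants = unique_variant_count(store),
       n_samples = length(samples),
       n_attribute_entries = n_attr,
       n_observation_entries = n_obs)
}

#' @export
print.variant_store <- function(x, ...) {
  st <- store_stats(x)
  cat("<variant_store>\n")
  cat("  variants:            ", st$n_variants, "\n")
  cat("  samples:             ", st$n_samples, "\n")
  cat("  attribute entries:   ", st$n_attribute_entries, "\n")
  cat("  observation entries: ", st$n_observation_entries, "\n")
  cat("  dialects: ", length(x$dialects),
      " panels: ", length(x$panels),
      " virtual panels: ", length(x$virtual_panels), "\n", sep = "")
  invisible(x)
}

# -- transactions -------------------------------------------------------------

snapshot_store <- function(store) {
  list(variants = as.list(store$variants, all.names = TRUE),
       attrs = as.list(store$attrs, all.names = TRUE),
       obs = as.list(store$obs, all.names = TRUE),
       dialects = store$dialects, panels = store$panels,
       virtual_panels = store$virtual_panels, seq = store$seq)
}

restore_store <- function(store, snap) {
  for (slot in c("variants", "attrs", "obs")) {
    e <- store[[slot]]
    rm(list = ls(e, all.names = TRUE), envir = e)
    list2env(snap[[slot]], envir = e)
  }
  store$dialects <- snap$dialects
  store$panels <- snap$panels
  store$virtual_panels <- snap$virtual_panels
  store$seq <- snap$seq
  invisible(store)
}

#' Run an import transactionally
#'
#' Evaluates `code`; on error the store is rolled back to its state at
#' entry, so an import either fully applies or not at all.
#'
#' @param store a `variant_store`.
#' @param code expression performing the writes.
#' @return the value of `code`.
#' @export
with_store_transaction <- function(store, code) {
  snap <- snapshot_store(store)
  tryCatch(code, error = function(e) {
    restore_store(store, snap)
    stop(e)
  })
}

# -- persistence --------------------------------------------------------------

#' Save a store to a single JSON file
#'
#' Serialization is deterministic (variants, attributes and observations in
#' canonical order), so two equal stores save to identical bytes and a
#' save/load round-trip is exact.
#'
#' @param store a `variant_store`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  ids <- variant_ids(store)
  vars <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), stringsAsFactors = FALSE
  )
  if (length(ids)) {
    parts <- do.call(rbind, strsplit(ids, "|", fixed = TRUE))
    vars <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                       ref = parts[, 3], alt = parts[, 4],
                       stringsAsFactors = FALSE)
  }
  attr_rows <- list()
  for (id in ids) {
    if (!exists(id, envir = store$attrs, inherits = FALSE)) next
    hist <- get(id, envir = store$attrs)
    for (nm in sort(names(hist))) {
      df <- entries_df(hist[[nm]])
      df$variant <- id
      df$name <- nm
      attr_rows[[length(attr_rows) + 1L]] <- df
    }
  }
  obs_rows <- list()
  for (id in ids) {
    if (!exists(id, envir = store$obs, inherits = FALSE)) next
    per_var <- get(id, envir = store$obs)
    for (smp in sort(names(per_var))) {
      for (nm in sort(names(per_var[[smp]]))) {
        df <- entries_df(per_var[[smp]][[nm]])
        df$variant <- id
        df$sample <- smp
        df$name <- nm
        obs_rows[[length(obs_rows) + 1L]] <- df
      }
    }
  }
  payload <- list(
    format = "varledger-store", version = 1L, seq = store$seq,
    variants = vars,
    attributes = if (length(attr_rows)) do.call(rbind, attr_rows) else
      list(),
    observations = if (length(obs_rows)) do.call(rbind, obs_rows) else
      list(),
    dialects = lapply(store$dialects, dialect_to_config),
    panels = lapply(store$panels, unclass),
    virtual_panels = lapply(store$virtual_panels, unclass)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a store saved with [save_store()]
#' @param path JSON file written by [save_store()].
#' @return a `variant_store`.
#' @export
load_store <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  if (!identical(payload$format, "varledger-store")) {
    stop("not a varledger store file: ", path, call. = FALSE)
  }
  store <- variant_store()
  v <- payload$variants
  if (is.data.frame(v) && nrow(v)) {
    for (i in seq_len(nrow(v))) {
      upsert_variant(store, variant_key(v$chrom[i], v$pos[i], v$ref[i],
                                        v$alt[i]))
    }
  }
  a <- payload$attributes
  if (is.data.frame(a) && nrow(a)) {
    for (i in seq_len(nrow(a))) {
      hist <- if (exists(a$variant[i], envir = store$attrs,
                         inherits = FALSE)) {
        get(a$variant[i], envir = store$attrs)
      } else {
        list()
      }
      ent <- hist[[a$name[i]]] %||% list()
      ent[[length(ent) + 1L]] <- list(value = a$value[i],
                                      imported_at = a$imported_at[i],
                                      source = a$source[i],
                                      seq = as.integer(a$seq[i]))
      hist[[a$name[i]]] <- ent
      assign(a$variant[i], hist, envir = store$attrs)
    }
  }
  o <- payload$observations
  if (is.data.frame(o) && nrow(o)) {
    for (i in seq_len(nrow(o))) {
      per_var <- if (exists(o$variant[i], envir = store$obs,
                            inherits = FALSE)) {
        get(o$variant[i], envir = store$obs)
      } else {
        list()
      }
      per_sample <- per_var[[o$sample[i]]] %||% list()
      ent <- per_sample[[o$name[i]]] %||% list()
      ent[[length(ent) + 1L]] <- list(value = o$value[i],
                                      imported_at = o$imported_at[i],
                                      source = o$source[i],
                                      seq = as.integer(o$seq[i]))
      per_sample[[o$name[i]]] <- ent
      per_var[[o$sample[i]]] <- per_sample
      assign(o$variant[i], per_var, envir = store$obs)
    }
  }
  store$dialects <- lapply(payload$dialects, dialect_from_config)
  store$panels <- lapply(payload$panels, function(p) {
    gene_panel(p$name, unlist(p$genes))
  })
  store$virtual_panels <- lapply(payload$virtual_panels, function(p) {
    structure(list(name = p$name, parent = p$parent,
                   genes = sort(unique(toupper(unlist(p$genes))))),
              class = "virtual_panel")
  })
  store$seq <- as.integer(payload$seq)
  store
}

#' Assert store-wide history well-formedness
#'
#' Checks, for every attribute and observation history, that no two
#' consecutive entries hold equal values and that the current value is the
#' last entry, and that every entry carries provenance (source, timestamp).
#'
#' @param store a `variant_store`.
#' @return `TRUE` invisibly; errors if a history is malformed.
#' @export
validate_store <- function(store) {
  check <- function(entries, what) {
    vals <- vapply(entries, `[[`, "", "value")
    if (any(!nzchar(vals))) {
      stop("empty value in history of ", what, call. = FALSE)
    }
    if (length(vals) > 1L && any(vals[-1] == vals[-length(vals)])) {
      stop("consecutive duplicate values in history of ", what,
           call. = FALSE)
    }
    src <- vapply(entries, `[[`, "", "source")
    ts <- vapply(entries, `[[`, "", "imported_at")
    if (any(!nzchar(src)) || any(!nzchar(ts))) {
      stop("missing provenance in history of ", what, call. = FALSE)
    }
  }
  for (id in ls(store$attrs, all.names = TRUE)) {
    hist <- get(id, envir = store$attrs)
    for (nm in names(hist)) check(hist[[nm]], paste0(id, ":", nm))
  }
  for (id in ls(store$obs, all.names = TRUE)) {
    per_var <- get(id, envir = store$obs)
    for (smp in names(per_var)) {
      for (nm in names(per_var[[smp]])) {
        check(per_var[[smp]][[nm]], paste0(id, ":", smp, ":", nm))
      }
    }
  }
  invisible(TRUE)
}
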