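# Declarative descriptions of input-file dialects: which fields map to which
# attributes, which rows to skip, when to stop, and how derived attributes
# (allele frequency from allelic/read depth) are computed.

FILTER_OPERATORS <- c("equals", "not-equals", "in-set", "not-in-set")

#' Define a row filter
#'
#' A single-field predicate used to drop (or keep only) matching data
#' lines, e.g. excluding hotspot-caller reference rows where the genotype
#' subfield GT is "0/0". A filter never matches a record in which its field
#' is absent.
#'
#' @param field subfield or column name the filter inspects.
#' @param operator one of `"equals"`, `"not-equals"`, `"in-set"`,
#'   `"not-in-set"`.
#' @param values a string or set of strings to compare against.
#' @param action `"exclude"` drops matching records; `"include-only"` drops
#'   non-matching records.
#' @return an object of class `row_filter`.
#' @examples
#' row_filter("GT", "equals", "0/0", "exclude")
#' @export
row_filter <- function(field, operator = "equals", values,
                       action = c("exclude", "include-only")) {
  action <- match.arg(action)
  operator <- match.arg(operator, FILTER_OPERATORS)
  field <- as.character(field)
  values <- as.character(values)
  if (length(field) != 1L || !nzchar(field)) {
    stop("row filter: 'field' must be a single non-empty name",
         call. = FALSE)
  }
  if (length(values) < 1L) {
    stop("row filter: at least one comparison value required",
         call. = FALSE)
  }
  structure(list(field = field, operator = operator, values = values,
                 action = action),
            class = "row_filter")
}

# Does the filter's predicate hold for this record? Absent fields never
# match. Used both for drop decisions and for break conditions.
row_filter_matches <- function(filter, record) {
  val <- record[[filter$field]]
  if (is.null(val) || length(val) == 0L || is.na(val)) return(FALSE)
  val <- as.character(val)
  hit <- val %in% filter$values
  switch(filter$operator,
         "equals" = hit,
         "in-set" = hit,
         "not-equals" = !hit,
         "not-in-set" = !hit)
}

#' Evaluate a row filter against a parsed record
#'
#' Pure and total: for every record exactly one of kept/dropped, never an
#' exception. Exclude-action filters drop matching records; include-only
#' filters drop non-matching records. A record lacking the filter's field
#' cannot match, so it survives an exclude filter (and is dropped by an
#' include-only filter).
#'
#' @param filter a [row_filter()].
#' @param record a named list or named character vector of parsed fields.
#' @return `TRUE` if the record is dropped.
#' @export
evaluate_row_filter <- function(filter, record) {
  stopifnot(inherits(filter, "row_filter"))
  match <- row_filter_matches(filter, as.list(record))
  if (filter$action == "exclude") match else !match
}

#' Define a derived sample attribute
#'
#' A ratio-of-subfields attribute scaled to percent, used to reconstruct an
#' allele frequency from allelic depth (AD) and read depth (DP) when a
#' dialect carries no AF subfield: `scale * numerator / denominator`.
#'
#' @param target_attr name of the attribute to create.
#' @param numerator_field FORMAT subfield supplying the numerator (for a
#'   comma-separated per-allele list such as AD, the entry for the record's
#'   alt allele is used).
#' @param denominator_field FORMAT subfield supplying the denominator.
#' @param scale multiplier, 100 for a percentage.
#' @return an object of class `derived_expr`.
#' @export
derived_expr <- function(target_attr, numerator_field, denominator_field,
                         scale = 100) {
  structure(list(target_attr = as.character(target_attr),
                 numerator_field = as.character(numerator_field),
                 denominator_field = as.character(denominator_field),
                 scale = as.numeric(scale)),
            class = "derived_expr")
}

# Pick the value for one alt allele out of a possibly comma-separated
# per-allele FORMAT value. For an R-numbered field like AD ("ref,alt1,..."),
# alt allele j sits at position j + 1; a scalar value is used as-is.
pick_allele_value <- function(raw, alt_index) {
  parts <- strsplit(as.character(raw), ",", fixed = TRUE)[[1]]
  if (length(parts) >= alt_index + 1L) {
    parts[[alt_index + 1L]]
  } else {
    parts[[1L]]
  }
}

#' Evaluate a derived attribute for one record
#'
#' Returns `scale * numerator / denominator`. The result is undefined (and
#' `NA` is returned with a warning) when the denominator is zero or either
#' field is absent or non-numeric; callers then omit the attribute.
#'
#' @param expr a [derived_expr()].
#' @param record named list of the record's FORMAT subfield values.
#' @param alt_index which alt allele this record represents after
#'   multiallelic splitting (1 = first alt).
#' @return numeric value, or `NA_real_` when undefined.
#' @examples
#' e <- derived_expr("allele_frequency", "AD", "DP")
#' evaluate_derived(e, list(AD = "39,13", DP = "52"))  # 25
#' @export
evaluate_derived <- function(expr, record, alt_index = 1L) {
  stopifnot(inherits(expr, "derived_expr"))
  record <- as.list(record)
  num_raw <- record[[expr$numerator_field]]
  den_raw <- record[[expr$denominator_field]]
  if (is.null(num_raw) || is.null(den_raw)) {
    warning("derived attribute '", expr$target_attr,
            "' undefined: field absent", call. = FALSE)
    return(NA_real_)
  }
  num <- suppressWarnings(as.numeric(pick_allele_value(num_raw, alt_index)))
  den <- suppressWarnings(
    as.numeric(strsplit(as.character(den_raw), ",", fixed = TRUE)[[1]][1])
  )
  if (is.na(num) || is.na(den)) {
    warning("derived attribute '", expr$target_attr,
            "' undefined: non-numeric field", call. = FALSE)
    return(NA_real_)
  }
  if (den == 0) {
    warning("derived attribute '", expr$target_attr,
            "' undefined: zero denominator", call. = FALSE)
    return(NA_real_)
  }
  expr$scale * num / den
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    stop("duplicate ", what, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
}

as_named_chr <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  out <- vapply(x, as.character, "")
  names(out) <- names(x)
  out
}

#' Define a VCF dialect
#'
#' A declarative description of how one flavour of VCF maps onto store
#' attributes: which FORMAT subfields become sample attributes, which INFO
#' subfields become variant attributes, derived attributes, an optional row
#' filter, and which INFO subfield resolves the record's gene symbol
#' (required when the dialect is used with virtual-panel filtering).
#'
#' @param name dialect identifier.
#' @param vcf_version declared VCF version string, e.g. `"4.1"`.
#' @param sample_attr_map named character vector, FORMAT subfield ->
#'   attribute name.
#' @param variant_attr_map named character vector, INFO subfield ->
#'   attribute name.
#' @param derived_attrs list of [derived_expr()].
#' @param row_filter optional [row_filter()] applied to each data line.
#' @param gene_symbol_source optional INFO subfield key resolving the gene
#'   symbol.
#' @param virtual_panel_compatible must the dialect support virtual-panel
#'   filtering? If `TRUE`, `gene_symbol_source` is mandatory.
#' @param format_fields FORMAT subfields declared present in the dialect;
#'   derived expressions may only reference these. Defaults to the mapped
#'   FORMAT subfields.
#' @param split_keys INFO subfields whose values are database
#'   cross-reference lists to be split into one `dbxref_<source>` attribute
#'   per source (see [split_dbxref()]). Defaults to a mapped key literally
#'   named `DBXREF`.
#' @return an object of class `vcf_dialect`.
#' @export
vcf_dialect <- function(name, vcf_version = "4.2",
                        sample_attr_map = character(0),
                        variant_attr_map = character(0),
                        derived_attrs = list(),
                        row_filter = NULL,
                        gene_symbol_source = NULL,
                        virtual_panel_compatible = FALSE,
                        format_fields = NULL,
                        split_keys = NULL) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("dialect: 'name' must be a single non-empty identifier",
         call. = FALSE)
  }
  sample_attr_map <- as_named_chr(sample_attr_map)
  variant_attr_map <- as_named_chr(variant_attr_map)
  if (inherits(derived_attrs, "derived_expr")) {
    derived_attrs <- list(derived_attrs)
  }
  if (length(sample_attr_map) + length(variant_attr_map) +
      length(derived_attrs) == 0L) {
    stop("dialect '", name, "': at least one attribute mapping required",
         call. = FALSE)
  }
  if (length(sample_attr_map)) check_unique(names(sample_attr_map),
                                            "FORMAT subfield mapping")
  if (length(variant_attr_map)) check_unique(names(variant_attr_map),
                                             "INFO subfield mapping")
  derived_targets <- vapply(derived_attrs, `[[`, "", "target_attr")
  check_unique(c(unname(sample_attr_map), unname(variant_attr_map),
                 derived_targets), "attribute name")
  if (is.null(format_fields)) format_fields <- names(sample_attr_map)
  format_fields <- unique(as.character(format_fields))
  for (d in derived_attrs) {
    if (!inherits(d, "derived_expr")) {
      stop("dialect '", name, "': derived_attrs must be derived_expr ",
           "objects", call. = FALSE)
    }
    for (f in c(d$numerator_field, d$denominator_field)) {
      if (!f %in% format_fields) {
        stop("dialect '", name, "': derived attribute '", d$target_attr,
             "' references FORMAT subfield '", f,
             "' not declared in format_fields", call. = FALSE)
      }
    }
  }
  if (!is.null(row_filter) && !inherits(row_filter, "row_filter")) {
    stop("dialect '", name, "': row_filter must be a row_filter object",
         call. = FALSE)
  }
  if (isTRUE(virtual_panel_compatible) && is.null(gene_symbol_source)) {
    stop("dialect '", name, "': virtual-panel compatibility requires ",
         "gene_symbol_source", call. = FALSE)
  }
  if (is.null(split_keys)) {
    split_keys <- intersect("DBXREF", names(variant_attr_map))
  }
  structure(
    list(kind = "vcf", name = name, vcf_version = as.character(vcf_version),
         sample_attr_map = sample_attr_map,
         variant_attr_map = variant_attr_map,
         derived_attrs = derived_attrs, row_filter = row_filter,
         gene_symbol_source = gene_symbol_source,
         virtual_panel_compatible = isTRUE(virtual_panel_compatible),
         format_fields = format_fields,
         split_keys = as.character(split_keys)),
    class = c("vcf_dialect", "dialect_spec")
  )
}

#' Define an annotation-file dialect
#'
#' Describes a tab- or comma-delimited annotation file: how its columns key
#' the variant, which columns become attributes, rows to skip, and an
#' optional break condition at which processing stops.
#'
#' @param name dialect identifier.
#' @param delimiter field delimiter, `"\t"` or `","`.
#' @param key_columns either four column names yielding chrom, pos, ref,
#'   alt (in that order), or one column name holding the combined
#'   `"chrom|pos|ref|alt"` form.
#' @param attr_map named character vector, column name -> attribute name.
#' @param row_filter optional [row_filter()] over column values.
#' @param break_condition optional [row_filter()]; processing stops just
#'   before the first data row its predicate matches.
#' @param header_rows leading rows to skip before the column-name header
#'   line.
#' @return an object of class `annotation_dialect`.
#' @export
annotation_dialect <- function(name, delimiter = "\t", key_columns,
                               attr_map = character(0),
                               row_filter = NULL, break_condition = NULL,
                               header_rows = 0L) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("dialect: 'name' must be a single non-empty identifier",
         call. = FALSE)
  }
  if (!delimiter %in% c("\t", ",")) {
    stop("dialect '", name, "': delimiter must be tab or comma",
         call. = FALSE)
  }
  key_columns <- as.character(key_columns)
  if (!length(key_columns) %in% c(1L, 4L)) {
    stop("dialect '", name, "': key_columns must name four columns ",
         "(chrom, pos, ref, alt) or one combined chrom|pos|ref|alt column",
         call. = FALSE)
  }
  check_unique(key_columns, "key column")
  attr_map <- as_named_chr(attr_map)
  if (length(attr_map)) {
    check_unique(names(attr_map), "annotation column")
    check_unique(unname(attr_map), "attribute name")
  }
  for (f in list(row_filter, break_condition)) {
    if (!is.null(f) && !inherits(f, "row_filter")) {
      stop("dialect '", name, "': filters must be row_filter objects",
           call. = FALSE)
    }
  }
  header_rows <- as.integer(header_rows)
  if (is.na(header_rows) || header_rows < 0L) {
    stop("dialect '", name, "': header_rows must be a non-negative integer",
         call. = FALSE)
  }
  structure(
    list(kind = "annotation", name = name, delimiter = delimiter,
         key_columns = key_columns, attr_map = attr_map,
         row_filter = row_filter, break_condition = break_condition,
         header_rows = header_rows),
    class = c("annotation_dialect", "dialect_spec")
  )
}

#' @export
print.dialect_spec <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$name, "\n", sep = "")
  if (x$kind == "vcf") {
    cat("  VCF version:", x$vcf_version, "\n")
    if (length(x$sample_attr_map)) {
      cat("  sample attrs: ",
          paste(names(x$sample_attr_map), x$sample_attr_map, sep = "->",
                collapse = ", "), "\n", sep = "")
    }
    if (length(x$variant_attr_map)) {
      cat("  variant attrs: ",
          paste(names(x$variant_attr_map), x$variant_attr_map, sep = "->",
                collapse = ", "), "\n", sep = "")
    }
    for (d in x$derived_attrs) {
      cat("  derived: ", d$target_attr, " = ", d$scale, " * ",
          d$numerator_field, "/", d$denominator_field, "\n", sep = "")
    }
  } else {
    cat("  delimiter:", if (x$delimiter == "\t") "tab" else "comma", "\n")
    cat("  key columns:", paste(x$key_columns, collapse = ", "), "\n")
  }
  if (!is.null(x$row_filter)) {
    f <- x$row_filter
    cat("  row filter: ", f$action, " where ", f$field, " ", f$operator,
        " {", paste(f$values, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

# -- config (de)serialization -------------------------------------------------

filter_to_config <- function(f) {
  if (is.null(f)) return(NULL)
  list(field = f$field, operator = f$operator, values = as.list(f$values),
       action = f$action)
}

filter_from_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  row_filter(cfg$field, cfg$operator, unlist(cfg$values), cfg$action)
}

#' Convert a dialect spec to a plain configuration list
#' @param spec a `vcf_dialect` or `annotation_dialect`.
#' @return a plain nested list suitable for YAML/JSON serialization.
#' @export
dialect_to_config <- function(spec) {
  stopifnot(inherits(spec, "dialect_spec"))
  if (spec$kind == "vcf") {
    list(kind = "vcf", name = spec$name, vcf_version = spec$vcf_version,
         sample_attr_map = as.list(spec$sample_attr_map),
         variant_attr_map = as.list(spec$variant_attr_map),
         derived_attrs = lapply(spec$derived_attrs, unclass),
         row_filter = filter_to_config(spec$row_filter),
         gene_symbol_source = spec$gene_symbol_source,
         virtual_panel_compatible = spec$virtual_panel_compatible,
         format_fields = as.list(spec$format_fields),
         split_keys = as.list(spec$split_keys))
  } else {
    list(kind = "annotation", name = spec$name,
         delimiter = if (spec$delimiter == "\t") "tab" else "comma",
         key_columns = as.list(spec$key_columns),
         attr_map = as.list(spec$attr_map),
         row_filter = filter_to_config(spec$row_filter),
         break_condition = filter_to_config(spec$break_condition),
         header_rows = spec$header_rows)
  }
}

unlist_named <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  out <- vapply(x, as.character, "")
  names(out) <- names(x)
  out
}

#' Build a validated dialect spec from a configuration list
#'
#' The inverse of [dialect_to_config()]: a spec validated once revalidates
#' identically after a round trip through the config format.
#'
#' @param cfg a nested list with a `kind` field (`"vcf"` or
#'   `"annotation"`).
#' @return a validated dialect spec.
#' @export
dialect_from_config <- function(cfg) {
  kind <- cfg$kind %||% "vcf"
  # a JSON reader may have simplified the derived-expression list into a
  # data.frame; restore one record per expression
  da <- cfg$derived_attrs
  if (is.data.frame(da)) {
    da <- lapply(seq_len(nrow(da)), function(i) as.list(da[i, ]))
  }
  if (identical(kind, "vcf")) {
    vcf_dialect(
      name = cfg$name, vcf_version = cfg$vcf_version %||% "4.2",
      sample_attr_map = unlist_named(cfg$sample_attr_map),
      variant_attr_map = unlist_named(cfg$variant_attr_map),
      derived_attrs = lapply(da, function(d) {
        derived_expr(d$target_attr, d$numerator_field, d$denominator_field,
                     d$scale %||% 100)
      }),
      row_filter = filter_from_config(cfg$row_filter),
      gene_symbol_source = cfg$gene_symbol_source,
      virtual_panel_compatible = isTRUE(cfg$virtual_panel_compatible),
      format_fields = if (is.null(cfg$format_fields)) NULL else
        unlist(cfg$format_fields),
      split_keys = if (is.null(cfg$split_keys)) NULL else
        unlist(cfg$split_keys)
    )
  } else if (identical(kind, "annotation")) {
    annotation_dialect(
      name = cfg$name,
      delimiter = if (identical(cfg$delimiter, "comma")) "," else "\t",
      key_columns = unlist(cfg$key_columns),
      attr_map = unlist_named(cfg$attr_map),
      row_filter = filter_from_config(cfg$row_filter),
      break_condition = filter_from_config(cfg$break_condition),
      header_rows = cfg$header_rows %||% 0L
    )
  } else {
    stop("unknown dialect kind: ", kind, call. = FALSE)
  }
}

#' Read a dialect definition from a YAML or JSON config file
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return a validated dialect spec.
#' @export
read_dialect <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dialect_from_config(cfg)
}

#' Write a dialect definition to a YAML or JSON config file
#' @param spec a dialect spec.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_dialect <- function(spec, path) {
  cfg <- dialect_to_config(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Built-in dialect presets
#'
#' Two VCF presets emulate the dialects the store is designed around:
#' `"tss-hotspot"`, a hotspot-caller VCF 4.1 with FORMAT GT:AF and a row
#' filter excluding reference rows (GT 0/0); and `"ddm"`, a commercial
#' VCF 4.2 with FORMAT GT:AD:DP (no AF), a derived allele-frequency
#' attribute 100*AD/DP, and INFO subfields SGVEP (gene symbol), DBXREF
#' (database cross-references) and TYPE (mutation type). The
#' `"annotation-tsv"` preset reads tab-delimited annotation files keyed by
#' chrom/pos/ref/alt columns with a ClinVar column.
#'
#' @param name preset name.
#' @return a validated dialect spec.
#' @export
dialect_preset <- function(name = c("tss-hotspot", "ddm",
                                    "annotation-tsv")) {
  name <- match.arg(name)
  switch(name,
    "tss-hotspot" = vcf_dialect(
      name = "tss-hotspot", vcf_version = "4.1",
      sample_attr_map = c(GT = "genotype", AF = "allele_frequency"),
      row_filter = row_filter("GT", "equals", "0/0", "exclude")
    ),
    "ddm" = vcf_dialect(
      name = "ddm", vcf_version = "4.2",
      sample_attr_map = c(GT = "genotype"),
      variant_attr_map = c(SGVEP = "gene", DBXREF = "dbxref",
                           TYPE = "mutation_type"),
      derived_attrs = list(derived_expr("allele_frequency", "AD", "DP")),
      gene_symbol_source = "SGVEP",
      virtual_panel_compatible = TRUE,
      format_fields = c("GT", "AD", "DP")
    ),
    "annotation-tsv" = annotation_dialect(
      name = "annotation-tsv", delimiter = "\t",
      key_columns = c("chrom", "pos", "ref", "alt"),
      attr_map = c(ClinVar = "ClinVar")
    )
  )
}

# -- dialect registry on a store ---------------------------------------------

#' Register a dialect on a store
#' @param store a `variant_store`.
#' @param spec a dialect spec.
#' @param overwrite replace an existing dialect of the same name?
#' @return the spec, invisibly.
#' @export
add_dialect <- function(store, spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "dialect_spec"))
  if (!overwrite && spec$name %in% names(store$dialects)) {
    stop("dialect already defined: ", spec$name, call. = FALSE)
  }
  store$dialects[[spec$name]] <- spec
  invisible(spec)
}

#' Look up a registered dialect by name
#' @param store a `variant_store`.
#' @param name dialect name.
#' @return the dialect spec; error if undefined.
#' @export
get_dialect <- function(store, name) {
  spec <- store$dialects[[name]]
  if (is.null(spec)) stop("undefined dialect: ", name, call. = FALSE)
  spec
}
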