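# Gene panels and virtual panels: the informed-consent filter restricting
# which variants a VCF import may load.

#' Create a gene panel
#'
#' @param name panel identifier.
#' @param genes character vector of gene symbols; uppercased and
#'   deduplicated, must be non-empty.
#' @return an object of class `gene_panel`.
#' @examples
#' gene_panel("BRCA_panel", c("BRCA1", "brca2"))
#' @export
gene_panel <- function(name, genes) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("panel: 'name' must be a single non-empty identifier",
         call. = FALSE)
  }
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    stop("panel '", name, "': gene list must be non-empty", call. = FALSE)
  }
  structure(list(name = name, genes = sort(genes)), class = "gene_panel")
}

#' Create a virtual panel
#'
#' A virtual panel restricts an import to a subset of its parent panel's
#' genes, so only variants complying with the patient's informed consent
#' are loaded. Its gene set must be a subset of the parent's.
#'
#' @param name virtual panel identifier.
#' @param parent the parent [gene_panel()].
#' @param genes gene symbols; normalized as in [gene_panel()].
#' @return an object of class `virtual_panel`.
#' @export
virtual_panel <- function(name, parent, genes) {
  stopifnot(inherits(parent, "gene_panel"))
  vp <- gene_panel(name, genes)
  extra <- setdiff(vp$genes, parent$genes)
  if (length(extra)) {
    stop("virtual panel '", name, "': genes not in parent panel '",
         parent$name, "': ", paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(name = vp$name, parent = parent$name, genes = vp$genes),
            class = "virtual_panel")
}

#' Does a gene symbol pass a virtual panel?
#'
#' Case-folded membership test. A record with no resolvable gene symbol
#' (missing, empty) fails, so it is dropped under an active virtual panel
#' and attributed to the panel filter in the ingest report — the
#' conservative consent interpretation.
#'
#' @param gene_symbol a gene symbol, or `NA`/empty when unresolvable.
#' @param vp a [virtual_panel()] (or [gene_panel()]).
#' @return `TRUE` iff the symbol is resolvable and in the panel's gene set.
#' @export
passes_virtual_panel <- function(gene_symbol, vp) {
  if (is.null(gene_symbol) || length(gene_symbol) != 1L ||
      is.na(gene_symbol)) {
    return(FALSE)
  }
  sym <- toupper(trimws(as.character(gene_symbol)))
  nzchar(sym) && sym %in% vp$genes
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
print.virtual_panel <- function(x, ...) {
  cat("<virtual_panel> ", x$name, " (parent ", x$parent, "): ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene panels from a two-column TSV
#'
#' @param path TSV with columns `panel_name`, `gene_symbol` (header
#'   optional; detected by the literal column names on the first line).
#' @return named list of [gene_panel()] objects.
#' @export
read_panel_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("panel_name", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          colClasses = "character")
  if (!has_header) names(df) <- c("panel_name", "gene_symbol")
  out <- list()
  for (nm in unique(df$panel_name)) {
    out[[nm]] <- gene_panel(nm, df$gene_symbol[df$panel_name == nm])
  }
  out
}

#' Register a panel on a store
#' @param store a `variant_store`.
#' @param panel a [gene_panel()].
#' @return the panel, invisibly; error on duplicate name.
#' @export
add_panel <- function(store, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (panel$name %in% names(store$panels)) {
    stop("panel already defined: ", panel$name, call. = FALSE)
  }
  store$panels[[panel$name]] <- panel
  invisible(panel)
}

#' Register a virtual panel on a store
#' @param store a `variant_store`.
#' @param vp a [virtual_panel()].
#' @return the virtual panel, invisibly; error on duplicate name or
#'   unknown parent.
#' @export
add_virtual_panel <- function(store, vp) {
  stopifnot(inherits(vp, "virtual_panel"))
  if (vp$name %in% names(store$virtual_panels)) {
    stop("virtual panel already defined: ", vp$name, call. = FALSE)
  }
  if (!vp$parent %in% names(store$panels)) {
    stop("virtual panel '", vp$name, "': unknown parent panel '",
         vp$parent, "'", call. = FALSE)
  }
  store$virtual_panels[[vp$name]] <- vp
  invisible(vp)
}

#' Look up a registered panel / virtual panel
#' @param store a `variant_store`.
#' @param name panel name.
#' @return the panel; error if undefined.
#' @export
get_panel <- function(store, name) {
  p <- store$panels[[name]]
  if (is.null(p)) stop("undefined panel: ", name, call. = FALSE)
  p
}

#' @rdname get_panel
#' @export
get_virtual_panel <- function(store, name) {
  p <- store$virtual_panels[[name]]
  if (is.null(p)) stop("undefined virtual panel: ", name, call. = FALSE)
  p
}
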