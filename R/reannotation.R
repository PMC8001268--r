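# Export of all unique variants as chunked minimal VCF files inside a ZIP
# archive, for annotation by external pipelines; re-import closes the loop
# through the annotation ingester.

#' Number of chunks needed
#' @param n number of records (>= 0).
#' @param chunk_size records per chunk (>= 1).
#' @return `ceiling(n / chunk_size)` as an integer.
#' @examples
#' chunk_count(22569, 10000)  # 3
#' @export
chunk_count <- function(n, chunk_size) {
  n <- as.integer(n)
  chunk_size <- as.integer(chunk_size)
  if (is.na(n) || n < 0L) stop("n must be >= 0", call. = FALSE)
  if (is.na(chunk_size) || chunk_size < 1L) {
    stop("chunk_size must be >= 1", call. = FALSE)
  }
  as.integer(ceiling(n / chunk_size))
}

minimal_vcf_lines <- function(ids) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varledger re-annotation export",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (length(ids) == 0L) return(header)
  parts <- do.call(rbind, strsplit(ids, "|", fixed = TRUE))
  c(header,
    paste(parts[, 1], parts[, 2], ".", parts[, 3], parts[, 4], ".", ".",
          ".", sep = "\t"))
}

#' Export all unique variants for re-annotation
#'
#' Writes every distinct variant in the store, sorted canonically
#' (chr1..chr22, chrX, chrY, chrM, then others; then position, ref, alt),
#' as minimal site-only VCF 4.2 files of at most `chunk_size` records
#' each, named `reannotation_0001.vcf`, ... inside a single ZIP archive.
#' An empty store yields a valid empty archive. The export carries no
#' annotations — the downstream annotator recomputes everything — and no
#' genotype columns.
#'
#' @param store a `variant_store`.
#' @param path output `.zip` path.
#' @param chunk_size maximum records per VCF file (default 10000).
#' @return list with `path`, `files` (entry names), `n_variants`, and
#'   `records_per_file`; invisibly.
#' @export
export_unique_variants <- function(store, path, chunk_size = 10000L) {
  stopifnot(inherits(store, "variant_store"))
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) {
    stop("chunk_size must be >= 1", call. = FALSE)
  }
  ids <- variant_ids(store)
  n <- length(ids)
  n_files <- chunk_count(n, chunk_size)
  entries <- list()
  sizes <- integer(0)
  for (f in seq_len(n_files)) {
    lo <- (f - 1L) * chunk_size + 1L
    hi <- min(f * chunk_size, n)
    nm <- sprintf("reannotation_%04d.vcf", f)
    entries[[nm]] <- minimal_vcf_lines(ids[lo:hi])
    sizes[nm] <- hi - lo + 1L
  }
  zip_write(path, entries)
  invisible(list(path = path, files = names(entries), n_variants = n,
                 records_per_file = sizes))
}
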