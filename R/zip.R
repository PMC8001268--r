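# Minimal ZIP archive writer (deflate entries), sufficient for packaging
# the chunked re-annotation VCFs. Deflate streams come from the zlib
# output of memCompress() with its 2-byte header and 4-byte Adler-32
# trailer stripped; the CRC-32 required by the ZIP format is computed with
# a table-driven implementation. Archives are deterministic: fixed entry
# timestamps, entries in the order given.

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$table)) {
    tb <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) == 1L) {
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # polynomial 0xEDB88320
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tb[n + 1L] <- c
    }
    crc32_env$table <- tb
  }
  crc32_env$table
}

crc32 <- function(raw) {
  tb <- crc32_table()
  crc <- -1L
  b <- as.integer(raw)
  for (i in seq_along(b)) {
    crc <- bitwXor(tb[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int_le <- function(x, nbytes) {
  as.raw(vapply(0:(nbytes - 1L),
                function(k) bitwAnd(bitwShiftR(as.integer(x), 8L * k), 255L),
                integer(1)))
}

deflate <- function(raw) {
  zl <- memCompress(raw, type = "gzip")  # zlib-wrapped deflate stream
  zl[3:(length(zl) - 4L)]
}

# Fixed DOS date/time (2021-01-01 00:00:00) for byte-reproducible archives.
ZIP_DOS_TIME <- 0L
ZIP_DOS_DATE <- 21025L

#' Write a ZIP archive
#'
#' Writes the named entries (character vectors of lines, or raw vectors)
#' as deflate-compressed members of a single ZIP file. Entry timestamps
#' are fixed so identical content yields identical archives. An empty
#' entry list produces a valid empty archive.
#'
#' @param path output `.zip` path.
#' @param entries named list; each element a character vector (joined with
#'   newlines, trailing newline added) or a raw vector.
#' @return `path`, invisibly.
#' @export
zip_write <- function(path, entries = list()) {
  stopifnot(is.list(entries))
  if (length(entries) && is.null(names(entries))) {
    stop("zip entries must be named", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- list()
  offset <- 0L
  for (nm in names(entries)) {
    content <- entries[[nm]]
    if (is.character(content)) {
      content <- charToRaw(paste0(paste(content, collapse = "\n"), "\n"))
    }
    stopifnot(is.raw(content))
    comp <- deflate(content)
    crc <- crc32(content)
    name_raw <- charToRaw(nm)
    local_header <- c(
      int_le(67324752L, 4),          # local file header signature
      int_le(20L, 2), int_le(0L, 2), # version needed, flags
      int_le(8L, 2),                 # method: deflate
      int_le(ZIP_DOS_TIME, 2), int_le(ZIP_DOS_DATE, 2),
      int_le(crc, 4),
      int_le(length(comp), 4), int_le(length(content), 4),
      int_le(length(name_raw), 2), int_le(0L, 2)
    )
    writeBin(c(local_header, name_raw, comp), con)
    central[[nm]] <- c(
      int_le(33639248L, 4),          # central directory signature
      int_le(20L, 2), int_le(20L, 2), int_le(0L, 2),
      int_le(8L, 2),
      int_le(ZIP_DOS_TIME, 2), int_le(ZIP_DOS_DATE, 2),
      int_le(crc, 4),
      int_le(length(comp), 4), int_le(length(content), 4),
      int_le(length(name_raw), 2),
      int_le(0L, 2), int_le(0L, 2), int_le(0L, 2), int_le(0L, 2),
      int_le(0L, 4),
      int_le(offset, 4)
    )
    central[[nm]] <- c(central[[nm]], name_raw)
    offset <- offset + length(local_header) + length(name_raw) +
      length(comp)
  }
  cd_start <- offset
  cd_size <- 0L
  for (nm in names(central)) {
    writeBin(central[[nm]], con)
    cd_size <- cd_size + length(central[[nm]])
  }
  eocd <- c(
    int_le(101010256L, 4), int_le(0L, 2), int_le(0L, 2),
    int_le(length(entries), 2), int_le(length(entries), 2),
    int_le(cd_size, 4), int_le(cd_start, 4), int_le(0L, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}
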