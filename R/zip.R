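# Self-contained ZIP writer (store method, no compression) used for the
# results bundle, so no external archiver is required. Archives unpack
# with any standard unzip (including utils::unzip). Timestamps are fixed
# at the DOS epoch for reproducibility.

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    poly <- -306674912L  # 0xEDB88320 as signed 32-bit
    tab <- integer(256L)
    for (nn in 0:255) {
      c <- as.integer(nn)
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), poly)
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tab[nn + 1L] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32_bytes <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  ints <- as.integer(bytes)
  for (b in ints) {
    c <- bitwXor(bitwShiftR(c, 8L),
                 tab[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

w4 <- function(con, v) writeBin(as.integer(v), con, size = 4L,
                                endian = "little")
w2 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                endian = "little")

#' Pack files into a ZIP archive (store method)
#'
#' Writes an uncompressed, fully deterministic ZIP archive containing the
#' given files. Entry names are the paths relative to `root`.
#'
#' @param zipfile Output archive path.
#' @param files Files to include (paths under `root`).
#' @param root Directory the entry names are made relative to.
#' @return `zipfile`, invisibly.
#' @export
zip_bundle <- function(zipfile, files, root = dirname(zipfile)) {
  con <- file(zipfile, open = "wb")
  on.exit(close(con))
  root_norm <- normalizePath(root)
  entries <- list()
  offset <- 0L
  for (f in files) {
    data <- readBin(f, what = "raw", n = file.info(f)$size)
    name <- sub("^/", "", sub(normalizePath(f), pattern = root_norm,
                              replacement = "", fixed = TRUE))
    nameb <- charToRaw(name)
    crc <- crc32_bytes(data)
    sz <- length(data)
    # local file header
    w4(con, 0x04034b50L); w2(con, 20L); w2(con, 0L); w2(con, 0L)
    w2(con, 0L); w2(con, 0x21L)  # time 00:00:00, date 1980-01-01
    w4(con, crc); w4(con, sz); w4(con, sz)
    w2(con, length(nameb)); w2(con, 0L)
    writeBin(nameb, con)
    writeBin(data, con)
    entries[[length(entries) + 1L]] <-
      list(name = nameb, crc = crc, size = sz, offset = offset)
    offset <- offset + 30L + length(nameb) + sz
  }
  cd_offset <- offset
  cd_size <- 0L
  for (e in entries) {
    w4(con, 0x02014b50L); w2(con, 20L); w2(con, 20L); w2(con, 0L)
    w2(con, 0L); w2(con, 0L); w2(con, 0x21L)
    w4(con, e$crc); w4(con, e$size); w4(con, e$size)
    w2(con, length(e$name)); w2(con, 0L); w2(con, 0L)
    w2(con, 0L); w2(con, 0L); w4(con, 0L); w4(con, e$offset)
    writeBin(e$name, con)
    cd_size <- cd_size + 46L + length(e$name)
  }
  w4(con, 0x06054b50L); w2(con, 0L); w2(con, 0L)
  w2(con, length(entries)); w2(con, length(entries))
  w4(con, cd_size); w4(con, cd_offset); w2(con, 0L)
  invisible(zipfile)
}
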