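# ViennaRNA-dialect PostScript dot plots: data lines "i j v ubox" where v
# is sqrt(P(i,j)), plus an embedded "/sequence { (...) } def" record.
# "lbox" lines (single-structure entries) are ignored with a warning.

EXPORT_EPS <- 1e-7  # probabilities below this are dropped from exports

#' Read a base-pair probability matrix from a PostScript dot plot
#'
#' Parses the ViennaRNA dot-plot dialect: the sequence is taken from the
#' embedded `/sequence` record and every `i j v ubox` data line
#' contributes `P(i, j) = v^2` (the file stores square roots of
#' probabilities). Entries absent from the file are 0; the matrix is
#' symmetrized. `lbox` entries are ignored with a warning.
#'
#' @param path Dot-plot file.
#' @return A `bp_matrix` (mode `"imported"`) with the sequence attached
#'   as attribute `"sequence"`.
#' @export
read_ps_dotplot <- function(path) {
  if (!file.exists(path)) snv_stop("dot-plot file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # sequence record: "/sequence { (\" then backslash-continued lines
  start <- grep("/sequence", lines, fixed = TRUE)
  if (length(start) == 0L) {
    snv_stop("no /sequence record in dot-plot file ", path)
  }
  seq_chars <- character(0L)
  k <- start[[1L]]
  repeat {
    cur <- if (k == start[[1L]]) sub(".*\\(", "", lines[[k]]) else lines[[k]]
    frag <- gsub("[[:space:]]", "", gsub("[\\\\)}].*$", "", cur))
    seq_chars <- c(seq_chars, frag)
    if (grepl(")", cur, fixed = TRUE)) break
    k <- k + 1L
    if (k > length(lines)) snv_stop("unterminated sequence record in ", path)
  }
  residues <- paste(seq_chars, collapse = "")
  if (nchar(residues) == 0L) snv_stop("empty sequence record in ", path)
  seq <- validate_sequence(residues,
                           id = tools::file_path_sans_ext(basename(path)))
  n <- seq$n
  P <- matrix(0, n, n)
  data_re <- "^[[:space:]]*([0-9]+)[[:space:]]+([0-9]+)[[:space:]]+([0-9.eE+-]+)[[:space:]]+(ubox|lbox)[[:space:]]*$"
  hits <- grep(data_re, lines)
  n_lbox <- 0L
  for (ln in hits) {
    m <- regmatches(lines[[ln]], regexec(data_re, lines[[ln]]))[[1L]]
    if (m[[5L]] == "lbox") {
      n_lbox <- n_lbox + 1L
      next
    }
    i <- as.integer(m[[2L]]); j <- as.integer(m[[3L]])
    v <- as.numeric(m[[4L]])
    if (is.na(v) || v < 0 || v > 1) {
      snv_stop("line ", ln, " of ", path, ": sqrt-probability ", m[[4L]],
               " outside [0, 1]")
    }
    if (i < 1L || j < 1L || i > n || j > n) {
      snv_stop("line ", ln, " of ", path, ": index outside sequence length ",
               n)
    }
    P[i, j] <- v^2
    P[j, i] <- v^2
  }
  if (n_lbox > 0L) {
    warning(n_lbox, " lbox (single-structure) entries in '", path,
            "' ignored; only ensemble ubox entries are used", call. = FALSE)
  }
  bp <- new_bp_matrix(P, folding_params(window = n, max_span = n),
                      model_id = "imported", mode = "imported")
  attr(bp, "sequence") <- seq
  bp
}

#' Write a base-pair probability matrix as a PostScript dot plot
#'
#' Emits a minimal file in the ViennaRNA dot-plot dialect (readable by
#' [read_ps_dotplot()] and by standard dot-plot consumers): square roots
#' of probabilities as `i j v ubox` lines, with the sequence embedded.
#' Entries below 1e-7 are omitted to bound file size.
#'
#' @param matrix A `bp_matrix` (or plain probability matrix).
#' @param seq The corresponding `rna_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ps_dotplot <- function(matrix, seq, path) {
  P <- as_matrix_values(matrix)
  stopifnot(inherits(seq, "rna_sequence"))
  if (nrow(P) != seq$n) snv_stop("matrix size and sequence length differ")
  n <- seq$n
  header <- c(
    "%!PS-Adobe-3.0 EPSF-3.0",
    "%%Creator: snvfold",
    "%%Title: RNA Dot Plot",
    "%%EndComments",
    "% This file contains the square roots of probabilities in the form",
    "% i  j  sqrt(p(i,j)) ubox",
    "/DPdict 100 dict def",
    "DPdict begin",
    "/sequence { (\\",
    paste0(seq$residues, "\\"),
    ") } def",
    "/len { sequence length } bind def",
    "%data starts here"
  )
  rows <- character(0L)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (P[i, j] >= EXPORT_EPS) {
        rows <- c(rows, sprintf("%d %d %.9f ubox", i, j, sqrt(P[i, j])))
      }
    }
  }
  writeLines(c(header, rows, "showpage", "end", "%%EOF"), path)
  invisible(path)
}
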