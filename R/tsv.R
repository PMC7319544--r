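# Long-format TSV exports. Header comment lines (leading '#') document
# the sign conventions so the files are self-describing.

#' Write the differential TSV tables (and impact JSON) of a run
#'
#' Produces `pairs.tsv` (columns i, j, p_wt, p_mut, delta; one row per
#' pair with any value above the export threshold 1e-7),
#' `accessibility.tsv` (pos, pu_wt, pu_mut, acc_delta) and, when a report
#' is given, `impact.json`.
#'
#' @param diff A `diff_result` from [structure_diff()].
#' @param wt_acc,mut_acc `accessibility_profile` objects.
#' @param report Optional `impact_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_tsv_outputs <- function(diff, wt_acc, mut_acc, report = NULL, dir) {
  stopifnot(inherits(diff, "diff_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- diff$n
  up <- which(upper.tri(diff$combined), arr.ind = TRUE)
  p_wt <- diff$combined[up]
  p_mut <- diff$combined[cbind(up[, 2L], up[, 1L])]
  p_wt[p_wt < EXPORT_EPS] <- 0
  p_mut[p_mut < EXPORT_EPS] <- 0
  delta <- p_mut - p_wt
  keep <- p_wt != 0 | p_mut != 0 | delta != 0
  pair_tab <- data.frame(i = up[keep, 1L], j = up[keep, 2L],
                         p_wt = p_wt[keep], p_mut = p_mut[keep],
                         delta = delta[keep])
  pair_tab <- pair_tab[order(pair_tab$i, pair_tab$j), , drop = FALSE]
  pair_path <- file.path(dir, "pairs.tsv")
  pair_hdr <- c(
    "# base-pair probabilities of the wildtype and mutant ensembles",
    "# delta = p_mut - p_wt: positive = pair strengthened by the mutation",
    paste0("# n = ", n, "; entries below 1e-7 stored as 0")
  )
  write_tsv_file(pair_tab, pair_path, pair_hdr)

  acc_path <- file.path(dir, "accessibility.tsv")
  acc_tab <- data.frame(pos = seq_len(n),
                        pu_wt = zap_eps(wt_acc$pu),
                        pu_mut = zap_eps(mut_acc$pu),
                        acc_delta = diff$acc_delta)
  acc_hdr <- c(
    "# position-wise unpaired probabilities (accessibility)",
    "# acc_delta = pu_wt - pu_mut: negative = more accessible in the mutant"
  )
  write_tsv_file(acc_tab, acc_path, acc_hdr)

  files <- c(pair_path, acc_path)
  if (!is.null(report)) {
    json_path <- file.path(dir, "impact.json")
    impact_report_json(report, json_path)
    files <- c(files, json_path)
  }
  files
}

zap_eps <- function(v) {
  v[v < EXPORT_EPS] <- 0
  v
}

write_tsv_file <- function(tab, path, header_comments) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header_comments, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a pairs.tsv file back into matrices
#' @param path File written by [write_tsv_outputs()].
#' @param n Sequence length (matrix dimension).
#' @return List with matrices `p_wt`, `p_mut`, `delta`.
#' @export
read_pair_table <- function(path, n) {
  tab <- utils::read.delim(path, comment.char = "#")
  mk <- function(col) {
    M <- matrix(0, n, n)
    M[cbind(tab$i, tab$j)] <- tab[[col]]
    M + t(M)
  }
  list(p_wt = mk("p_wt"), p_mut = mk("p_mut"),
       delta = { D <- matrix(0, n, n)
                 D[cbind(tab$i, tab$j)] <- tab$delta
                 D + t(D) })
}

#' Read an accessibility.tsv file
#' @param path File written by [write_tsv_outputs()].
#' @return Data frame with columns pos, pu_wt, pu_mut, acc_delta.
#' @export
read_accessibility_table <- function(path) {
  utils::read.delim(path, comment.char = "#")
}
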