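# Restricted fold: only pairs canonical under BOTH residue vectors are
# legal. Energies come from `chars`; the mask encodes the common
# structure space.
common_legal_mask <- function(chars_a, chars_b) {
  n <- length(chars_a)
  legal <- matrix(FALSE, n, n)
  if (n >= MIN_HAIRPIN + 2L) {
    for (i in seq_len(n - MIN_HAIRPIN - 1L)) {
      for (j in seq.int(i + MIN_HAIRPIN + 1L, n)) {
        legal[i, j] <- is_canonical(chars_a[i], chars_a[j]) &&
          is_canonical(chars_b[i], chars_b[j])
      }
    }
  }
  legal
}

#' Ensemble relative entropy between wildtype and mutant
#'
#' Kullback-Leibler divergence between the wildtype and mutant Boltzmann
#' distributions, conditioned on the common structure space `S_common`
#' (structures legal for both sequences): with `q_x` the Boltzmann
#' distribution of sequence `x` renormalized over `S_common`,
#' `d_common = sum q_wt log(q_wt / q_mut)` (nats). The strict, full-space
#' relative entropy is infinite whenever the wildtype supports structures
#' the mutant cannot form, so the conditional value is reported together
#' with the coverage of `S_common` under each full ensemble and an
#' `infinite_flag` raised when `coverage_wt < 1`.
#'
#' The divergence is computed without enumeration via
#' `d_common = <E_mut - E_wt>_{q_wt} / RT + log(Z'_mut / Z'_wt)`,
#' where primed partition functions are restricted to jointly legal pairs
#' and the energy expectation decomposes over pair (and, for the stacking
#' model, stack) features using restricted-ensemble feature
#' probabilities.
#'
#' @param wt,mut `rna_sequence` objects of equal length.
#' @param model An `energy_model`.
#' @return Object of class `relative_entropy_result`: `d_common` (nats),
#'   `d_bits`, `coverage_wt`, `coverage_mut`, `infinite_flag`.
#' @examples
#' wt <- validate_sequence("GAAAC", "wt")
#' mut <- apply_mutations(wt, "C5U")
#' ensemble_relative_entropy(wt, mut, energy_model("toy-pairtype"))$d_common
#' @export
ensemble_relative_entropy <- function(wt, mut, model) {
  stopifnot(inherits(wt, "rna_sequence"), inherits(mut, "rna_sequence"))
  if (wt$n != mut$n) snv_stop("sequences differ in length")
  ca <- seq_chars(wt); cb <- seq_chars(mut)
  legal <- common_legal_mask(ca, cb)

  z_wt <- fold_chars(ca, model, need_outside = FALSE)$Z
  z_mut <- fold_chars(cb, model, need_outside = FALSE)$Z
  r_wt <- fold_chars(ca, model, legal = legal, need_outside = TRUE)
  r_mut <- fold_chars(cb, model, legal = legal, need_outside = FALSE)

  n <- wt$n
  # per-pair energy difference over jointly legal pairs
  dE <- 0
  idx <- which(legal, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    p <- r_wt$P[i, j]
    if (p > 0) {
      dE <- dE + p * (pair_type_energy(model, cb[i], cb[j]) -
                        pair_type_energy(model, ca[i], ca[j]))
    }
  }
  if (!is.null(model$stack) && !is.null(r_wt$Pstack)) {
    nz <- which(r_wt$Pstack > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1L]; j <- nz[r, 2L]
      dE <- dE + r_wt$Pstack[i, j] *
        (stack_term_energy(model, cb[i], cb[j], cb[i + 1L], cb[j - 1L]) -
           stack_term_energy(model, ca[i], ca[j], ca[i + 1L], ca[j - 1L]))
    }
  }
  d_common <- dE / model$RT + log(r_mut$Z / r_wt$Z)
  # guard against tiny negative rounding
  if (d_common < 0 && d_common > -1e-12) d_common <- 0
  coverage_wt <- r_wt$Z / z_wt
  coverage_mut <- r_mut$Z / z_mut
  structure(
    list(d_common = d_common,
         d_bits = d_common / log(2),
         coverage_wt = coverage_wt,
         coverage_mut = coverage_mut,
         infinite_flag = coverage_wt < 1 - 1e-12),
    class = "relative_entropy_result"
  )
}

#' @export
print.relative_entropy_result <- function(x, ...) {
  cat("<relative_entropy_result> d_common = ", format(x$d_common, digits = 6),
      " nats; coverage WT ", format(x$coverage_wt, digits = 6),
      ", mutant ", format(x$coverage_mut, digits = 6),
      if (x$infinite_flag) "; strict divergence infinite" else "",
      "\n", sep = "")
  invisible(x)
}

# Upper-triangle values of pairs fully inside [a, b].
window_vec <- function(P, a, b) {
  sub <- P[a:b, a:b, drop = FALSE]
  sub[upper.tri(sub)]
}

# Correlation with the degenerate-variance convention: 1 if either vector
# has zero variance and the vectors are equal, 0 if one has zero variance
# and they differ.
safe_cor <- function(x, y) {
  vx <- stats::var(x) > 0
  vy <- stats::var(y) > 0
  if (!vx || !vy) {
    if (isTRUE(all.equal(x, y, tolerance = 0))) return(1)
    return(0)
  }
  stats::cor(x, y)
}

#' Region scan for the largest local structure change
#'
#' Slides windows of the given lengths over the sequence (stride `step`)
#' and, for each interval, compares the wildtype and mutant pair
#' probabilities of all pairs with both ends inside the interval: the
#' Euclidean distance `d = sqrt(sum (P_wt - P_mut)^2)` and the Pearson
#' correlation `r` of the two flattened upper-triangle vectors. Reports
#' the interval maximizing `d` and the interval minimizing `r`; ties are
#' broken toward the smallest start, then the smallest length.
#'
#' @param wt,mut `bp_matrix` objects with identical folding settings.
#' @param window_lengths Interval lengths in nt (clipped to `n`).
#' @param step Stride between interval starts.
#' @return Object of class `region_scan_result`: `d_max`,
#'   `best_d_interval`, `r_min`, `best_r_interval`, and the full scan
#'   table `scan` (data frame with start, end, length, d, r).
#' @export
region_distance_scan <- function(wt, mut, window_lengths = 50L, step = 5L) {
  check_same_fold(wt, mut)
  n <- wt$n
  window_lengths <- sort(unique(pmin(as.integer(window_lengths), n)))
  if (any(window_lengths < 4L)) {
    snv_stop("scan window length below 4 nt admits no base pair")
  }
  step <- max(1L, as.integer(step))
  rows <- list()
  for (a in seq.int(1L, n, by = step)) {
    for (len in window_lengths) {
      b <- a + len - 1L
      if (b > n) next
      x <- window_vec(wt$P, a, b)
      y <- window_vec(mut$P, a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = b, length = len,
        d = sqrt(sum((x - y)^2)),
        r = safe_cor(x, y)
      )
    }
  }
  if (length(rows) == 0L) snv_stop("no scan interval fits the sequence")
  scan <- do.call(rbind, rows)
  # scan rows are ordered by (start, length); which.max/min return the
  # first maximal/minimal row, implementing the tie-break rule
  bi_d <- which.max(scan$d)
  bi_r <- which.min(scan$r)
  structure(
    list(d_max = scan$d[bi_d],
         best_d_interval = c(scan$start[bi_d], scan$end[bi_d]),
         r_min = scan$r[bi_r],
         best_r_interval = c(scan$start[bi_r], scan$end[bi_r]),
         window_lengths = window_lengths, step = step,
         scan = scan),
    class = "region_scan_result"
  )
}

#' @export
print.region_scan_result <- function(x, ...) {
  cat("<region_scan_result> d_max = ", format(x$d_max, digits = 6),
      " in [", x$best_d_interval[1L], ", ", x$best_d_interval[2L],
      "]; r_min = ", format(x$r_min, digits = 6),
      " in [", x$best_r_interval[1L], ", ", x$best_r_interval[2L], "]\n",
      sep = "")
  invisible(x)
}

# Scan scores of all 3n single-nucleotide substitutions of `wt`, each
# refolded and rescanned with the shared configuration. Deterministic.
mutation_background <- function(wt, model, params = folding_params(),
                                window_lengths = 50L, step = 5L,
                                wt_bp = NULL) {
  stopifnot(inherits(wt, "rna_sequence"))
  if (is.null(wt_bp)) wt_bp <- pair_probabilities_local(wt, model, params)
  chars <- seq_chars(wt)
  bases <- c("A", "C", "G", "U")
  out <- list()
  for (pos in seq_len(wt$n)) {
    for (b in setdiff(bases, chars[pos])) {
      mut_chars <- chars
      mut_chars[pos] <- b
      mut <- validate_sequence(paste(mut_chars, collapse = ""),
                               id = sprintf("%s_%s%d%s", wt$id, chars[pos],
                                            pos, b))
      mut_bp <- pair_probabilities_local(mut, model, params)
      sc <- region_distance_scan(wt_bp, mut_bp,
                                 window_lengths = window_lengths,
                                 step = step)
      out[[length(out) + 1L]] <- data.frame(
        position = pos, wt_base = chars[pos], mut_base = b,
        d = sc$d_max, r = sc$r_min, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Empirical p-value of a scan score against the exhaustive SNV background
#'
#' The background model is the set of scores of all `3n` single-nucleotide
#' substitutions of the wildtype sequence, each obtained by refolding the
#' variant and rescanning with the same configuration. For the distance
#' mode the p-value is `p = (1 + #{background >= observed}) / (1 + 3n)`;
#' for the correlation mode the comparison is `<=` (smaller correlations
#' are more extreme). The `+1` correction keeps `p > 0`.
#'
#' @param observed Observed score (`d_max` or `r_min`).
#' @param wt Wildtype `rna_sequence`.
#' @param model An `energy_model`.
#' @param params A `folding_params`.
#' @param window_lengths,step Scan configuration (must match the one that
#'   produced `observed`).
#' @param mode `"d"` (Euclidean distance) or `"r"` (correlation).
#' @param background Optional precomputed background table from
#'   `mutation_background()` (re-used when scoring several mutations of
#'   the same wildtype).
#' @return List with `p`, `background_size`, `background` (the score
#'   table).
#' @export
empirical_pvalue <- function(observed, wt, model,
                             params = folding_params(),
                             window_lengths = 50L, step = 5L,
                             mode = c("d", "r"), background = NULL) {
  mode <- match.arg(mode)
  if (wt$n < 2L) snv_stop("sequence too short for a mutation background")
  if (is.null(background)) {
    background <- mutation_background(wt, model, params,
                                      window_lengths = window_lengths,
                                      step = step)
  }
  scores <- background[[mode]]
  hits <- if (mode == "d") sum(scores >= observed) else sum(scores <= observed)
  list(p = (1 + hits) / (1 + length(scores)),
       background_size = length(scores),
       background = background)
}

#' Leave-one-out p-value calibration over all point mutations
#'
#' Scores every single-nucleotide substitution of `seq` against the
#' background formed by the other `3n - 1` substitutions (plus the `+1`
#' correction). The refolds are shared, so the whole calibration costs
#' `3n` folds. Under the null that no substitution is special, the
#' p-values are uniform on `{1/(3n+1), ..., 3n/(3n+1)}` up to ties, and
#' the smallest (the most disruptive variant, if its score is uniquely
#' maximal) is `1/(3n+1)`.
#'
#' @inheritParams empirical_pvalue
#' @param seq Wildtype `rna_sequence`.
#' @return Data frame: the background table plus a `p` column.
#' @export
pvalue_calibration <- function(seq, model, params = folding_params(),
                               window_lengths = 50L, step = 5L,
                               mode = c("d", "r")) {
  mode <- match.arg(mode)
  bg <- mutation_background(seq, model, params,
                            window_lengths = window_lengths, step = step)
  scores <- bg[[mode]]
  m <- length(scores)
  bg$p <- vapply(seq_len(m), function(k) {
    others <- scores[-k]
    hits <- if (mode == "d") sum(others >= scores[k]) else
      sum(others <= scores[k])
    (1 + hits) / (1 + m)
  }, numeric(1L))
  bg
}

#' Full impact report for one mutation
#'
#' Runs the ensemble relative entropy and the region scan (with empirical
#' p-values for both the distance and the correlation score) on shared
#' folding results.
#'
#' @param wt Wildtype `rna_sequence`.
#' @param mutation A `mutation_spec` or mutation code string.
#' @param model An `energy_model`.
#' @param params A `folding_params`.
#' @param window_lengths,step Scan configuration.
#' @param pvalues Compute empirical p-values (3n refolds)? Default `TRUE`.
#' @return Object of class `impact_report`.
#' @export
build_impact_report <- function(wt, mutation, model = energy_model("toy-pairtype"),
                                params = folding_params(),
                                window_lengths = 50L, step = 5L,
                                pvalues = TRUE) {
  if (is.character(mutation)) mutation <- parse_mutation_code(mutation)
  mut <- apply_mutations(wt, mutation)
  wt_bp <- pair_probabilities_local(wt, model, params)
  mut_bp <- pair_probabilities_local(mut, model, params)
  relent <- ensemble_relative_entropy(wt, mut, model)
  scan <- region_distance_scan(wt_bp, mut_bp,
                               window_lengths = window_lengths, step = step)
  p_d <- NA_real_; p_r <- NA_real_; bg_size <- NA_integer_
  if (pvalues) {
    bg <- mutation_background(wt, model, params,
                              window_lengths = window_lengths, step = step,
                              wt_bp = wt_bp)
    p_d <- empirical_pvalue(scan$d_max, wt, model, params, window_lengths,
                            step, mode = "d", background = bg)$p
    p_r <- empirical_pvalue(scan$r_min, wt, model, params, window_lengths,
                            step, mode = "r", background = bg)$p
    bg_size <- nrow(bg)
  }
  structure(
    list(mutation = format_mutation_spec(mutation),
         model_id = model$model_id,
         params = list(window = params$window, max_span = params$max_span,
                       u_lengths = params$u_lengths),
         scan_config = list(window_lengths = window_lengths, step = step),
         relent = list(d_common = relent$d_common, d_bits = relent$d_bits,
                       coverage_wt = relent$coverage_wt,
                       coverage_mut = relent$coverage_mut,
                       infinite_flag = relent$infinite_flag),
         scan = list(d_max = scan$d_max,
                     best_d_interval = scan$best_d_interval,
                     r_min = scan$r_min,
                     best_r_interval = scan$best_r_interval,
                     p_d = p_d, p_r = p_r, background_size = bg_size),
         note = paste("relative entropy is conditional on the common",
                      "structure space; scan scheme and exhaustive SNV",
                      "background are native to this package")),
    class = "impact_report"
  )
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report> ", x$mutation, " (model ", x$model_id, ")\n",
      "  d_common = ", format(x$relent$d_common, digits = 6), " nats",
      if (x$relent$infinite_flag) " (strict divergence infinite)" else "",
      "\n  d_max = ", format(x$scan$d_max, digits = 6),
      " in [", x$scan$best_d_interval[1L], ", ",
      x$scan$best_d_interval[2L], "], p_d = ",
      format(x$scan$p_d, digits = 4),
      "\n  r_min = ", format(x$scan$r_min, digits = 6), ", p_r = ",
      format(x$scan$p_r, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Serialize an impact report to JSON
#' @param report An `impact_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
impact_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "impact_report"))
  payload <- unclass(report)
  payload$tool <- list(name = "snvfold",
                       version = as.character(utils::packageVersion("snvfold")))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an impact report back from JSON
#' @param path JSON file written by [impact_report_json()].
#' @return An `impact_report`.
#' @export
read_impact_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  payload$tool <- NULL
  structure(payload, class = "impact_report")
}
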