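check_same_fold <- function(wt, mut) {
  stopifnot(inherits(wt, "bp_matrix"), inherits(mut, "bp_matrix"))
  if (wt$n != mut$n) snv_stop("matrix sizes differ (", wt$n, " vs ", mut$n, ")")
  if (!params_equal(wt$params, mut$params) || !identical(wt$mode, mut$mode)) {
    snv_stop("wildtype and mutant matrices were folded with different ",
             "parameters; differences are only defined for identical settings")
  }
}

#' Base-pair probability difference matrix (mutant minus wildtype)
#'
#' Positive entries mean the mutation increases the pairing potential of
#' `(i, j)`; negative entries mean it weakens the pair. Note the opposite
#' sign convention of [accessibility_delta()].
#'
#' @param wt,mut `bp_matrix` objects folded with identical parameters.
#' @return An `n x n` numeric matrix in `[-1, 1]`.
#' @export
diff_matrix <- function(wt, mut) {
  check_same_fold(wt, mut)
  mut$P - wt$P
}

#' Split a difference matrix into weakened and strengthened parts
#'
#' `weakened = max(0, -delta)` holds probability lost from the wildtype;
#' `strengthened = max(0, delta)` holds probability gained by the mutant.
#' Exactly one of the two is nonzero at any cell and
#' `strengthened - weakened == delta`.
#'
#' @param delta Difference matrix from [diff_matrix()].
#' @return List with `weakened` and `strengthened` matrices.
#' @export
split_weakened_strengthened <- function(delta) {
  weakened <- -delta
  weakened[weakened < 0] <- 0
  strengthened <- delta
  strengthened[strengthened < 0] <- 0
  list(weakened = weakened, strengthened = strengthened)
}

#' Combine wildtype and mutant matrices into a single triangle matrix
#'
#' Entry `(i, j)` with `i < j` holds the wildtype probability; entry
#' `(j, i)` holds the mutant probability; the diagonal is 0. Reading the
#' two triangles back reconstructs both inputs exactly.
#'
#' @param wt,mut `bp_matrix` objects of equal size.
#' @return An `n x n` numeric matrix.
#' @export
combined_triangle_matrix <- function(wt, mut) {
  if (wt$n != mut$n) snv_stop("matrix sizes differ")
  n <- wt$n
  M <- matrix(0, n, n)
  up <- upper.tri(M)
  M[up] <- wt$P[up]
  lo <- lower.tri(M)
  M[lo] <- mut$P[lo]
  M
}

#' Accessibility change (wildtype minus mutant)
#'
#' Follows the convention of differential accessibility tracks: negative
#' values mark positions that are more likely to be unpaired (more
#' accessible) in the mutant than in the wildtype. This is the opposite
#' sign convention of [diff_matrix()]; both are kept deliberately and the
#' plot axes are labelled accordingly.
#'
#' @param wt,mut `accessibility_profile` objects with equal length and u
#'   settings.
#' @return Numeric vector in `[-1, 1]` (the `u = 1` track).
#' @export
accessibility_delta <- function(wt, mut) {
  stopifnot(inherits(wt, "accessibility_profile"),
            inherits(mut, "accessibility_profile"))
  if (wt$n != mut$n) snv_stop("profile lengths differ")
  if (!identical(names(wt$pu_u), names(mut$pu_u))) {
    snv_stop("profiles computed with different u settings")
  }
  wt$pu - mut$pu
}

#' Full differential comparison of wildtype and mutant ensembles
#'
#' Convenience wrapper bundling [diff_matrix()],
#' [split_weakened_strengthened()], [combined_triangle_matrix()] and
#' [accessibility_delta()].
#'
#' @param wt_bp,mut_bp `bp_matrix` objects (identical folding settings).
#' @param wt_acc,mut_acc `accessibility_profile` objects.
#' @return Object of class `diff_result` with fields `delta`, `weakened`,
#'   `strengthened`, `combined`, `acc_delta`, `n`.
#' @export
structure_diff <- function(wt_bp, mut_bp, wt_acc, mut_acc) {
  delta <- diff_matrix(wt_bp, mut_bp)
  ws <- split_weakened_strengthened(delta)
  structure(
    list(n = wt_bp$n,
         delta = delta,
         weakened = ws$weakened,
         strengthened = ws$strengthened,
         combined = combined_triangle_matrix(wt_bp, mut_bp),
         acc_delta = accessibility_delta(wt_acc, mut_acc),
         params = wt_bp$params,
         model_id = wt_bp$model_id),
    class = "diff_result"
  )
}
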