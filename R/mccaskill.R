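#' Folding parameters
#'
#' `window` (W) is the local folding window length in nt; `max_span` (L)
#' caps the pair span `j - i + 1`; `u_lengths` are the stretch lengths for
#' which stretch-unpaired probabilities are computed. `W >= n` means
#' global folding (a single window). The shipped presets are
#' `preset = "global"` (W = L = n, resolved at fold time) and
#' `preset = "local"` (W = 200, L = 150, typical local-folding practice).
#'
#' @param window Window size W in nt, or `NA` for global.
#' @param max_span Maximum pair span L in nt (`NA`: equal to `window`).
#' @param u_lengths Integer vector of stretch lengths (default 1).
#' @param preset Optional `"global"` or `"local"`, overriding
#'   `window`/`max_span`.
#' @return An object of class `folding_params`.
#' @export
folding_params <- function(window = NA, max_span = NA, u_lengths = 1L,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("global", "local"))
    if (preset == "global") {
      window <- NA; max_span <- NA
    } else {
      window <- 200L; max_span <- 150L
    }
  }
  u_lengths <- sort(unique(as.integer(u_lengths)))
  if (any(u_lengths < 1L)) snv_stop("u_lengths must be >= 1")
  if (!is.na(window) && window < 1L) snv_stop("window must be >= 1")
  if (!is.na(window) && !is.na(max_span) && max_span > window) {
    snv_stop("max_span (L) must not exceed window (W)")
  }
  if (!is.na(max_span) && max_span < 1L) snv_stop("max_span must be >= 1")
  structure(
    list(window = if (is.na(window)) NA_integer_ else as.integer(window),
         max_span = if (is.na(max_span)) NA_integer_ else as.integer(max_span),
         u_lengths = u_lengths),
    class = "folding_params"
  )
}

# Resolve NA window/span against a concrete sequence length.
resolve_params <- function(params, n) {
  W <- if (is.na(params$window)) n else min(params$window, n)
  L <- if (is.na(params$max_span)) W else min(params$max_span, W)
  list(W = W, L = L, u_lengths = params$u_lengths)
}

params_equal <- function(a, b) {
  identical(a$window, b$window) && identical(a$max_span, b$max_span) &&
    identical(a$u_lengths, b$u_lengths)
}

# ---- engine internals -------------------------------------------------

# Boltzmann pair-weight matrix B (upper triangle) and stack-weight matrix S.
# B[i,j] = exp(-E_pair(i,j)/RT) for legal pairs, 0 otherwise. `legal` is an
# optional extra n x n logical mask (joint-canonicity restriction);
# `blocked` an optional logical vector of positions barred from pairing.
pair_weights <- function(chars, model, max_span = Inf, legal = NULL,
                         blocked = NULL) {
  n <- length(chars)
  B <- matrix(0, n, n)
  S <- matrix(1, n, n)
  if (n >= MIN_HAIRPIN + 2L) {
    for (i in seq_len(n - MIN_HAIRPIN - 1L)) {
      for (j in seq.int(i + MIN_HAIRPIN + 1L, n)) {
        if (j - i + 1L > max_span) break
        if (!is_canonical(chars[i], chars[j])) next
        if (!is.null(legal) && !legal[i, j]) next
        if (!is.null(blocked) && (blocked[i] || blocked[j])) next
        B[i, j] <- exp(-pair_type_energy(model, chars[i], chars[j]) / model$RT)
      }
    }
  }
  if (!is.null(model$stack)) {
    for (i in seq_len(max(0L, n - MIN_HAIRPIN - 2L))) {
      for (j in seq.int(min(i + MIN_HAIRPIN + 2L, n), n)) {
        if (B[i, j] > 0 && B[i + 1L, j - 1L] > 0) {
          S[i, j] <- exp(-stack_term_energy(model, chars[i], chars[j],
                                            chars[i + 1L], chars[j - 1L]) /
                           model$RT)
        }
      }
    }
  }
  list(B = B, S = S, n = n)
}

# Inside recursion. Q[i,j]: partition function over [i,j] (empty interval
# = 1, handled by qv). Qb[i,j]: restricted to structures where (i,j) pair.
# Under the stacking model Qb separates the stacked and unstacked inner
# continuation: Qb(i,j) = B(i,j) * (S(i,j) Qb(i+1,j-1)
#                                   + Q(i+1,j-1) - Qb(i+1,j-1)).
inside_dp <- function(w) {
  n <- w$n; B <- w$B; S <- w$S
  Q <- matrix(1, n, n)
  Qb <- matrix(0, n, n)
  qv <- function(i, j) if (j < i) 1 else Q[i, j]
  for (d in seq_len(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (B[i, j] > 0) {
        inner_all <- qv(i + 1L, j - 1L)
        inner_qb <- if (j - 1L >= i + 1L) Qb[i + 1L, j - 1L] else 0
        Qb[i, j] <- B[i, j] *
          (S[i, j] * inner_qb + (inner_all - inner_qb))
      }
      acc <- qv(i, j - 1L)
      if (j - MIN_HAIRPIN - 1L >= i) {
        ks <- i:(j - MIN_HAIRPIN - 1L)
        qb_col <- Qb[ks, j]
        nz <- which(qb_col > 0)
        if (length(nz) > 0L) {
          kk <- ks[nz]
          left <- ifelse(kk - 1L < i, 1, Q[i, pmax(kk - 1L, i)])
          acc <- acc + sum(left * qb_col[nz])
        }
      }
      Q[i, j] <- acc
    }
  }
  if (!is.finite(Q[1L, n])) {
    snv_stop("partition function overflow; sequence too long for ",
             "direct Boltzmann weighting under this model")
  }
  list(Q = Q, Qb = Qb, Z = Q[1L, n])
}

# Outside recursion; returns pair probabilities and (stacking model) the
# probability that (i,j) and (i+1,j-1) are simultaneously paired.
# Qout[i,j] sums the Boltzmann weight of everything outside pair (i,j):
# either (i,j) is exterior, or it is immediately enclosed by a pair (k,l)
# (k < i, l > j), with the two gap intervals folding independently (a gap-
# spanning pair would itself be a closer enclosure and is counted there).
outside_dp <- function(w, ins) {
  n <- w$n; B <- w$B; S <- w$S
  Q <- ins$Q; Qb <- ins$Qb; Z <- ins$Z
  Qout <- matrix(0, n, n)
  M <- matrix(0, n, n)  # Qout * B for spans already finished
  qv <- function(i, j) if (j < i) 1 else Q[i, j]
  stacking <- any(S != 1)
  spans <- sort(unique(which(Qb > 0, arr.ind = TRUE)[, 2L] -
                         which(Qb > 0, arr.ind = TRUE)[, 1L]),
                decreasing = TRUE)
  for (d in spans) {
    idx <- which(Qb > 0 & row(Qb) + d == col(Qb), arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      ext <- qv(1L, i - 1L) * qv(j + 1L, n)
      term <- 0
      if (i > 1L && j < n) {
        ks <- seq_len(i - 1L)
        a <- vapply(ks, function(k) qv(k + 1L, i - 1L), numeric(1L))
        ls <- seq.int(j + 1L, n)
        b <- vapply(ls, function(l) qv(j + 1L, l - 1L), numeric(1L))
        Msub <- M[ks, ls, drop = FALSE]
        term <- as.numeric(a %*% Msub %*% b)
        if (stacking && B[i - 1L, j + 1L] > 0) {
          term <- term + M[i - 1L, j + 1L] * (S[i - 1L, j + 1L] - 1)
        }
      }
      Qout[i, j] <- ext + term
    }
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      M[i, j] <- Qout[i, j] * B[i, j]
    }
  }
  P <- Qb * Qout / Z
  P <- P + t(P)
  Pstack <- NULL
  if (!is.null(w$S)) {
    Pstack <- matrix(0, n, n)
    nz <- which(Qb > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1L]; j <- nz[r, 2L]
      if (j - 1L >= i + 1L && Qb[i + 1L, j - 1L] > 0) {
        Pstack[i, j] <- Qout[i, j] * B[i, j] * S[i, j] *
          Qb[i + 1L, j - 1L] / Z
      }
    }
  }
  list(Qout = Qout, P = P, Pstack = Pstack)
}

# Full inside/outside fold of a residue vector.
fold_chars <- function(chars, model, max_span = Inf, legal = NULL,
                       blocked = NULL, need_outside = TRUE) {
  w <- pair_weights(chars, model, max_span = max_span, legal = legal,
                    blocked = blocked)
  ins <- inside_dp(w)
  out <- if (need_outside) outside_dp(w, ins) else NULL
  list(weights = w, inside = ins, outside = out, Z = ins$Z,
       P = if (need_outside) out$P else NULL,
       Pstack = if (need_outside) out$Pstack else NULL)
}

new_bp_matrix <- function(P, params, model_id, mode) {
  structure(
    list(n = nrow(P), P = P, params = params, model_id = model_id,
         mode = mode),
    class = "bp_matrix"
  )
}

#' @export
print.bp_matrix <- function(x, ...) {
  cat("<bp_matrix> ", x$n, " x ", x$n, " (", x$mode, ", model ",
      x$model_id, ")\n", sep = "")
  invisible(x)
}

# ---- public folding operations ---------------------------------------

#' Global base-pair probabilities (McCaskill inside/outside)
#'
#' Computes the exact Boltzmann pair-probability matrix over the full
#' sequence by inside/outside dynamic programming. Agrees with
#' [bruteforce_ensemble()] to numerical precision.
#'
#' @param seq An `rna_sequence`.
#' @param model An `energy_model`.
#' @param max_span Optional span cap L (`j - i + 1 <= L`).
#' @return A `bp_matrix`.
#' @examples
#' s <- validate_sequence("GAAAC", "toy")
#' pair_probabilities_global(s, energy_model("toy-uniform"))$P[1, 5]
#' @export
pair_probabilities_global <- function(seq, model, max_span = Inf) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(model, "energy_model"))
  f <- fold_chars(seq_chars(seq), model, max_span = max_span)
  params <- folding_params(window = seq$n,
                           max_span = if (is.finite(max_span))
                             min(max_span, seq$n) else seq$n)
  new_bp_matrix(f$P, params, model$model_id, mode = "global")
}

#' Probability that a stretch of positions is unpaired
#'
#' Computed as the ratio `Z_constrained / Z`, where the constrained
#' partition function forbids any pair touching positions
#' `i .. i + u - 1`.
#'
#' @param seq An `rna_sequence`.
#' @param model An `energy_model`.
#' @param i 1-based start of the stretch.
#' @param u Stretch length in nt.
#' @param max_span Optional span cap.
#' @return Probability in `[0, 1]`.
#' @export
unpaired_region_probability <- function(seq, model, i, u = 1L,
                                        max_span = Inf) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (i < 1L || u < 1L || i + u - 1L > seq$n) {
    snv_stop("unpaired region [", i, ", ", i + u - 1L,
             "] out of range for length ", seq$n)
  }
  chars <- seq_chars(seq)
  full <- fold_chars(chars, model, max_span = max_span, need_outside = FALSE)
  blocked <- rep(FALSE, seq$n)
  blocked[i:(i + u - 1L)] <- TRUE
  constrained <- fold_chars(chars, model, max_span = max_span,
                            blocked = blocked, need_outside = FALSE)
  constrained$Z / full$Z
}

# Accessibility of every start position for each u, on one residue vector,
# by constrained partition functions (positions barred from pairing).
access_chars <- function(chars, model, u_lengths, max_span = Inf) {
  n <- length(chars)
  full <- fold_chars(chars, model, max_span = max_span, need_outside = FALSE)
  pu_u <- lapply(u_lengths, function(u) {
    if (u > n) return(numeric(0L))
    vapply(seq_len(n - u + 1L), function(i) {
      blocked <- rep(FALSE, n)
      blocked[i:(i + u - 1L)] <- TRUE
      fold_chars(chars, model, max_span = max_span, blocked = blocked,
                 need_outside = FALSE)$Z / full$Z
    }, numeric(1L))
  })
  names(pu_u) <- as.character(u_lengths)
  pu_u
}

#' Accessibility profile (position-wise unpaired probabilities)
#'
#' For each requested stretch length `u`, the probability that positions
#' `i .. i + u - 1` are simultaneously unpaired, for every start `i`.
#' Under global folding (`W >= n`) values are exact constrained-ensemble
#' probabilities; under local folding (`W < n`) each value is the
#' unweighted mean over all length-W windows that fully contain the
#' stretch.
#'
#' @param seq An `rna_sequence`.
#' @param model An `energy_model`.
#' @param params A `folding_params`.
#' @return An object of class `accessibility_profile` with fields `n`,
#'   `pu` (the `u = 1` track, always present), `pu_u` (named list by `u`),
#'   `params`, `model_id`.
#' @export
accessibility_profile <- function(seq, model, params = folding_params()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(params, "folding_params"))
  rp <- resolve_params(params, seq$n)
  u_lengths <- sort(unique(c(1L, rp$u_lengths)))
  if (any(u_lengths > rp$W)) snv_stop("u exceeds the folding window W")
  chars <- seq_chars(seq)
  n <- seq$n
  if (rp$W >= n) {
    pu_u <- access_chars(chars, model, u_lengths, max_span = rp$L)
  } else {
    sums <- lapply(u_lengths, function(u) numeric(max(0L, n - u + 1L)))
    cnts <- lapply(u_lengths, function(u) numeric(max(0L, n - u + 1L)))
    for (a in seq_len(n - rp$W + 1L)) {
      win <- chars[a:(a + rp$W - 1L)]
      loc <- access_chars(win, model, u_lengths, max_span = rp$L)
      for (t in seq_along(u_lengths)) {
        u <- u_lengths[t]
        if (u > rp$W) next
        idx <- seq_len(rp$W - u + 1L)
        gidx <- a + idx - 1L
        sums[[t]][gidx] <- sums[[t]][gidx] + loc[[t]]
        cnts[[t]][gidx] <- cnts[[t]][gidx] + 1
      }
    }
    pu_u <- lapply(seq_along(u_lengths), function(t) {
      v <- sums[[t]]
      v[cnts[[t]] > 0] <- v[cnts[[t]] > 0] / cnts[[t]][cnts[[t]] > 0]
      v
    })
    names(pu_u) <- as.character(u_lengths)
  }
  structure(
    list(n = n, pu = pu_u[["1"]], pu_u = pu_u, params = params,
         model_id = model$model_id),
    class = "accessibility_profile"
  )
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat("<accessibility_profile> n = ", x$n, ", u = {",
      paste(names(x$pu_u), collapse = ", "), "} (model ", x$model_id,
      ")\n", sep = "")
  invisible(x)
}

#' Local (windowed) base-pair probabilities
#'
#' Folds every length-W window of the sequence with pair span capped at L
#' and reports, for each pair `(i, j)`, the unweighted mean of its
#' probability over all windows that fully contain it (pairs near the
#' sequence ends are covered by fewer windows; the divisor is the number
#' of covering windows, not a constant). With `W = L = n` this reduces
#' exactly to [pair_probabilities_global()].
#'
#' @param seq An `rna_sequence`.
#' @param model An `energy_model`.
#' @param params A `folding_params`.
#' @return A `bp_matrix` with mode `"local"` (or `"global"` when
#'   `W >= n`).
#' @export
pair_probabilities_local <- function(seq, model, params = folding_params()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(params, "folding_params"))
  rp <- resolve_params(params, seq$n)
  n <- seq$n
  chars <- seq_chars(seq)
  if (rp$W >= n) {
    f <- fold_chars(chars, model, max_span = rp$L)
    return(new_bp_matrix(f$P, params, model$model_id, mode = "global"))
  }
  sums <- matrix(0, n, n)
  cnts <- matrix(0, n, n)
  for (a in seq_len(n - rp$W + 1L)) {
    idx <- a:(a + rp$W - 1L)
    f <- fold_chars(chars[idx], model, max_span = rp$L)
    sums[idx, idx] <- sums[idx, idx] + f$P
    cnts[idx, idx] <- cnts[idx, idx] + 1
  }
  P <- sums
  P[cnts > 0] <- P[cnts > 0] / cnts[cnts > 0]
  new_bp_matrix(P, params, model$model_id, mode = "local")
}
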