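#' Enumerate all legal secondary structures of a short sequence
#'
#' Exhaustively lists every pseudoknot-free structure over canonical pairs
#' with hairpin loops of at least 3 nt, including the open chain. Intended
#' as a brute-force oracle for the dynamic-programming routines; guarded
#' to sequences of at most `max_n` nucleotides.
#'
#' @param seq An `rna_sequence`.
#' @param max_span Optional maximum pair span `j - i + 1` (defaults to no
#'   cap).
#' @param max_n Length guard (default 25).
#' @return List of structures, each a two-column matrix of pairs (the open
#'   chain is the zero-row matrix). Every legal structure appears exactly
#'   once.
#' @export
enumerate_structures <- function(seq, max_span = Inf, max_n = 25L) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (seq$n > max_n) {
    snv_stop("enumeration guard: length ", seq$n, " exceeds ", max_n)
  }
  chars <- seq_chars(seq)
  n <- seq$n
  can <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i >= MIN_HAIRPIN + 1L && j - i + 1L <= max_span &&
          is_canonical(chars[i], chars[j])) {
        can[i, j] <- TRUE
      }
    }
  }
  memo <- new.env(parent = emptyenv())
  empty <- list(matrix(integer(0L), ncol = 2L))
  rec <- function(i, j) {
    if (j - i < MIN_HAIRPIN + 1L) return(empty)
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # position i unpaired
    out <- rec(i + 1L, j)
    # position i paired with k
    for (k in seq.int(i + MIN_HAIRPIN + 1L, j)) {
      if (!can[i, k]) next
      inner <- rec(i + 1L, k - 1L)
      rest <- if (k < j) rec(k + 1L, j) else empty
      for (a in inner) {
        for (b in rest) {
          out <- c(out, list(rbind(matrix(c(i, k), ncol = 2L), a, b)))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < 2L) return(empty)
  rec(1L, n)
}

#' Brute-force Boltzmann ensemble of a short sequence
#'
#' Enumerates all structures, Boltzmann-weights them with
#' [structure_energy()], and marginalizes exact pair probabilities. The
#' independent oracle against which the inside/outside implementation is
#' validated.
#'
#' @inheritParams enumerate_structures
#' @param model An `energy_model`.
#' @return List with `Z` (partition function), `P` (symmetric pair
#'   probability matrix), `energies`, `weights` and `structures`.
#' @examples
#' s <- validate_sequence("GAAAC", "toy")
#' bruteforce_ensemble(s, energy_model("toy-uniform"))$P[1, 5] # e/(1+e)
#' @export
bruteforce_ensemble <- function(seq, model, max_span = Inf, max_n = 25L) {
  structs <- enumerate_structures(seq, max_span = max_span, max_n = max_n)
  energies <- vapply(structs, function(s) structure_energy(seq, s, model),
                     numeric(1L))
  weights <- exp(-energies / model$RT)
  Z <- sum(weights)
  n <- seq$n
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    if (nrow(s) == 0L) next
    for (r in seq_len(nrow(s))) {
      P[s[r, 1L], s[r, 2L]] <- P[s[r, 1L], s[r, 2L]] + weights[k]
    }
  }
  P <- (P + t(P)) / Z
  list(Z = Z, P = P, energies = energies, weights = weights,
       structures = structs)
}
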