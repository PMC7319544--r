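CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")
MIN_HAIRPIN <- 3L  # minimum unpaired nucleotides enclosed by a pair

#' Is a base combination a canonical pair?
#'
#' Canonical means Watson-Crick (AU, GC) or wobble (GU), in either
#' orientation.
#'
#' @param a,b Residues in `A`, `C`, `G`, `U` (vectorized).
#' @return Logical.
#' @examples
#' is_canonical("G", "U") # TRUE
#' @export
is_canonical <- function(a, b) {
  paste0(a, b) %in% CANONICAL_PAIRS
}

#' Construct one of the shipped energy models
#'
#' Three models are available:
#' \describe{
#'   \item{`toy-uniform`}{-1.0 kcal/mol per base pair, RT = 1.0; admits
#'     closed-form expected values.}
#'   \item{`toy-pairtype`}{per-pair-type energies (GC/CG -3.0, AU/UA -2.0,
#'     GU/UG -1.0 kcal/mol, RT = 1.0); sensitive to which pair forms.}
#'   \item{`stacking`}{nearest-neighbor model: a per-pair baseline plus a
#'     stacking term for each pair of adjacent nested pairs (i,j),
#'     (i+1,j-1), with RT = 0.6163 kcal/mol (37 C). Parameters ship in
#'     `inst/extdata/stacking.params`.}
#' }
#' The structure space is identical under all models: pseudoknot-free,
#' canonical pairs only, hairpin loops of at least 3 nt, lonely pairs
#' allowed. Dangling ends and coaxial stacking are not modelled.
#'
#' @param model_id One of `"toy-uniform"`, `"toy-pairtype"`, `"stacking"`.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(model_id = c("toy-uniform", "toy-pairtype", "stacking")) {
  model_id <- match.arg(model_id)
  if (model_id == "toy-uniform") {
    pair <- stats::setNames(rep(-1.0, 6L), CANONICAL_PAIRS)
    new_energy_model("toy-uniform", RT = 1.0, pair = pair, stack = NULL)
  } else {
    fn <- paste0(model_id, ".params")
    path <- system.file("extdata", fn, package = "snvfold", mustWork = TRUE)
    load_energy_parameters(path)
  }
}

new_energy_model <- function(model_id, RT, pair, stack, source = NA_character_) {
  stopifnot(RT > 0, all(CANONICAL_PAIRS %in% names(pair)))
  structure(
    list(model_id = model_id, RT = RT, pair = pair[CANONICAL_PAIRS],
         stack = stack, source = source),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", x$model_id, " (RT = ", x$RT, " kcal/mol)\n", sep = "")
  invisible(x)
}

stack_keys <- function() {
  as.vector(outer(CANONICAL_PAIRS, CANONICAL_PAIRS,
                  function(a, b) paste(a, b, sep = ".")))
}

#' Load an energy model from a parameter file
#'
#' The file is plain text with `key = value` lines and `#` comments.
#' Required keys: `model`, `RT`; `pair.XY` for each canonical pair type
#' (except `toy-uniform`, where pair energies are fixed at -1.0); for the
#' `stacking` model additionally `stack.XY.ZW` for every ordered
#' combination of outer pair `XY` ((i,j) bases) and inner pair `ZW`
#' ((i+1,j-1) bases). Missing keys, unknown pair types and non-numeric
#' values are rejected.
#'
#' @param path Parameter file path.
#' @return An `energy_model`.
#' @export
load_energy_parameters <- function(path) {
  if (!file.exists(path)) snv_stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) snv_stop("malformed parameter line: '", ln, "'")
    kv[[trimws(parts[[1L]])]] <- trimws(parts[[2L]])
  }
  need <- function(key) {
    if (is.null(kv[[key]])) snv_stop("parameter file ", path,
                                     " is missing key '", key, "'")
    kv[[key]]
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(need(key)))
    if (is.na(v)) snv_stop("non-numeric value for '", key, "' in ", path)
    v
  }
  model_id <- need("model")
  if (!model_id %in% c("toy-uniform", "toy-pairtype", "stacking")) {
    snv_stop("unknown model id '", model_id, "' in ", path)
  }
  RT <- num("RT")
  pair_keys <- grep("^pair\\.", names(kv), value = TRUE)
  unknown <- setdiff(sub("^pair\\.", "", pair_keys), CANONICAL_PAIRS)
  if (length(unknown) > 0L) {
    snv_stop("unknown pair type key 'pair.", unknown[[1L]], "' in ", path)
  }
  if (model_id == "toy-uniform") {
    pair <- stats::setNames(rep(-1.0, 6L), CANONICAL_PAIRS)
  } else {
    missing <- setdiff(CANONICAL_PAIRS, sub("^pair\\.", "", pair_keys))
    if (length(missing) > 0L) {
      snv_stop("parameter file ", path, " is missing keys: ",
               paste0("pair.", missing, collapse = ", "))
    }
    pair <- vapply(CANONICAL_PAIRS, function(p) num(paste0("pair.", p)),
                   numeric(1L))
  }
  stack <- NULL
  if (model_id == "stacking") {
    keys <- stack_keys()
    missing <- keys[!paste0("stack.", keys) %in% names(kv)]
    if (length(missing) > 0L) {
      snv_stop("parameter file ", path, " is missing keys: ",
               paste0("stack.", utils::head(missing, 3L), collapse = ", "),
               if (length(missing) > 3L) " ..." else "")
    }
    stack <- vapply(keys, function(k) num(paste0("stack.", k)), numeric(1L))
  }
  new_energy_model(model_id, RT = RT, pair = pair, stack = stack,
                   source = path)
}

#' Write an energy model to a parameter file
#' @param model An `energy_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_parameters <- function(model, path) {
  stopifnot(inherits(model, "energy_model"))
  lines <- c(
    "# snvfold energy model parameters (kcal/mol)",
    paste0("model = ", model$model_id),
    paste0("RT = ", format(model$RT, digits = 15L))
  )
  if (model$model_id != "toy-uniform") {
    lines <- c(lines, sprintf("pair.%s = %s", names(model$pair),
                              format(model$pair, digits = 15L, trim = TRUE)))
  }
  if (!is.null(model$stack)) {
    lines <- c(lines, sprintf("stack.%s = %s", names(model$stack),
                              format(model$stack, digits = 15L, trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

# Energy of one pair (i,j) of residues a, b under the model. The stacking
# model's per-pair term is its baseline; stack terms are added separately.
pair_type_energy <- function(model, a, b) {
  key <- paste0(a, b)
  if (!key %in% CANONICAL_PAIRS) {
    snv_stop("non-canonical pair ", a, "-", b)
  }
  unname(model$pair[[key]])
}

stack_term_energy <- function(model, outer_a, outer_b, inner_a, inner_b) {
  if (is.null(model$stack)) return(0)
  key <- paste0(outer_a, outer_b, ".", inner_a, inner_b)
  unname(model$stack[[key]])
}

#' Energy of a secondary structure
#'
#' The structure is a set of pairs given as a two-column matrix of 1-based
#' positions `(i, j)`, `i < j`; a zero-row matrix is the open chain, whose
#' energy is exactly 0 under every model. Under the toy models the energy
#' is the sum of per-pair terms; under the stacking model it is the sum of
#' per-pair baselines plus one stack term for each pair of adjacent nested
#' pairs `(i,j)`, `(i+1,j-1)` both present.
#'
#' @param seq An `rna_sequence`.
#' @param pairs Two-column integer matrix of pairs (or `NULL` for the open
#'   chain).
#' @param model An `energy_model`.
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(seq, pairs, model) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(model, "energy_model"))
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0L) return(0)
  chars <- seq_chars(seq)
  if (any(pairs < 1L) || any(pairs > seq$n)) {
    snv_stop("pair index out of range for sequence of length ", seq$n)
  }
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    e <- e + pair_type_energy(model, chars[pairs[k, 1L]], chars[pairs[k, 2L]])
  }
  if (!is.null(model$stack)) {
    key <- paste(pairs[, 1L], pairs[, 2L])
    has <- function(i, j) paste(i, j) %in% key
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (has(i + 1L, j - 1L)) {
        e <- e + stack_term_energy(model, chars[i], chars[j],
                                   chars[i + 1L], chars[j - 1L])
      }
    }
  }
  e
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs)) return(matrix(integer(0L), ncol = 2L))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) as.integer(p)))
    if (is.null(pairs)) return(matrix(integer(0L), ncol = 2L))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L && any(pairs[, 1L] >= pairs[, 2L])) {
    snv_stop("pairs must satisfy i < j")
  }
  pairs
}
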