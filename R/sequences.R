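# Internal condition helpers: data errors get class "snvfold_error" so the
# command-line front end can map them to exit code 1.
snv_stop <- function(..., class = "snvfold_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

#' Validate and normalize an RNA sequence
#'
#' Accepts DNA or RNA input, upper- or lowercase; `T` is mapped to `U` and
#' everything is uppercased. Any character outside `A`, `C`, `G`, `U`
#' (after normalization) is rejected with its position.
#'
#' @param raw Character scalar with the residues. Whitespace is stripped.
#' @param id Label for the sequence.
#' @return An object of class `rna_sequence`: a list with `id`, `residues`
#'   (normalized string) and `n` (length).
#' @examples
#' validate_sequence("gattaca", "x")$residues # "GAUUACA"
#' @export
validate_sequence <- function(raw, id = "seq") {
  stopifnot(is.character(raw), length(raw) == 1L)
  residues <- gsub("[[:space:]]", "", raw)
  if (nchar(residues) == 0L) {
    snv_stop("empty sequence for '", id, "'")
  }
  residues <- toupper(residues)
  residues <- chartr("T", "U", residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    snv_stop(
      "non-nucleotide character '", chars[bad[1L]], "' at position ",
      bad[1L], " in sequence '", id, "'"
    )
  }
  structure(
    list(id = id, residues = residues, n = length(chars)),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60L) res <- paste0(substr(res, 1L, 57L), "...")
  cat("<rna_sequence> ", x$id, " (", x$n, " nt)\n  ", res, "\n", sep = "")
  invisible(x)
}

# Residue vector of an rna_sequence.
seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Read a single-record FASTA file
#'
#' Reads the first record of a FASTA file; additional records are ignored
#' with a warning. A bare sequence file without a `>` header is accepted
#' too, in which case the file name (without extension) becomes the id.
#'
#' @param path Path to the FASTA (or bare-sequence) file.
#' @return An `rna_sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) snv_stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) snv_stop("empty FASTA file: ", path)
  if (startsWith(nonblank[[1L]], ">")) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) > 1L) {
      warning("FASTA file '", path, "' has ", length(set),
              " records; using the first", call. = FALSE)
    }
    validate_sequence(as.character(set[[1L]]), id = names(set)[[1L]])
  } else {
    id <- tools::file_path_sans_ext(basename(path))
    validate_sequence(paste(nonblank, collapse = ""), id = id)
  }
}

#' Write an `rna_sequence` to a FASTA file
#' @param seq An `rna_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path) {
  writeLines(c(paste0(">", seq$id), seq$residues), path)
  invisible(path)
}

#' Parse a mutation code into a mutation specification
#'
#' A mutation code is a `-`-separated list of point substitutions, each of
#' the form `<wt base><1-based position><mutant base>`, e.g. `"G10A"` for a
#' single substitution or `"G10A-C12G"` for a double. Parsing is
#' case-insensitive and `T` is normalized to `U`. Positions must be
#' strictly increasing. Identity edits such as `"A5A"` are legal and are
#' flagged; they give a null differential run.
#'
#' @param code Mutation code string.
#' @return An object of class `mutation_spec`: a data frame of edits with
#'   columns `position`, `wt_base`, `mut_base`, `is_identity`.
#' @examples
#' parse_mutation_code("G10A-C12G")
#' @export
parse_mutation_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- gsub("[[:space:]]", "", code)
  if (nchar(code) == 0L) snv_stop("empty mutation code")
  tokens <- strsplit(code, "-", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    snv_stop("malformed mutation code '", code, "'")
  }
  edits <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok))[[1L]]
    if (length(m) != 4L) {
      snv_stop("malformed mutation token '", tok, "' (expected e.g. G10A)")
    }
    norm <- function(b) chartr("T", "U", toupper(b))
    wt <- norm(m[[2L]]); mu <- norm(m[[4L]])
    pos <- suppressWarnings(as.integer(m[[3L]]))
    for (b in c(wt, mu)) {
      if (!b %in% c("A", "C", "G", "U")) {
        snv_stop("'", b, "' in token '", tok, "' is not a nucleotide")
      }
    }
    if (is.na(pos) || pos <= 0L) {
      snv_stop("position in token '", tok, "' must be a positive integer")
    }
    data.frame(position = pos, wt_base = wt, mut_base = mu,
               is_identity = wt == mu, stringsAsFactors = FALSE)
  })
  edits <- do.call(rbind, edits)
  if (anyDuplicated(edits$position)) {
    snv_stop("duplicate position ", edits$position[duplicated(edits$position)][1L],
             " in mutation code '", code, "'")
  }
  if (is.unsorted(edits$position, strictly = TRUE)) {
    snv_stop("positions in mutation code '", code,
             "' must be strictly increasing")
  }
  structure(list(edits = edits, code = format_edits(edits)),
            class = "mutation_spec")
}

format_edits <- function(edits) {
  paste(sprintf("%s%d%s", edits$wt_base, edits$position, edits$mut_base),
        collapse = "-")
}

#' Render a mutation specification back to its code string
#' @param spec A `mutation_spec`.
#' @return The canonical code string, e.g. `"G10A-C12G"`.
#' @export
format_mutation_spec <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  format_edits(spec$edits)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec> ", format_mutation_spec(x), "\n", sep = "")
  invisible(x)
}

#' Apply a mutation specification to a wildtype sequence
#'
#' Each edit's stated wildtype base is checked against the sequence before
#' substituting; a mismatch or out-of-range position is an error.
#'
#' @param wt Wildtype `rna_sequence`.
#' @param spec A `mutation_spec` or a mutation code string.
#' @return The mutant `rna_sequence` (id gets the code appended).
#' @examples
#' wt <- validate_sequence("GAAAC", "toy")
#' apply_mutations(wt, "C5U")$residues # "GAAAU"
#' @export
apply_mutations <- function(wt, spec) {
  stopifnot(inherits(wt, "rna_sequence"))
  if (is.character(spec)) spec <- parse_mutation_code(spec)
  stopifnot(inherits(spec, "mutation_spec"))
  chars <- seq_chars(wt)
  for (k in seq_len(nrow(spec$edits))) {
    e <- spec$edits[k, ]
    if (e$position > wt$n) {
      snv_stop("mutation position ", e$position, " exceeds sequence length ",
               wt$n)
    }
    if (chars[e$position] != e$wt_base) {
      snv_stop("expected ", e$wt_base, " at position ", e$position,
               ", found ", chars[e$position])
    }
    chars[e$position] <- e$mut_base
  }
  validate_sequence(paste(chars, collapse = ""),
                    id = paste0(wt$id, "_", format_mutation_spec(spec)))
}

#' Generate reproducible fixture sequences with planted structure
#'
#' Draws random sequences and plants a perfect complementary stem of at
#' least 4 base pairs (separated by a hairpin loop of 3 or more
#' nucleotides) so that every fixture has non-trivial ensemble structure.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param count Number of sequences (>= 1).
#' @param length Sequence length in nt (>= 8).
#' @return List of `rna_sequence` objects.
#' @export
make_fixture_sequences <- function(seed, count, length) {
  stopifnot(count >= 1)
  if (length < 8) snv_stop("fixture length must be at least 8 nt")
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  out <- vector("list", count)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  for (k in seq_len(count)) {
    chars <- sample(bases, length, replace = TRUE)
    # stem length: 4 up to what fits with a 3-nt loop
    max_stem <- (length - 3L) %/% 2L
    stem <- if (max_stem > 4L) sample(4:max_stem, 1L) else 4L
    loop <- 3L
    span <- 2L * stem + loop
    start <- if (length - span >= 1L) sample(seq_len(length - span + 1L), 1L) else 1L
    left <- sample(bases, stem, replace = TRUE)
    for (t in seq_len(stem)) {
      i <- start + t - 1L
      j <- start + span - t
      chars[i] <- left[t]
      chars[j] <- comp[[left[t]]]
    }
    out[[k]] <- validate_sequence(paste(chars, collapse = ""),
                                  id = sprintf("fixture_s%d_%02d", seed, k))
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
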