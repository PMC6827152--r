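DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fraction checks used by the spec constructors.
check_fraction <- function(x, name, min = 0, max = 1,
                           include_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      (if (include_max) x > max else x >= max))
    stop(sprintf("'%s' must be a single number in [%g, %s]", name, min,
                 if (include_max) format(max) else paste0(format(max), ")")),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Coerce sequence input (character vector, DNAStringSet, or FASTA path)
# to a named character vector.
as_seq_vector <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString")) {
    out <- as.character(Biostrings::DNAStringSet(x))
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !grepl("^[ACGTNacgtn]+$", x)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected sequences as a character vector, DNAStringSet or FASTA path")
  }
  if (is.null(names(out)))
    names(out) <- paste0("seq_", seq_along(out))
  out
}
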