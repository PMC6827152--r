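#' Construct a read batch
#'
#' A read batch is the unit flowing through quality control: parallel
#' vectors of read identifiers, sequences and Phred+33-encoded quality
#' strings. Two batches of equal length form a read pair (mate 1 / mate 2).
#'
#' @param seq Character vector of read sequences (A/C/G/T/N).
#' @param qual Character vector of Phred+33 quality strings, same lengths
#'   as `seq`.
#' @param id Character vector of read identifiers; generated if missing.
#' @return An object of class `read_batch`: a list with elements `id`,
#'   `seq` and `qual`.
#' @examples
#' b <- read_batch(c("ACGT", "GGCC"), c("IIII", "II#I"))
#' length(b)
#' @export
read_batch <- function(seq, qual, id = NULL) {
  if (length(seq) != length(qual))
    stop("'seq' and 'qual' must have the same length")
  if (any(nchar(seq) != nchar(qual)))
    stop("per-record sequence and quality lengths differ")
  if (is.null(id)) id <- paste0("read_", seq_along(seq))
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)),
            class = "read_batch")
}

#' @export
length.read_batch <- function(x) length(x$seq)

#' @export
print.read_batch <- function(x, ...) {
  cat(sprintf("read_batch: %d reads, %.0f bases\n",
              length(x), sum(nchar(x$seq))))
  invisible(x)
}

# Total base count of one or more batches.
batch_bases <- function(...) {
  sum(vapply(list(...), function(b) sum(nchar(b$seq)), numeric(1)))
}

check_paired <- function(mate1, mate2) {
  stopifnot(inherits(mate1, "read_batch"), inherits(mate2, "read_batch"))
  if (length(mate1) != length(mate2))
    stop("paired batches must have equal record counts")
  invisible(TRUE)
}

#' Write a read batch to FASTQ
#'
#' Standard 4-line FASTQ with Phred+33 qualities, via Biostrings.
#'
#' @param batch A [read_batch()].
#' @param path Output file path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(batch, path) {
  stopifnot(inherits(batch, "read_batch"))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(batch$seq),
    Biostrings::PhredQuality(batch$qual))
  names(x) <- batch$id
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a read batch
#'
#' @param path FASTQ file (optionally gzipped), Phred+33.
#' @return A [read_batch()].
#' @export
read_fastq <- function(path) {
  # record metadata is intentionally reduced to id/seq/qual vectors
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  read_batch(as.character(x), as.character(Biostrings::quality(x)),
             id = names(x))
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences or a `DNAStringSet`.
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  s <- Biostrings::DNAStringSet(as_seq_vector(x))
  Biostrings::writeXStringSet(s, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}
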