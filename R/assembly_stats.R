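#' Assembly summary statistics (total, max, N50, N90)
#'
#' Computes the standard draft-assembly report for a contig or scaffold
#' set. N50 (N90) follows the accumulation definition: sort sequences
#' longest first, add lengths until the running sum reaches 50% (90%) of
#' the total; the length of the last sequence added is the N50 (N90),
#' with "reaches" meaning `>=`.
#'
#' @param x Sequences as a named character vector, `DNAStringSet`,
#'   FASTA file path, or a numeric vector of lengths.
#' @param count_n_in_length Include `N` gap characters in scaffold
#'   lengths (the standard convention). Requires sequences, not bare
#'   lengths, when `FALSE`.
#' @return An object of class `assembly_stats`: list with
#'   `total_length`, `total_number`, `max_length`, `n50`, `n90`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1))  # n50 = 4, n90 = 2
#' @export
assembly_stats <- function(x, count_n_in_length = TRUE) {
  if (is.numeric(x)) {
    if (!count_n_in_length)
      stop("count_n_in_length = FALSE requires sequences, not lengths")
    lens <- as.numeric(x)
  } else {
    seqs <- as_seq_vector(x)
    lens <- nchar(seqs)
    if (!count_n_in_length) {
      lens <- lens - vapply(strsplit(seqs, ""), function(ch)
        sum(ch %in% c("N", "n")), numeric(1))
    }
  }
  if (length(lens) == 0L) stop("empty sequence set")
  if (any(lens == 0)) {
    warning("skipping ", sum(lens == 0), " zero-length sequence(s)")
    lens <- lens[lens > 0]
    if (length(lens) == 0L) stop("no non-empty sequences")
  }
  lens <- sort(unname(lens), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  structure(list(
    total_length = total,
    total_number = length(lens),
    max_length = lens[1L],
    n50 = lens[which(cum >= 0.5 * total)[1L]],
    n90 = lens[which(cum >= 0.9 * total)[1L]]),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "assembly_stats: total %s bp in %s sequences (max %s, N50 %s, N90 %s)\n",
    format(x$total_length, big.mark = ","),
    format(x$total_number, big.mark = ","),
    format(x$max_length, big.mark = ","),
    format(x$n50, big.mark = ","), format(x$n90, big.mark = ",")))
  invisible(x)
}

#' Write assembly statistics as a one-row TSV
#'
#' @param stats An `assembly_stats` object (or named list of them, one
#'   row each, e.g. `list(contig = ..., scaffold = ...)`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  if (inherits(stats, "assembly_stats")) stats <- list(stats)
  rows <- do.call(rbind, lapply(stats, function(s)
    data.frame(total_length = s$total_length,
               total_number = s$total_number,
               max_length = s$max_length, n50 = s$n50, n90 = s$n90)))
  rows <- cbind(set = names(stats) %||% seq_along(stats), rows)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
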