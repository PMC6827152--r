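# Per-read counts of a logical flag over the concatenated base buffer.
per_read_counts <- function(flag, lens) {
  cs <- cumsum(flag)
  ends <- cumsum(lens)
  diff(c(0, cs[ends]))
}

# Decode a batch's qualities into one integer Phred vector.
phred_ints <- function(batch) {
  utf8ToInt(paste(batch$qual, collapse = "")) - 33L
}

#' Filter paired reads
#'
#' Drops a read *pair* when either mate contains one of the adapter
#' sequences as an exact substring, has more than `max_n_frac` ambiguous
#' (N) bases, or has more than `max_lowq_frac` of its bases below Phred
#' `min_q`. Surviving pairs pass through unmodified (whole-pair drop, no
#' trimming), so downstream k-mer coverage stays unbiased.
#'
#' @param mate1,mate2 Paired [read_batch()]s with equal record counts.
#' @param adapter_seqs Character vector of adapter sequences (exact
#'   substring match); empty for none.
#' @param max_n_frac Maximum tolerated fraction of N bases per read.
#' @param min_q Phred threshold defining a low-quality base.
#' @param max_lowq_frac Maximum tolerated fraction of bases below
#'   `min_q` per read.
#' @return List with filtered `mate1`, `mate2`, logical `keep` (per
#'   pair), and `stats`: raw/clean base counts and
#'   `effective_rate = 100 * clean / raw`.
#' @examples
#' b1 <- read_batch(c("ACGTACGT", "NNNNNNNN"), c("IIIIIIII", "IIIIIIII"))
#' b2 <- read_batch(c("TTTTACGT", "ACGTACGT"), c("IIIIIIII", "IIIIIIII"))
#' filter_reads(b1, b2)$stats$effective_rate
#' @export
filter_reads <- function(mate1, mate2, adapter_seqs = character(),
                         max_n_frac = 0.1, min_q = 5L,
                         max_lowq_frac = 0.5) {
  check_paired(mate1, mate2)
  bad_one <- function(b) {
    lens <- nchar(b$seq)
    bad <- rep(FALSE, length(b))
    for (ad in adapter_seqs)
      bad <- bad | grepl(ad, b$seq, fixed = TRUE)
    sbuf <- charToRaw(paste(b$seq, collapse = ""))
    n_count <- per_read_counts(sbuf == charToRaw("N"), lens)
    bad <- bad | n_count / lens > max_n_frac
    lowq <- per_read_counts(phred_ints(b) < min_q, lens)
    bad | lowq / lens > max_lowq_frac
  }
  drop <- bad_one(mate1) | bad_one(mate2)
  keep <- !drop
  sub <- function(b) read_batch(b$seq[keep], b$qual[keep], b$id[keep])
  raw_bases <- batch_bases(mate1, mate2)
  out1 <- sub(mate1); out2 <- sub(mate2)
  clean_bases <- batch_bases(out1, out2)
  list(mate1 = out1, mate2 = out2, keep = keep,
       stats = list(raw_bases = raw_bases, clean_bases = clean_bases,
                    effective_rate = 100 * clean_bases / raw_bases,
                    pairs_in = length(mate1),
                    pairs_kept = sum(keep)))
}

#' Quality statistics of a (clean) read set
#'
#' Computes the survey-sequencing report statistics: Q20 and Q30 (percent
#' of bases whose Phred quality implies base-call accuracy of at least
#' 99% and 99.9%), the mean per-base error rate implied by the qualities
#' (`100 * mean(10^(-Q/10))`), and GC content as a percent of unambiguous
#' (A/C/G/T) bases.
#'
#' @param mate1 A [read_batch()].
#' @param mate2 Optional second batch pooled with the first.
#' @return An object of class `qc_stats`: list with `bases`, `q20`,
#'   `q30`, `error_rate`, `gc_content` (all rates in percent), and
#'   `raw_bases`/`clean_bases`/`effective_rate` set to `NA` until filled
#'   in by a filtering step.
#' @examples
#' b <- read_batch("ACGT", rawToChar(as.raw(33 + c(20, 20, 35, 35))))
#' compute_quality_stats(b)$q20
#' @export
compute_quality_stats <- function(mate1, mate2 = NULL) {
  batches <- if (is.null(mate2)) list(mate1) else list(mate1, mate2)
  q <- unlist(lapply(batches, phred_ints))
  if (length(q) == 0L) stop("empty read batch")
  qtab <- tabulate(q + 1L, nbins = max(q) + 1L)  # depth of each Phred value
  qvals <- seq_along(qtab) - 1L
  n <- sum(qtab)
  sbuf <- charToRaw(paste(unlist(lapply(batches, `[[`, "seq")),
                          collapse = ""))
  btab <- tabulate(as.integer(sbuf), nbins = 256L)
  base_n <- btab[utf8ToInt("A")] + btab[utf8ToInt("C")] +
    btab[utf8ToInt("G")] + btab[utf8ToInt("T")]
  gc_n <- btab[utf8ToInt("G")] + btab[utf8ToInt("C")]
  structure(list(
    bases = n,
    q20 = 100 * sum(qtab[qvals >= 20]) / n,
    q30 = 100 * sum(qtab[qvals >= 30]) / n,
    error_rate = 100 * sum(qtab * 10^(-qvals / 10)) / n,
    gc_content = if (base_n > 0) 100 * gc_n / base_n else NA_real_,
    raw_bases = NA_real_, clean_bases = NA_real_,
    effective_rate = NA_real_), class = "qc_stats")
}

#' Filter paired reads and report full QC statistics
#'
#' One-call QC stage: applies [filter_reads()] then
#' [compute_quality_stats()] on the survivors, returning the clean
#' batches plus a complete `qc_stats` row (raw/clean bases, effective
#' rate, error rate, Q20, Q30, GC content).
#'
#' @inheritParams filter_reads
#' @return List with `mate1`, `mate2` (clean batches) and `stats`
#'   (`qc_stats`).
#' @export
qc_reads <- function(mate1, mate2, adapter_seqs = character(),
                     max_n_frac = 0.1, min_q = 5L, max_lowq_frac = 0.5) {
  f <- filter_reads(mate1, mate2, adapter_seqs, max_n_frac, min_q,
                    max_lowq_frac)
  stats <- compute_quality_stats(f$mate1, f$mate2)
  stats$raw_bases <- f$stats$raw_bases
  stats$clean_bases <- f$stats$clean_bases
  stats$effective_rate <- f$stats$effective_rate
  list(mate1 = f$mate1, mate2 = f$mate2, stats = stats)
}

#' @export
print.qc_stats <- function(x, ...) {
  cat("Read quality statistics\n")
  cat(sprintf("  Raw bases:      %s\n", format(x$raw_bases, big.mark = ",")))
  cat(sprintf("  Clean bases:    %s\n", format(x$clean_bases, big.mark = ",")))
  cat(sprintf("  Effective rate: %.2f%%\n", x$effective_rate))
  cat(sprintf("  Error rate:     %.4f%%\n", x$error_rate))
  cat(sprintf("  Q20: %.2f%%   Q30: %.2f%%   GC: %.2f%%\n",
              x$q20, x$q30, x$gc_content))
  invisible(x)
}

#' Write QC statistics as TSV and JSON
#'
#' @param stats A `qc_stats` object.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_qc_stats <- function(stats, prefix) {
  row <- data.frame(raw_bases = stats$raw_bases,
                    effective_rate = stats$effective_rate,
                    clean_bases = stats$clean_bases,
                    error_rate = stats$error_rate,
                    q20 = stats$q20, q30 = stats$q30,
                    gc_content = stats$gc_content)
  write.table(row, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(stats), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
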