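# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by direct string
# comparison / literal accumulation, independent of the package's
# implementations.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Literal accumulation N50/N90: sort longest-first, add until the running
# sum reaches the threshold, report the last added length.
oracle_nxx <- function(lengths, frac) {
  lengths <- sort(lengths, decreasing = TRUE)
  target <- frac * sum(lengths)
  acc <- 0
  for (len in lengths) {
    acc <- acc + len
    if (acc >= target) return(len)
  }
  stop("unreachable")
}

# Exhaustive perfect-SSR search: for every (start, unit length) count
# complete copies by direct substring equality, keep maximal, primitive,
# long-enough runs, then drop same-unit-length runs overlapping a
# leftmost-kept run.
oracle_find_ssrs <- function(s, min_total_len = 12) {
  L <- nchar(s)
  recs <- list()
  nr <- 0L
  for (m in 2:6) {
    max_start <- L - 2L * m + 1L
    if (max_start < 1L) next
    starts <- seq_len(max_start)
    units <- substring(s, starts, starts + m - 1L)
    ok_unit <- grepl("^[ACGT]+$", units)
    copies <- rep(1L, length(starts))
    alive <- ok_unit
    j <- 1L
    while (any(alive)) {
      cs <- starts + j * m
      ce <- cs + m - 1L
      inb <- alive & ce <= L
      eq <- rep(FALSE, length(starts))
      if (any(inb))
        eq[inb] <- substring(s, cs[inb], ce[inb]) == units[inb]
      copies[eq] <- copies[eq] + 1L
      alive <- eq
      j <- j + 1L
    }
    for (i in which(ok_unit & copies >= 2L & copies * m >= min_total_len)) {
      if (i - m >= 1L && substring(s, i - m, i - 1L) == units[i]) next
      prim <- TRUE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L &&
            strrep(substring(units[i], 1L, d), m %/% d) == units[i]) {
          prim <- FALSE
          break
        }
      }
      if (!prim) next
      nr <- nr + 1L
      recs[[nr]] <- data.frame(start = i - 1L,
                               end = i - 1L + copies[i] * m,
                               unit_length = m, copies = copies[i])
    }
  }
  if (nr == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), copies = integer(0)))
  out <- do.call(rbind, recs)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  last_end <- integer(7L)
  for (i in seq_len(nrow(out))) {
    m <- out$unit_length[i]
    if (out$start[i] < last_end[m]) keep[i] <- FALSE
    else last_end[m] <- out$end[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build a kmer_histogram with arbitrary bins through the package's own
# TSV reader (the on-disk format is the public contract).
hist_from_counts <- function(depth, count, k = 17) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(data.frame(depth, count), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  read_kmer_histogram(tmp, k = k)
}

# Phred+33 quality string from integer qualities.
qual_string <- function(q) rawToChar(as.raw(33L + q))

# Coverage giving a target k-mer depth for 150 bp reads.
coverage_for_kmer_depth <- function(lambda, read_length = 150, k = 17) {
  lambda * read_length / (read_length - k + 1)
}
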