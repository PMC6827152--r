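# Collect read sequences from read batches / sim_reads / character input.
collect_reads <- function(reads) {
  if (inherits(reads, "sim_reads")) reads <- list(reads$mate1, reads$mate2)
  if (inherits(reads, "read_batch")) reads <- list(reads)
  if (is.character(reads)) return(reads)
  unlist(lapply(reads, function(b) {
    if (inherits(b, "read_batch")) b$seq else as.character(b)
  }), use.names = FALSE)
}

check_k <- function(k) {
  k <- check_count(k, "k", min = 3)
  if (k %% 2L == 0L)
    stop("k must be odd: canonical form is ill-defined for palindromic even k-mers")
  if (k > 26L) stop("k must be <= 26")
  k
}

#' Exact canonical k-mer depth table
#'
#' Counts every N-free length-`k` window of the reads as one instance of
#' the lexicographically smaller of the window and its reverse
#' complement. Counting is exact (hashed 2-bit encodings, no sketches).
#'
#' @param reads Read input: a [read_batch()], a list of batches, a
#'   [simulate_reads()] result, or a character vector of sequences.
#' @param k Odd k-mer length, 3-25 (default 17).
#' @return An object of class `kmer_table`: data.frame with numeric
#'   `code` (2-bit encoding of the canonical k-mer) and integer `count`
#'   (its depth), with attribute `k`. Decode codes with [kmer_decode()].
#' @seealso [kmer_histogram()], [count_kmers()]
#' @export
kmer_depth_table <- function(reads, k = 17L) {
  k <- check_k(k)
  seqs <- collect_reads(reads)
  if (any(nchar(seqs) >= k) == FALSE)
    stop("k exceeds every read length")
  tab <- kmer_count_cpp(seqs, k)
  out <- data.frame(code = tab$code, count = tab$count)
  attr(out, "k") <- k
  class(out) <- c("kmer_table", "data.frame")
  out
}

#' Decode canonical k-mer codes
#'
#' @param codes Numeric 2-bit k-mer codes (as in a `kmer_table`).
#' @param k K-mer length.
#' @return Character vector of k-mer sequences.
#' @export
kmer_decode <- function(codes, k) kmer_decode_cpp(codes, check_k(k))

#' Build a k-mer depth histogram
#'
#' Collapses a k-mer depth table into the depth spectrum: for each depth
#' `d`, the number of distinct canonical k-mers seen exactly `d` times.
#' Depths above `max_depth_tracked` collapse into the final bin; their
#' full volume is preserved in the `extra_volume` attribute so volume
#' accounting stays exact.
#'
#' @param x A `kmer_table` from [kmer_depth_table()].
#' @param max_depth_tracked Depth at which the histogram is truncated.
#' @return An object of class `kmer_histogram`: data.frame with `depth`
#'   and `count` (only non-empty bins), attributes `k`, `total_volume`
#'   (exact total k-mer instances) and `extra_volume`.
#' @export
kmer_histogram <- function(x, max_depth_tracked = 10000L) {
  stopifnot(inherits(x, "kmer_table"))
  depth <- pmin(x$count, max_depth_tracked)
  counts <- tabulate(depth, nbins = max_depth_tracked)
  keep <- which(counts > 0L)
  h <- data.frame(depth = keep, count = counts[keep])
  attr(h, "k") <- attr(x, "k")
  attr(h, "total_volume") <- sum(as.numeric(x$count))
  attr(h, "extra_volume") <-
    sum(as.numeric(x$count[x$count > max_depth_tracked]) -
          max_depth_tracked)
  attr(h, "max_depth_tracked") <- max_depth_tracked
  class(h) <- c("kmer_histogram", "data.frame")
  h
}

#' Count k-mers and build the depth spectrum in one step
#'
#' @inheritParams kmer_depth_table
#' @inheritParams kmer_histogram
#' @return A `kmer_histogram` (see [kmer_histogram()]).
#' @examples
#' h <- count_kmers(c("ACGTACG"), k = 3)
#' kmer_volume(h)  # 5 windows
#' @export
count_kmers <- function(reads, k = 17L, max_depth_tracked = 10000L) {
  kmer_histogram(kmer_depth_table(reads, k), max_depth_tracked)
}

#' Total k-mer volume of a histogram
#'
#' Volume is the number of counted k-mer instances,
#' `sum(depth * count)`, optionally restricted to a depth range.
#'
#' @param h A `kmer_histogram`.
#' @param min_depth,max_depth Inclusive depth range.
#' @return Numeric volume (exact, including any collapsed deep bin when
#'   the range covers it).
#' @export
kmer_volume <- function(h, min_depth = 1L, max_depth = Inf) {
  stopifnot(inherits(h, "kmer_histogram"))
  sel <- h$depth >= min_depth & h$depth <= max_depth
  v <- sum(as.numeric(h$depth[sel]) * h$count[sel])
  if (max_depth >= attr(h, "max_depth_tracked"))
    v <- v + attr(h, "extra_volume")
  v
}

# Dense count vector indexed by depth 1..max(depth).
dense_counts <- function(h) {
  out <- numeric(max(h$depth))
  out[h$depth] <- h$count
  out
}

# Centered 3-bin moving average with replicated edges.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  (c(x[1L], x[-n]) + x + c(x[-1L], x[n])) / 3
}

#' Locate the error valley of a k-mer spectrum
#'
#' Sequencing errors produce a spike of low-depth k-mers; the valley is
#' the first local minimum after that spike on the 3-bin-smoothed
#' histogram: the smallest depth `d >= 2` with
#' `count(d) < count(d - 1)` and `count(d) <= count(d + 1)`. An error
#' spike, when present, towers over the genuine coverage peak, so the
#' spectrum is considered error-free unless its depth-1 smoothed bin is
#' the modal bin; in that case (or for a monotone histogram with no
#' local minimum) depth 1 is returned with attribute `no_error = TRUE`
#' and no volume is attributed to error.
#'
#' @param h A `kmer_histogram`.
#' @return Integer valley depth with logical attribute `no_error`.
#' @export
find_error_valley <- function(h) {
  stopifnot(inherits(h, "kmer_histogram"))
  sm <- smooth3(dense_counts(h))
  n <- length(sm)
  if (n < 3L || sm[1L] < max(sm[-1L]))
    return(structure(1L, no_error = TRUE))
  for (d in 2:max(2L, n - 1L)) {
    if (d + 1L > n) break
    if (sm[d] < sm[d - 1L] && sm[d] <= sm[d + 1L])
      return(structure(as.integer(d), no_error = FALSE))
  }
  structure(1L, no_error = TRUE)
}

# Local maxima (>= both neighbours) of a numeric vector, as indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] >= x[1:(n - 2L)] &
          x[2:(n - 1L)] >= x[3:n]) + 1L
}

#' Locate the homozygous peak depth of a k-mer spectrum
#'
#' Returns the depth of the main (homozygous) coverage peak: the argmax
#' of the 3-bin-smoothed counts at depths above the error valley. In a
#' heterozygous genome the half-depth (heterozygous) peak can exceed the
#' homozygous peak; if a comparably tall local maximum sits near twice
#' the argmax depth, that full-depth maximum is returned instead. Ties
#' break toward the lower depth.
#'
#' @param h A `kmer_histogram`.
#' @param valley Error valley from [find_error_valley()].
#' @return Integer peak depth.
#' @export
find_peak_depth <- function(h, valley) {
  stopifnot(inherits(h, "kmer_histogram"))
  sm <- smooth3(dense_counts(h))
  depths <- seq_along(sm)
  cand <- depths > valley
  if (!any(cand) || all(sm[cand] == 0))
    stop("no k-mer depth peak above the error valley")
  p <- depths[cand][which.max(sm[cand])]
  # Half-depth heterozygous peak guard: a local maximum of at least half
  # the candidate's height near depth 2p marks p as the het peak.
  lm <- local_maxima(sm)
  lm <- lm[lm > valley]
  harmonic <- lm[lm >= round(1.7 * p) & lm <= round(2.3 * p)]
  if (length(harmonic)) {
    m2 <- harmonic[which.max(sm[harmonic])]
    if (sm[m2] >= 0.5 * sm[p]) return(as.integer(m2))
  }
  as.integer(p)
}

#' Estimate genome size from k-mer volume and peak depth
#'
#' The standard k-mer estimator: genome size = k-mer number / peak
#' depth, where the k-mer number is the total spectrum volume and the
#' peak depth is the mode of the underlying Poisson coverage
#' distribution.
#'
#' @param kmer_number Total k-mer volume (instances counted).
#' @param peak_depth Peak (modal) k-mer depth.
#' @return Genome size in bases (real division; round at the reporting
#'   layer).
#' @examples
#' estimate_genome_size(36648430961, 70) / 1e6  # 523.55 Mbp
#' @export
estimate_genome_size <- function(kmer_number, peak_depth) {
  if (!is.numeric(kmer_number) || length(kmer_number) != 1L ||
      kmer_number < 0)
    stop("'kmer_number' must be a single non-negative number")
  if (!is.numeric(peak_depth) || length(peak_depth) != 1L ||
      peak_depth < 1)
    stop("'peak_depth' must be >= 1")
  kmer_number / peak_depth
}

#' Error k-mer volume fraction
#'
#' Fraction of the total k-mer volume sitting at depths at or below the
#' error valley — the share of counted k-mer instances attributable to
#' sequencing error. Zero when the spectrum has no error component.
#'
#' @param h A `kmer_histogram`.
#' @param valley Valley from [find_error_valley()].
#' @return Fraction in \[0, 1).
#' @export
error_kmer_fraction <- function(h, valley) {
  if (isTRUE(attr(valley, "no_error"))) return(0)
  kmer_volume(h, 1L, valley) / kmer_volume(h)
}

#' Revise a genome size estimate for error k-mers
#'
#' Error k-mers inflate the spectrum volume without representing genome
#' sequence; the revised size is
#' `genome_size * (1 - error_kmer_fraction)`.
#'
#' @param genome_size Unrevised size in bases.
#' @param error_kmer_fraction Error volume fraction in \[0, 1), from
#'   [error_kmer_fraction()].
#' @return Revised genome size in bases.
#' @export
revise_genome_size <- function(genome_size, error_kmer_fraction) {
  check_fraction(error_kmer_fraction, "error_kmer_fraction",
                 include_max = FALSE)
  genome_size * (1 - error_kmer_fraction)
}

#' Estimate the heterozygosity ratio from a k-mer spectrum
#'
#' Heterozygous sites split k-mer coverage between two alleles, adding a
#' spectrum component centred at half the homozygous peak depth. Both
#' components are modelled as Poisson-shaped; their weights are fitted
#' by least squares to the counts in `(valley, 1.5 * peak]`. With `a`
#' the heterozygous share of distinct non-error k-mers, the per-base
#' heterozygosity is `100 * (1 - (1 - a/2)^(1/k))` percent (a
#' small-rate inversion of the probability that a k-mer overlaps no
#' heterozygous site).
#'
#' @param h A `kmer_histogram`.
#' @param peak_depth Homozygous peak depth from [find_peak_depth()].
#' @param valley Error valley from [find_error_valley()].
#' @param k K-mer length; defaults to the histogram's `k`.
#' @return Heterozygosity ratio in percent. Negative fitted weights are
#'   clamped to zero with a warning.
#' @export
estimate_het_ratio <- function(h, peak_depth, valley,
                               k = attr(h, "k")) {
  stopifnot(inherits(h, "kmer_histogram"))
  if (valley >= peak_depth) stop("valley must lie below the peak depth")
  dmax <- min(round(1.5 * peak_depth), max(h$depth))
  d <- (valley + 1L):dmax
  dense <- dense_counts(h)
  y <- dense[d]
  X <- cbind(hom = dpois(d, peak_depth), het = dpois(d, peak_depth / 2))
  w <- stats::lm.fit(X, y)$coefficients
  if (any(w < 0)) {
    warning("degenerate two-component fit: negative weight clamped to zero")
    w <- pmax(w, 0)
  }
  if (sum(w) == 0) return(0)
  a <- w[["het"]] / sum(w)
  100 * (1 - (1 - a / 2)^(1 / k))
}

#' Estimate the repeat ratio from a k-mer spectrum
#'
#' Multi-copy sequence places k-mers at integer multiples of the peak
#' depth. The repeat ratio is the k-mer-volume share beyond the
#' homozygous peak's reach: volume at depths above
#' `2 * peak_depth - valley`, relative to all non-error volume (depths
#' above the valley).
#'
#' @inheritParams estimate_het_ratio
#' @return Repeat ratio in percent.
#' @export
estimate_repeat_ratio <- function(h, peak_depth, valley) {
  stopifnot(inherits(h, "kmer_histogram"))
  thr <- 2 * peak_depth - valley
  100 * kmer_volume(h, thr + 1L) / kmer_volume(h, valley + 1L)
}

#' Full spectrum-based genome profile
#'
#' Runs the complete estimation chain on a k-mer histogram: error
#' valley, homozygous peak, total k-mer number, genome size
#' (volume / peak), error-revised size, heterozygosity ratio and repeat
#' ratio.
#'
#' @param h A `kmer_histogram`.
#' @return An object of class `spectrum_estimate`: list with `k`,
#'   `peak_depth`, `kmer_number`, `error_valley`,
#'   `error_kmer_fraction`, `genome_size`, `revised_genome_size`,
#'   `het_ratio` and `repeat_ratio` (sizes in bases, ratios in percent).
#' @export
summarize_spectrum <- function(h) {
  stopifnot(inherits(h, "kmer_histogram"))
  valley <- find_error_valley(h)
  peak <- find_peak_depth(h, valley)
  vol <- kmer_volume(h)
  err_frac <- error_kmer_fraction(h, valley)
  gs <- estimate_genome_size(vol, peak)
  structure(list(
    k = attr(h, "k"),
    peak_depth = peak,
    kmer_number = vol,
    error_valley = as.integer(valley),
    error_kmer_fraction = err_frac,
    genome_size = gs,
    revised_genome_size = revise_genome_size(gs, err_frac),
    het_ratio = estimate_het_ratio(h, peak, valley),
    repeat_ratio = estimate_repeat_ratio(h, peak, valley)),
    class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat("K-mer spectrum genome profile\n")
  cat(sprintf("  k = %d, peak depth = %d, error valley = %d\n",
              x$k, x$peak_depth, x$error_valley))
  cat(sprintf("  K-mer number:        %s\n",
              format(x$kmer_number, big.mark = ",")))
  cat(sprintf("  Genome size:         %.2f Mbp\n", x$genome_size / 1e6))
  cat(sprintf("  Revised genome size: %.2f Mbp (error k-mer fraction %.4f)\n",
              x$revised_genome_size / 1e6, x$error_kmer_fraction))
  cat(sprintf("  Heterozygosity:      %.2f%%\n", x$het_ratio))
  cat(sprintf("  Repeat ratio:        %.2f%%\n", x$repeat_ratio))
  invisible(x)
}

#' Read / write a k-mer histogram as two-column TSV
#'
#' The on-disk format is `depth<TAB>count`, one bin per line, compatible
#' with Jellyfish `histo` output, so externally produced spectra can be
#' analysed.
#'
#' @param h A `kmer_histogram`.
#' @param path TSV file path.
#' @param k K-mer length to attach when reading (the file stores none).
#' @return `write_kmer_histogram()`: `path`, invisibly.
#'   `read_kmer_histogram()`: a `kmer_histogram`.
#' @export
write_kmer_histogram <- function(h, path) {
  stopifnot(inherits(h, "kmer_histogram"))
  write.table(data.frame(h$depth, h$count), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_histogram
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("depth", "count"))
  df <- df[df$count > 0, , drop = FALSE]
  h <- data.frame(depth = as.integer(df$depth), count = df$count)
  attr(h, "k") <- check_k(k)
  attr(h, "total_volume") <- sum(as.numeric(h$depth) * h$count)
  attr(h, "extra_volume") <- 0
  attr(h, "max_depth_tracked") <- max(h$depth)
  class(h) <- c("kmer_histogram", "data.frame")
  h
}
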