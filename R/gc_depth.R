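#' Per-window GC content and k-mer depth of an assembly
#'
#' Tiles each assembly sequence with fixed-size windows (a trailing
#' window shorter than half the window size is merged into its
#' predecessor) and reports, per window, GC percent over unambiguous
#' bases and the mean canonical-k-mer depth of the window's N-free
#' k-mers, looked up in a read-derived depth table. Depth comes from
#' k-mer counts rather than read alignment: for a coverage-vs-GC quality
#' profile the k-mer depth is an adequate and much cheaper proxy.
#'
#' @param assembly Sequences (named character vector, `DNAStringSet`, or
#'   FASTA path).
#' @param depth_table A `kmer_table` from [kmer_depth_table()] built on
#'   the same read set.
#' @param window Window size in bases (>= k).
#' @return An object of class `gc_depth_records`: data.frame with
#'   `seq_id`, `window_start`, `window_end` (0-based half-open),
#'   `gc_percent`, `mean_depth`. Sequences shorter than k are skipped
#'   with a warning.
#' @export
window_gc_depth <- function(assembly, depth_table, window = 500L) {
  stopifnot(inherits(depth_table, "kmer_table"))
  k <- attr(depth_table, "k")
  window <- check_count(window, "window")
  if (window < k) stop("window must be >= k")
  seqs <- as_seq_vector(assembly)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning("skipping ", sum(short), " sequence(s) shorter than k")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0L) stop("no sequence of at least k bases")

  per_seq <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    len <- nchar(s)
    ws <- seq(0L, len - 1L, by = window)
    we <- pmin(ws + window, len)
    n_win <- length(ws)
    if (n_win > 1L && (we[n_win] - ws[n_win]) < window / 2) {
      we[n_win - 1L] <- we[n_win]
      ws <- ws[-n_win]; we <- we[-n_win]
      n_win <- n_win - 1L
    }
    dna <- Biostrings::DNAString(s)
    v <- Biostrings::Views(dna, start = ws + 1L, end = we)
    af <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(acgt > 0,
                 100 * rowSums(af[, c("G", "C"), drop = FALSE]) / acgt,
                 NA_real_)
    codes <- kmer_codes_cpp(s, k)
    depth <- depth_table$count[match(codes, depth_table$code)]
    depth[is.na(depth) & !is.na(codes)] <- 0L
    mean_depth <- vapply(seq_len(n_win), function(i) {
      idx <- (ws[i] + 1L):(we[i] - k + 1L)
      idx <- idx[idx >= 1L & idx <= length(depth)]
      d <- depth[idx]
      if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }, numeric(1))
    data.frame(seq_id = id, window_start = ws, window_end = we,
               gc_percent = gc, mean_depth = mean_depth)
  })
  out <- do.call(rbind, per_seq)
  rownames(out) <- NULL
  class(out) <- c("gc_depth_records", "data.frame")
  out
}

#' Summarize a GC-depth profile
#'
#' @param records A `gc_depth_records` data.frame from
#'   [window_gc_depth()].
#' @return List with `mean_gc` (percent, weighted by window base
#'   count), `gc_range` (0.5th-99.5th percentile of per-window GC, the
#'   band holding 99% of windows), `depth_quantiles`
#'   (5/25/50/75/95th percentiles of window mean depth) and `n_windows`.
#' @export
summarize_gc <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0L) stop("no GC-depth records")
  wlen <- records$window_end - records$window_start
  ok <- !is.na(records$gc_percent)
  structure(list(
    mean_gc = weighted.mean(records$gc_percent[ok], wlen[ok]),
    gc_range = quantile(records$gc_percent, c(0.005, 0.995),
                        na.rm = TRUE, names = FALSE),
    depth_quantiles = quantile(records$mean_depth,
                               c(0.05, 0.25, 0.5, 0.75, 0.95),
                               na.rm = TRUE, names = FALSE),
    n_windows = nrow(records)), class = "gc_summary")
}

#' @export
print.gc_summary <- function(x, ...) {
  cat(sprintf(
    "GC-depth summary: mean GC %.2f%% (99%% of %d windows in %.1f-%.1f%%), median depth %.1f\n",
    x$mean_gc, x$n_windows, x$gc_range[1], x$gc_range[2],
    x$depth_quantiles[3]))
  invisible(x)
}

#' Plot a GC-content vs depth profile
#'
#' Scatter of per-window GC percent (x) against mean k-mer depth (y)
#' with marginal histograms — the classic survey-sequencing
#' contamination/QC panel.
#'
#' @param records A `gc_depth_records` data.frame.
#' @param ... Passed to [graphics::plot()].
#' @return `records`, invisibly.
#' @export
plot_gc_depth <- function(records, ...) {
  ok <- !is.na(records$gc_percent) & !is.na(records$mean_depth)
  gc <- records$gc_percent[ok]; dp <- records$mean_depth[ok]
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::layout(matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE),
                   widths = c(4, 1), heights = c(1, 4))
  graphics::par(mar = c(4, 4, 0.5, 0.5))
  graphics::plot(gc, dp, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "GC content (%)", ylab = "Mean k-mer depth", ...)
  graphics::par(mar = c(0.5, 4, 0.5, 0.5))
  gh <- graphics::hist(gc, breaks = 40, plot = FALSE)
  graphics::barplot(gh$counts, space = 0, border = NA,
                    col = "steelblue", axes = FALSE)
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  dh <- graphics::hist(dp, breaks = 40, plot = FALSE)
  graphics::barplot(dh$counts, space = 0, border = NA,
                    col = "steelblue", axes = FALSE, horiz = TRUE)
  invisible(records)
}

#' Plot a k-mer depth spectrum
#'
#' @param h A `kmer_histogram`.
#' @param max_depth Right edge of the plotted depth range.
#' @param ... Passed to [graphics::plot()].
#' @return `h`, invisibly.
#' @export
plot_kmer_spectrum <- function(h, max_depth = NULL, ...) {
  stopifnot(inherits(h, "kmer_histogram"))
  if (is.null(max_depth)) max_depth <- min(max(h$depth), 300L)
  sel <- h$depth <= max_depth
  graphics::plot(h$depth[sel], h$count[sel], type = "l", lwd = 2,
                 col = "steelblue", xlab = "K-mer depth",
                 ylab = "Distinct k-mers", ...)
  invisible(h)
}

#' Write per-window GC-depth records as TSV
#'
#' @param records A `gc_depth_records` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gc_depth <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
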