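SSR_CLASSES <- c(`2` = "di", `3` = "tri", `4` = "tetra", `5` = "penta",
                 `6` = "hexa")

# Smallest primitive unit of a repeat motif ("ATAT" -> "AT").
primitive_unit <- function(unit) {
  m <- nchar(unit)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (strrep(substr(unit, 1L, d), m %/% d) == unit)
      return(substr(unit, 1L, d))
  }
  unit
}

all_rotations <- function(unit) {
  m <- nchar(unit)
  doubled <- paste0(unit, unit)
  vapply(seq_len(m), function(i) substr(doubled, i, i + m - 1L),
         character(1))
}

#' Canonical form of a microsatellite motif
#'
#' Reduces the unit to its primitive form (e.g. `"ATAT"` to `"AT"`) and
#' returns the lexicographically smallest string among all rotations of
#' the primitive unit and all rotations of its reverse complement, so
#' that one motif label covers every phase and strand (e.g. `"TG"`,
#' `"GT"`, `"CA"` and `"AC"` all map to `"AC"`).
#'
#' @param unit Repeat unit, 2-6 bases of A/C/G/T (units that are powers
#'   of a shorter unit are classified by that primitive unit;
#'   homopolymer powers are rejected).
#' @return Canonical motif string.
#' @examples
#' canonical_motif("TG")    # "AC"
#' canonical_motif("ATAT")  # "AT"
#' @export
canonical_motif <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      !grepl("^[ACGT]{2,6}$", unit))
    stop("'unit' must be a single 2-6 bp A/C/G/T string")
  p <- primitive_unit(unit)
  if (nchar(p) == 1L)
    stop("homopolymer unit: no di- to hexa-nucleotide motif")
  min(c(all_rotations(p), all_rotations(revcomp(p))))
}

# SSR scan of one sequence. Vectorized period detection: position i is
# period-m-matching when s[i] == s[i+m] and both are unambiguous; runs
# of matches give periodic regions, trimmed to complete copies anchored
# at the region's left end.
.find_ssrs_one <- function(s, seq_id, min_total_len) {
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit_length = integer(0), ssr_class = character(0),
                      copies = integer(0), span_length = integer(0))
  L <- nchar(s)
  if (L < min_total_len) return(empty)
  x <- utf8ToInt(toupper(s))
  valid <- x == 65L | x == 67L | x == 71L | x == 84L  # A C G T
  rows <- vector("list", 64L); nr <- 0L
  for (m in 2:6) {
    if (L < 2L * m) next
    n <- L - m
    eq <- x[1:n] == x[(m + 1L):L] & valid[1:n] & valid[(m + 1L):L]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    min_run <- max(min_total_len, 2L * m) - m  # need t + m >= span floor
    sel <- which(r$values & r$lengths >= min_run)
    for (j in sel) {
      i <- run_start[j]
      copies <- (r$lengths[j] + m) %/% m
      span <- copies * m
      if (span < min_total_len || copies < 2L) next
      unit <- substr(s, i, i + m - 1L)
      if (nchar(primitive_unit(unit)) != m) next
      nr <- nr + 1L
      rows[[nr]] <- list(start = i - 1L, m = m, copies = copies,
                         span = span, unit = unit)
    }
  }
  if (nr == 0L) return(empty)
  rec <- do.call(rbind, lapply(rows[seq_len(nr)], as.data.frame))
  out <- data.frame(seq_id = seq_id, start = rec$start,
                    end = rec$start + rec$span,
                    motif = vapply(rec$unit, canonical_motif, character(1),
                                   USE.NAMES = FALSE),
                    unit_length = rec$m,
                    ssr_class = unname(SSR_CLASSES[as.character(rec$m)]),
                    copies = rec$copies, span_length = rec$span)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  # No two same-unit-length records may overlap; keep the leftmost.
  keep <- rep(TRUE, nrow(out))
  last_end <- integer(7L)  # per unit length
  for (i in seq_len(nrow(out))) {
    m <- out$unit_length[i]
    if (out$start[i] < last_end[m]) keep[i] <- FALSE
    else last_end[m] <- out$end[i]
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find perfect microsatellites (SSRs)
#'
#' Detects every maximal run of complete copies of a primitive 2-6 bp
#' unit whose total span is at least `min_total_len` bases (default 12,
#' i.e. minimum copy numbers 6/4/3/3/2 for unit lengths 2-6). Partial
#' trailing units are not counted; runs are split at ambiguous (N)
#' bases; a span expressible with several unit lengths is reported under
#' the shortest primitive unit; mononucleotide runs are excluded.
#'
#' @param x Sequences (named character vector, `DNAStringSet`, or FASTA
#'   path).
#' @param min_total_len Minimum SSR span in bases.
#' @return An object of class `ssr_records`: data.frame with `seq_id`,
#'   0-based half-open `start`/`end`, canonical `motif`, `unit_length`,
#'   `ssr_class` (di-hexa), `copies` and `span_length`. Empty (zero
#'   rows) for SSR-free input.
#' @examples
#' find_ssrs(c(chr = "GGGACACACACACACGGG"))  # one di record, 6 copies
#' @export
find_ssrs <- function(x, min_total_len = 12L) {
  min_total_len <- check_count(min_total_len, "min_total_len", min = 4)
  seqs <- as_seq_vector(x)
  out <- do.call(rbind, lapply(names(seqs), function(id)
    .find_ssrs_one(seqs[[id]], id, min_total_len)))
  rownames(out) <- NULL
  class(out) <- c("ssr_records", "data.frame")
  out
}

#' Summarize SSRs by motif class
#'
#' Tallies di- to hexa-nucleotide counts and their percentages of the
#' total (rounded to 2 decimals).
#'
#' @param x An `ssr_records` data.frame from [find_ssrs()], or a
#'   numeric vector of five class counts ordered (or named) di, tri,
#'   tetra, penta, hexa.
#' @return An object of class `ssr_summary`: list with `counts` (named
#'   integer vector), `total` and `percentages` (named, 2 dp).
#' @examples
#' s <- summarize_ssrs(c(di = 84406, tri = 50420, tetra = 11361,
#'                       penta = 2200, hexa = 870))
#' s$total        # 149257
#' s$percentages  # 56.55 33.78 7.61 1.47 0.58
#' @export
summarize_ssrs <- function(x) {
  cls <- unname(SSR_CLASSES)
  if (is.numeric(x)) {
    if (length(x) != 5L)
      stop("expected five class counts (di..hexa)")
    counts <- if (!is.null(names(x))) x[cls] else stats::setNames(x, cls)
    if (any(is.na(counts))) stop("counts must be named di..hexa (or unnamed)")
  } else {
    stopifnot(inherits(x, "data.frame"))
    counts <- vapply(cls, function(cl) sum(x$ssr_class == cl), numeric(1))
  }
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 2)
         else stats::setNames(rep(0, 5L), cls)
  structure(list(counts = counts, total = total, percentages = pct),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %s loci\n", format(x$total, big.mark = ",")))
  df <- data.frame(class = names(x$counts),
                   count = format(x$counts, big.mark = ","),
                   percent = sprintf("%.2f%%", x$percentages))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write SSR records as TSV and optionally GFF3
#'
#' @param records An `ssr_records` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ssr_tsv
#' @param gff3_path Output GFF3 path (features of type `microsatellite`;
#'   requires GenomicRanges and rtracklayer).
#' @export
write_ssr_gff3 <- function(records, gff3_path) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 export requires the GenomicRanges and rtracklayer packages")
  gr <- GenomicRanges::GRanges(
    seqnames = records$seq_id,
    ranges = IRanges::IRanges(start = records$start + 1L,
                              end = records$end),
    type = "microsatellite", motif = records$motif,
    copies = records$copies)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(gff3_path)
}
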