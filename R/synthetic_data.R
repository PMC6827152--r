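#' Specify a synthetic diploid genome
#'
#' Defines the ground-truth parameters of a simulated diploid genome:
#' haploid length, GC content, the fraction of the genome covered by
#' multi-copy (repeat) sequence, and the per-base heterozygous-site rate.
#' Defaults emulate a small teleost-like genome survey: GC 45%,
#' heterozygosity 0.92%, repeat fraction 21%.
#'
#' @param haploid_length Haploid genome length in bases.
#' @param gc_fraction GC content as a fraction in \[0, 1\].
#' @param repeat_fraction Fraction of the genome covered by duplicated
#'   segments (donors and copies together), in \[0, 1).
#' @param repeat_unit_length Length in bases of each duplicated segment.
#' @param het_rate Per-base probability of a heterozygous site, in
#'   \[0, 0.05\].
#' @param seed Integer RNG seed; identical specs reproduce identical
#'   genomes byte for byte.
#' @return An object of class `genome_spec`.
#' @seealso [generate_genome()]
#' @export
genome_spec <- function(haploid_length, gc_fraction = 0.45,
                        repeat_fraction = 0, repeat_unit_length = 500L,
                        het_rate = 0, seed = 1L) {
  haploid_length <- check_count(haploid_length, "haploid_length")
  check_fraction(gc_fraction, "gc_fraction")
  check_fraction(repeat_fraction, "repeat_fraction", include_max = FALSE)
  repeat_unit_length <- check_count(repeat_unit_length, "repeat_unit_length")
  check_fraction(het_rate, "het_rate", max = 0.05)
  if (repeat_fraction > 0 && haploid_length < 10L * repeat_unit_length)
    stop("haploid_length must be >= 10 * repeat_unit_length when repeats are requested")
  structure(list(haploid_length = haploid_length, gc_fraction = gc_fraction,
                 repeat_fraction = repeat_fraction,
                 repeat_unit_length = repeat_unit_length,
                 het_rate = het_rate, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a diploid genome with known ground truth
#'
#' Draws an i.i.d. base sequence at the requested GC content, overlays
#' repeat families (exact duplications of donor segments, so repeat
#' k-mers sit at integer multiples of the coverage peak), and creates a
#' second haplotype differing from the first by biallelic substitutions
#' at Bernoulli(`het_rate`) positions. Repeat families receive a
#' geometric copy number (minimum 2, mean 3), mimicking the heavy-tailed
#' copy-number spectra of genomic repeat families.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `diploid_genome`: list with `haplotype_a`,
#'   `haplotype_b` (character scalars of equal length), `het_positions`
#'   (0-based sorted integer positions where the haplotypes differ),
#'   `repeat_intervals` (data.frame of 0-based half-open `start`, `end`,
#'   `family` on haplotype A), and the originating `spec`.
#' @examples
#' g <- generate_genome(genome_spec(10000, het_rate = 0.01, seed = 7))
#' length(g$het_positions) / 10000
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$haploid_length
    gc <- spec$gc_fraction
    bases <- sample(DNA_BASES, L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

    rep_intervals <- data.frame(start = integer(0), end = integer(0),
                                family = integer(0))
    if (spec$repeat_fraction > 0) {
      u <- spec$repeat_unit_length
      n_blocks <- L %/% u
      target_blocks <- round(spec$repeat_fraction * L / u)
      block_order <- sample.int(n_blocks)
      used <- 0L; ptr <- 1L; fam <- 0L
      rows <- list()
      while (used < target_blocks && ptr + 1L <= n_blocks) {
        copies <- 2L + stats::rgeom(1L, 0.5)
        copies <- min(copies, n_blocks - ptr + 1L,
                      max(2L, target_blocks - used))
        fam <- fam + 1L
        blocks <- block_order[ptr:(ptr + copies - 1L)]
        ptr <- ptr + copies
        donor_idx <- ((blocks[1L] - 1L) * u + 1L):(blocks[1L] * u)
        for (b in blocks[-1L])
          bases[((b - 1L) * u + 1L):(b * u)] <- bases[donor_idx]
        rows[[fam]] <- data.frame(start = (blocks - 1L) * u,
                                  end = blocks * u, family = fam)
        used <- used + copies
      }
      rep_intervals <- do.call(rbind, rows)
      rep_intervals <- rep_intervals[order(rep_intervals$start), ,
                                     drop = FALSE]
      rownames(rep_intervals) <- NULL
    }

    het_pos <- which(runif(L) < spec$het_rate)
    bases_b <- bases
    if (length(het_pos)) {
      cur <- match(bases[het_pos], DNA_BASES)
      shift <- sample.int(3L, length(het_pos), replace = TRUE)
      bases_b[het_pos] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
    }

    structure(list(haplotype_a = paste(bases, collapse = ""),
                   haplotype_b = paste(bases_b, collapse = ""),
                   het_positions = het_pos - 1L,
                   repeat_intervals = rep_intervals,
                   spec = spec),
              class = "diploid_genome")
  })
}

#' @export
print.diploid_genome <- function(x, ...) {
  L <- nchar(x$haplotype_a)
  cat(sprintf(
    "diploid_genome: %d bp haploid, %d heterozygous sites (%.3f%%), %d repeat intervals (%.1f%% of genome)\n",
    L, length(x$het_positions), 100 * length(x$het_positions) / L,
    nrow(x$repeat_intervals),
    100 * sum(x$repeat_intervals$end - x$repeat_intervals$start) / L))
  invisible(x)
}

#' Specify a paired-end read simulation
#'
#' Parameters of a 2 x `read_length` paired-end sequencing run: insert
#' size distribution, fold coverage, per-base substitution error rate,
#' and a two-valued quality model (high Phred for correct bases, low for
#' erroneous ones). Defaults emulate a 2 x 150 bp library with ~350 bp
#' inserts.
#'
#' @param coverage Fold base coverage of the haploid genome (> 0).
#' @param read_length Read length in bases.
#' @param insert_size Mean insert (fragment) length in bases.
#' @param insert_sd Standard deviation of the insert length.
#' @param error_rate Per-base probability of a substitution error.
#' @param quality_high Phred quality assigned to correct bases.
#' @param quality_low Phred quality assigned to erroneous bases.
#' @param allow_overlap Permit `insert_size < 2 * read_length`
#'   (overlapping mates); otherwise rejected.
#' @param seed Integer RNG seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(coverage, read_length = 150L, insert_size = 350L,
                          insert_sd = 35, error_rate = 0,
                          quality_high = 36L, quality_low = 2L,
                          allow_overlap = FALSE, seed = 1L) {
  if (!is.numeric(coverage) || coverage <= 0)
    stop("'coverage' must be > 0")
  read_length <- check_count(read_length, "read_length")
  insert_size <- check_count(insert_size, "insert_size")
  check_fraction(error_rate, "error_rate", max = 0.5)
  if (!allow_overlap && insert_size < 2L * read_length)
    stop("insert_size < 2 * read_length; set allow_overlap = TRUE to permit overlapping mates")
  structure(list(coverage = coverage, read_length = read_length,
                 insert_size = insert_size, insert_sd = insert_sd,
                 error_rate = error_rate,
                 quality_high = as.integer(quality_high),
                 quality_low = as.integer(quality_low),
                 allow_overlap = allow_overlap, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate paired-end reads from a diploid genome
#'
#' Draws fragments uniformly from the two haplotypes with equal
#' probability, reads `read_length` bases inward from both fragment ends
#' (mate 2 reverse-complemented), flips each base to a different base
#' with probability `error_rate`, and assigns the two-valued quality
#' model. The returned ground truth (fragment coordinates and error
#' positions) is sufficient to recompute the true error rate without
#' re-alignment.
#'
#' @param genome A [generate_genome()] result.
#' @param sim A [read_sim_spec()].
#' @return An object of class `sim_reads`: list with `mate1`, `mate2`
#'   ([read_batch()]s), and `truth` (list with `hap`, `frag_start`
#'   (0-based), `insert` per pair, and `errors`, a data.frame of
#'   1-based `read` index into `c(mate1, mate2)` and `pos` within the
#'   read for every injected error).
#' @export
simulate_reads <- function(genome, sim) {
  stopifnot(inherits(genome, "diploid_genome"), inherits(sim, "read_sim_spec"))
  L <- nchar(genome$haplotype_a)
  if (L == 0L) stop("empty genome")
  rl <- sim$read_length
  if (L < sim$insert_size) stop("genome shorter than the insert size")
  n_pairs <- round(sim$coverage * L / (2 * rl))
  if (n_pairs < 1L)
    stop("coverage too low: zero read pairs would be drawn")
  with_seed(sim$seed, {
    hap <- sample(1:2, n_pairs, replace = TRUE)
    ins <- as.integer(round(rnorm(n_pairs, sim$insert_size, sim$insert_sd)))
    min_ins <- if (sim$allow_overlap) rl else 2L * rl
    ins <- pmax(pmin(ins, L), min_ins)
    start <- as.integer(floor(runif(n_pairs) * (L - ins + 1)))  # 0-based
    hapseq <- c(genome$haplotype_a, genome$haplotype_b)[hap]
    r1 <- substring(hapseq, start + 1L, start + rl)
    r2 <- revcomp(substring(hapseq, start + ins - rl + 1L, start + ins))

    total <- 2L * n_pairs * rl
    buf <- charToRaw(paste(c(r1, r2), collapse = ""))
    n_err <- rbinom(1L, total, sim$error_rate)
    err <- data.frame(read = integer(0), pos = integer(0))
    if (n_err > 0) {
      pos <- sort(sample.int(total, n_err))
      base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
      cur <- match(buf[pos], base_raw)
      shift <- sample.int(3L, n_err, replace = TRUE)
      buf[pos] <- base_raw[(cur - 1L + shift) %% 4L + 1L]
      err <- data.frame(read = (pos - 1L) %/% rl + 1L,
                        pos = (pos - 1L) %% rl + 1L)
    }
    qbuf <- rep(as.raw(33L + sim$quality_high), total)
    if (n_err > 0) qbuf[pos] <- as.raw(33L + sim$quality_low)

    all_seq <- substring(rawToChar(buf),
                         seq(1L, by = rl, length.out = 2L * n_pairs),
                         seq(rl, by = rl, length.out = 2L * n_pairs))
    all_qual <- substring(rawToChar(qbuf),
                          seq(1L, by = rl, length.out = 2L * n_pairs),
                          seq(rl, by = rl, length.out = 2L * n_pairs))
    ids <- paste0("sim_", seq_len(n_pairs))
    structure(list(
      mate1 = read_batch(all_seq[seq_len(n_pairs)],
                         all_qual[seq_len(n_pairs)],
                         id = paste0(ids, "/1")),
      mate2 = read_batch(all_seq[n_pairs + seq_len(n_pairs)],
                         all_qual[n_pairs + seq_len(n_pairs)],
                         id = paste0(ids, "/2")),
      truth = list(hap = hap, frag_start = start, insert = ins,
                   errors = err, n_errors = n_err)),
      class = "sim_reads")
  })
}

#' Fragment a genome into a contig/scaffold fixture
#'
#' Partitions haplotype A into contigs (conserving every base exactly
#' once) and joins runs of consecutive contigs into scaffolds with
#' `'N' x gap_length` spacers, producing a matched contig/scaffold set
#' for exercising assembly statistics and GC-depth profiling.
#'
#' @param genome A [generate_genome()] result.
#' @param n_contigs Number of contigs (>= 1, <= haploid length).
#' @param gap_length Number of `N` characters inserted between joined
#'   contigs within a scaffold.
#' @param seed Integer RNG seed for the fragmentation.
#' @param lengths Optional integer vector of forced contig lengths
#'   (must sum to the haploid length); random partition otherwise.
#' @param contigs_per_scaffold Mean number of contigs joined per
#'   scaffold (group sizes drawn uniformly from 1 to
#'   `2 * contigs_per_scaffold - 1`).
#' @return List with named character vectors `contigs` and `scaffolds`.
#' @export
fragment_assembly <- function(genome, n_contigs, gap_length = 100L,
                              seed = 1L, lengths = NULL,
                              contigs_per_scaffold = 3L) {
  stopifnot(inherits(genome, "diploid_genome"))
  L <- nchar(genome$haplotype_a)
  n_contigs <- check_count(n_contigs, "n_contigs")
  if (n_contigs > L) stop("n_contigs exceeds the genome length")
  with_seed(seed, {
    if (is.null(lengths)) {
      breaks <- if (n_contigs > 1L) sort(sample.int(L - 1L, n_contigs - 1L))
                else integer(0)
      lengths <- diff(c(0L, breaks, L))
    } else {
      lengths <- as.integer(lengths)
      if (length(lengths) != n_contigs || sum(lengths) != L ||
          any(lengths < 1L))
        stop("'lengths' must be ", n_contigs,
             " positive integers summing to the haploid length")
    }
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1L
    contigs <- substring(genome$haplotype_a, starts, ends)
    names(contigs) <- sprintf("contig_%d", seq_along(contigs))

    sizes <- integer(0)
    while (sum(sizes) < n_contigs)
      sizes <- c(sizes, sample.int(2L * contigs_per_scaffold - 1L, 1L))
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_contigs)
    sizes <- sizes[sizes > 0L]
    grp <- rep(seq_along(sizes), sizes)
    gap <- strrep("N", gap_length)
    scaffolds <- vapply(split(contigs, grp), paste,
                        character(1), collapse = gap)
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
    list(contigs = contigs, scaffolds = scaffolds,
         contig_lengths = lengths)
  })
}

#' Write simulation ground truth sidecar files
#'
#' Emits the simulator's stored truth as plain text: heterozygous
#' positions and repeat intervals as TSV and the genome/read specs as
#' JSON, so downstream parameter-recovery checks never re-infer truth.
#'
#' @param genome A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @param sim Optional [read_sim_spec()] echoed into the JSON.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(genome, dir, sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(position = genome$het_positions),
              file.path(dir, "het_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(genome$repeat_intervals,
              file.path(dir, "repeat_intervals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(genome_spec = unclass(genome$spec),
         read_sim_spec = if (!is.null(sim)) unclass(sim)),
    file.path(dir, "simulation_spec.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
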