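test_that("canonical counting matches exhaustive enumeration", {
  # "ACGTACG", k = 3: windows ACG,CGT,GTA,TAC,ACG; min(window, revcomp)
  # gives ACG,ACG,GTA,GTA,ACG (revcomp(CGT)=ACG, revcomp(TAC)=GTA)
  tab <- kmer_depth_table("ACGTACG", k = 3)
  got <- setNames(tab$count, kmer_decode(tab$code, 3))
  expect_mapequal(as.list(got), list(ACG = 3L, GTA = 2L))
  expect_equal(sum(tab$count), 5)  # 7 - 3 + 1 windows

  # N windows are skipped
  tabn <- kmer_depth_table("ACGNACG", k = 3)
  expect_equal(sum(tabn$count), 2)

  expect_error(kmer_depth_table("ACGT", k = 4), "odd")
})

test_that("histogram is strand-invariant and conserves volume", {
  set.seed(41)
  reads <- vapply(rep(80, 300), random_dna, character(1))
  h_fwd <- count_kmers(reads, k = 17)
  h_rev <- count_kmers(revcomp(reads), k = 17)
  expect_identical(as.data.frame(h_fwd), as.data.frame(h_rev))
  expect_equal(kmer_volume(h_fwd), sum(nchar(reads) - 17 + 1))

  # volume conservation bin by bin against the depth table
  tab <- kmer_depth_table(reads, k = 17)
  expect_equal(kmer_volume(h_fwd), sum(as.numeric(tab$count)))
})

test_that("deep bins collapse into the final bin without losing volume", {
  reads <- rep("ACGTTGCAACGTTGCAA", 50)  # one 17-mer seen 50 times
  h <- count_kmers(reads, k = 17, max_depth_tracked = 10)
  expect_equal(max(h$depth), 10)
  expect_equal(kmer_volume(h), 50)
})

test_that("error valley matches a brute-force scan of the smoothed spectrum", {
  oracle_valley <- function(depth, count) {
    dense <- numeric(max(depth)); dense[depth] <- count
    n <- length(dense)
    padded <- c(dense[1], dense, dense[n])
    sm <- vapply(seq_len(n), function(i)
      (padded[i] + padded[i + 1] + padded[i + 2]) / 3, numeric(1))
    if (sm[1] < max(sm[-1])) return(1L)  # no dominant error spike
    for (d in 2:(n - 1))
      if (sm[d] < sm[d - 1] && sm[d] <= sm[d + 1]) return(d)
    1L
  }
  set.seed(42)
  for (i in 1:25) {
    lambda <- sample(30:90, 1)
    d <- 1:200
    count <- round(1e6 * exp(-d / runif(1, 0.3, 2)) +
                     2e4 * dpois(d, lambda) + runif(200, 0, 5))
    h <- hist_from_counts(d, count)
    v <- find_error_valley(h)
    expect_equal(as.integer(v), oracle_valley(d, count))
  }

  # strictly decreasing spectrum: no error component to separate
  hmono <- hist_from_counts(1:50, floor(1e5 / (1:50)))
  v <- find_error_valley(hmono)
  expect_equal(as.integer(v), 1)
  expect_true(attr(v, "no_error"))
  expect_equal(error_kmer_fraction(hmono, v), 0)

  # spectrum whose modal bin is the coverage peak, not depth 1:
  # treated as error-free
  hclean <- hist_from_counts(1:100, round(5e4 * dpois(1:100, 50)) +
                               c(5, 3, 2, rep(0, 97)))
  vc <- find_error_valley(hclean)
  expect_true(attr(vc, "no_error"))
})

test_that("peak detection recovers the homozygous coverage peak", {
  # single spike
  hs <- hist_from_counts(c(1, 70), c(10, 1000))
  expect_equal(find_peak_depth(hs, 1L), 70)

  # simulated Poisson coverage at target k-mer depth 50 (mode = mean)
  g <- generate_genome(genome_spec(2e5, seed = 51))
  r <- simulate_reads(g, read_sim_spec(
    coverage = coverage_for_kmer_depth(50), error_rate = 0, seed = 52))
  h <- count_kmers(r, k = 17)
  valley <- find_error_valley(h)
  peak <- find_peak_depth(h, valley)
  expect_lte(abs(peak - 50), 1)

  # strongly heterozygous genome: the half-depth peak must not win
  ghet <- generate_genome(genome_spec(15e4, het_rate = 0.02, seed = 53))
  rhet <- simulate_reads(ghet, read_sim_spec(
    coverage = coverage_for_kmer_depth(70), error_rate = 0, seed = 54))
  hhet <- count_kmers(rhet, k = 17)
  peak_het <- find_peak_depth(hhet, find_error_valley(hhet))
  expect_gt(peak_het, 55)   # full-depth peak (~70), not ~35
  expect_lt(peak_het, 85)

  expect_error(find_peak_depth(hist_from_counts(1:3, c(5, 4, 1)), 10L),
               "no k-mer depth peak")
})

test_that("genome size formula is exact division (worked example 523.55 Mbp)", {
  gs <- estimate_genome_size(36648430961, 70)
  expect_equal(round(gs / 1e6, 2), 523.55)
  expect_equal(gs * 70, 36648430961)  # Eq. echo to within one ulp
  expect_equal(estimate_genome_size(1000, 10), 100)
  expect_error(estimate_genome_size(1000, 0), "peak_depth")
})

test_that("revision scales by the error k-mer volume fraction", {
  expect_equal(revise_genome_size(500e6, 0), 500e6)
  # fraction implying the published-style 523.55 -> 508.50 Mbp revision
  expect_equal(round(revise_genome_size(523.549e6, 0.02874) / 1e6, 2),
               508.50)
  expect_error(revise_genome_size(1e6, 1), "error_kmer_fraction")

  # error-free simulation: revised size equals unrevised exactly
  g <- generate_genome(genome_spec(5e4, seed = 61))
  r <- simulate_reads(g, read_sim_spec(coverage = 30, error_rate = 0,
                                       seed = 62))
  est <- suppressWarnings(summarize_spectrum(count_kmers(r, k = 17)))
  expect_equal(est$revised_genome_size, est$genome_size)
  expect_lt(abs(est$genome_size - 5e4) / 5e4, 0.02)
})

test_that("heterozygosity estimates are near zero without variants and ordered in rate", {
  g0 <- generate_genome(genome_spec(1e5, het_rate = 0, seed = 71))
  r0 <- simulate_reads(g0, read_sim_spec(
    coverage = coverage_for_kmer_depth(70), error_rate = 0, seed = 72))
  h0 <- count_kmers(r0, k = 17)
  v0 <- find_error_valley(h0)
  p0 <- find_peak_depth(h0, v0)
  expect_lt(suppressWarnings(estimate_het_ratio(h0, p0, v0)), 0.05)

  est_for <- function(rate, seed) {
    g <- generate_genome(genome_spec(1e5, het_rate = rate, seed = seed))
    r <- simulate_reads(g, read_sim_spec(
      coverage = coverage_for_kmer_depth(70), error_rate = 0,
      seed = seed + 1))
    h <- count_kmers(r, k = 17)
    v <- find_error_valley(h)
    estimate_het_ratio(h, find_peak_depth(h, v), v)
  }
  expect_lt(est_for(0.003, 73), est_for(0.012, 75))
})

test_that("repeat ratio is near zero without repeats and grows with repeat content", {
  est_for <- function(frac, seed) {
    g <- generate_genome(genome_spec(15e4, repeat_fraction = frac,
                                     seed = seed))
    r <- simulate_reads(g, read_sim_spec(
      coverage = coverage_for_kmer_depth(60), error_rate = 0,
      seed = seed + 1))
    h <- count_kmers(r, k = 17)
    v <- find_error_valley(h)
    estimate_repeat_ratio(h, find_peak_depth(h, v), v)
  }
  expect_lt(est_for(0, 81), 2)
  expect_gt(est_for(0.2, 83), est_for(0.1, 85))
})

test_that("histogram TSV round-trips through the Jellyfish-style format", {
  set.seed(91)
  reads <- vapply(rep(60, 100), random_dna, character(1))
  h <- count_kmers(reads, k = 17)
  tmp <- tempfile(fileext = ".tsv")
  write_kmer_histogram(h, tmp)
  h2 <- read_kmer_histogram(tmp, k = 17)
  expect_equal(h$depth, h2$depth)
  expect_equal(h$count, h2$count)
  expect_equal(kmer_volume(h), kmer_volume(h2))
  unlink(tmp)
})
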