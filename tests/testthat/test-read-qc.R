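make_batch <- function(seqs, q = 38L) {
  read_batch(seqs, vapply(nchar(seqs), function(n)
    qual_string(rep(q, n)), character(1)))
}

test_that("filter_reads drops contaminated, ambiguous and low-quality pairs jointly", {
  set.seed(5)
  good <- vapply(rep(60, 10), random_dna, character(1))
  b1 <- make_batch(good)
  b2 <- make_batch(vapply(rep(60, 10), random_dna, character(1)))

  # clean high-quality input passes through untouched
  f <- filter_reads(b1, b2)
  expect_identical(f$mate1$seq, b1$seq)
  expect_equal(f$stats$effective_rate, 100)

  # adapter injected into 3 known mate-1 reads: 7 pairs survive
  adapter <- "AGATCGGAAGAGC"
  contaminated <- good
  hit <- c(2L, 5L, 9L)
  contaminated[hit] <- paste0(substr(good[hit], 1, 30), adapter,
                              substr(good[hit], 44, 60))
  fa <- filter_reads(make_batch(contaminated), b2,
                     adapter_seqs = adapter)
  expect_equal(fa$stats$pairs_kept, 7)
  expect_identical(which(!fa$keep), hit)

  # an all-N mate sinks its pair regardless of quality
  nb <- make_batch(c(good[1], strrep("N", 60), good[3]))
  fn <- filter_reads(make_batch(good[1:3]), nb)
  expect_identical(fn$keep, c(TRUE, FALSE, TRUE))

  # low-quality drop: second read mostly below min_q
  q <- c(rep(38, 10), rep(2, 50))
  lb <- read_batch(good[1:2], c(qual_string(rep(38, 60)), qual_string(q)))
  fl <- filter_reads(lb, make_batch(good[1:2]), min_q = 5,
                     max_lowq_frac = 0.5)
  expect_identical(fl$keep, c(TRUE, FALSE))

  expect_error(filter_reads(make_batch(good[1:2]), make_batch(good)),
               "equal record counts")
})

test_that("raising min_q never increases the number of retained pairs", {
  set.seed(6)
  n <- 50
  seqs <- vapply(rep(40, n), random_dna, character(1))
  quals <- vapply(seq_len(n), function(i)
    qual_string(sample(0:40, 40, replace = TRUE)), character(1))
  b1 <- read_batch(seqs, quals)
  b2 <- read_batch(rev(seqs), rev(quals))
  kept <- vapply(c(2, 5, 10, 20, 30, 38), function(mq)
    filter_reads(b1, b2, min_q = mq)$stats$pairs_kept, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("quality statistics match their closed forms", {
  # all bases at Q20: q20 = 100, q30 = 0, error rate exactly 1%
  b20 <- read_batch(strrep("ACGT", 25), qual_string(rep(20L, 100)))
  s <- compute_quality_stats(b20)
  expect_equal(s$q20, 100)
  expect_equal(s$q30, 0)
  expect_equal(s$error_rate, 1)
  expect_equal(s$gc_content, 50)

  # all bases at Q35: error rate = 100 * 10^-3.5 ~ 0.0316%
  b35 <- read_batch(strrep("AT", 50), qual_string(rep(35L, 100)))
  expect_equal(compute_quality_stats(b35)$error_rate, 100 * 10^-3.5)
  expect_equal(compute_quality_stats(b35)$gc_content, 0)

  # N bases are excluded from the GC denominator
  bn <- read_batch("GGNNAA", qual_string(rep(30L, 6)))
  expect_equal(compute_quality_stats(bn)$gc_content, 50)

  expect_error(compute_quality_stats(read_batch(character(0),
                                                character(0))),
               "empty")
})

test_that("q30 <= q20 on arbitrary quality profiles", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    b <- read_batch(random_dna(n), qual_string(sample(0:41, n, TRUE)))
    s <- compute_quality_stats(b)
    expect_lte(s$q30, s$q20)
  }
})

test_that("simulated two-valued qualities reproduce Q30 and GC ground truth", {
  g <- generate_genome(genome_spec(5e4, gc_fraction = 0.45, seed = 21))
  r <- simulate_reads(g, read_sim_spec(coverage = 20, error_rate = 0.003,
                                       quality_high = 36, quality_low = 2,
                                       seed = 22))
  s <- compute_quality_stats(r$mate1, r$mate2)
  expect_lt(abs(s$q30 - 99.7), 0.1)   # correct bases carry Q36
  expect_lt(abs(s$gc_content - 45), 1)  # >= 10x coverage tracks genome GC
  expect_lte(s$q30, s$q20)
})

test_that("qc_reads assembles the full survey statistics row", {
  g <- generate_genome(genome_spec(2e4, seed = 31))
  r <- simulate_reads(g, read_sim_spec(coverage = 5, error_rate = 0.001,
                                       seed = 32))
  out <- qc_reads(r$mate1, r$mate2)
  expect_equal(out$stats$effective_rate,
               100 * out$stats$clean_bases / out$stats$raw_bases)
  expect_lte(out$stats$clean_bases, out$stats$raw_bases)
  tmp <- tempfile()
  write_qc_stats(out$stats, tmp)
  tsv <- read.table(paste0(tmp, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(tsv$q30, out$stats$q30)
  unlink(paste0(tmp, c(".tsv", ".json")))
})
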