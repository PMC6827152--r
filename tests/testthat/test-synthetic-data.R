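test_that("generator hits its ground-truth dials (het, GC, repeats)", {
  # zero-rate boundary cases
  g0 <- generate_genome(genome_spec(5000, het_rate = 0, seed = 1))
  expect_length(g0$het_positions, 0)
  expect_identical(g0$haplotype_a, g0$haplotype_b)
  expect_equal(nrow(g0$repeat_intervals), 0)

  # heterozygous-site density: oracle = direct count of mismatching bases
  g <- generate_genome(genome_spec(1e6, het_rate = 0.0092, seed = 1))
  a <- charToRaw(g$haplotype_a)
  b <- charToRaw(g$haplotype_b)
  mismatch <- which(a != b)
  expect_identical(mismatch - 1L, g$het_positions)
  dens <- length(mismatch) / 1e6
  expect_gte(dens, 0.0083)
  expect_lte(dens, 0.0101)

  # realized GC within 1 pp at >= 100 kb
  gcg <- generate_genome(genome_spec(1e5, gc_fraction = 0.45, seed = 2))
  counts <- table(strsplit(gcg$haplotype_a, "")[[1]])
  gc <- (counts[["G"]] + counts[["C"]]) / 1e5
  expect_lt(abs(gc - 0.45), 0.01)

  # repeat intervals: coverage within 2 pp, disjoint, exact copies
  gr <- generate_genome(genome_spec(2e5, repeat_fraction = 0.21, seed = 3))
  ri <- gr$repeat_intervals
  expect_true(all(ri$start[-1] >= head(ri$end, -1)))
  cov <- sum(ri$end - ri$start) / 2e5
  expect_lt(abs(cov - 0.21), 0.02)
  for (fam in split(ri, ri$family)) {
    segs <- substring(gr$haplotype_a, fam$start + 1, fam$end)
    expect_gte(nrow(fam), 2)
    expect_true(all(segs == segs[1]))
  }

  expect_error(genome_spec(1e5, repeat_fraction = 1), "repeat_fraction")
  expect_error(genome_spec(1000, repeat_fraction = 0.2,
                           repeat_unit_length = 500), "10")
})

test_that("read simulator honours coverage, error model and ground truth", {
  g <- generate_genome(genome_spec(1e5, het_rate = 0.005, seed = 11))

  # accounting identity: total bases within one pair of coverage * length
  r <- simulate_reads(g, read_sim_spec(coverage = 50, seed = 12))
  total <- sum(nchar(r$mate1$seq)) + sum(nchar(r$mate2$seq))
  expect_lte(abs(total - 50 * 1e5), 300)

  # error-free reads occur verbatim at their recorded coordinates
  r0 <- simulate_reads(g, read_sim_spec(coverage = 2, error_rate = 0,
                                        seed = 13))
  hapseq <- c(g$haplotype_a, g$haplotype_b)[r0$truth$hap]
  st <- r0$truth$frag_start
  ins <- r0$truth$insert
  expect_identical(r0$mate1$seq, substring(hapseq, st + 1, st + 150))
  expect_identical(r0$mate2$seq,
                   revcomp(substring(hapseq, st + ins - 149, st + ins)))

  # realized substitution rate vs source haplotype, via stored coordinates
  re <- simulate_reads(g, read_sim_spec(coverage = 50, error_rate = 0.003,
                                        seed = 14))
  hapseq <- c(g$haplotype_a, g$haplotype_b)[re$truth$hap]
  st <- re$truth$frag_start
  ins <- re$truth$insert
  true1 <- substring(hapseq, st + 1, st + 150)
  true2 <- revcomp(substring(hapseq, st + ins - 149, st + ins))
  obs <- charToRaw(paste(c(re$mate1$seq, re$mate2$seq), collapse = ""))
  tru <- charToRaw(paste(c(true1, true2), collapse = ""))
  rate <- mean(obs != tru)
  expect_gte(rate, 0.0025)
  expect_lte(rate, 0.0035)
  # ... and the truth sidecar accounts for every flipped base
  expect_equal(sum(obs != tru), re$truth$n_errors)
  expect_equal(nrow(re$truth$errors), re$truth$n_errors)

  # erroneous bases carry quality_low, correct bases quality_high
  qual <- charToRaw(paste(c(re$mate1$qual, re$mate2$qual), collapse = ""))
  expect_true(all(qual[obs != tru] == as.raw(33 + 2)))
  expect_true(all(qual[obs == tru] == as.raw(33 + 36)))

  expect_error(simulate_reads(g, read_sim_spec(coverage = 1e-9, seed = 1)),
               "zero read pairs")
})

test_that("simulation is deterministic in (spec, seed)", {
  s <- genome_spec(2e4, het_rate = 0.01, repeat_fraction = 0.1, seed = 7)
  g1 <- generate_genome(s)
  g2 <- generate_genome(s)
  expect_identical(g1, g2)
  rs <- read_sim_spec(coverage = 5, error_rate = 0.01, seed = 8)
  r1 <- simulate_reads(g1, rs)
  r2 <- simulate_reads(g2, rs)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1$mate1, f1)
  write_fastq(r2$mate1, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("fragment_assembly partitions the genome and scaffolds with gaps", {
  g <- generate_genome(genome_spec(15, seed = 1))

  one <- fragment_assembly(g, 1, gap_length = 10, seed = 1)
  expect_identical(unname(one$contigs), g$haplotype_a)

  forced <- fragment_assembly(g, 5, gap_length = 0, seed = 2,
                              lengths = c(5, 4, 3, 2, 1))
  expect_identical(sum(nchar(forced$contigs)), 15L)
  expect_equal(assembly_stats(nchar(forced$contigs))$n50, 4)
  # gap_length 0: scaffolds are plain concatenations, no N characters
  expect_false(any(grepl("N", forced$scaffolds)))
  expect_identical(paste(forced$contigs, collapse = ""),
                   paste(forced$scaffolds, collapse = ""))

  g2 <- generate_genome(genome_spec(5000, seed = 3))
  fr <- fragment_assembly(g2, 40, gap_length = 25, seed = 4)
  expect_identical(sum(nchar(fr$contigs)), 5000L)  # conservation
  n_gaps <- sum(vapply(gregexpr("N+", fr$scaffolds), function(m)
    sum(m > 0), numeric(1)))
  expect_equal(sum(nchar(fr$scaffolds)), 5000 + 25 * n_gaps)
  expect_error(fragment_assembly(g, 16, seed = 1), "exceeds")
})
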