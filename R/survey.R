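#' Build a survey configuration
#'
#' Assembles and validates the configuration of a full genome-survey
#' run. Inputs are either existing FASTQ/FASTA files or a `simulate`
#' block, in which case the synthetic-data generator produces reads and
#' a fragmented assembly fixture inside the output directory. The
#' configuration is serialized verbatim into the output directory and
#' hashed into the report provenance.
#'
#' @param out_dir Output directory for all stage files.
#' @param fastq1,fastq2 Paired FASTQ paths (ignored when `simulate` is
#'   given).
#' @param contig_fasta,scaffold_fasta Optional assembly FASTA paths;
#'   when absent and not simulating, assembly-based stages are skipped.
#' @param simulate Optional list of generator parameters:
#'   `haploid_length`, `gc_fraction`, `repeat_fraction`, `het_rate`,
#'   `coverage`, `error_rate`, `n_contigs`, plus any other
#'   [genome_spec()] / [read_sim_spec()] field.
#' @param k K-mer length.
#' @param window GC-depth window size in bases.
#' @param ssr_min_len Minimum SSR span in bases.
#' @param qc List of QC thresholds: `adapters`, `max_n_frac`, `min_q`,
#'   `max_lowq_frac`.
#' @param seed Integer seed governing every stochastic stage.
#' @return An object of class `survey_config`.
#' @seealso [run_survey()]
#' @export
survey_config <- function(out_dir, fastq1 = NULL, fastq2 = NULL,
                          contig_fasta = NULL, scaffold_fasta = NULL,
                          simulate = NULL, k = 17L, window = 500L,
                          ssr_min_len = 12L,
                          qc = list(), seed = 1L) {
  qc_defaults <- list(adapters = character(), max_n_frac = 0.1,
                      min_q = 5L, max_lowq_frac = 0.5)
  qc <- utils::modifyList(qc_defaults, qc)
  if (is.null(simulate)) {
    if (is.null(fastq1) || is.null(fastq2))
      stop("either paired FASTQ inputs or a 'simulate' block is required")
    for (f in c(fastq1, fastq2, contig_fasta, scaffold_fasta))
      if (!file.exists(f)) stop("input does not exist: ", f)
  }
  structure(list(out_dir = out_dir, fastq1 = fastq1, fastq2 = fastq2,
                 contig_fasta = contig_fasta,
                 scaffold_fasta = scaffold_fasta, simulate = simulate,
                 k = check_k(k), window = check_count(window, "window"),
                 ssr_min_len = check_count(ssr_min_len, "ssr_min_len"),
                 qc = qc, seed = as.integer(seed)),
            class = "survey_config")
}

#' Read a survey configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [survey_config()]
#'   arguments.
#' @return A `survey_config`.
#' @export
read_survey_config <- function(path) {
  do.call(survey_config, yaml::read_yaml(path))
}

# Stable hash of the configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             tmp)
  unname(tools::md5sum(tmp))
}

# Run one pipeline stage; on failure leave a .partial marker and abort
# with a stage-named error.
run_stage <- function(name, out_dir, expr) {
  marker <- file.path(out_dir, paste0(name, ".partial"))
  file.create(marker)
  result <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  unlink(marker)
  result
}

#' Run the complete genome survey pipeline
#'
#' Orchestrates QC, k-mer spectrum profiling, assembly statistics,
#' GC-depth profiling and SSR mining (simulating the inputs first when
#' the configuration asks for it). Stages communicate through files in
#' `out_dir`; each stage writes its own TSV/JSON output, and a
#' consolidated `report.json` collects every section. Rerunning an
#' identical configuration reproduces byte-identical numeric outputs;
#' timestamps live only in `run.log`.
#'
#' @param config A [survey_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `survey_report`: list with sections `qc`,
#'   `spectrum`, `assembly` (`contig`/`scaffold`), `gc`, `ssr` (each a
#'   stage result or the string `"skipped"`) and `provenance`.
#' @export
run_survey <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "survey_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  contigs <- scaffolds <- NULL
  if (!is.null(config$simulate)) {
    sim_out <- run_stage("simulate", out_dir, {
      p <- config$simulate
      gs_args <- p[intersect(names(p), names(formals(genome_spec)))]
      gs_args$seed <- gs_args$seed %||% config$seed
      genome <- generate_genome(do.call(genome_spec, gs_args))
      rs_args <- p[intersect(names(p), names(formals(read_sim_spec)))]
      rs_args$seed <- rs_args$seed %||% (config$seed + 1L)
      reads <- simulate_reads(genome, do.call(read_sim_spec, rs_args))
      asm <- fragment_assembly(genome,
                               n_contigs = p$n_contigs %||% 200L,
                               gap_length = p$gap_length %||% 100L,
                               seed = config$seed + 2L)
      write_fastq(reads$mate1, file.path(out_dir, "sim_1.fastq"))
      write_fastq(reads$mate2, file.path(out_dir, "sim_2.fastq"))
      write_fasta(asm$contigs, file.path(out_dir, "sim_contigs.fasta"))
      write_fasta(asm$scaffolds, file.path(out_dir, "sim_scaffolds.fasta"))
      write_ground_truth(genome, file.path(out_dir, "ground_truth"))
      say("simulate: %d read pairs from a %d bp genome",
          length(reads$mate1), nchar(genome$haplotype_a))
      list(reads = reads, asm = asm)
    })
    mate1 <- sim_out$reads$mate1; mate2 <- sim_out$reads$mate2
    contigs <- sim_out$asm$contigs; scaffolds <- sim_out$asm$scaffolds
  } else {
    mate1 <- run_stage("load_reads", out_dir, read_fastq(config$fastq1))
    mate2 <- run_stage("load_reads", out_dir, read_fastq(config$fastq2))
    if (!is.null(config$contig_fasta))
      contigs <- read_fasta(config$contig_fasta)
    if (!is.null(config$scaffold_fasta))
      scaffolds <- read_fasta(config$scaffold_fasta)
  }

  qc_out <- run_stage("qc", out_dir, {
    r <- qc_reads(mate1, mate2, adapter_seqs = config$qc$adapters,
                  max_n_frac = config$qc$max_n_frac,
                  min_q = config$qc$min_q,
                  max_lowq_frac = config$qc$max_lowq_frac)
    write_qc_stats(r$stats, file.path(out_dir, "qc_stats"))
    say("qc: %d of %d pairs retained (%.2f%% of bases)",
        length(r$mate1), length(mate1), r$stats$effective_rate)
    r
  })

  spectrum <- run_stage("kmer", out_dir, {
    tab <- kmer_depth_table(list(qc_out$mate1, qc_out$mate2), config$k)
    h <- kmer_histogram(tab)
    write_kmer_histogram(h, file.path(out_dir, "kmer_histo.tsv"))
    est <- summarize_spectrum(h)
    jsonlite::write_json(unclass(est), file.path(out_dir, "estimate.json"),
                         auto_unbox = TRUE, digits = NA)
    say("kmer: peak %d, genome size %.2f Mbp (revised %.2f)",
        est$peak_depth, est$genome_size / 1e6,
        est$revised_genome_size / 1e6)
    list(table = tab, estimate = est)
  })

  assembly <- gc <- ssr <- "skipped"
  if (!is.null(scaffolds)) {
    assembly <- run_stage("asm_stats", out_dir, {
      st <- list(scaffold = assembly_stats(scaffolds))
      if (!is.null(contigs))
        st <- c(list(contig = assembly_stats(contigs)), st)
      write_assembly_stats(st, file.path(out_dir, "assembly_stats.tsv"))
      say("asm_stats: scaffold N50 %d", st$scaffold$n50)
      st
    })
    gc <- run_stage("gc_depth", out_dir, {
      rec <- window_gc_depth(scaffolds, spectrum$table,
                             window = config$window)
      write_gc_depth(rec, file.path(out_dir, "gc_depth.tsv"))
      s <- summarize_gc(rec)
      say("gc_depth: mean GC %.2f%% over %d windows", s$mean_gc,
          s$n_windows)
      s
    })
    ssr <- run_stage("ssr", out_dir, {
      rec <- find_ssrs(scaffolds, min_total_len = config$ssr_min_len)
      write_ssr_tsv(rec, file.path(out_dir, "ssr_loci.tsv"))
      s <- summarize_ssrs(rec)
      write.table(
        data.frame(class = names(s$counts), count = s$counts,
                   percent = s$percentages),
        file.path(out_dir, "ssr_summary.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      say("ssr: %d loci", s$total)
      s
    })
  }

  report <- structure(list(
    qc = unclass(qc_out$stats),
    spectrum = unclass(spectrum$estimate),
    assembly = if (identical(assembly, "skipped")) "skipped"
               else lapply(assembly, unclass),
    gc = if (identical(gc, "skipped")) "skipped" else unclass(gc),
    ssr = if (identical(ssr, "skipped")) "skipped" else unclass(ssr),
    provenance = list(package = "genomesurvey",
                      version = as.character(packageVersion("genomesurvey")),
                      config_hash = config_hash(config))),
    class = "survey_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("survey complete: %s", file.path(out_dir, "report.json"))
  report
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Genome survey report\n")
  cat(sprintf("  QC: %.0f clean bases (%.2f%% effective), Q20 %.2f%%, Q30 %.2f%%, GC %.2f%%\n",
              x$qc$clean_bases, x$qc$effective_rate, x$qc$q20, x$qc$q30,
              x$qc$gc_content))
  cat(sprintf("  Spectrum: peak %d, size %.2f Mbp (revised %.2f), het %.2f%%, repeat %.2f%%\n",
              x$spectrum$peak_depth, x$spectrum$genome_size / 1e6,
              x$spectrum$revised_genome_size / 1e6, x$spectrum$het_ratio,
              x$spectrum$repeat_ratio))
  if (!identical(x$assembly, "skipped"))
    cat(sprintf("  Assembly: scaffold N50 %d (N90 %d)\n",
                x$assembly$scaffold$n50, x$assembly$scaffold$n90))
  if (!identical(x$gc, "skipped"))
    cat(sprintf("  GC-depth: mean GC %.2f%%\n", x$gc$mean_gc))
  if (!identical(x$ssr, "skipped"))
    cat(sprintf("  SSR: %d loci (%.2f%% dinucleotide)\n", x$ssr$total,
                x$ssr$percentages[["di"]]))
  invisible(x)
}
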