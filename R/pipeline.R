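#' Run the mining pipeline end to end
#'
#' Reads input sequences (FASTQ, or FASTA with optional QUAL),
#' demultiplexes them by MID barcode, runs the filter cascade, and
#' writes the artifacts into `outdir`: `demux_counts.tsv`, `hits.tsv`
#' (coordinates 0-based half-open, noted in a header comment),
#' `cascade_report.tsv` and `candidates.tsv`. When `tally_file` (a TSV
#' with per-species `ntpp` and `sipl` wet-lab outcomes) is supplied, the
#' PAL report `pal_report.tsv` is written too, using the cascade's
#' `quality_pass` counts as the candidate numbers.
#'
#' @param fasta,qual,fastq input paths; give either `fastq` or `fasta`
#'   (with optional `qual`).
#' @param mid_file MID configuration TSV (default: the packaged newt
#'   tags).
#' @param outdir output directory (created if needed).
#' @param config a [cascade_config()].
#' @param max_mismatch MID mismatch allowance (default 0).
#' @param tally_file optional TSV with columns `species`, `ntpp`, `sipl`.
#' @return Invisibly, a list with `demux`, `cascade` and (if computed)
#'   `report`.
#' @export
run_mine <- function(fasta = NULL, qual = NULL, fastq = NULL,
                     mid_file = NULL, outdir = ".",
                     config = cascade_config(), max_mismatch = 0L,
                     tally_file = NULL) {
  if (is.null(fastq) && is.null(fasta)) stop("usage: give --fastq or --fasta input")
  df <- if (!is.null(fastq)) read_fastq_reads(fastq) else read_fasta_qual(fasta, qual)
  tags <- if (is.null(mid_file)) newt_mid_tags() else read_mid_tags(mid_file)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dm <- demultiplex(df, tags, max_mismatch = max_mismatch)
  counts <- as.data.frame(table(factor(dm$assigned$species,
                                       levels = sort(unique(tags$species)))),
                          stringsAsFactors = FALSE)
  names(counts) <- c("species", "n_reads")
  counts <- rbind(counts, data.frame(species = "unassigned",
                                     n_reads = nrow(dm$unassigned)))
  write.table(counts, file.path(outdir, "demux_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  casc <- run_cascade(dm$assigned, config)
  hits <- mine_reads(dm$assigned, config$unit_len, config$min_units)
  con <- file(file.path(outdir, "hits.tsv"), "w")
  writeLines("# start/end are 0-based half-open coordinates in the MID-trimmed read", con)
  write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write.table(casc$tallies, file.path(outdir, "cascade_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(casc$candidates, file.path(outdir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- list(demux = dm, cascade = casc)
  if (!is.null(tally_file)) {
    lab <- read.delim(tally_file, stringsAsFactors = FALSE)
    t <- merge(casc$tallies, lab, by = "species")
    tall <- data.frame(species = t$species, n_reads = t$n_reads,
                       n_repeat_reads = t$n_repeat_reads,
                       n_candidates = t$quality_pass,
                       ntpp = t$ntpp, sipl = t$sipl, stringsAsFactors = FALSE)
    out$report <- build_report(tall)
    write_report(out$report, file.path(outdir, "pal_report.tsv"))
  }
  invisible(out)
}

#' Estimate PALs and success rates from a tally table
#'
#' Thin wrapper over [read_tally()] and [build_report()] that also
#' writes TSV/JSON (and optionally Markdown) artifacts.
#'
#' @param tally_file tally TSV (see [read_tally()]).
#' @param outdir optional output directory for `pal_report.tsv` and
#'   `pal_report.json` (+ `pal_report.md` with `markdown = TRUE`).
#' @param markdown also render a Markdown table (default FALSE).
#' @return The report `data.frame`.
#' @export
run_estimate <- function(tally_file, outdir = NULL, markdown = FALSE) {
  report <- build_report(read_tally(tally_file))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(outdir, "pal_report.tsv"), "tsv")
    write_report(report, file.path(outdir, "pal_report.json"), "json")
    if (markdown) write_report(report, file.path(outdir, "pal_report.md"), "markdown")
  }
  report
}

#' Simulate a run and write its artifacts
#'
#' Writes `reads.fasta` + `reads.qual`, `reads.fastq`, `manifest.tsv`
#' and `expected_tally.tsv` into `outdir`. Deterministic under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @return Invisibly, the simulation list from [simulate_reads()].
#' @export
run_simulate <- function(config = sim_config(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reads(config)
  write_fasta_qual(sim$reads, file.path(outdir, "reads.fasta"),
                   file.path(outdir, "reads.qual"))
  write_fastq_reads(sim$reads, file.path(outdir, "reads.fastq"))
  write.table(sim$manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(expected_tally(sim$manifest),
              file.path(outdir, "expected_tally.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Summarize a genotype table and write the marker report
#'
#' @param genotype_file long-format genotype TSV (see
#'   [read_genotypes()]).
#' @param outdir optional output directory for `marker_summary.tsv`.
#' @param n_permutations,seed passed to [hwe_exact()].
#' @return The summary `data.frame` from [summarize_markers()].
#' @export
run_summarize_markers <- function(genotype_file, outdir = NULL,
                                  n_permutations = 10000L, seed = 1L) {
  g <- read_genotypes(genotype_file)
  s <- summarize_markers(g, n_permutations = n_permutations, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(s, file.path(outdir, "marker_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  s
}
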