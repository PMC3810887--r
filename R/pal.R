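#' SIPL/NTPP ratio
#'
#' Fraction of tested primer pairs (NTPP) that yielded successfully
#' isolated polymorphic loci (SIPL). This wet-lab yield is the basis of
#' the PAL extrapolation.
#'
#' @param sipl integer count(s) of successfully isolated polymorphic loci.
#' @param ntpp integer count(s) of tested primer pairs.
#' @return Numeric fraction(s) `sipl / ntpp`.
#' @examples
#' sipl_ntpp_ratio(11, 41)  # 0.2683 -> prints as 26.83%
#' @export
sipl_ntpp_ratio <- function(sipl, ntpp) {
  if (any(ntpp == 0)) stop("SIPL/NTPP ratio undefined: NTPP is zero")
  if (any(sipl < 0 | sipl > ntpp)) stop("require 0 <= SIPL <= NTPP")
  sipl / ntpp
}

#' Extrapolate potentially amplifiable loci (PALs)
#'
#' Scales the SIPL/NTPP ratio to the number of filter-passing candidate
#' sequences and rounds to the nearest integer, **with exact halves
#' rounded down**. Half-down is the rounding rule consistent with all
#' published values this pipeline reproduces (28.71 -> 29, 154.15 ->
#' 154, and the exact tie 217.5 -> 217); a small numeric guard keeps
#' rational ties such as 15/22 x 319 = 217.5 exact under floating point.
#'
#' @param ratio SIPL/NTPP fraction(s) in `[0, 1]`.
#' @param n_candidates integer candidate count(s).
#' @return Integer PAL count(s).
#' @examples
#' extrapolate_pals(11 / 41, 107)  # 29
#' extrapolate_pals(15 / 22, 319)  # 217.5 exactly -> 217
#' @export
extrapolate_pals <- function(ratio, n_candidates) {
  stopifnot(all(ratio >= 0 & ratio <= 1), all(n_candidates >= 0))
  y <- ratio * n_candidates
  as.integer(pmax(0, ceiling(y - 0.5 - 1e-9)))
}

#' Overall success rate
#'
#' Extrapolated PALs divided by the species' total read count.
#'
#' @param pals integer PAL count(s).
#' @param n_reads integer read count(s).
#' @return Numeric fraction(s).
#' @examples
#' success_rate(29, 19562)  # prints as 0.15%
#' @export
success_rate <- function(pals, n_reads) {
  if (any(n_reads == 0)) stop("success rate undefined: read count is zero")
  pals / n_reads
}

#' Round a fraction to a percentage, half-up
#'
#' @param x numeric fraction(s).
#' @param decimals digits after the decimal point (default 2).
#' @return Numeric percentage(s) rounded half-up.
#' @examples
#' percent_round(936 / 19562)  # 4.78
#' @export
percent_round <- function(x, decimals = 2L) {
  stopifnot(decimals >= 0)
  sgn <- ifelse(x < 0, -1, 1)
  v <- abs(x) * 100 * 10^decimals
  sgn * floor(v + 0.5 + 1e-9) / 10^decimals
}

#' Format a fraction as a percentage string
#'
#' Half-up rounding at the requested precision, with a trailing `%`.
#'
#' @inheritParams percent_round
#' @return Character vector like `"26.83%"`.
#' @examples
#' format_percent(11 / 41)         # "26.83%"
#' format_percent(80 / 128773, 3)  # "0.062%"
#' @export
format_percent <- function(x, decimals = 2L) {
  paste0(sprintf(paste0("%.", decimals, "f"), percent_round(x, decimals)), "%")
}

#' Read a species tally table
#'
#' Loads a TSV with one row per species and columns `species`,
#' `n_reads`, `n_repeat_reads`, `n_candidates`, `ntpp`, `sipl` (NTPP and
#' SIPL are wet-lab outcomes supplied by the user, not computed).
#'
#' @param path path to the tally TSV.
#' @return A validated tally `data.frame`.
#' @export
read_tally <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  validate_tally(t)
  t
}

validate_tally <- function(t) {
  need <- c("species", "n_reads", "n_repeat_reads", "n_candidates", "ntpp", "sipl")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("tally table missing column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(t))) {
    v <- t[i, ]
    chain <- c(sipl = v$sipl, ntpp = v$ntpp, n_candidates = v$n_candidates,
               n_repeat_reads = v$n_repeat_reads, n_reads = v$n_reads)
    if (any(chain < 0) || any(diff(chain) < 0)) {
      bad <- which(diff(chain) < 0)[1]
      stop("tally invariant violated for ", v$species, ": require 0 <= ",
           paste(names(chain), collapse = " <= "),
           if (!is.na(bad)) paste0(" (", names(chain)[bad], " > ",
                                   names(chain)[bad + 1L], ")"))
    }
  }
  invisible(t)
}

#' Build the per-species PAL report
#'
#' One row per species plus a pooled `Total` row, with the demultiplex
#' share of reads, the repeat-bearing share, the SIPL/NTPP ratio, the
#' extrapolated PAL count and the overall success rate. Formatted
#' percentage columns use half-up rounding at `decimals` digits. Pure
#' function of the tallies: identical input gives identical output.
#'
#' @param tallies a tally `data.frame` (see [read_tally()]).
#' @param decimals digits for the percentage columns (default 2).
#' @return A `data.frame` with numeric columns (`ratio`, `pals`,
#'   `success`) and formatted columns (`read_share_pct`,
#'   `repeat_share_pct`, `ratio_pct`, `success_pct`).
#' @examples
#' t <- data.frame(species = "T. cristatus", n_reads = 19562,
#'                 n_repeat_reads = 936, n_candidates = 107,
#'                 ntpp = 41, sipl = 11)
#' build_report(t)
#' @export
build_report <- function(tallies, decimals = 2L) {
  validate_tally(tallies)
  total_reads <- sum(tallies$n_reads)
  ratio <- sipl_ntpp_ratio(tallies$sipl, tallies$ntpp)
  pals <- extrapolate_pals(ratio, tallies$n_candidates)
  succ <- success_rate(pals, tallies$n_reads)
  rep <- data.frame(
    species = tallies$species,
    n_reads = tallies$n_reads,
    read_share_pct = format_percent(tallies$n_reads / total_reads, decimals),
    n_repeat_reads = tallies$n_repeat_reads,
    repeat_share_pct = format_percent(tallies$n_repeat_reads / tallies$n_reads,
                                      decimals),
    n_candidates = tallies$n_candidates,
    ntpp = tallies$ntpp,
    sipl = tallies$sipl,
    ratio = ratio,
    ratio_pct = format_percent(ratio, decimals),
    pals = pals,
    success = succ,
    success_pct = format_percent(succ, decimals),
    stringsAsFactors = FALSE
  )
  pooled_ratio <- sipl_ntpp_ratio(sum(tallies$sipl), sum(tallies$ntpp))
  pooled_pals <- sum(pals)
  pooled_succ <- success_rate(pooled_pals, total_reads)
  total <- data.frame(
    species = "Total",
    n_reads = total_reads,
    read_share_pct = format_percent(1, decimals),
    n_repeat_reads = sum(tallies$n_repeat_reads),
    repeat_share_pct = format_percent(sum(tallies$n_repeat_reads) / total_reads,
                                      decimals),
    n_candidates = sum(tallies$n_candidates),
    ntpp = sum(tallies$ntpp),
    sipl = sum(tallies$sipl),
    ratio = pooled_ratio,
    ratio_pct = format_percent(pooled_ratio, decimals),
    pals = pooled_pals,
    success = pooled_succ,
    success_pct = format_percent(pooled_succ, decimals),
    stringsAsFactors = FALSE
  )
  out <- rbind(rep, total)
  rownames(out) <- NULL
  out
}

#' Write a PAL report
#'
#' @param report a report `data.frame` from [build_report()].
#' @param path output path.
#' @param format `"tsv"`, `"json"`, or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA)
  } else {
    cols <- c("species", "n_reads", "n_repeat_reads", "n_candidates",
              "ntpp", "sipl", "ratio_pct", "pals", "success_pct")
    hdr <- c("Species", "Reads", "Repeat reads", "Candidates", "NTPP",
             "SIPL", "SIPL/NTPP", "PALs", "Success rate")
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
               vapply(seq_len(nrow(report)), function(i) {
                 paste0("| ", paste(unlist(report[i, cols]), collapse = " | "), " |")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
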