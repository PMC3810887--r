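#' Flank-length filter
#'
#' A candidate repeat needs at least `min_flank` bases of sequence on
#' each side of the repeat region for primers to bind ("at least" is
#' inclusive: 25/25 passes at the default).
#'
#' @param left_flank,right_flank integer vectors of flank lengths (bp).
#' @param min_flank minimum flank length (default 25).
#' @return Logical vector.
#' @export
check_flanks <- function(left_flank, right_flank, min_flank = 25L) {
  left_flank >= min_flank & right_flank >= min_flank
}

# longest single-base run in a string (0 for empty)
max_homopolymer_run <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(0L)
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Flank homopolymer filter
#'
#' Rejects a hit when either flank contains a single-base run longer
#' than `max_run` (default: runs of 6 or more fail). Only the flanks are
#' scanned: a perfect repeat of a minimal-period-4 motif cannot itself
#' contain a run longer than 5, and the screen targets primer regions.
#'
#' @param sequence the (MID-trimmed) read sequence.
#' @param start,end 0-based half-open coordinates of the repeat region.
#' @param max_run longest tolerated single-base run (default 5).
#' @return `TRUE` if both flanks are clean.
#' @export
check_homopolymer <- function(sequence, start, end, max_run = 5L) {
  left <- substr(sequence, 1L, start)
  right <- substr(sequence, end + 1L, nchar(sequence))
  max_homopolymer_run(left) <= max_run && max_homopolymer_run(right) <= max_run
}

#' Read-quality filter
#'
#' A read passes when its summary quality statistic is at least
#' `min_score` ("below 20 ... discarded": exactly 20 is kept). The
#' default statistic is the arithmetic mean of per-base scores over the
#' whole (MID-trimmed) read; `stat = "min"` instead requires every base
#' of `region` (or the whole read) to reach the threshold. Reads without
#' quality values pass, with a warning.
#'
#' @param quality integer vector of per-base scores, or `NULL`.
#' @param min_score quality threshold (default 20).
#' @param stat `"mean"` (default) or `"min"`.
#' @param region optional integer positions (1-based) to restrict the
#'   statistic to, e.g. flank positions.
#' @return `TRUE` or `FALSE`.
#' @export
check_quality <- function(quality, min_score = 20, stat = c("mean", "min"),
                          region = NULL) {
  stat <- match.arg(stat)
  if (is.null(quality)) {
    warning("read has no quality values; quality filter passes by default")
    return(TRUE)
  }
  if (!is.null(region)) quality <- quality[region]
  v <- if (stat == "mean") mean(quality) else min(quality)
  v >= min_score
}

#' Primer-screen configuration
#'
#' Thresholds of the simplified primer suitability screen. The screen is
#' deliberately not a Primer3 clone: it scans each flank for windows
#' whose nearest-neighbour melting temperature is closest to `opt_tm`,
#' subject to length, Tm window, GC fraction, homopolymer and 3'-end
#' complementarity constraints. Defaults mirror common Primer3 settings
#' (optimum 60 degrees C). The Tm model is pinned for reproducibility:
#' SantaLucia (1998) unified nearest-neighbour parameters, `na_mM`
#' monovalent salt entropy correction and `primer_nM` excess-primer
#' concentration.
#'
#' @param min_len,max_len primer length bounds (default 18-27).
#' @param opt_tm,min_tm,max_tm melting temperature optimum and window, in
#'   degrees C (defaults 60, 57, 63).
#' @param min_gc,max_gc GC-fraction bounds (defaults 0.20, 0.80).
#' @param max_run longest tolerated single-base run inside a primer
#'   (default 4).
#' @param gc_clamp require a G or C at the 3' terminus (default FALSE).
#' @param max_end_comp maximum consecutive complementary bases between
#'   the forward and reverse 3' ends (default 3).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param primer_nM primer concentration in nM (default 50).
#' @return A named list of class `primer_config`.
#' @export
primer_config <- function(min_len = 18L, max_len = 27L, opt_tm = 60,
                          min_tm = 57, max_tm = 63, min_gc = 0.20,
                          max_gc = 0.80, max_run = 4L, gc_clamp = FALSE,
                          max_end_comp = 3L, na_mM = 50, primer_nM = 50) {
  structure(list(min_len = min_len, max_len = max_len, opt_tm = opt_tm,
                 min_tm = min_tm, max_tm = max_tm, min_gc = min_gc,
                 max_gc = max_gc, max_run = max_run, gc_clamp = gc_clamp,
                 max_end_comp = max_end_comp, na_mM = na_mM,
                 primer_nM = primer_nM),
            class = "primer_config")
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH kcal/mol, dS cal/(mol K); keyed by top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbour melting temperature
#'
#' Duplex melting temperature from SantaLucia (1998) unified
#' nearest-neighbour thermodynamics with terminal initiation penalties,
#' an entropy salt correction of `0.368 (N-1) ln[Na+]`, and the
#' excess-primer concentration term `R ln(Ct)`. By duplex symmetry,
#' `primer_tm(revcomp(x)) == primer_tm(x)`.
#'
#' @param x character vector of primer sequences (ACGT).
#' @param na_mM monovalent cation concentration in mM.
#' @param primer_nM primer concentration in nM.
#' @return Numeric vector of melting temperatures in degrees C.
#' @examples
#' primer_tm("TAGCTGAGCGGCGAACCACT")  # ~60 C
#' @export
primer_tm <- function(x, na_mM = 50, primer_nM = 50) {
  if (any(grepl("[^ACGT]", x))) stop("primer sequences must be ACGT only")
  vapply(x, function(s) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    steps <- paste0(b[-n], b[-1L])
    dh <- sum(NN_DH[steps])
    ds <- sum(NN_DS[steps])
    for (t in b[c(1L, n)]) {
      if (t %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
    dh * 1000 / (ds + 1.987 * log(primer_nM * 1e-9)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Candidate primer windows in s (character vector form) restricted to
# 1-based inclusive positions [lo, hi]. Returns data.frame of windows
# passing the single-primer constraints, with Tm and GC.
# Cumulative-sum trick: window stacking energies, GC counts, N flags and
# homopolymer-run flags are all range sums over precomputed positions.
primer_windows <- function(b, lo, hi, cfg) {
  n_pos <- hi - lo + 1L
  if (n_pos < cfg$min_len) return(NULL)
  s <- b[lo:hi]
  n <- length(s)
  steps <- paste0(s[-n], s[-1L])
  known <- steps %in% names(NN_DH)
  dh <- ifelse(known, NN_DH[steps], NA_real_)
  ds <- ifelse(known, NN_DS[steps], NA_real_)
  cdh <- c(0, cumsum(ifelse(is.na(dh), 0, dh)))
  cds <- c(0, cumsum(ifelse(is.na(ds), 0, ds)))
  cN <- c(0L, cumsum(as.integer(s == "N")))
  cGC <- c(0L, cumsum(as.integer(s %in% c("G", "C"))))
  # run flag: position i starts a homopolymer of length max_run + 1
  rl <- cfg$max_run + 1L
  runflag <- integer(n)
  if (n >= rl) {
    same <- s[-n] == s[-1L]
    csame <- c(0L, cumsum(as.integer(same)))
    idx <- seq_len(n - rl + 1L)
    runflag[idx] <- as.integer(csame[idx + rl - 1L] - csame[idx] == rl - 1L)
  }
  crun <- c(0L, cumsum(runflag))
  out <- NULL
  for (len in cfg$min_len:min(cfg$max_len, n)) {
    a <- seq_len(n - len + 1L)       # window start, local 1-based
    z <- a + len - 1L                # window end
    has_n <- (cN[z + 1L] - cN[a]) > 0L
    bad_run <- (crun[pmin(z - rl + 2L, n + 1L)] - crun[a]) > 0L
    bad_run[z - rl + 2L <= a] <- FALSE
    gc <- (cGC[z + 1L] - cGC[a]) / len
    dh_w <- cdh[z] - cdh[a]
    ds_w <- cds[z] - cds[a]
    term <- matrix(c(s[a], s[z]), ncol = 2L)
    gc_term <- term %in% c("G", "C")
    dim(gc_term) <- dim(term)
    dh_w <- dh_w + ifelse(gc_term[, 1L], 0.1, 2.3) + ifelse(gc_term[, 2L], 0.1, 2.3)
    ds_w <- ds_w + ifelse(gc_term[, 1L], -2.8, 4.1) + ifelse(gc_term[, 2L], -2.8, 4.1)
    ds_w <- ds_w + 0.368 * (len - 1L) * log(cfg$na_mM / 1000)
    tm <- dh_w * 1000 / (ds_w + 1.987 * log(cfg$primer_nM * 1e-9)) - 273.15
    ok <- !has_n & !bad_run & gc >= cfg$min_gc & gc <= cfg$max_gc &
      tm >= cfg$min_tm & tm <= cfg$max_tm
    if (!any(ok)) next
    out <- rbind(out, data.frame(
      start = lo + a[ok] - 1L,       # 1-based in full sequence
      len = len, tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE))
  }
  out
}

# consecutive complementary bases between the two 3' ends
end_complementarity <- function(fwd, rev) {
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(chartr("ACGT", "TGCA", rev), "")[[1]]
  nf <- length(f); nr <- length(r)
  k <- 0L
  while (k < min(nf, nr) && f[nf - k] == r[nr - k]) k <- k + 1L
  k
}

#' Screen a candidate locus for a primer pair
#'
#' Scans the left flank for a forward primer and the right flank for a
#' reverse primer (reported 5'->3' on the opposite strand), each
#' confined entirely to its flank so the amplicon spans the repeat.
#' Windows must satisfy the single-primer constraints of
#' [primer_config()]; among admissible pairs with 3'-end
#' complementarity at most `max_end_comp`, the pair minimizing
#' `|Tm_f - opt| + |Tm_r - opt|` wins, ties broken by shorter amplicon,
#' then by leftmost forward position.
#'
#' @param sequence the (MID-trimmed) read sequence.
#' @param start,end 0-based half-open repeat-region coordinates.
#' @param config a [primer_config()].
#' @param top_k number of best windows per side to consider when pairing
#'   (default 25).
#' @return A one-row `data.frame` with `forward`, `reverse`, `fwd_start`,
#'   `rev_end` (0-based, half-open), `tm_forward`, `tm_reverse`,
#'   `gc_forward`, `gc_reverse`, `amplicon_len`; or `NULL` when no
#'   admissible pair exists.
#' @export
screen_primers <- function(sequence, start, end, config = primer_config(),
                           top_k = 25L) {
  b <- strsplit(toupper(sequence), "")[[1]]
  L <- length(b)
  if (start < config$min_len || L - end < config$min_len) return(NULL)
  fw <- primer_windows(b, 1L, start, config)            # left flank
  rv <- primer_windows(b, end + 1L, L, config)          # right flank
  if (is.null(fw) || is.null(rv)) return(NULL)
  if (config$gc_clamp) {
    # forward 3' end = window last base; reverse primer 3' end is the
    # complement of the window's first base (G/C closed under complement)
    fw <- fw[b[fw$start + fw$len - 1L] %in% c("G", "C"), , drop = FALSE]
    rv <- rv[b[rv$start] %in% c("G", "C"), , drop = FALSE]
    if (!nrow(fw) || !nrow(rv)) return(NULL)
  }
  fw <- fw[order(abs(fw$tm - config$opt_tm), fw$start, fw$len), , drop = FALSE]
  rv <- rv[order(abs(rv$tm - config$opt_tm), rv$start, rv$len), , drop = FALSE]
  fw <- utils::head(fw, top_k)
  rv <- utils::head(rv, top_k)
  best <- NULL
  for (i in seq_len(nrow(fw))) {
    f_seq <- paste(b[fw$start[i]:(fw$start[i] + fw$len[i] - 1L)], collapse = "")
    for (j in seq_len(nrow(rv))) {
      r_window <- paste(b[rv$start[j]:(rv$start[j] + rv$len[j] - 1L)], collapse = "")
      r_seq <- revcomp(r_window)
      if (end_complementarity(f_seq, r_seq) > config$max_end_comp) next
      score <- abs(fw$tm[i] - config$opt_tm) + abs(rv$tm[j] - config$opt_tm)
      amp <- (rv$start[j] + rv$len[j] - 1L) - (fw$start[i] - 1L)
      cand <- list(score = score, amp = amp, i = i, j = j,
                   f_seq = f_seq, r_seq = r_seq)
      if (is.null(best) ||
          score < best$score - 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (amp < best$amp ||
            (amp == best$amp && fw$start[i] < fw$start[best$i])))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  i <- best$i; j <- best$j
  data.frame(
    forward = best$f_seq, reverse = best$r_seq,
    fwd_start = fw$start[i] - 1L,                  # 0-based
    rev_end = rv$start[j] + rv$len[j] - 1L,        # 0-based half-open end
    tm_forward = fw$tm[i], tm_reverse = rv$tm[j],
    gc_forward = fw$gc[i], gc_reverse = rv$gc[j],
    amplicon_len = best$amp, stringsAsFactors = FALSE
  )
}

#' Cascade configuration
#'
#' Threshold block for [run_cascade()]. Defaults are the published
#' screening criteria: tetra-nucleotide motifs with at least 10
#' uninterrupted units, flanks of at least 25 bp, no flank homopolymer
#' run over 5 bases, and mean read quality of at least 20 (of a maximum
#' of 40).
#'
#' @param unit_len repeat unit length (default 4).
#' @param min_units minimum complete repeat units (default 10).
#' @param min_flank minimum flank length in bp (default 25).
#' @param max_homopolymer longest tolerated flank homopolymer (default 5).
#' @param min_quality quality threshold (default 20).
#' @param quality_stat `"mean"` over the read (default) or `"min"` over
#'   flank bases.
#' @param primer a [primer_config()].
#' @param screen run the primer screen stage (default TRUE).
#' @return A named list of class `cascade_config`.
#' @export
cascade_config <- function(unit_len = 4L, min_units = 10L, min_flank = 25L,
                           max_homopolymer = 5L, min_quality = 20,
                           quality_stat = c("mean", "min"),
                           primer = primer_config(), screen = TRUE) {
  quality_stat <- match.arg(quality_stat)
  stopifnot(unit_len > 0, min_units > 1, min_flank > 0, max_homopolymer > 0,
            min_quality > 0)
  structure(list(unit_len = unit_len, min_units = min_units,
                 min_flank = min_flank, max_homopolymer = max_homopolymer,
                 min_quality = min_quality, quality_stat = quality_stat,
                 primer = primer, screen = screen),
            class = "cascade_config")
}

#' Run the candidate filter cascade
#'
#' Applies, in order: repeat mining, primary-hit selection, the flank
#' length filter, the flank homopolymer filter, the read quality filter
#' and (optionally) the primer screen. Emits per-stage survivor counts
#' per species; survivor sets are nested across stages. Reads lacking
#' quality values pass the quality stage (one summary warning).
#'
#' @param df a demultiplexed, MID-trimmed read `data.frame` with a
#'   `species` column.
#' @param config a [cascade_config()].
#' @return A list with `candidates` (one row per repeat-bearing read:
#'   hit fields, per-filter outcomes, `stage_reached` in
#'   `mined < flank_pass < clean_flanks < quality_pass < primer_designed`,
#'   and primer fields where designed) and `tallies` (per-species stage
#'   counts: `n_reads`, `n_repeat_reads`, `flank_pass`, `clean_flanks`,
#'   `quality_pass`, `primer_designed`).
#' @export
run_cascade <- function(df, config = cascade_config()) {
  validate_reads(df)
  if (!"species" %in% names(df)) stop("reads must carry a species column")
  species_levels <- sort(unique(df$species))
  cand <- NULL
  n_noqual <- 0L
  for (i in seq_len(nrow(df))) {
    hits <- find_perfect_repeats(df$sequence[i], config$unit_len, config$min_units)
    if (!nrow(hits)) next
    h <- select_primary_hit(hits)
    seq_i <- df$sequence[i]
    q <- df$quality[[i]]
    flank_ok <- check_flanks(h$left_flank, h$right_flank, config$min_flank)
    homopolymer_ok <- flank_ok &&
      check_homopolymer(seq_i, h$start, h$end, config$max_homopolymer)
    quality_ok <- FALSE
    if (homopolymer_ok) {
      if (is.null(q)) {
        n_noqual <- n_noqual + 1L
        quality_ok <- TRUE
      } else {
        region <- if (config$quality_stat == "min") {
          c(seq_len(h$start), seq(h$end + 1L, nchar(seq_i)))
        } else NULL
        quality_ok <- check_quality(q, config$min_quality,
                                    stat = config$quality_stat, region = region)
      }
    }
    primer <- NULL
    if (quality_ok && config$screen) {
      primer <- screen_primers(seq_i, h$start, h$end, config$primer)
    }
    stage <- if (!flank_ok) "mined"
      else if (!homopolymer_ok) "flank_pass"
      else if (!quality_ok) "clean_flanks"
      else if (config$screen && is.null(primer)) "quality_pass"
      else if (config$screen) "primer_designed"
      else "quality_pass"
    row <- cbind(
      read_id = df$read_id[i], species = df$species[i], h,
      flank_ok = flank_ok, homopolymer_ok = homopolymer_ok,
      quality_ok = quality_ok, stage_reached = stage,
      stringsAsFactors = FALSE)
    if (!is.null(primer)) row <- cbind(row, primer) else {
      row <- cbind(row, data.frame(
        forward = NA_character_, reverse = NA_character_,
        fwd_start = NA_integer_, rev_end = NA_integer_,
        tm_forward = NA_real_, tm_reverse = NA_real_,
        gc_forward = NA_real_, gc_reverse = NA_real_,
        amplicon_len = NA_integer_, stringsAsFactors = FALSE))
    }
    cand <- rbind(cand, row)
  }
  if (n_noqual > 0L) {
    warning(n_noqual, " read(s) had no quality values; quality filter passed by default")
  }
  if (is.null(cand)) {
    cand <- cbind(read_id = character(), species = character(), empty_hits(),
                  data.frame(flank_ok = logical(), homopolymer_ok = logical(),
                             quality_ok = logical(), stage_reached = character(),
                             forward = character(), reverse = character(),
                             fwd_start = integer(), rev_end = integer(),
                             tm_forward = numeric(), tm_reverse = numeric(),
                             gc_forward = numeric(), gc_reverse = numeric(),
                             amplicon_len = integer(), stringsAsFactors = FALSE))
  }
  cand <- cand[order(cand$species, cand$read_id), , drop = FALSE]
  rownames(cand) <- NULL
  stage_rank <- c(mined = 1L, flank_pass = 2L, clean_flanks = 3L,
                  quality_pass = 4L, primer_designed = 5L)
  tallies <- do.call(rbind, lapply(species_levels, function(sp) {
    r <- stage_rank[cand$stage_reached[cand$species == sp]]
    data.frame(
      species = sp,
      n_reads = sum(df$species == sp),
      n_repeat_reads = length(r),
      flank_pass = sum(r >= 2L),
      clean_flanks = sum(r >= 3L),
      quality_pass = sum(r >= 4L),
      primer_designed = sum(r >= 5L),
      stringsAsFactors = FALSE)
  }))
  if (is.null(tallies)) {
    tallies <- data.frame(species = character(), n_reads = integer(),
                          n_repeat_reads = integer(), flank_pass = integer(),
                          clean_flanks = integer(), quality_pass = integer(),
                          primer_designed = integer(), stringsAsFactors = FALSE)
  }
  rownames(tallies) <- NULL
  list(candidates = cand, tallies = tallies)
}
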