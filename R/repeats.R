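#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGTN strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical motif class of a repeat unit
#'
#' Tandem-repeat motifs are equivalent under cyclic rotation (the same
#' physical run can be read in any phase) and reverse complement (the
#' same locus read off the other strand). The canonical representative
#' is the lexicographically smallest string among the `k` rotations of
#' the motif and the `k` rotations of its reverse complement, so e.g.
#' `GATA`, `ATAG`, `TATC` and `AGAT` all map to `AGAT`. Idempotent.
#'
#' @param motif character vector of DNA motifs (alphabet `A,C,G,T`).
#' @return Character vector of canonical motifs, same length as input.
#' @examples
#' canonical_motif(c("GATA", "AAAA", "CTAG"))
#' @export
canonical_motif <- function(motif) {
  if (any(grepl("[^ACGT]", motif))) {
    stop("motifs must be over {A,C,G,T}: ", motif[grepl("[^ACGT]", motif)][1])
  }
  vapply(motif, function(m) {
    k <- nchar(m)
    strands <- c(m, revcomp(m))
    variants <- unlist(lapply(strands, function(v) {
      b <- strsplit(v, "")[[1]]
      vapply(seq_len(k) - 1L, function(r) {
        paste(b[((seq_len(k) - 1L + r) %% k) + 1L], collapse = "")
      }, character(1))
    }))
    min(variants)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if the motif's minimal period equals its length (i.e. it is not a
# repetition of a shorter unit). Only proper divisors can be periods of a
# string repeated indefinitely.
has_full_period <- function(motif) {
  k <- nchar(motif)
  b <- strsplit(motif, "")[[1]]
  for (p in seq_len(k - 1L)) {
    if (k %% p != 0L) next
    if (all(b == b[((seq_len(k) - 1L) %% p) + 1L])) return(FALSE)
  }
  TRUE
}

empty_hits <- function() {
  data.frame(motif = character(), canonical_motif = character(),
             unit_count = integer(), start = integer(), end = integer(),
             left_flank = integer(), right_flank = integer(),
             stringsAsFactors = FALSE)
}

#' Find maximal perfect tandem repeats in a sequence
#'
#' Detects every maximal run of an exactly repeated `unit_len`-mer whose
#' complete-unit count is at least `min_units` and whose motif has
#' minimal period exactly `unit_len` (so homopolymer runs and
#' dinucleotide-type repeats written as tetramers are rejected). Runs are
#' maximal: they cannot be extended by one base on either side as an
#' exact continuation of the periodic pattern. `end` includes trailing
#' partial-unit bases that continue the period; `unit_count` counts
#' complete units only. One hit is reported per physical run (leftmost
#' phase). `N` never matches inside a repeat.
#'
#' Coordinates are 0-based half-open, so `left_flank = start` and
#' `right_flank = nchar(sequence) - end`.
#'
#' @param sequence a single DNA string over `A,C,G,T,N`.
#' @param unit_len repeat unit length (default 4, tetra-nucleotides).
#' @param min_units minimum number of complete units (default 10).
#' @return A `data.frame` with columns `motif`, `canonical_motif`,
#'   `unit_count`, `start`, `end`, `left_flank`, `right_flank`, sorted by
#'   `start`; zero rows when there is no hit.
#' @examples
#' find_perfect_repeats(paste0(strrep("C", 5), strrep("AGAT", 10)), 4, 10)
#' @export
find_perfect_repeats <- function(sequence, unit_len = 4L, min_units = 10L) {
  stopifnot(length(sequence) == 1L, unit_len >= 1L, min_units >= 2L)
  sequence <- toupper(sequence)
  s <- strsplit(sequence, "")[[1]]
  L <- length(s)
  if (L < unit_len * min_units) return(empty_hits())
  a <- s[seq_len(L - unit_len)]
  b <- s[(unit_len + 1L):L]
  ok <- a == b & a != "N"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths + unit_len >= unit_len * min_units
  if (!any(keep)) return(empty_hits())
  st <- starts[keep]
  len <- r$lengths[keep] + unit_len
  motif <- substr(rep(sequence, length(st)), st, st + unit_len - 1L)
  units <- len %/% unit_len
  full <- vapply(motif, has_full_period, logical(1), USE.NAMES = FALSE)
  sel <- full & units >= min_units
  if (!any(sel)) return(empty_hits())
  st <- st[sel]; len <- len[sel]; motif <- motif[sel]; units <- units[sel]
  data.frame(
    motif = motif,
    canonical_motif = canonical_motif(motif),
    unit_count = as.integer(units),
    start = as.integer(st - 1L),
    end = as.integer(st - 1L + len),
    left_flank = as.integer(st - 1L),
    right_flank = as.integer(L - (st - 1L + len)),
    stringsAsFactors = FALSE
  )
}

#' Mine repeats across a read table
#'
#' Runs [find_perfect_repeats()] on every read and binds the hits with
#' `read_id` and `species` columns.
#'
#' @param df a read `data.frame` (MID-trimmed).
#' @inheritParams find_perfect_repeats
#' @return A hit `data.frame` with `read_id` and `species` prepended.
#' @export
mine_reads <- function(df, unit_len = 4L, min_units = 10L) {
  validate_reads(df)
  out <- lapply(seq_len(nrow(df)), function(i) {
    h <- find_perfect_repeats(df$sequence[i], unit_len, min_units)
    if (!nrow(h)) return(NULL)
    cbind(read_id = df$read_id[i],
          species = if ("species" %in% names(df)) df$species[i] else NA_character_,
          h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(read_id = character(), species = character(), empty_hits())
  }
  rownames(out) <- NULL
  out
}

#' Select the primary repeat hit of a read
#'
#' One primer pair is designed per read, so multi-repeat reads are
#' reduced to a single hit: the largest `unit_count`, ties broken by
#' smallest `start`.
#'
#' @param hits a hit `data.frame`, all rows from the same read.
#' @return A one-row hit `data.frame`, or `NULL` for empty input.
#' @export
select_primary_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if ("read_id" %in% names(hits) && length(unique(hits$read_id)) > 1L) {
    stop("select_primary_hit expects hits from a single read")
  }
  ord <- order(-hits$unit_count, hits$start)
  hits[ord[1L], , drop = FALSE]
}
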