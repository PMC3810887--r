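#' Construct a read table
#'
#' Reads are kept in a plain `data.frame` with one row per read:
#' `read_id` (character), `sequence` (uppercase DNA over `A,C,G,T,N`),
#' `quality` (list column of integer Phred-like scores in `[0, 40]`, or
#' `NULL` per read when absent) and `species` (character, `NA` before
#' demultiplexing).
#'
#' @param read_id character vector of identifiers.
#' @param sequence character vector of DNA sequences (uppercased).
#' @param quality optional list of integer vectors, one per read, each the
#'   same length as its sequence; or `NULL`.
#' @param species optional character vector of species labels.
#' @return A validated read `data.frame`.
#' @examples
#' reads(c("r1", "r2"), c("ACGT", "GGGTT"))
#' @export
reads <- function(read_id, sequence, quality = NULL, species = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (is.null(quality)) quality <- rep(list(NULL), length(sequence))
  df <- data.frame(
    read_id = as.character(read_id),
    sequence = sequence,
    species = rep_len(as.character(species), length(sequence)),
    stringsAsFactors = FALSE
  )
  df$quality <- quality
  validate_reads(df)
  df
}

validate_reads <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("read_id", "sequence", "quality") %in% names(df)))
  bad <- grepl("[^ACGTN]", df$sequence) | !nzchar(df$sequence)
  if (any(bad)) {
    stop("invalid sequence (empty or non-ACGTN) for read(s): ",
         paste(utils::head(df$read_id[bad], 5), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    q <- df$quality[[i]]
    if (is.null(q)) next
    if (length(q) != nchar(df$sequence[i])) {
      stop("quality length != sequence length for read ", df$read_id[i])
    }
    if (any(q < 0L | q > 40L)) {
      stop("quality values outside [0, 40] for read ", df$read_id[i])
    }
  }
  invisible(df)
}

empty_reads <- function() {
  df <- data.frame(read_id = character(), sequence = character(),
                   species = character(), stringsAsFactors = FALSE)
  df$quality <- list()
  df
}

#' Read sequences from FASTA with an optional 454-style QUAL file
#'
#' The QUAL file follows the 454 convention: FASTA-like headers with
#' whitespace-separated integer Phred scores per record. Record IDs and
#' lengths must match the FASTA one-to-one, in order.
#'
#' @param path_fasta path to a FASTA file.
#' @param path_qual optional path to the matching QUAL file.
#' @return A read `data.frame` (see [reads()]), in file order.
#' @export
read_fasta_qual <- function(path_fasta, path_qual = NULL) {
  if (file.size(path_fasta) == 0) return(empty_reads())
  dna <- Biostrings::readDNAStringSet(path_fasta)
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- toupper(as.character(dna))
  qual <- rep(list(NULL), length(dna))
  if (!is.null(path_qual)) {
    ql <- parse_qual(path_qual)
    if (!identical(names(ql), ids)) {
      stop("FASTA/QUAL record IDs do not match (first difference: ",
           ids[which(ids != names(ql))[1]], " vs ",
           names(ql)[which(ids != names(ql))[1]], ")")
    }
    len_ok <- lengths(ql) == nchar(seqs)
    if (!all(len_ok)) {
      stop("FASTA/QUAL length mismatch for record ", ids[!len_ok][1])
    }
    qual <- unname(ql)
  }
  reads(ids, seqs, qual)
}

# 454 QUAL dialect: ">id" header lines, integer score lines.
parse_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("malformed QUAL file: no leading '>' in ", path)
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  out <- lapply(split(lines[!hdr], rec[!hdr]), function(x) {
    v <- suppressWarnings(as.integer(strsplit(paste(x, collapse = " "), "\\s+")[[1]]))
    v[!is.na(v)]
  })
  setNames(out[as.character(seq_along(ids))], ids)
}

#' Read a Sanger-offset FASTQ file
#'
#' Qualities above the 454 ceiling of 40 are clipped to 40 with a warning.
#'
#' @param path path to a FASTQ file (Phred+33).
#' @return A read `data.frame` (see [reads()]).
#' @export
read_fastq_reads <- function(path) {
  if (file.size(path) == 0) return(empty_reads())
  dna <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(dna))
  qstr <- as.character(mcols(dna)$qualities)
  qual <- lapply(qstr, function(s) as.integer(charToRaw(s)) - 33L)
  clipped <- vapply(qual, function(q) any(q > 40L), logical(1))
  if (any(clipped)) {
    warning(sum(clipped), " read(s) had quality > 40; clipped to 40 (454 ceiling)")
    qual <- lapply(qual, function(q) pmin(q, 40L))
  }
  reads(ids, toupper(as.character(dna)), qual)
}

#' Write reads to FASTA (and optionally a 454-style QUAL file)
#'
#' @param df a read `data.frame`.
#' @param path_fasta output FASTA path.
#' @param path_qual optional output QUAL path; requires all reads to carry
#'   quality values.
#' @return Invisibly, the paths written.
#' @export
write_fasta_qual <- function(df, path_fasta, path_qual = NULL) {
  validate_reads(df)
  dna <- Biostrings::DNAStringSet(setNames(df$sequence, df$read_id))
  Biostrings::writeXStringSet(dna, path_fasta)
  if (!is.null(path_qual)) {
    if (any(vapply(df$quality, is.null, logical(1)))) {
      stop("cannot write QUAL: some reads lack quality values")
    }
    con <- file(path_qual, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(c(paste0(">", df$read_id[i]),
                   paste(df$quality[[i]], collapse = " ")), con)
    }
  }
  invisible(c(path_fasta, path_qual))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param df a read `data.frame`; all reads must carry quality values.
#' @param path output FASTQ path.
#' @return Invisibly, the path written.
#' @export
write_fastq_reads <- function(df, path) {
  validate_reads(df)
  if (any(vapply(df$quality, is.null, logical(1)))) {
    stop("cannot write FASTQ: some reads lack quality values")
  }
  dna <- Biostrings::DNAStringSet(setNames(df$sequence, df$read_id))
  qs <- Biostrings::BStringSet(vapply(
    df$quality, function(q) rawToChar(as.raw(q + 33L)), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' MID barcode configurations
#'
#' `read_mid_tags()` loads a two-column TSV (`species`, `tag`);
#' `newt_mid_tags()` returns the packaged six-tag set used for the three
#' newt species libraries (two 11-bp Roche Rapid Library MIDs per
#' species). Every configuration is checked for prefix ambiguity: no tag
#' may be a prefix of another (nor duplicated).
#'
#' @param path path to a TSV with columns `species` and `tag`.
#' @return A `data.frame` with columns `species`, `tag`.
#' @export
read_mid_tags <- function(path) {
  tags <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "tag") %in% names(tags))) {
    stop("MID table needs columns 'species' and 'tag'")
  }
  tags$tag <- toupper(tags$tag)
  validate_mid_tags(tags)
  tags
}

#' @rdname read_mid_tags
#' @export
newt_mid_tags <- function() {
  read_mid_tags(system.file("extdata", "mid_tags.tsv", package = "palmine"))
}

#' @rdname read_mid_tags
#' @param tags a MID configuration `data.frame`.
#' @export
validate_mid_tags <- function(tags) {
  stopifnot(all(c("species", "tag") %in% names(tags)))
  if (any(grepl("[^ACGT]", tags$tag))) stop("MID tags must be ACGT only")
  if (anyDuplicated(tags$tag)) {
    stop("ambiguous MID configuration: duplicated tag ",
         tags$tag[duplicated(tags$tag)][1])
  }
  for (i in seq_len(nrow(tags))) {
    pre <- startsWith(tags$tag, tags$tag[i])
    pre[i] <- FALSE
    if (any(pre)) {
      stop("ambiguous MID configuration: tag ", tags$tag[i],
           " is a prefix of ", tags$tag[pre][1])
    }
  }
  invisible(tags)
}

#' Assign reads to species by MID barcode
#'
#' Matches each tag as a prefix of the read sequence. The default policy
#' is exact (0 mismatches); `max_mismatch` allows limited tolerance for
#' robustness experiments. `N` bases never match a tag base. If more than
#' one species matches (possible only with `max_mismatch > 0`) the read
#' is left unassigned.
#'
#' @param sequence character vector of read sequences.
#' @param tags MID configuration (see [read_mid_tags()]).
#' @param max_mismatch maximum mismatches allowed in the tag prefix
#'   (default 0).
#' @return Character vector of species labels, `"unassigned"` where no
#'   (unique) tag matches.
#' @export
assign_species <- function(sequence, tags, max_mismatch = 0L) {
  validate_mid_tags(tags)
  out <- rep("unassigned", length(sequence))
  n_mm <- matrix(NA_integer_, length(sequence), nrow(tags))
  for (j in seq_len(nrow(tags))) {
    tg <- strsplit(tags$tag[j], "")[[1]]
    pre <- substr(sequence, 1L, length(tg))
    n_mm[, j] <- vapply(strsplit(pre, ""), function(b) {
      if (length(b) < length(tg)) return(length(tg))  # read shorter than tag
      sum(b != tg | b == "N")
    }, integer(1))
  }
  hit <- n_mm <= max_mismatch
  n_hit_species <- vapply(seq_len(nrow(hit)), function(i) {
    length(unique(tags$species[hit[i, ]]))
  }, integer(1))
  one <- n_hit_species == 1L
  out[one] <- vapply(which(one), function(i) tags$species[hit[i, ]][1], character(1))
  out
}

#' Trim a MID tag off the start of a read
#'
#' Removes the tag bases (and the matching quality positions) from a
#' single read; the tag must be an exact prefix.
#'
#' @param read a one-row read `data.frame`.
#' @param tag the tag sequence (character scalar).
#' @return The trimmed one-row read `data.frame`.
#' @export
trim_mid <- function(read, tag) {
  stopifnot(nrow(read) == 1L)
  if (!startsWith(read$sequence, tag)) {
    stop("tag ", tag, " is not a prefix of read ", read$read_id)
  }
  k <- nchar(tag)
  read$sequence <- substr(read$sequence, k + 1L, nchar(read$sequence))
  if (!is.null(read$quality[[1]])) {
    read$quality[[1]] <- read$quality[[1]][-seq_len(k)]
  }
  read
}

#' Demultiplex reads by MID barcode
#'
#' Assigns every read to a species (or leaves it unassigned), optionally
#' trimming the matched barcode and its quality positions. Every input
#' read lands in exactly one bucket and input order is preserved.
#'
#' @param df a read `data.frame`.
#' @param tags MID configuration (see [read_mid_tags()]).
#' @param max_mismatch see [assign_species()]. Trimming with mismatches
#'   removes the matched tag's length.
#' @param trim trim the matched barcode off assigned reads (default TRUE).
#' @return A list with `assigned` (read `data.frame` with `species`
#'   filled) and `unassigned` (read `data.frame`).
#' @export
demultiplex <- function(df, tags, max_mismatch = 0L, trim = TRUE) {
  validate_reads(df)
  sp <- assign_species(df$sequence, tags, max_mismatch)
  assigned <- df[sp != "unassigned", , drop = FALSE]
  assigned$species <- sp[sp != "unassigned"]
  unassigned <- df[sp == "unassigned", , drop = FALSE]
  if (trim && nrow(assigned)) {
    # with max_mismatch 0 the matching tag is the literal prefix; with
    # tolerance, re-derive the matched tag per read
    tag_of <- function(seq_i, sp_i) {
      cand <- tags$tag[tags$species == sp_i]
      for (tg in cand) {
        b <- strsplit(substr(seq_i, 1, nchar(tg)), "")[[1]]
        t <- strsplit(tg, "")[[1]]
        if (length(b) == length(t) && sum(b != t | b == "N") <= max_mismatch) return(tg)
      }
      stop("internal: no tag re-matched")
    }
    for (i in seq_len(nrow(assigned))) {
      tg <- tag_of(assigned$sequence[i], assigned$species[i])
      k <- nchar(tg)
      assigned$sequence[i] <- substr(assigned$sequence[i], k + 1L,
                                     nchar(assigned$sequence[i]))
      if (!is.null(assigned$quality[[i]])) {
        assigned$quality[[i]] <- assigned$quality[[i]][-seq_len(k)]
      }
    }
  }
  rownames(assigned) <- rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}
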