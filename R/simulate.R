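#' The thirteen tetra-nucleotide enrichment probe motifs
#'
#' Motif pool used for library enrichment; all have minimal period 4.
#' These are the default planted motifs of the simulator.
#'
#' @return Character vector of 13 motifs.
#' @export
enrichment_probe_motifs <- function() {
  c("AAGT", "AGAT", "ACAT", "AAAT", "AACT", "AAAC", "AAAG",
    "AATC", "ACAG", "ACTC", "ACTG", "AATG", "ACCT")
}

#' Simulation configuration
#'
#' Describes a 454-like run with planted tetra-nucleotide repeats and
#' margin-separated decoy classes so every read's fate in the filter
#' cascade is provable from the manifest. Decoy classes:
#' `sub_threshold` (planted repeat of 5-9 units, drops at mining),
#' `interrupted` (two 5-9-unit halves split by one non-continuing base,
#' drops at mining), `short_flank` (one flank of `min_flank - 1` bp),
#' `homopolymer_flank` (a planted 6-base run in one flank),
#' `low_quality` (mean read quality drawn at `low_quality_mean`). The
#' remaining planted reads are full candidates (>= 10 units, flanks >=
#' `flank_min`, clean flanks, mean quality ~ `quality_mean`); all other
#' reads are repeat-free background.
#'
#' @param seed RNG seed.
#' @param species `data.frame` with columns `species`, `tag`, `n_reads`;
#'   default: the three newt libraries, first MID each, 1000 reads each.
#' @param read_length length-2 integer range of total read length
#'   (including the MID), default `c(200, 600)`.
#' @param repeat_incidence fraction of reads carrying a fully qualifying
#'   planted repeat (default 0.03, echoing the observed 2-5 percent
#'   repeat-bearing rates).
#' @param motif_pool planted motifs (default [enrichment_probe_motifs()]).
#' @param unit_count length-2 range of planted complete units; values
#'   below 10 are used by the sub-threshold decoy class, values >= 10 by
#'   qualifying classes (default `c(5, 30)`).
#' @param flank_min minimum planted flank for passing reads (default 26,
#'   one margin above the 25-bp filter).
#' @param decoy_mix named fractions for the five decoy classes (defaults
#'   0.01 each); `repeat_incidence + sum(decoy_mix)` must be <= 1.
#' @param quality_mean,quality_sd per-read mean quality distribution for
#'   normal reads (default 30, 3).
#' @param quality_jitter per-base jitter s.d. (default 2).
#' @param low_quality_mean per-read mean for low-quality decoys
#'   (default 15).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species = NULL,
                       read_length = c(200L, 600L),
                       repeat_incidence = 0.03,
                       motif_pool = enrichment_probe_motifs(),
                       unit_count = c(5L, 30L),
                       flank_min = 26L,
                       decoy_mix = c(sub_threshold = 0.01, interrupted = 0.01,
                                     short_flank = 0.01,
                                     homopolymer_flank = 0.01,
                                     low_quality = 0.01),
                       quality_mean = 30, quality_sd = 3,
                       quality_jitter = 2, low_quality_mean = 15) {
  if (is.null(species)) {
    tags <- newt_mid_tags()
    first <- tags[!duplicated(tags$species), ]
    species <- data.frame(species = first$species, tag = first$tag,
                          n_reads = 1000L, stringsAsFactors = FALSE)
  }
  need <- c("sub_threshold", "interrupted", "short_flank",
            "homopolymer_flank", "low_quality")
  stopifnot(all(need %in% names(decoy_mix)),
            all(decoy_mix >= 0), all(decoy_mix <= 1),
            repeat_incidence >= 0, repeat_incidence + sum(decoy_mix) <= 1)
  if (any(!vapply(motif_pool, has_full_period, logical(1))) ||
      any(nchar(motif_pool) != 4L)) {
    stop("motif_pool must contain tetramers of minimal period 4")
  }
  mid_len <- max(nchar(species$tag))
  need_len <- mid_len + 4L * max(unit_count) + 2L * (flank_min + 2L)
  if (read_length[2] < need_len) {
    stop("infeasible config: max read length ", read_length[2],
         " < MID + repeat + flanks (", need_len, ")")
  }
  structure(list(seed = seed, species = species, read_length = read_length,
                 repeat_incidence = repeat_incidence, motif_pool = motif_pool,
                 unit_count = unit_count, flank_min = flank_min,
                 decoy_mix = decoy_mix[need], quality_mean = quality_mean,
                 quality_sd = quality_sd, quality_jitter = quality_jitter,
                 low_quality_mean = low_quality_mean),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# i.i.d. uniform ACGT string; rejection-sampled so it contains no
# perfect tetra repeat of >= reject_units complete units and (optionally)
# no homopolymer run > max_run
rand_clean_seq <- function(n, reject_units = 10L, max_run = 5L) {
  if (n == 0L) return("")
  repeat {
    b <- sample(BASES, n, replace = TRUE)
    if (!is.null(max_run) && n > max_run) {
      r <- rle(b)
      if (max(r$lengths) > max_run) next
    }
    s <- paste(b, collapse = "")
    if (n >= 4L * reject_units &&
        nrow(find_perfect_repeats(s, 4L, reject_units))) next
    return(s)
  }
}

# resample the junction base(s) of a flank so it cannot periodically
# extend the adjacent repeat, while keeping homopolymer runs <= max_run
fix_junction <- function(flank, side, forbidden, max_run = 5L) {
  if (!nzchar(flank)) return(flank)
  b <- strsplit(flank, "")[[1]]
  pos <- if (side == "left") length(b) else 1L
  repeat {
    cur <- b[pos]
    if (!cur %in% forbidden) {
      # also re-check run constraint around the junction base
      r <- rle(b)
      if (max(r$lengths) <= max_run) break
    }
    b[pos] <- sample(BASES, 1L)
  }
  paste(b, collapse = "")
}

# plant a homopolymer run of exactly len bases at an interior position
plant_homopolymer <- function(flank, len = 6L) {
  b <- strsplit(flank, "")[[1]]
  n <- length(b)
  stopifnot(n >= len + 4L)
  pos <- sample(2L:(n - len - 1L), 1L)       # keep first/last base untouched
  base <- sample(BASES, 1L)
  b[pos:(pos + len - 1L)] <- base
  # neighbours must differ so the run is exactly len
  if (b[pos - 1L] == base) b[pos - 1L] <- sample(setdiff(BASES, base), 1L)
  if (b[pos + len] == base) b[pos + len] <- sample(setdiff(BASES, base), 1L)
  paste(b, collapse = "")
}

#' Simulate a 454-like run with a ground-truth manifest
#'
#' Generates MID-prefixed reads per species with planted repeats and
#' decoys as configured (see [sim_config()]), plus a manifest recording
#' every read's planted attributes: class, motif, complete unit count,
#' repeat coordinates (0-based half-open, in MID-trimmed coordinates),
#' flank lengths, largest flank homopolymer run, and realized mean
#' quality of the trimmed read. Background flanks are rejection-sampled
#' to contain no qualifying tetra repeat and no homopolymer run over 5,
#' and the flank base adjacent to a planted repeat never continues its
#' period, so the manifest values are exact, not merely probable.
#' Reproducible: the same config (including seed) yields identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A list with `reads` (a read `data.frame`, MID untrimmed) and
#'   `manifest` (a `data.frame`, one row per read).
#' @export
simulate_reads <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(config$seed)
  classes <- c("candidate", names(config$decoy_mix), "background")
  probs <- c(config$repeat_incidence, unname(config$decoy_mix))
  probs <- c(probs, 1 - sum(probs))
  rows <- list()
  idx <- 0L
  for (s in seq_len(nrow(config$species))) {
    sp <- config$species$species[s]
    tag <- config$species$tag[s]
    n <- config$species$n_reads[s]
    if (n == 0L) next
    cls <- sample(classes, n, replace = TRUE, prob = probs)
    for (k in seq_len(n)) {
      idx <- idx + 1L
      r <- build_read(cls[k], tag, config)
      r$read_id <- sprintf("sim_%06d", idx)
      r$species <- sp
      rows[[idx]] <- r
    }
  }
  if (idx == 0L) {
    all_reads <- empty_reads()
    all_manifest <- data.frame(
      read_id = character(), species = character(), class = character(),
      has_repeat = logical(), motif = character(), unit_count = integer(),
      start = integer(), end = integer(), left_flank = integer(),
      right_flank = integer(), max_flank_run = integer(),
      mean_quality = numeric(), stringsAsFactors = FALSE)
    return(list(reads = all_reads, manifest = all_manifest))
  }
  pull <- function(f, mode) vapply(rows, function(r) r[[f]], mode)
  all_reads <- data.frame(
    read_id = pull("read_id", character(1)),
    sequence = pull("sequence", character(1)),
    species = pull("species", character(1)),
    stringsAsFactors = FALSE)
  all_reads$quality <- lapply(rows, `[[`, "quality")
  all_manifest <- data.frame(
    read_id = all_reads$read_id,
    species = all_reads$species,
    class = pull("class", character(1)),
    has_repeat = pull("has_repeat", logical(1)),
    motif = pull("motif", character(1)),
    unit_count = pull("unit_count", integer(1)),
    start = pull("start", integer(1)),
    end = pull("end", integer(1)),
    left_flank = pull("left_flank", integer(1)),
    right_flank = pull("right_flank", integer(1)),
    max_flank_run = pull("max_flank_run", integer(1)),
    mean_quality = pull("mean_quality", numeric(1)),
    stringsAsFactors = FALSE)
  list(reads = all_reads, manifest = all_manifest)
}

# one read + manifest row (flat list of scalars + quality vector) for a
# given class
build_read <- function(cls, tag, cfg) {
  mid_len <- nchar(tag)
  lo <- cfg$read_length[1]; hi <- cfg$read_length[2]
  fmin <- cfg$flank_min
  if (cls == "background") {
    L <- sample(lo:hi, 1L)
    body <- rand_clean_seq(L - mid_len, max_run = NULL)
    man <- list(class = cls, has_repeat = FALSE, motif = NA_character_,
                unit_count = NA_integer_, start = NA_integer_,
                end = NA_integer_, left_flank = NA_integer_,
                right_flank = NA_integer_, max_flank_run = NA_integer_)
  } else {
    motif <- sample(cfg$motif_pool, 1L)
    mb <- strsplit(motif, "")[[1]]
    u_lo <- max(10L, cfg$unit_count[1]); u_hi <- max(u_lo, cfg$unit_count[2])
    if (cls == "sub_threshold") {
      u <- sample(5L:9L, 1L)
      region <- strrep(motif, u)
    } else if (cls == "interrupted") {
      u1 <- sample(5L:9L, 1L); u2 <- sample(5L:9L, 1L)
      u <- u1 + u2
      x <- sample(setdiff(BASES, c(mb[1], mb[4])), 1L)
      region <- paste0(strrep(motif, u1), x, strrep(motif, u2))
    } else {
      u <- sample(u_lo:u_hi, 1L)
      region <- strrep(motif, u)
    }
    rlen <- nchar(region)
    lf_len <- fmin + sample(0:15, 1L)
    rf_len <- fmin + sample(0:15, 1L)
    grow <- "right"                       # flank that absorbs surplus length
    if (cls == "short_flank") {
      if (sample(c(TRUE, FALSE), 1L)) {
        lf_len <- fmin - 2L               # short side stays short
      } else {
        rf_len <- fmin - 2L
        grow <- "left"
      }
    }
    need <- mid_len + rlen + lf_len + rf_len
    L <- if (need >= hi) need else sample(max(lo, need):hi, 1L)
    if (grow == "right") rf_len <- rf_len + (L - need)
    else lf_len <- lf_len + (L - need)
    lf <- rand_clean_seq(lf_len)
    rf <- rand_clean_seq(rf_len)
    if (cls == "homopolymer_flank") {
      if (sample(c(TRUE, FALSE), 1L)) lf <- plant_homopolymer(lf)
      else rf <- plant_homopolymer(rf)
    }
    # junction bases must not continue the repeat's period: extending
    # left needs motif[4] before the region, extending right needs
    # motif[1] after it
    jrun <- if (cls == "homopolymer_flank") 6L else 5L
    lf <- fix_junction(lf, "left", mb[4], max_run = jrun)
    rf <- fix_junction(rf, "right", mb[1], max_run = jrun)
    body <- paste0(lf, region, rf)
    man <- list(class = cls, has_repeat = TRUE, motif = motif,
                unit_count = if (cls == "interrupted") NA_integer_ else u,
                start = lf_len, end = lf_len + rlen,
                left_flank = lf_len, right_flank = rf_len,
                max_flank_run = max(max_homopolymer_run(lf),
                                    max_homopolymer_run(rf)))
  }
  full <- paste0(tag, body)
  nb <- nchar(full)
  # per-read mean offset truncated away from the quality threshold so
  # the low-quality and normal classes stay margin-separated
  m <- if (cls == "low_quality") {
    min(cfg$low_quality_mean + rnorm(1, 0, cfg$quality_sd), 18)
  } else {
    max(cfg$quality_mean + rnorm(1, 0, cfg$quality_sd), 22)
  }
  q <- as.integer(pmin(40, pmax(0, round(rnorm(nb, m, cfg$quality_jitter)))))
  trimmed_q <- q[(mid_len + 1L):nb]
  man$mean_quality <- mean(trimmed_q)
  c(man, list(sequence = full, quality = q))
}

#' Expected cascade tally from a manifest
#'
#' Computes, from the planted attributes alone, the per-stage survivor
#' counts the filter cascade must produce under the given thresholds
#' (the primer-screen stage is excluded: primers are not engineered into
#' simulated flanks).
#'
#' @param manifest a manifest `data.frame` from [simulate_reads()].
#' @param min_units,min_flank,max_homopolymer,min_quality cascade
#'   thresholds; must match those the cascade will use.
#' @return A `data.frame`, one row per species: `n_reads`,
#'   `n_repeat_reads`, `flank_pass`, `clean_flanks`, `quality_pass`.
#' @export
expected_tally <- function(manifest, min_units = 10L, min_flank = 25L,
                           max_homopolymer = 5L, min_quality = 20) {
  mined <- manifest$has_repeat & !is.na(manifest$unit_count) &
    manifest$unit_count >= min_units
  flank <- mined & manifest$left_flank >= min_flank &
    manifest$right_flank >= min_flank
  clean <- flank & manifest$max_flank_run <= max_homopolymer
  qual <- clean & manifest$mean_quality >= min_quality
  out <- do.call(rbind, lapply(sort(unique(manifest$species)), function(sp) {
    i <- manifest$species == sp
    data.frame(species = sp, n_reads = sum(i),
               n_repeat_reads = sum(mined & i),
               flank_pass = sum(flank & i),
               clean_flanks = sum(clean & i),
               quality_pass = sum(qual & i), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(species = character(), n_reads = integer(),
                      n_repeat_reads = integer(), flank_pass = integer(),
                      clean_flanks = integer(), quality_pass = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
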