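# Independent brute-force oracles used across the suite. These
# deliberately take different computational routes than the package.

# reverse complement without the package helper
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force tandem-repeat finder by direct periodic extension: for
# every start position, extend to the right while each base equals the
# base one unit earlier, then keep maximal, full-period, >= min_units
# runs. Reports one row per physical run (leftmost start).
oracle_find_repeats <- function(seq, unit_len = 4L, min_units = 10L) {
  unit_len <- as.integer(unit_len)
  min_units <- as.integer(min_units)
  b <- strsplit(toupper(seq), "")[[1]]
  L <- length(b)
  out <- NULL
  i <- 1L
  while (i + unit_len - 1L <= L) {
    # extend periodic run starting at i
    j <- i + unit_len
    while (j <= L && b[j] != "N" && b[j - unit_len] != "N" &&
           b[j] == b[j - unit_len]) j <- j + 1L
    run_len <- j - i
    if (run_len > unit_len) {  # at least one repeated base
      # maximal on the left?
      left_ext <- i > 1L && b[i - 1L] != "N" &&
        b[i + unit_len - 1L] != "N" && b[i - 1L] == b[i + unit_len - 1L]
      if (!left_ext) {
        units <- run_len %/% unit_len
        motif <- paste(b[i:(i + unit_len - 1L)], collapse = "")
        full <- TRUE
        for (p in seq_len(unit_len - 1L)) {
          if (unit_len %% p == 0L) {
            mb <- strsplit(motif, "")[[1]]
            if (all(mb == mb[((seq_len(unit_len) - 1L) %% p) + 1L])) full <- FALSE
          }
        }
        if (units >= min_units && full && !any(b[i:(j - 1L)] == "N")) {
          out <- rbind(out, data.frame(
            motif = motif, unit_count = as.integer(units),
            start = as.integer(i - 1L), end = as.integer(i - 1L + run_len),
            stringsAsFactors = FALSE))
        }
      }
    }
    i <- i + 1L
  }
  if (is.null(out)) {
    out <- data.frame(motif = character(), unit_count = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  # one row per physical run: drop non-leftmost phases (same end)
  out <- out[!duplicated(out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# longest single-base run, scanning character by character
oracle_max_run <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (!length(b)) return(0L)
  best <- 1L
  cur <- 1L
  for (i in seq_along(b)[-1]) {
    cur <- if (b[i] == b[i - 1L]) cur + 1L else 1L
    best <- max(best, cur)
  }
  best
}

# heterozygosities by explicit counting over individuals/gene copies
oracle_het <- function(a1, a2) {
  n <- length(a1)
  ho <- sum(a1 != a2) / n
  copies <- c(a1, a2)
  ps <- sapply(unique(copies), function(al) sum(copies == al) / (2 * n))
  he <- (2 * n / (2 * n - 1)) * (1 - sum(ps^2))
  c(ho = ho, he = he)
}

# closed-form conditional probability of h heterozygotes given 2-allele
# counts (nA, na), and the exact HWE p for an observed table
oracle_hwe_2allele <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  prob_h <- function(h) {
    exp(lfactorial(n) + lfactorial(nA) + lfactorial(na) + h * log(2) -
          lfactorial(2 * n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2))
  }
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  probs <- sapply(hs, prob_h)
  p_obs <- prob_h(nAa)
  sum(probs[probs <= p_obs + 1e-10])
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# genotype data.frame builder
geno_df <- function(locus, a1, a2, individual = NULL, population = "pop1") {
  if (is.null(individual)) individual <- sprintf("i%03d", seq_along(a1))
  as_genotypes(data.frame(individual = individual, population = population,
                          locus = locus, allele1 = a1, allele2 = a2,
                          stringsAsFactors = FALSE))
}
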