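#' Read a long-format genotype table
#'
#' Loads a TSV with columns `individual`, `population`, `locus`,
#' `allele1`, `allele2` (allele sizes in bp; blank or NA = missing
#' call). Allele pairs are unordered and stored sorted.
#'
#' @param path path to the genotype TSV.
#' @return A genotype `data.frame` (class `genotypes`).
#' @export
read_genotypes <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(allele1 = "integer", allele2 = "integer"))
  as_genotypes(g)
}

#' @rdname read_genotypes
#' @param g a `data.frame` with the genotype columns.
#' @export
as_genotypes <- function(g) {
  need <- c("individual", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("genotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"population" %in% names(g)) g$population <- NA_character_
  one_na <- xor(is.na(g$allele1), is.na(g$allele2))
  if (any(one_na)) stop("half-missing genotype for individual ",
                        g$individual[one_na][1], " at locus ", g$locus[one_na][1])
  ok <- is.na(g$allele1) | (g$allele1 > 0 & g$allele2 > 0)
  if (!all(ok)) stop("allele sizes must be positive")
  swap <- !is.na(g$allele1) & g$allele1 > g$allele2
  tmp <- g$allele1[swap]
  g$allele1[swap] <- g$allele2[swap]
  g$allele2[swap] <- tmp
  class(g) <- c("genotypes", "data.frame")
  g
}

locus_calls <- function(g, locus) {
  x <- g[g$locus == locus & !is.na(g$allele1), , drop = FALSE]
  if (!nrow(x) && !locus %in% g$locus) stop("locus not in table: ", locus)
  x
}

#' Allele statistics for one locus
#'
#' @param g a genotype table (see [read_genotypes()]).
#' @param locus locus name.
#' @return A list with `n_alleles`, `size_min`, `size_max`.
#' @export
allele_stats <- function(g, locus) {
  x <- locus_calls(g, locus)
  if (!nrow(x)) stop("no data: all calls missing at locus ", locus)
  alleles <- c(x$allele1, x$allele2)
  list(n_alleles = length(unique(alleles)),
       size_min = min(alleles), size_max = max(alleles))
}

#' Observed and unbiased expected heterozygosity
#'
#' `ho` is the fraction of heterozygous individuals among non-missing
#' calls. `he` is Nei's unbiased expected heterozygosity,
#' `2n/(2n - 1) * (1 - sum p_i^2)`, with allele frequencies `p_i` taken
#' over the `2n` gene copies.
#'
#' @inheritParams allele_stats
#' @return A list with `ho` and `he`.
#' @export
heterozygosities <- function(g, locus) {
  x <- locus_calls(g, locus)
  if (nrow(x) < 2L) stop("no data: need >= 2 non-missing calls at locus ", locus)
  ho <- mean(x$allele1 != x$allele2)
  p <- table(c(x$allele1, x$allele2)) / (2L * nrow(x))
  n2 <- 2L * nrow(x)
  he <- n2 / (n2 - 1L) * (1 - sum(p^2))
  list(ho = ho, he = he)
}

# log conditional (Levene) probability of a genotype-count table given
# its allele counts: P = n! prod(a_i!) 2^h / ((2n)! prod(n_ij!))
log_table_prob <- function(het_counts, hom_counts, allele_counts) {
  n <- sum(het_counts) + sum(hom_counts)
  h <- sum(het_counts)
  lfactorial(n) + sum(lfactorial(allele_counts)) + h * log(2) -
    lfactorial(2L * n) - sum(lfactorial(het_counts)) - sum(lfactorial(hom_counts))
}

genotype_counts <- function(x) {
  k <- sort(unique(c(x$allele1, x$allele2)))
  m <- length(k)
  cnt <- matrix(0L, m, m, dimnames = list(k, k))
  for (i in seq_len(nrow(x))) {
    a <- match(x$allele1[i], k)
    b <- match(x$allele2[i], k)
    cnt[a, b] <- cnt[a, b] + 1L
  }
  cnt
}

#' Exact / Monte-Carlo test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts given allele counts. For
#' loci with at most 3 alleles, all genotype tables with the observed
#' allele counts are enumerated and the p-value is the total conditional
#' probability of tables no more probable than the observed one. For
#' more alleles, gene copies are shuffled (`n_permutations` times, fixed
#' `seed`) and the p-value is `(1 + #{P <= P_obs}) / (B + 1)`.
#'
#' @inheritParams allele_stats
#' @param n_permutations Monte-Carlo sample size (default 10000).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return The p-value.
#' @export
hwe_exact <- function(g, locus, n_permutations = 10000L, seed = 1L) {
  x <- locus_calls(g, locus)
  cnt <- genotype_counts(x)
  m <- nrow(cnt)
  if (m < 2L) stop("HWE test undefined for a monomorphic locus: ", locus)
  a <- integer(m)
  for (i in seq_len(m)) a[i] <- sum(cnt[i, ]) + sum(cnt[, i])  # gene copies
  obs_het <- cnt[upper.tri(cnt)]
  obs_hom <- diag(cnt)
  lp_obs <- log_table_prob(obs_het, obs_hom, a)
  tol <- 1e-10
  if (m <= 3L) {
    lps <- enumerate_tables(a)
    p <- sum(exp(lps[lps <= lp_obs + tol]))
    return(min(p, 1))
  }
  copies <- rep(seq_len(m), times = a)
  n <- length(copies) / 2L
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(copies)
    g1 <- perm[seq_len(n)]
    g2 <- perm[n + seq_len(n)]
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    tab <- matrix(0L, m, m)
    for (i in seq_len(n)) tab[lo[i], hi[i]] <- tab[lo[i], hi[i]] + 1L
    lp <- log_table_prob(tab[upper.tri(tab)], diag(tab), a)
    if (lp <= lp_obs + tol) hits <- hits + 1L
  }
  (1L + hits) / (n_permutations + 1L)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# log-probabilities of every genotype table consistent with allele
# counts a (length 2 or 3)
enumerate_tables <- function(a) {
  m <- length(a)
  lps <- numeric(0)
  if (m == 2L) {
    for (h in seq(a[1] %% 2L, min(a[1], a[2]), by = 2L)) {
      hom <- c((a[1] - h) / 2L, (a[2] - h) / 2L)
      lps <- c(lps, log_table_prob(h, hom, a))
    }
  } else if (m == 3L) {
    for (n12 in 0:min(a[1], a[2])) {
      for (n13 in 0:min(a[1] - n12, a[3])) {
        if ((a[1] - n12 - n13) %% 2L != 0L) next
        n11 <- (a[1] - n12 - n13) / 2L
        for (n23 in 0:min(a[2] - n12, a[3] - n13)) {
          if ((a[2] - n12 - n23) %% 2L != 0L) next
          if ((a[3] - n13 - n23) %% 2L != 0L) next
          n22 <- (a[2] - n12 - n23) / 2L
          n33 <- (a[3] - n13 - n23) / 2L
          lps <- c(lps, log_table_prob(c(n12, n13, n23), c(n11, n22, n33), a))
        }
      }
    }
  } else stop("enumeration supports 2 or 3 alleles")
  lps
}

#' Cross-amplification summary
#'
#' For primers developed in one species applied to another: a locus with
#' no successful calls counts as not amplified; otherwise its allele
#' count decides polymorphism (`>= 2` alleles).
#'
#' @param g a genotype table from the cross-amplification trial.
#' @param loci optional character vector of all tested loci (so loci
#'   absent from the table are reported as failed).
#' @return A list with `per_locus` (`data.frame`: `locus`, `amplified`,
#'   `n_alleles`, `polymorphic`) and counts `n_polymorphic`,
#'   `n_monomorphic`, `n_failed`.
#' @export
cross_amp_summary <- function(g, loci = NULL) {
  if (is.null(loci)) loci <- unique(g$locus)
  per <- do.call(rbind, lapply(loci, function(lc) {
    x <- g[g$locus == lc & !is.na(g$allele1), , drop = FALSE]
    if (!nrow(x)) {
      return(data.frame(locus = lc, amplified = FALSE, n_alleles = 0L,
                        polymorphic = FALSE, stringsAsFactors = FALSE))
    }
    k <- length(unique(c(x$allele1, x$allele2)))
    data.frame(locus = lc, amplified = TRUE, n_alleles = k,
               polymorphic = k >= 2L, stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(locus = character(), amplified = logical(),
                      n_alleles = integer(), polymorphic = logical(),
                      stringsAsFactors = FALSE)
  }
  list(per_locus = per,
       n_polymorphic = sum(per$polymorphic),
       n_monomorphic = sum(per$amplified & !per$polymorphic),
       n_failed = sum(!per$amplified))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha nominal significance level.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Summarize all loci of a genotype table
#'
#' Marker-characterization table: allele counts, fragment size range,
#' observed and unbiased expected heterozygosity, exact HWE p-value and
#' a polymorphism flag (`n_alleles >= 2`) for every locus. The HWE
#' p-value is `NA` for monomorphic loci.
#'
#' @param g a genotype table (see [read_genotypes()]).
#' @param n_permutations,seed passed to [hwe_exact()].
#' @return A `data.frame`, one row per locus.
#' @export
summarize_markers <- function(g, n_permutations = 10000L, seed = 1L) {
  loci <- unique(g$locus)
  out <- do.call(rbind, lapply(loci, function(lc) {
    x <- g[g$locus == lc & !is.na(g$allele1), , drop = FALSE]
    if (!nrow(x)) {
      return(data.frame(locus = lc, n_individuals = 0L, n_alleles = 0L,
                        size_min = NA_integer_, size_max = NA_integer_,
                        ho = NA_real_, he = NA_real_, hwe_p = NA_real_,
                        polymorphic = FALSE, stringsAsFactors = FALSE))
    }
    st <- allele_stats(g, lc)
    het <- if (nrow(x) >= 2L) heterozygosities(g, lc) else list(ho = NA_real_, he = NA_real_)
    p <- if (st$n_alleles >= 2L) hwe_exact(g, lc, n_permutations, seed) else NA_real_
    data.frame(locus = lc, n_individuals = nrow(x), n_alleles = st$n_alleles,
               size_min = st$size_min, size_max = st$size_max,
               ho = het$ho, he = het$he, hwe_p = p,
               polymorphic = st$n_alleles >= 2L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
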