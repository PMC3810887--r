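test_that("allele statistics count distinct sizes over non-missing calls", {
  g <- geno_df("L1", 150, 150)
  expect_equal(allele_stats(g, "L1"), list(n_alleles = 1L, size_min = 150,
                                           size_max = 150))
  g2 <- geno_df("L1", c(150, 154), c(154, 158))
  expect_equal(allele_stats(g2, "L1"),
               list(n_alleles = 3L, size_min = 150, size_max = 158))
  g3 <- geno_df("L1", c(150, NA), c(154, NA))
  expect_equal(allele_stats(g3, "L1")$n_alleles, 2L)
  g4 <- geno_df("L1", NA_integer_, NA_integer_)
  expect_error(allele_stats(g4, "L1"), "no data")
  expect_error(allele_stats(g, "Lmissing"), "not in table")
})

test_that("heterozygosities match closed forms and the direct-count oracle", {
  # monomorphic locus
  g0 <- geno_df("L1", rep(150, 10), rep(150, 10))
  h0 <- heterozygosities(g0, "L1")
  expect_equal(h0$ho, 0)
  expect_equal(h0$he, 0)
  # 50 individuals all heterozygous 150/154: ho = 1, he = (100/99) * 0.5
  g1 <- geno_df("L1", rep(150, 50), rep(154, 50))
  h1 <- heterozygosities(g1, "L1")
  expect_equal(h1$ho, 1)
  expect_equal(h1$he, (100 / 99) * 0.5)
  # randomized tables vs the independent direct-count oracle
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    pool <- sample(seq(100, 180, by = 4), sample(2:6, 1))
    a1 <- sample(pool, n, TRUE)
    a2 <- sample(pool, n, TRUE)
    g <- geno_df("L", a1, a2)
    h <- heterozygosities(g, "L")
    want <- oracle_het(pmin(a1, a2), pmax(a1, a2))
    expect_equal(h$ho, unname(want["ho"]), tolerance = 1e-12)
    expect_equal(h$he, unname(want["he"]), tolerance = 1e-12)
  }
  # invariance under relabeling of individuals and allele order
  g_a <- geno_df("L", c(150, 154, 150), c(154, 150, 150))
  g_b <- geno_df("L", c(154, 150, 150), c(150, 150, 154),
                 individual = c("z", "y", "x"))
  expect_equal(heterozygosities(g_a, "L"), heterozygosities(g_b, "L"))
})

test_that("exact HWE enumeration matches the closed-form two-allele test", {
  # genotype counts (AA, Aa, aa) = (3, 4, 3)
  g <- geno_df("L", c(rep(150, 3), rep(150, 4), rep(154, 3)),
               c(rep(150, 3), rep(154, 4), rep(154, 3)))
  p <- hwe_exact(g, "L")
  expect_equal(p, oracle_hwe_2allele(3, 4, 3), tolerance = 1e-10)
  # extreme heterozygote excess: 20 individuals all heterozygous
  g2 <- geno_df("L", rep(150, 20), rep(154, 20))
  p2 <- hwe_exact(g2, "L")
  expect_lt(p2, 0.05)
  expect_equal(p2, oracle_hwe_2allele(0, 20, 0), tolerance = 1e-10)
  # more 2-allele cases against the closed form
  set.seed(19)
  for (i in 1:20) {
    nAA <- sample(0:8, 1); nAa <- sample(0:8, 1); naa <- sample(0:8, 1)
    if (nAa + nAA == 0 || nAa + naa == 0) next  # monomorphic
    a1 <- c(rep(150, nAA), rep(150, nAa), rep(154, naa))
    a2 <- c(rep(150, nAA), rep(154, nAa), rep(154, naa))
    g <- geno_df("L", a1, a2)
    expect_equal(hwe_exact(g, "L"), oracle_hwe_2allele(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
  # monomorphic locus is undefined
  expect_error(hwe_exact(geno_df("L", rep(1, 5), rep(1, 5)), "L"), "monomorphic")
})

test_that("Monte-Carlo HWE agrees with enumeration and is seed-deterministic", {
  # a 3-allele table: enumeration is the exact reference
  set.seed(23)
  a1 <- sample(c(100, 104, 108), 30, TRUE)
  a2 <- sample(c(100, 104, 108), 30, TRUE)
  g <- geno_df("L", a1, a2)
  p_exact <- hwe_exact(g, "L")
  # force the Monte-Carlo path by mimicking the internal estimator on a
  # 4-allele-augmented version is not comparable; instead check the MC
  # estimator through a 4-allele table's determinism and the 3-allele
  # exact value against an MC run done by hand below
  copies <- c(pmin(a1, a2), pmax(a1, a2))
  B <- 4000
  lp_of <- function(v1, v2) {
    k <- sort(unique(c(v1, v2)))
    m <- length(k)
    tab <- matrix(0L, m, m)
    for (i in seq_along(v1)) {
      a <- match(min(v1[i], v2[i]), k); b <- match(max(v1[i], v2[i]), k)
      tab[a, b] <- tab[a, b] + 1L
    }
    acount <- sapply(seq_len(m), function(i) sum(tab[i, ]) + sum(tab[, i]))
    n <- length(v1)
    lfactorial(n) + sum(lfactorial(acount)) + sum(tab[upper.tri(tab)]) * log(2) -
      lfactorial(2 * n) - sum(lfactorial(tab))
  }
  lp_obs <- lp_of(a1, a2)
  set.seed(1)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample(copies)
    v1 <- perm[1:30]; v2 <- perm[31:60]
    if (lp_of(v1, v2) <= lp_obs + 1e-10) hits <- hits + 1L
  }
  p_mc <- (1 + hits) / (B + 1)
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / B)

  # >3 alleles triggers the internal Monte-Carlo path: determinism
  a1 <- sample(c(100, 104, 108, 112), 25, TRUE)
  a2 <- sample(c(100, 104, 108, 112), 25, TRUE)
  g4 <- geno_df("L", a1, a2)
  p_a <- hwe_exact(g4, "L", n_permutations = 2000, seed = 42)
  p_b <- hwe_exact(g4, "L", n_permutations = 2000, seed = 42)
  expect_identical(p_a, p_b)
  expect_true(p_a > 0 && p_a <= 1)
})

test_that("cross-amplification summary classifies loci by call success", {
  # empty table
  empty <- as_genotypes(data.frame(individual = character(),
                                   population = character(),
                                   locus = character(),
                                   allele1 = integer(), allele2 = integer()))
  expect_equal(cross_amp_summary(empty)$n_polymorphic, 0L)

  # single locus, one allele: amplified but monomorphic
  g1 <- geno_df("LocX", 160, 160)
  s1 <- cross_amp_summary(g1)
  expect_true(s1$per_locus$amplified)
  expect_false(s1$per_locus$polymorphic)

  # simulated cross-species panel: 10 polymorphic, 2 monomorphic, 8 failed
  set.seed(31)
  loci <- sprintf("Loc%02d", 1:20)
  rows <- list()
  for (i in 1:10) {
    rows[[i]] <- data.frame(individual = sprintf("i%d", 1:6), population = "p",
                            locus = loci[i], allele1 = c(100, 100, 104, 104, 100, 104),
                            allele2 = c(100, 104, 104, 108, 100, 108))
  }
  for (i in 11:12) {
    rows[[i]] <- data.frame(individual = sprintf("i%d", 1:6), population = "p",
                            locus = loci[i], allele1 = 120, allele2 = 120)
  }
  g <- as_genotypes(do.call(rbind, rows))
  s <- cross_amp_summary(g, loci = loci)
  expect_equal(s$n_polymorphic, 10L)
  expect_equal(s$n_monomorphic, 2L)
  expect_equal(s$n_failed, 8L)
  # polymorphic <=> n_alleles >= 2, everywhere
  expect_equal(s$per_locus$polymorphic, s$per_locus$n_alleles >= 2L)
})

test_that("marker summary table combines the per-locus statistics", {
  g <- read_genotypes(system.file("extdata", "toy_genotypes.tsv",
                                  package = "palmine"))
  s <- summarize_markers(g, n_permutations = 500, seed = 3)
  expect_equal(nrow(s), 3L)
  la <- s[s$locus == "LocA", ]
  expect_equal(la$n_alleles, 2L)
  expect_equal(la$ho, 0.4)                       # 4 of 10 heterozygous
  expect_equal(la$hwe_p, oracle_hwe_2allele(3, 4, 3), tolerance = 1e-10)
  expect_true(la$polymorphic)
  lb <- s[s$locus == "LocB", ]
  expect_false(lb$polymorphic)
  expect_true(is.na(lb$hwe_p))
  expect_equal(lb$he, 0)
  lc <- s[s$locus == "LocC", ]
  expect_equal(lc$n_individuals, 9L)             # one missing call
  expect_equal(lc$n_alleles, 3L)
  expect_equal(c(lc$size_min, lc$size_max), c(180, 188))
  # Bonferroni utility
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
})
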