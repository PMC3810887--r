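test_that("flank filter is inclusive at the 25-bp boundary", {
  expect_true(check_flanks(25, 25))
  expect_false(check_flanks(24, 100))
  expect_false(check_flanks(100, 24))
  expect_true(all(check_flanks(c(25, 30), c(26, 25))))
})

test_that("flank filter agrees with simulator-planted flank lengths", {
  cfg <- sim_config(seed = 21, species = data.frame(
    species = "S", tag = "ACACTACTCGT", n_reads = 600L),
    repeat_incidence = 0.4,
    decoy_mix = c(sub_threshold = 0, interrupted = 0, short_flank = 0.3,
                  homopolymer_flank = 0, low_quality = 0))
  sim <- simulate_reads(cfg)
  man <- sim$manifest[sim$manifest$has_repeat, ]
  got <- check_flanks(man$left_flank, man$right_flank)
  expect_equal(got, man$class != "short_flank")
  expect_gt(sum(man$class == "short_flank"), 50)
})

test_that("homopolymer filter scans flanks only, boundary at runs of 5", {
  # 6 A's in the left flank fail
  s1 <- paste0("CCCGG", strrep("A", 6), "CCGGC", strrep("AGAT", 10), "GCCGG")
  expect_false(check_homopolymer(s1, 16, 56))
  # runs of exactly 5 pass
  s2 <- paste0("CCCGG", strrep("A", 5), "CCGGC", strrep("AGAT", 10), "GCCGG")
  expect_true(check_homopolymer(s2, 15, 55))
  # a run inside the repeat region itself is not scanned
  s3 <- paste0("CGCGC", strrep("AAAT", 10), "GCGCG")
  expect_true(check_homopolymer(s3, 5, 45))
})

test_that("homopolymer verdicts match a brute-force longest-run scanner", {
  set.seed(55)
  for (i in 1:1000) {
    lf <- rand_dna(sample(5:40, 1))
    rf <- rand_dna(sample(5:40, 1))
    s <- paste0(lf, strrep("AGAT", 10), rf)
    start <- nchar(lf); end <- start + 40L
    want <- oracle_max_run(lf) <= 5 && oracle_max_run(rf) <= 5
    expect_equal(check_homopolymer(s, start, end), want)
  }
})

test_that("quality filter keeps mean exactly 20 and warns without quality", {
  expect_true(check_quality(rep(40L, 10)))
  expect_false(check_quality(rep(19L, 10)))
  # mixed profile with mean exactly 20: 'below 20' is discarded, 20 kept
  q <- c(rep(10L, 5), rep(30L, 5))
  expect_equal(mean(q), 20)
  expect_true(check_quality(q))
  expect_warning(ok <- check_quality(NULL), "no quality")
  expect_true(ok)
  # min-statistic mode over a region
  expect_false(check_quality(c(40L, 19L, 40L), stat = "min"))
  expect_true(check_quality(c(40L, 19L, 40L), stat = "min", region = c(1, 3)))
})

test_that("nearest-neighbour Tm matches independently computed references", {
  # reference values from SantaLucia-1998 unified parameters at
  # 50 mM Na+, 50 nM excess primer
  ref <- c(ACGTACGTACGTACGTACGT = 54.9256,
           GCGCGCGCGCGCGCGCGCGC = 78.9228,
           ATATATATATATATATATAT = 26.0465,
           AGCTTGCCAAGGTTCACAGC = 57.5486,
           TAGCTGAGCGGCGAACCACT = 60.0781)
  for (s in names(ref)) {
    expect_equal(primer_tm(s), unname(ref[s]), tolerance = 1e-4)
  }
  # duplex symmetry
  set.seed(9)
  for (i in 1:20) {
    s <- rand_dna(sample(18:27, 1))
    expect_equal(primer_tm(s), primer_tm(oracle_revcomp(s)), tolerance = 1e-9)
  }
})

test_that("primer screen returns engineered pairs and rejects hopeless flanks", {
  repeat_seq <- strrep("AGAT", 12)
  # two engineered 20-mers with Tm ~60 C embedded in clean flanks
  fwd <- "TAGCTGAGCGGCGAACCACT"   # Tm 60.08
  rev_window <- "GCACTCGTCCCTGGTCACGA"  # Tm 60.36
  set.seed(77)
  s <- paste0("CCGGC", fwd, "TCGGC", repeat_seq, "CTTGC", rev_window, "CGGCC")
  start <- 30L; end <- start + 48L
  pp <- screen_primers(s, start, end)
  expect_false(is.null(pp))
  # the reported pair satisfies every constraint and the engineered
  # near-60 windows make the optimum reachable on both sides
  expect_true(abs(pp$tm_forward - 60) <= 3)
  expect_true(abs(pp$tm_reverse - 60) <= 3)
  # independent Tm recomputation for the reported sequences (the reverse
  # primer melts identically to its template window, by duplex symmetry)
  expect_equal(pp$tm_forward, primer_tm(pp$forward), tolerance = 1e-9)
  expect_equal(pp$tm_reverse, primer_tm(oracle_revcomp(pp$reverse)),
               tolerance = 1e-9)
  expect_true(pp$gc_forward >= 0.2 && pp$gc_forward <= 0.8)
  # the forward primer is drawn from the engineered left flank
  expect_equal(pp$forward,
               substr(s, pp$fwd_start + 1, pp$fwd_start + nchar(pp$forward)))
  # primers confined to their flanks; amplicon spans the repeat
  expect_true(pp$fwd_start + nchar(pp$forward) <= start)
  expect_true(pp$rev_end - nchar(pp$reverse) >= end)
  expect_equal(pp$amplicon_len, pp$rev_end - pp$fwd_start)

  # a flank of 30 A's is unsatisfiable (GC, homopolymer, Tm)
  s_a <- paste0(strrep("A", 30), repeat_seq, strrep("A", 30))
  expect_null(screen_primers(s_a, 30L, 30L + 48L))
  # flanks shorter than the minimum primer length yield nothing
  s_short <- paste0(rand_dna(10), repeat_seq, rand_dna(10))
  expect_null(screen_primers(s_short, 10L, 10L + 48L))
})

test_that("the cascade is monotone, order-invariant and idempotent", {
  tags <- data.frame(species = c("A", "B"), tag = c("ACACTACTCGT", "ACGAGTAGACT"),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 99, species = cbind(tags, n_reads = 250L))
  sim <- simulate_reads(cfg)
  dm <- demultiplex(sim$reads, tags)
  casc <- run_cascade(dm$assigned)
  t <- casc$tallies
  # monotone survivor counts
  expect_true(all(t$n_repeat_reads <= t$n_reads))
  expect_true(all(t$flank_pass <= t$n_repeat_reads))
  expect_true(all(t$clean_flanks <= t$flank_pass))
  expect_true(all(t$quality_pass <= t$clean_flanks))
  expect_true(all(t$primer_designed <= t$quality_pass))
  # stage labels are monotone per candidate
  ranks <- c(mined = 1, flank_pass = 2, clean_flanks = 3, quality_pass = 4,
             primer_designed = 5)
  r <- ranks[casc$candidates$stage_reached]
  expect_true(all((r >= 2) == casc$candidates$flank_ok))
  expect_true(all((r >= 3) == casc$candidates$homopolymer_ok))
  expect_true(all((r >= 4) == casc$candidates$quality_ok))

  # shuffling the input order changes nothing
  set.seed(1)
  shuf <- dm$assigned[sample(nrow(dm$assigned)), , drop = FALSE]
  casc2 <- run_cascade(shuf)
  expect_equal(casc2$tallies, casc$tallies)
  expect_equal(casc2$candidates, casc$candidates)

  # re-running the cascade on survivors reproduces the survivor set
  surv_ids <- casc$candidates$read_id[casc$candidates$stage_reached %in%
                                        c("quality_pass", "primer_designed")]
  surv <- dm$assigned[dm$assigned$read_id %in% surv_ids, , drop = FALSE]
  casc3 <- run_cascade(surv)
  expect_equal(sum(casc3$tallies$quality_pass), length(surv_ids))

  # zero reads give zero tallies
  empty <- dm$assigned[0, , drop = FALSE]
  casc0 <- run_cascade(empty)
  expect_equal(nrow(casc0$candidates), 0L)
  expect_equal(nrow(casc0$tallies), 0L)
})
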