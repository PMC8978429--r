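test_that("1U/10A fractions count bases in read orientation", {
  rs <- make_reads(start = c(1, 100, 200), length = 10L,
                   sequence = c("TAAAAAAAAA", "TCCCCCCCCA", "GGGGGGGGGG"))
  b <- u1_a10_bias(rs, check_range = FALSE)
  expect_equal(b$u1_fraction, 2 / 3)
  expect_equal(b$a10_fraction, 2 / 3)
  allt <- make_reads(start = c(1, 100), length = 10L,
                     sequence = c("TAAAAAAAAA", "TAAAAAAAAA"))
  expect_equal(u1_a10_bias(allt, check_range = FALSE)$u1_fraction, 1.0)
  empty <- u1_a10_bias(make_reads(start = integer(0)))
  expect_true(is.na(empty$u1_fraction))
})

test_that("planted 1U/10A biases are recovered within binomial error", {
  g <- make_toy_genome(seed = 6, genome_length = 200000L, n_clusters = 5L,
                       cluster_size = c(2000L, 4000L),
                       cluster_pingpong = 0, cluster_phased = 0)
  cl <- g$clusters
  cl$u1 <- 0.8
  cl$a10 <- 0.4
  rs <- simulate_tissue_library(
    g, "bias", "ovary", 5000L, seed = 6,
    profile = c(mirna = 0, pirna = 1, trf = 0, background = 0),
    cluster_overrides = cl)
  b <- u1_a10_bias(rs)
  expect_true(abs(b$u1_fraction - 0.8) <= 0.02)
  expect_true(abs(b$a10_fraction - 0.4) <= 0.02)
})

test_that("ping-pong overlap histogram bins 5'-end overlaps", {
  rs <- ReadSet(data.frame(
    read_id = c("p", "q"), sequence = strrep("A", 28), length = 28L,
    chrom = "c1", start = c(100L, 82L), end = c(128L, 110L),
    strand = c("+", "-"), n_hits = 1L, copy_count = 1L))
  # + 5' at 100, - 5' at 109: overlap 10
  h <- pingpong_overlap_histogram(rs)
  expect_equal(unname(h[10]), 1)
  expect_equal(sum(h), 1)
  same <- make_reads(start = c(100, 200), length = 28L, strand = "+")
  expect_true(all(pingpong_overlap_histogram(same) == 0))
})

test_that("ping-pong and phasing histograms match brute-force oracles", {
  for (seed in 1:4) {
    set.seed(seed)
    rs <- random_reads(200, genome_len = 4000L, chroms = c("c1", "c2"),
                       copy_max = 3L)
    expect_equal(pingpong_overlap_histogram(rs), oracle_pingpong(rs))
    expect_equal(phasing_distance_histogram(rs), oracle_phasing(rs))
  }
})

test_that("Z-scores are 0 on flat histograms and undefined without variance scale", {
  flat <- setNames(rep(5, 30), 1:30)
  expect_equal(pingpong_zscore(flat), 0)
  flat50 <- setNames(rep(2, 50), 1:50)
  expect_equal(as.numeric(phasing_zscore(flat50)), 0)
  # a spike over a tight background is scaled by the Poisson floor
  spike <- setNames(c(9, rep(2, 49)), 1:50)
  expect_equal(as.numeric(phasing_zscore(spike)), 7 / sqrt(2), tolerance = 1e-12)
  # no background counts at all: no scale, flagged NA
  expect_true(is.na(pingpong_zscore(setNames(c(rep(0, 9), 5, rep(0, 20)), 1:30))))
})

test_that("phasing distances are measured 3' to 5' in transcription direction", {
  # + reads [100,128) then [128,156): d = 128 - 127 = 1
  rs <- make_reads(start = c(100, 128), length = 28L, strand = "+")
  h <- phasing_distance_histogram(rs)
  expect_equal(unname(h[1]), 1)
  single <- make_reads(start = 100, length = 28L)
  expect_true(all(phasing_distance_histogram(single) == 0))
  # mirrored on the minus strand: [128,156) upstream, [100,128) downstream
  rsm <- make_reads(start = c(100, 128), length = 28L, strand = "-")
  expect_equal(unname(phasing_distance_histogram(rsm)[1]), 1)
})

test_that("strand mirror symmetry leaves both Z-scores unchanged", {
  set.seed(31)
  g <- make_toy_genome(seed = 31, genome_length = 150000L, n_clusters = 4L,
                       cluster_size = c(2000L, 3000L))
  rs <- simulate_tissue_library(
    g, "mir", "ovary", 2000L, seed = 31,
    profile = c(mirna = 0, pirna = 1, trf = 0, background = 0))
  L <- 150000L
  flipped <- rs$reads
  flipped$strand <- ifelse(rs$reads$strand == "+", "-", "+")
  flipped$start <- L - rs$reads$end
  flipped$end <- L - rs$reads$start
  flipped$sequence <- rs$reads$sequence  # sequence content irrelevant here
  rsf <- ReadSet(flipped)
  expect_equal(pingpong_zscore(pingpong_overlap_histogram(rsf)),
               pingpong_zscore(pingpong_overlap_histogram(rs)))
  expect_equal(as.numeric(phasing_zscore(phasing_distance_histogram(rsf))),
               as.numeric(phasing_zscore(phasing_distance_histogram(rs))))
})

test_that("planted ping-pong pairs give Z >= 3 and the null stays below |Z| < 2", {
  g <- make_toy_genome(seed = 7, genome_length = 150000L, n_clusters = 4L,
                       cluster_size = c(2000L, 4000L),
                       cluster_pingpong = 0.5, cluster_phased = 0,
                       strand_modes = "bidirectional")
  rs <- simulate_tissue_library(
    g, "pp", "ovary", 2000L, seed = 7,
    profile = c(mirna = 0, pirna = 1, trf = 0, background = 0))
  z <- pingpong_zscore(pingpong_overlap_histogram(rs))
  expect_gte(z, 3)

  # calibration null: uniform 5' position sampling (no base
  # conditioning, which would freeze genome-specific dyad patterns
  # into the bins) and fixed cluster width to control pair density
  g0 <- make_toy_genome(seed = 8, genome_length = 150000L, n_clusters = 4L,
                        cluster_size = c(3000L, 3000L), cluster_u1 = NA,
                        cluster_pingpong = 0, cluster_phased = 0,
                        strand_modes = "bidirectional")
  zs <- vapply(1:100, function(i) {
    rs0 <- simulate_tissue_library(
      g0, sprintf("null%03d", i), "ovary", 350L, seed = 8,
      profile = c(mirna = 0, pirna = 1, trf = 0, background = 0))
    pingpong_zscore(pingpong_overlap_histogram(rs0))
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2, na.rm = TRUE), 0.95)
})

test_that("planted phased trails give Z >= 3 and the null stays below |Z| < 2", {
  g <- make_toy_genome(seed = 9, genome_length = 150000L, n_clusters = 4L,
                       cluster_size = c(2000L, 4000L),
                       cluster_pingpong = 0, cluster_phased = 0.8)
  rs <- simulate_tissue_library(
    g, "ph", "semen", 2000L, seed = 9,
    profile = c(mirna = 0, pirna = 1, trf = 0, background = 0))
  z <- as.numeric(phasing_zscore(phasing_distance_histogram(rs)))
  expect_gte(z, 3)

  # null = uniform random 5' ends: genome-wide rain with mean spacing
  # (~500 bp) far above the 50 nt window so the distance histogram is
  # flat, and enough reads that every bin is populated
  g0 <- make_toy_genome(seed = 10, genome_length = 1000000L, n_clusters = 4L,
                        cluster_size = c(2000L, 4000L),
                        cluster_pingpong = 0, cluster_phased = 0)
  zs <- vapply(1:100, function(i) {
    rs0 <- simulate_tissue_library(
      g0, sprintf("null%03d", i), "semen", 4000L, seed = 10,
      profile = c(mirna = 0, pirna = 0, trf = 0, background = 1))
    as.numeric(phasing_zscore(phasing_distance_histogram(rs0)))
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2, na.rm = TRUE), 0.95)
})

test_that("increasing the planted ping-pong fraction never decreases Z", {
  # coupled design: one fixed layout of read pairs; raising the planted
  # fraction moves partner 5' ends from random offsets onto offset 9
  set.seed(55)
  npair <- 400L
  p5 <- sample.int(3000L, npair, replace = TRUE) + 1000L
  plen <- sample(26:31, npair, TRUE)
  qlen <- sample(26:31, npair, TRUE)
  qoff <- sample(12:30, npair, TRUE)
  zs <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(f) {
    k <- round(f * npair)
    q5 <- ifelse(seq_len(npair) <= k, p5 + 9L, p5 + qoff)
    rs <- ReadSet(data.frame(
      read_id = sprintf("r%04d", seq_len(2L * npair)),
      sequence = strrep("A", c(plen, qlen)),
      length = c(plen, qlen), chrom = "c1",
      start = c(p5, q5 + 1L - qlen), end = c(p5 + plen, q5 + 1L),
      strand = rep(c("+", "-"), each = npair),
      n_hits = 1L, copy_count = 1L))
    pingpong_zscore(pingpong_overlap_histogram(rs))
  }, numeric(1))
  expect_true(all(diff(zs) >= -1e-9))
})

test_that("signatures below the minimum read count are flagged undefined", {
  rs <- make_reads(start = c(100, 200), length = 28L)
  sig <- compute_signatures(rs, min_reads = 50)
  expect_false(sig$defined)
  expect_true(is.na(sig$pingpong_z))
})

test_that("per-cluster biases reproduce planted values at depth", {
  g <- make_toy_genome(seed = 12, genome_length = 250000L, n_clusters = 5L,
                       cluster_size = c(2500L, 4000L),
                       cluster_pingpong = 0, cluster_phased = 0)
  cl <- g$clusters
  cl$u1 <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  rs <- simulate_tissue_library(
    g, "percl", "ovary", 5000L, seed = 12,
    profile = c(mirna = 0, pirna = 1, trf = 0, background = 0),
    cluster_overrides = cl)
  sig <- cluster_signatures(cl, rs)
  ok <- sig$n_reads >= 200
  expect_true(any(ok))
  expect_true(all(abs(sig$u1_fraction[ok] - cl$u1[ok]) <= 0.05))
})
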