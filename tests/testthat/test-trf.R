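test_that("reads map to mature tRNA coordinates with strand mirroring and clipping", {
  trna_plus <- data.frame(trna_id = "t1", isodecoder = "GlyGCC", length = 76L,
                          anticodon_start = 34L, has_CCA = TRUE, chrom = "c1",
                          start = 1000L, end = 1076L, strand = "+")
  rs <- make_reads(start = 1000L, length = 33L)
  m <- map_to_mature(rs, trna_plus)
  expect_equal(c(m$s, m$e), c(1L, 33L))

  trna_minus <- transform(trna_plus, strand = "-")
  # read abutting the genomic end of a minus-strand tRNA starts at s = 1
  rs2 <- make_reads(start = 1076L - 33L, length = 33L, strand = "-")
  m2 <- map_to_mature(rs2, trna_minus)
  expect_equal(c(m2$s, m2$e), c(1L, 33L))

  # antisense reads are excluded and counted
  rs3 <- make_reads(start = 1000L, length = 33L, strand = "-")
  m3 <- map_to_mature(rs3, trna_plus)
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "n_antisense"), 1L)

  # <= 2 nt run-over past the 3' end is clipped to L, more is dropped
  over2 <- make_reads(start = 1050L, length = 28L)   # e = 78 -> clipped to 76
  m4 <- map_to_mature(over2, trna_plus)
  expect_equal(m4$e, 76L)
  over3 <- make_reads(start = 1051L, length = 28L)   # e = 79 -> dropped
  expect_equal(nrow(map_to_mature(over3, trna_plus)), 0L)
})

test_that("the tRF rule table classifies the canonical fragments", {
  # L = 76, anticodon at 34: loop window [31, 39]
  expect_equal(classify_trf(1, 33, 76, 34), "five_tRH")
  expect_equal(classify_trf(1, 20, 76, 34), "five_tRF")
  expect_equal(classify_trf(58, 76, 76, 34), "three_tRF")
  expect_equal(classify_trf(20, 50, 76, 34), "i_tRF")
  expect_equal(classify_trf(31, 76, 76, 34), "three_tRH")
})

test_that("the five classes partition all (s, e) pairs and match the oracle", {
  L <- 76L; a <- 34L
  grid <- expand.grid(s = 1:L, e = 1:L)
  grid <- grid[grid$s <= grid$e, ]
  got <- classify_trf(grid$s, grid$e, L, a)
  want <- mapply(oracle_trf_class, grid$s, grid$e,
                 MoreArgs = list(L = L, a = a))
  expect_equal(got, unname(want))
  expect_true(all(got %in% c("five_tRH", "three_tRH", "five_tRF",
                             "three_tRF", "i_tRF")))
  expect_equal(sort(unique(got)),
               sort(c("five_tRH", "three_tRH", "five_tRF", "three_tRF", "i_tRF")))
})

test_that("classification is invariant to the tRNA's genomic strand", {
  L <- 75L
  tr_p <- data.frame(trna_id = "tp", isodecoder = "X", length = L,
                     anticodon_start = 34L, has_CCA = TRUE, chrom = "c1",
                     start = 1000L, end = 1000L + L, strand = "+")
  tr_m <- transform(tr_p, strand = "-")
  frags <- data.frame(s = c(1L, 1L, 20L, 31L, 44L), e = c(33L, 18L, 52L, 75L, 75L))
  # place equivalent reads on each strand and compare classes
  rs_p <- make_reads(start = 1000L + frags$s - 1L, length = frags$e - frags$s + 1L,
                     strand = "+")
  rs_m <- make_reads(start = 1000L + L - frags$e, length = frags$e - frags$s + 1L,
                     strand = "-")
  mp <- map_to_mature(rs_p, tr_p)
  mm <- map_to_mature(rs_m, tr_m)
  expect_equal(mp[, c("s", "e")], mm[, c("s", "e")])
  expect_equal(classify_trf(mp$s, mp$e, L, 34L), classify_trf(mm$s, mm$e, L, 34L))
})

test_that("tRF abundance tables normalize within sample and rank planted fragments", {
  tr <- data.frame(trna_id = "t1", isodecoder = "GlyGCC", length = 76L,
                   anticodon_start = 34L, has_CCA = TRUE, chrom = "c1",
                   start = 1000L, end = 1076L, strand = "+")
  rs <- ReadSet(data.frame(
    read_id = c("a", "b"), sequence = c(strrep("A", 33), strrep("C", 20)),
    length = c(33L, 20L), chrom = "c1", start = c(1000L, 1000L),
    end = c(1033L, 1020L), strand = "+", n_hits = 1L,
    copy_count = c(30L, 10L)))
  tab <- trf_abundance_table(list(s1 = rs), tr)
  expect_equal(sort(tab$proportions$s1), c(0.25, 0.75))
  expect_equal(sum(tab$proportions$s1), 1, tolerance = 1e-9)

  one <- subset_reads(rs, 1)
  tab1 <- trf_abundance_table(list(s1 = one), tr)
  expect_equal(tab1$proportions$s1, 1.0)

  # generator: the most-planted fragment is the top-ranked tRF
  g <- make_toy_genome(seed = 11, genome_length = 150000L, n_clusters = 3L,
                       cluster_size = c(1000L, 3000L), n_trna = 6L)
  rs2 <- simulate_tissue_library(
    g, "sem", "semen", 4000L, seed = 11,
    profile = c(mirna = 0, pirna = 0, trf = 1, background = 0))
  tab2 <- trf_abundance_table(list(sem = rs2), g$trnas)
  alloc <- attr(rs2, "manifest")$trf_alloc
  top_planted <- alloc[which.max(alloc$n), ]
  expect_equal(tab2$top$trna_id[1], top_planted$trna_id)
  expect_equal(tab2$top$s[1], top_planted$s)
  expect_equal(tab2$top$e[1], top_planted$e)
  # and recovered (s, e) equal the planted coordinates overall
  cls <- classify_trfs(rs2, g$trnas)
  merged <- merge(cls, alloc, by = c("trna_id", "s", "e"), all = TRUE)
  expect_false(any(is.na(merged$copy_count)))
  expect_equal(merged$copy_count, merged$n)
})

test_that("a sample without tRFs yields a flagged all-NA proportion column", {
  tr <- data.frame(trna_id = "t1", isodecoder = "GlyGCC", length = 76L,
                   anticodon_start = 34L, has_CCA = TRUE, chrom = "c1",
                   start = 1000L, end = 1076L, strand = "+")
  with_trf <- make_reads(start = 1000L, length = 33L)
  without <- make_reads(start = 5000L, length = 28L)
  tab <- trf_abundance_table(list(a = with_trf, b = without), tr)
  expect_true(all(is.na(tab$proportions$b)))
  expect_equal(tab$counts$b, 0)
})

test_that("isodecoder coverage aggregates gene copies on mature coordinates", {
  tr <- data.frame(trna_id = c("t1", "t2"), isodecoder = "GlyGCC",
                   length = 76L, anticodon_start = 34L, has_CCA = TRUE,
                   chrom = "c1", start = c(1000L, 5000L), end = c(1076L, 5076L),
                   strand = c("+", "-"))
  rs <- ReadSet(data.frame(
    read_id = c("a", "b"), sequence = strrep("A", 33), length = 33L,
    chrom = "c1", start = c(1000L, 5076L - 33L), end = c(1033L, 5076L),
    strand = c("+", "-"), n_hits = 1L, copy_count = 1L))
  cov <- isodecoder_coverage(rs, tr, "GlyGCC")
  expect_equal(cov$depth[1], 2)
  expect_equal(cov$depth[33], 2)
  expect_equal(cov$depth[34], 0)
})
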