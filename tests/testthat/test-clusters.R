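test_that("putative piRNA filtering removes ncRNA reads and applies the length window", {
  an <- fixture_annots()
  rs <- make_reads(start = c(9000, 610, 9100), length = c(25L, 29L, 29L),
                   strand = "+")
  # 25 nt unannotated read: kept without the length filter, dropped with it
  no_len <- filter_putative_pirnas(rs, an, length_filter = FALSE)
  expect_equal(length(no_len), 2L)   # tRNA read removed regardless
  with_len <- filter_putative_pirnas(rs, an, length_filter = TRUE)
  expect_equal(length(with_len), 1L)
  expect_equal(with_len$reads$start, 9100L)
})

test_that("island calling obeys the gap, count and density thresholds", {
  # 40 distinct reads within 2 kb -> one cluster spanning them
  set.seed(21)
  starts <- sort(sample.int(2000L, 40L))
  rs <- make_reads(start = 5000L + starts, length = 28L,
                   sequence = vapply(1:40, function(i)
                     paste(sample(c("A","C","G","T"), 28, TRUE), collapse = ""),
                     character(1)))
  cl <- call_clusters(rs, max_gap = 1000L, min_reads = 35L, min_density = 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, min(rs$reads$start))
  expect_equal(cl$end, max(rs$reads$end))

  # 10 unique reads only: below min_reads, no cluster
  rs10 <- subset_reads(rs, 1:10)
  expect_equal(nrow(call_clusters(rs10)), 0L)
})

test_that("island calling matches the brute-force oracle on random layouts", {
  for (seed in 1:5) {
    set.seed(seed)
    rs <- random_reads(300, genome_len = 30000L, chroms = c("c1", "c2"))
    got <- call_clusters(rs, max_gap = 400L, min_reads = 5L, min_density = 2)
    col <- collapse_reads(rs)$reads
    want <- oracle_islands(col, max_gap = 400L, min_reads = 5L, min_density = 2)
    want <- want[order(want$chrom, want$start), , drop = FALSE]
    expect_equal(got[, c("chrom", "start", "end", "n_collapsed")],
                 want, ignore_attr = TRUE)
  }
})

test_that("the size-fraction rule removes <50% clusters and keeps the boundary", {
  mk <- function(n_in, n_out, at) {
    make_reads(start = at + seq_len(n_in + n_out) * 3L,
               length = c(rep(28L, n_in), rep(22L, n_out)))
  }
  rs <- ReadSet(rbind(mk(40, 60, 1000)$reads,   # 0.40 -> removed
                      mk(50, 50, 20000)$reads,  # 0.50 -> retained (boundary)
                      mk(90, 10, 40000)$reads)) # 0.90 -> retained
  clusters <- data.frame(cluster_id = c("a", "b", "c"), chrom = "c1",
                         start = c(1000L, 20000L, 40000L),
                         end = c(1400L, 20400L, 40400L),
                         stringsAsFactors = FALSE)
  ann <- annotate_clusters(clusters, rs)
  expect_equal(ann$size_fraction, c(0.40, 0.50, 0.90))
  kept <- filter_size_fraction(ann)
  expect_equal(kept$cluster_id, c("b", "c"))

  # planted fractions {0.3, 0.6, 0.9} -> survivors {0.6, 0.9}
  rs2 <- ReadSet(rbind(mk(30, 70, 1000)$reads, mk(60, 40, 20000)$reads,
                       mk(90, 10, 40000)$reads))
  ann2 <- annotate_clusters(clusters, rs2)
  expect_equal(filter_size_fraction(ann2)$size_fraction, c(0.6, 0.9))
})

test_that("merging respects the 1 kb rule, the 200 bp minimum, and is idempotent", {
  cl <- data.frame(chrom = "c1", start = c(100L, 1300L), end = c(400L, 1500L))
  m <- merge_and_min_length(cl, merge_dist = 1000L, min_len = 200L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 1500L))

  short <- data.frame(chrom = "c1", start = 0L, end = 150L)
  expect_equal(nrow(merge_and_min_length(short)), 0L)

  # brute-force transitive closure on random intervals + idempotence
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    s <- sample.int(50000L, n)
    iv <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE), start = s,
                     end = s + sample(200:2000, n, TRUE))
    got <- merge_and_min_length(iv, merge_dist = 500L, min_len = 1L)
    want <- oracle_merge(iv, merge_dist = 500L)
    expect_equal(got[, c("chrom", "start", "end")],
                 want[, c("chrom", "start", "end")], ignore_attr = TRUE)
    again <- merge_and_min_length(got, merge_dist = 500L, min_len = 1L)
    expect_equal(again[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")])
  }
})

test_that("strandedness uses the strict >2x rule as a per-tissue conjunction", {
  expect_equal(assign_strandedness(21, 10), "plus")          # 21 > 20
  expect_equal(assign_strandedness(20, 10), "bidirectional") # not MORE than double
  expect_equal(assign_strandedness(10, 21), "minus")
  expect_equal(assign_strandedness(10, 10), "bidirectional")
  # two tissues: (30,5) passes, (8,5) fails -> bidirectional
  expect_equal(assign_strandedness(c(30, 8), c(5, 5)), "bidirectional")
  expect_equal(assign_strandedness(c(30, 11), c(5, 5)), "plus")
  # undetected tissues are excluded from the conjunction
  expect_equal(assign_strandedness(c(30, 0), c(5, 0)), "plus")
  expect_error(assign_strandedness(0, 0), "zero reads")
})

test_that("cluster read fractions split clustered and unclustered reads", {
  rs <- make_reads(start = c(rep(1000L, 75), rep(5000L, 25), 9000L),
                   length = 28L)
  clusters <- data.frame(cluster_id = c("X", "Y"), chrom = "c1",
                         start = c(900L, 4900L), end = c(1200L, 5200L),
                         stringsAsFactors = FALSE)
  fr <- cluster_read_fractions(clusters, rs)
  expect_equal(fr$per_cluster$fraction, c(0.75, 0.25))
  expect_equal(sum(fr$per_cluster$fraction), 1)
  expect_equal(fr$clustered_fraction, 100 / 101)
  none <- cluster_read_fractions(clusters[0, ], rs)
  expect_equal(none$clustered_fraction, 0)
})

test_that("cross-tissue overlap sets match a union-find oracle", {
  a <- data.frame(cluster_id = "a1", chrom = "c1", start = 1000L, end = 2000L)
  b <- data.frame(cluster_id = "b1", chrom = "c1", start = 1000L, end = 2000L)
  u <- cluster_overlap_sets(list(t1 = a, t2 = b))
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_tissues, 2L)

  far <- data.frame(cluster_id = "b2", chrom = "c1", start = 4000L, end = 4500L)
  u2 <- cluster_overlap_sets(list(t1 = a, t2 = far))
  expect_equal(nrow(u2), 2L)
  expect_equal(u2$n_tissues, c(1L, 1L))

  for (seed in 1:3) {
    set.seed(seed)
    per <- lapply(1:3, function(i) {
      s <- sample.int(30000L, 12L)
      data.frame(cluster_id = sprintf("t%d_%d", i, 1:12), chrom = "c1",
                 start = s, end = s + sample(200:1500, 12, TRUE))
    })
    names(per) <- c("tA", "tB", "tC")
    got <- cluster_overlap_sets(per, merge_dist = 800L)
    pooled <- do.call(rbind, lapply(names(per), function(tn)
      cbind(per[[tn]][, c("chrom", "start", "end")], tissue = tn)))
    comps <- oracle_overlap_sets(pooled, merge_dist = 800L)
    expect_equal(nrow(got), length(comps))
    want_sets <- sort(unname(vapply(comps, function(ix)
      paste(sort(unique(pooled$tissue[ix])), collapse = ","), character(1))))
    expect_equal(sort(got$tissues), want_sets)
  }
})

test_that("coverage tracks are RPM-conserving and zero where uncovered", {
  rs <- make_reads(start = 1000L, length = 28L)
  cl <- data.frame(chrom = "c1", start = 950L, end = 1100L)
  tr <- coverage_track(cl, rs, total_mapped = 1e6)
  expect_equal(tr$log10_rpm[tr$pos == 960 & tr$strand == "+"], 0)
  expect_equal(tr$log10_rpm[tr$pos == 1010 & tr$strand == "+"], log10(2),
               tolerance = 1e-12)
  expect_true(all(tr$depth[tr$strand == "-"] == 0))
  # depth integrates to read length x copy count within the window
  set.seed(5)
  rs2 <- make_reads(start = 1000L + sample.int(80, 30, TRUE), length = 28L,
                    strand = sample(c("+", "-"), 30, TRUE),
                    copy_count = sample.int(3, 30, TRUE))
  cl2 <- data.frame(chrom = "c1", start = 900L, end = 1300L)
  tr2 <- coverage_track(cl2, rs2, total_mapped = 1e6)
  expect_equal(sum(tr2$depth), sum(rs2$reads$length * rs2$reads$copy_count))
})

test_that("final clusters always satisfy the length and size-fraction rules", {
  g <- make_toy_genome(seed = 5, genome_length = 300000L, n_clusters = 6L,
                       cluster_size = c(1000L, 4000L))
  rs <- simulate_tissue_library(g, "ov", "ovary", 6000L, seed = 5)
  cl <- find_pirna_clusters(rs, g$annots)
  expect_true(all(cl$end - cl$start >= 200L))
  expect_true(all(cl$size_fraction >= 0.5))
  expect_true(all(cl$plus_collapsed + cl$minus_collapsed >= 1L))
})
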