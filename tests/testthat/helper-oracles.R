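# Independent brute-force oracles and fixture builders. These are
# deliberately naive re-derivations of each rule, kept structurally
# different from the package implementations they check.

# quick ReadSet builder; sequences default to all-A of the right length
make_reads <- function(chrom = "c1", start, length = 28L, strand = "+",
                       sequence = NULL, copy_count = 1L, ...) {
  n <- base::length(start)
  if (n == 0L) return(ReadSet(data.frame(), ...))
  start <- as.integer(start)
  length <- rep_len(as.integer(length), n)
  strand <- rep_len(strand, n)
  if (is.null(sequence)) sequence <- strrep("A", length)
  ReadSet(data.frame(read_id = sprintf("r%04d", seq_len(n)),
                     sequence = sequence, length = length,
                     chrom = rep_len(chrom, n), start = start,
                     end = start + length, strand = strand,
                     n_hits = 1L, copy_count = rep_len(as.integer(copy_count), n),
                     stringsAsFactors = FALSE), ...)
}

# random read layout on a small genome, both strands
random_reads <- function(n, genome_len = 20000L, len_range = c(26L, 31L),
                         chroms = "c1", copy_max = 1L) {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sapply(len, function(l) sample.int(genome_len - l, 1L))
  make_reads(chrom = sample(chroms, n, replace = TRUE), start = start,
             length = len, strand = sample(c("+", "-"), n, replace = TRUE),
             copy_count = sample.int(copy_max, n, replace = TRUE))
}

# --- island calling oracle: check every candidate contiguous run of
# sorted collapsed reads for the gap condition, keep maximal ones
oracle_islands <- function(df, max_gap, min_reads, min_density) {
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && d$start[j + 1] - d$start[j] <= max_gap) j <- j + 1
      s <- min(d$start[i:j]); e <- max(d$end[i:j]); cnt <- j - i + 1
      if (cnt >= min_reads && cnt / ((e - s) / 1000) >= min_density)
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                             n_collapsed = cnt)
      i <- j + 1
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), n_collapsed = integer()))
  do.call(rbind, out)
}

# --- transitive merge oracle: repeated pairwise merging to fixpoint
oracle_merge <- function(iv, merge_dist) {
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv$chrom[i] == iv$chrom[i + 1] &&
          iv$start[i + 1] - iv$end[i] <= merge_dist) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        merged_any <- TRUE
      } else i <- i + 1
    }
    if (!merged_any) break
  }
  rownames(iv) <- NULL
  iv
}

# --- union-find oracle for cross-tissue cluster membership
oracle_overlap_sets <- function(pooled, merge_dist) {
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && pooled$chrom[i] == pooled$chrom[j] &&
        pooled$start[j] <= pooled$end[i] + merge_dist &&
        pooled$start[i] <= pooled$end[j] + merge_dist) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# --- ping-pong histogram oracle: all pairs, double loop
oracle_pingpong <- function(rs, max_overlap = 30L) {
  df <- collapse_reads(rs)$reads
  hist <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (nrow(df) < 2) return(hist)
  f5 <- ifelse(df$strand == "+", df$start, df$end - 1L)
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (df$strand[i] == "+" && df$strand[j] == "-" &&
        df$chrom[i] == df$chrom[j]) {
      o <- f5[j] - f5[i] + 1L
      if (o >= 1 && o <= max_overlap)
        hist[o] <- hist[o] + df$copy_count[i] * df$copy_count[j]
    }
  }
  hist
}

# --- phasing histogram oracle: per group, sort 5' ends and diff
oracle_phasing <- function(rs, max_dist = 50L) {
  df <- collapse_reads(rs)$reads
  hist <- setNames(numeric(max_dist), seq_len(max_dist))
  for (ch in unique(df$chrom)) for (s in c("+", "-")) {
    d <- df[df$chrom == ch & df$strand == s, , drop = FALSE]
    if (nrow(d) < 2) next
    if (s == "+") {
      d <- d[order(d$start, d$end), , drop = FALSE]
      dist <- d$start[-1] - (d$end[-nrow(d)] - 1L)
    } else {
      d <- d[order(d$end, d$start, decreasing = TRUE), , drop = FALSE]
      dist <- d$start[-nrow(d)] - (d$end[-1] - 1L)
    }
    for (x in dist) if (x >= 1 && x <= max_dist) hist[x] <- hist[x] + 1
  }
  hist
}

# --- tRF class oracle: plain decision list over named conditions
oracle_trf_class <- function(s, e, L, a, hw = 3L) {
  starts_5p <- s <= 2
  ends_3p <- e >= L - 2
  loop <- (a - hw):(a + 2 + hw)
  e_in_loop <- e %in% loop
  s_in_loop <- s %in% loop
  if (starts_5p && e_in_loop) return("five_tRH")
  if (ends_3p && s_in_loop) return("three_tRH")
  if (starts_5p && !e_in_loop && e < L - 2) return("five_tRF")
  if (ends_3p && !s_in_loop) return("three_tRF")
  "i_tRF"
}

# --- BH step-up oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- exact-test oracle: enumerate the conditional split distribution
# directly from NB densities at an arbitrary mean (the conditional is
# mean-free, which this oracle verifies by construction)
oracle_exact_p <- function(a, b, nA = 1L, nB = 1L, phi = 0, mu = 7.3) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  dens <- function(x, nrep) {
    if (phi == 0) dpois(x, nrep * mu)
    else dnbinom(x, size = nrep / phi, mu = nrep * mu)
  }
  w <- dens(k, nA) * dens(t - k, nB)
  p <- w / sum(w)
  sum(p[p <= p[a + 1] * (1 + 1e-8)])
}

# minimal annotation fixture: one of each biotype on a 10 kb toy chrom
fixture_annots <- function() {
  AnnotationSet(data.frame(
    feature_id = c("rr1", "tr1", "mir1", "nc1", "g1", "g1_e1", "g1_e2", "te1"),
    chrom = "c1",
    start = c(100L, 600L, 1000L, 1400L, 2000L, 2000L, 2600L, 4000L),
    end = c(400L, 675L, 1080L, 1600L, 3000L, 2300L, 3000L, 4500L),
    strand = c("+", "+", "+", "-", "+", "+", "+", "-"),
    biotype = c("rRNA", "tRNA", "pre_miRNA", "other_ncRNA", "gene", "exon",
                "exon", "TE"),
    te_class = c(NA, NA, NA, NA, NA, NA, NA, "II"),
    te_family = c(NA, NA, NA, NA, NA, NA, NA, "Mariner/TC1"),
    anticodon_start = c(NA, 33L, NA, NA, NA, NA, NA, NA),
    cca = c(NA, TRUE, NA, NA, NA, NA, NA, NA),
    isodecoder = c(NA, "GlyGCC", NA, NA, NA, NA, NA, NA),
    parent = c(NA, NA, NA, NA, NA, "g1", "g1", NA),
    stringsAsFactors = FALSE))
}
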