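# piRNA cluster identification: density-based island calling on
# ncRNA-filtered reads, then the post-filters applied in order --
# size-fraction (>= 50% of reads 26-31 nt), merging of clusters
# overlapping or within 1 kb, removal of clusters < 200 bp, and
# strandedness assignment by the strict >2x collapsed-read rule.

#' Filter a library down to putative piRNAs
#'
#' Removes reads assigned to structural/regulatory ncRNA biotypes
#' (rRNA, tRNA, pre_miRNA, other_ncRNA) but keeps protein-coding and
#' unannotated reads. With `length_filter = TRUE` only 26-31 nt reads
#' are retained; the length filter is off for cluster seeding and on
#' for signature analyses, matching the order the filters are applied.
#'
#' @param rs a ReadSet.
#' @param annots an AnnotationSet.
#' @param length_filter apply the 26-31 nt window.
#' @param len_range the piRNA length window.
#' @return filtered ReadSet (library metadata preserved).
#' @export
filter_putative_pirnas <- function(rs, annots, length_filter = FALSE,
                                   len_range = c(26L, 31L)) {
  if (nrow(rs$reads) == 0L) return(rs)
  labels <- assign_biotype(rs, annots)
  keep <- !(labels %in% c("rRNA", "tRNA", "pre_miRNA", "other_ncRNA"))
  if (length_filter)
    keep <- keep & rs$reads$length >= len_range[1] & rs$reads$length <= len_range[2]
  subset_reads(rs, keep)
}

#' Call raw piRNA clusters as dense read islands
#'
#' On collapsed reads sorted by (chrom, start), islands are maximal
#' runs in which consecutive read starts are at most `max_gap` apart.
#' An island becomes a raw cluster iff it holds at least `min_reads`
#' unique (collapsed) reads and its collapsed-read density is at least
#' `min_density` per kb. Cluster bounds are the min start / max end of
#' member reads.
#'
#' @param rs ReadSet of ncRNA-filtered reads; collapsed internally if
#'   rows are not already unique (sequence, locus) entries.
#' @param max_gap maximum start-to-start gap within an island (bp).
#' @param min_reads minimum unique reads per cluster.
#' @param min_density minimum collapsed reads per kb.
#' @return data.frame with columns cluster_id, chrom, start, end,
#'   n_collapsed.
#' @export
call_clusters <- function(rs, max_gap = 1000L, min_reads = 35L,
                          min_density = 10) {
  df <- collapse_reads(rs)$reads
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_collapsed = integer(), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  new_chrom <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)])
  gap_break <- c(TRUE, diff(df$start) > max_gap)
  island <- cumsum(new_chrom | gap_break)
  dt <- data.table(chrom = df$chrom, start = df$start, end = df$end,
                   island = island)
  isl <- dt[, list(chrom = chrom[1], start = min(start), end = max(end),
                   n_collapsed = .N), by = island]
  width <- isl$end - isl$start
  dens <- isl$n_collapsed / (width / 1000)
  keep <- isl$n_collapsed >= min_reads & dens >= min_density
  isl <- as.data.frame(isl)[keep, c("chrom", "start", "end", "n_collapsed")]
  if (nrow(isl) == 0L) return(empty)
  rownames(isl) <- NULL
  cbind(data.frame(cluster_id = sprintf("cl%04d", seq_len(nrow(isl))),
                   stringsAsFactors = FALSE), isl)
}

#' Attach read statistics to cluster intervals
#'
#' For each cluster interval, counts overlapping reads from `rs`
#' (all lengths, ncRNA-filtered): total (uncollapsed) reads, unique
#' collapsed reads per strand, and the fraction of total reads in the
#' 26-31 nt piRNA size window.
#' @param clusters data.frame with chrom/start/end (and any id cols).
#' @param rs ReadSet of putative piRNAs, all lengths.
#' @param len_range the piRNA size window.
#' @return `clusters` with columns total_reads, plus_collapsed,
#'   minus_collapsed, reads_in_range, size_fraction appended/updated.
#' @export
annotate_clusters <- function(clusters, rs, len_range = c(26L, 31L)) {
  n <- nrow(clusters)
  clusters$total_reads <- integer(n)
  clusters$plus_collapsed <- integer(n)
  clusters$minus_collapsed <- integer(n)
  clusters$reads_in_range <- integer(n)
  clusters$size_fraction <- rep(NA_real_, n)
  if (n == 0L) return(clusters)
  col <- collapse_reads(rs)$reads
  cgr <- GenomicRanges::GRanges(clusters$chrom,
                                IRanges::IRanges(clusters$start + 1L, clusters$end))
  hits_tot <- GenomicRanges::findOverlaps(as_granges(rs), cgr, ignore.strand = TRUE)
  hits_col <- GenomicRanges::findOverlaps(as_granges(col), cgr, ignore.strand = TRUE)
  qt <- S4Vectors::queryHits(hits_tot); st <- S4Vectors::subjectHits(hits_tot)
  qc <- S4Vectors::queryHits(hits_col); sc <- S4Vectors::subjectHits(hits_col)
  w <- rs$reads$copy_count
  inr <- rs$reads$length >= len_range[1] & rs$reads$length <= len_range[2]
  add <- function(idx, vals) {
    out <- numeric(n)
    if (length(idx)) {
      s <- tapply(vals, idx, sum)
      out[as.integer(names(s))] <- s
    }
    out
  }
  clusters$total_reads <- as.integer(add(st, w[qt]))
  clusters$reads_in_range <- as.integer(add(st, (w * inr)[qt]))
  clusters$plus_collapsed <- as.integer(add(sc[col$strand[qc] == "+"],
                                            rep(1L, sum(col$strand[qc] == "+"))))
  clusters$minus_collapsed <- as.integer(add(sc[col$strand[qc] == "-"],
                                             rep(1L, sum(col$strand[qc] == "-"))))
  clusters$size_fraction <- ifelse(clusters$total_reads > 0,
                                   clusters$reads_in_range / clusters$total_reads,
                                   NA_real_)
  clusters
}

#' Remove clusters failing the 50% size-fraction rule
#'
#' Clusters in which fewer than half of the (total, uncollapsed) reads
#' are 26-31 nt are dropped; exactly 50% is retained, since the rule
#' removes only clusters with *less than* 50%.
#' @param clusters annotated cluster data.frame (see
#'   [annotate_clusters()]); if `size_fraction` is missing and `rs`
#'   given, statistics are computed first.
#' @param rs optional ReadSet to (re)compute statistics from.
#' @param min_fraction threshold (default 0.5).
#' @return filtered cluster data.frame.
#' @export
filter_size_fraction <- function(clusters, rs = NULL, min_fraction = 0.5) {
  if (is.null(clusters$size_fraction)) {
    if (is.null(rs)) stopf("size_fraction absent; supply rs")
    clusters <- annotate_clusters(clusters, rs)
  }
  keep <- !is.na(clusters$size_fraction) & clusters$size_fraction >= min_fraction
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby clusters and apply the minimum length rule
#'
#' Transitively merges clusters that overlap or whose gap is at most
#' `merge_dist` bp (envelope bounds, per-strand/total tallies summed,
#' size_fraction recomputed from the summed tallies), then removes
#' merged clusters shorter than `min_len` bp. Idempotent.
#' @param clusters cluster data.frame (annotated columns optional).
#' @param merge_dist maximum gap for merging (bp).
#' @param min_len minimum retained cluster length (bp).
#' @return merged, filtered cluster data.frame.
#' @export
merge_and_min_length <- function(clusters, merge_dist = 1000L, min_len = 200L) {
  if (nrow(clusters) == 0L) return(clusters)
  cl <- clusters[order(clusters$chrom, clusters$start, clusters$end), , drop = FALSE]
  n <- nrow(cl)
  # running envelope end per chrom gives transitive closure in one pass
  grp <- integer(n); g <- 1L; grp[1] <- 1L
  env_end <- cl$end[1]
  if (n > 1) for (i in 2:n) {
    if (cl$chrom[i] != cl$chrom[i - 1] || cl$start[i] - env_end > merge_dist) {
      g <- g + 1L
      env_end <- cl$end[i]
    } else {
      env_end <- max(env_end, cl$end[i])
    }
    grp[i] <- g
  }
  sum_col <- function(col) if (is.null(cl[[col]])) NULL else
    as.integer(tapply(cl[[col]], grp, sum))
  out <- data.frame(
    chrom = as.character(tapply(cl$chrom, grp, `[`, 1)),
    start = as.integer(tapply(cl$start, grp, min)),
    end = as.integer(tapply(cl$end, grp, max)),
    stringsAsFactors = FALSE)
  for (col in c("n_collapsed", "total_reads", "plus_collapsed",
                "minus_collapsed", "reads_in_range")) {
    v <- sum_col(col)
    if (!is.null(v)) out[[col]] <- v
  }
  if (!is.null(out$total_reads) && !is.null(out$reads_in_range))
    out$size_fraction <- ifelse(out$total_reads > 0,
                                out$reads_in_range / out$total_reads, NA_real_)
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out))
    out <- cbind(data.frame(cluster_id = sprintf("cl%04d", seq_len(nrow(out))),
                            stringsAsFactors = FALSE), out)
  else
    out <- cbind(data.frame(cluster_id = character(0), stringsAsFactors = FALSE), out)
  out
}

#' Assign cluster strandedness by the strict >2x rule
#'
#' A cluster is called `plus` (or `minus`) iff that strand's collapsed
#' read count strictly exceeds twice the other strand's count in
#' *every* tissue where the cluster is detected (>= 1 collapsed read);
#' otherwise it is `bidirectional`. Equal counts, or exactly double,
#' are bidirectional.
#'
#' @param plus_counts,minus_counts integer vectors of per-tissue
#'   collapsed read counts for one cluster.
#' @return one of "plus", "minus", "bidirectional".
#' @export
assign_strandedness <- function(plus_counts, minus_counts) {
  stopifnot(length(plus_counts) == length(minus_counts))
  detected <- (plus_counts + minus_counts) >= 1
  if (!any(detected)) stopf("cluster with zero reads in all tissues")
  p <- plus_counts[detected]; m <- minus_counts[detected]
  if (all(p > 2 * m)) return("plus")
  if (all(m > 2 * p)) return("minus")
  "bidirectional"
}

#' Full single-library cluster calling pipeline
#'
#' ncRNA filter (length filter off) -> collapse -> island calling ->
#' size-fraction filter -> merge within 1 kb -> 200 bp minimum ->
#' re-annotate -> per-cluster strand call (single-library mode: the
#' >2x rule applied to this library alone).
#' @param rs a ReadSet (raw library).
#' @param annots an AnnotationSet.
#' @param max_gap,min_reads,min_density island-calling parameters.
#' @param merge_dist,min_len merge/minimum-length parameters.
#' @param min_fraction size-fraction threshold.
#' @return cluster data.frame with strand_call column; attribute
#'   `putative` carries the filtered ReadSet.
#' @export
find_pirna_clusters <- function(rs, annots, max_gap = 1000L, min_reads = 35L,
                                min_density = 10, merge_dist = 1000L,
                                min_len = 200L, min_fraction = 0.5) {
  put <- filter_putative_pirnas(rs, annots, length_filter = FALSE)
  raw <- call_clusters(put, max_gap = max_gap, min_reads = min_reads,
                       min_density = min_density)
  raw <- annotate_clusters(raw, put)
  kept <- filter_size_fraction(raw, min_fraction = min_fraction)
  merged <- merge_and_min_length(kept, merge_dist = merge_dist, min_len = min_len)
  merged <- annotate_clusters(merged, put)
  merged$strand_call <- if (nrow(merged)) {
    vapply(seq_len(nrow(merged)), function(i)
      assign_strandedness(merged$plus_collapsed[i], merged$minus_collapsed[i]),
      character(1))
  } else character(0)
  structure(merged, putative = put)
}

#' Per-cluster read fractions and the clustered/unclustered split
#'
#' Computed on total (uncollapsed) length-filtered putative piRNAs.
#' Per-cluster fractions are over clustered reads and sum to 1; the
#' overall `clustered_fraction` is the share of all putative piRNAs
#' falling inside any cluster.
#' @param clusters final cluster data.frame.
#' @param rs length-filtered putative piRNA ReadSet.
#' @return list(per_cluster = data.frame(cluster_id, reads, fraction),
#'   clustered_fraction, n_total).
#' @export
cluster_read_fractions <- function(clusters, rs) {
  total <- sum(rs$reads$copy_count)
  if (nrow(clusters) == 0L || total == 0) {
    return(list(per_cluster = data.frame(cluster_id = character(),
                                         reads = numeric(), fraction = numeric()),
                clustered_fraction = 0, n_total = total))
  }
  cgr <- GenomicRanges::GRanges(clusters$chrom,
                                IRanges::IRanges(clusters$start + 1L, clusters$end))
  hits <- GenomicRanges::findOverlaps(as_granges(rs), cgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  # a read overlapping several clusters counts once, at its first cluster
  first <- !duplicated(qi)
  qi <- qi[first]; si <- si[first]
  w <- rs$reads$copy_count[qi]
  per <- numeric(nrow(clusters))
  if (length(si)) {
    s <- tapply(w, si, sum)
    per[as.integer(names(s))] <- s
  }
  clustered <- sum(per)
  list(per_cluster = data.frame(cluster_id = clusters$cluster_id,
                                reads = per,
                                fraction = if (clustered > 0) per / clustered else rep(0, length(per)),
                                stringsAsFactors = FALSE),
       clustered_fraction = clustered / total,
       n_total = total)
}

#' Unify per-tissue cluster sets and record detection membership
#'
#' Clusters from different tissues that overlap or lie within
#' `merge_dist` of each other are unified (same transitive rule as
#' within-tissue merging); each unified cluster carries the set of
#' tissues whose clusters it absorbed.
#' @param per_tissue named list of final cluster data.frames.
#' @param merge_dist maximum gap for unification (bp).
#' @return data.frame cluster_id, chrom, start, end, n_tissues,
#'   tissues (comma-separated).
#' @export
cluster_overlap_sets <- function(per_tissue, merge_dist = 1000L) {
  stopifnot(!is.null(names(per_tissue)))
  pooled <- do.call(rbind, lapply(names(per_tissue), function(tn) {
    cl <- per_tissue[[tn]]
    if (is.null(cl) || nrow(cl) == 0L) return(NULL)
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               tissue = tn, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_tissues = integer(), tissues = character(),
                      stringsAsFactors = FALSE))
  }
  cl <- pooled[order(pooled$chrom, pooled$start, pooled$end), , drop = FALSE]
  n <- nrow(cl)
  grp <- integer(n); g <- 1L; grp[1] <- 1L
  env_end <- cl$end[1]
  if (n > 1) for (i in 2:n) {
    if (cl$chrom[i] != cl$chrom[i - 1] || cl$start[i] - env_end > merge_dist) {
      g <- g + 1L; env_end <- cl$end[i]
    } else env_end <- max(env_end, cl$end[i])
    grp[i] <- g
  }
  tiss <- tapply(cl$tissue, grp, function(z) sort(unique(z)))
  out <- data.frame(
    chrom = as.character(tapply(cl$chrom, grp, `[`, 1)),
    start = as.integer(tapply(cl$start, grp, min)),
    end = as.integer(tapply(cl$end, grp, max)),
    n_tissues = vapply(tiss, length, integer(1)),
    tissues = vapply(tiss, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cbind(data.frame(cluster_id = sprintf("u%04d", seq_len(nrow(out))),
                   stringsAsFactors = FALSE), out)
}

#' Stranded log10(RPM+1) coverage track for a cluster
#'
#' Per-base read depth (copy-weighted) within the cluster interval,
#' RPM-normalized by `total_mapped` and transformed as log10(RPM + 1)
#' so zero-coverage positions are 0.
#' @param cluster one-row cluster data.frame (chrom, start, end).
#' @param rs a ReadSet.
#' @param total_mapped library size; defaults to `rs$total_mapped`.
#' @return data.frame chrom, pos (0-based), strand, depth, log10_rpm.
#' @export
coverage_track <- function(cluster, rs, total_mapped = NULL) {
  total_mapped <- total_mapped %||% rs$total_mapped
  pos <- cluster$start:(cluster$end - 1L)
  out <- expand.grid(pos = pos, strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  out$chrom <- cluster$chrom
  out$depth <- 0
  df <- rs$reads
  sel <- df$chrom == cluster$chrom & df$start < cluster$end & df$end > cluster$start
  df <- df[sel, , drop = FALSE]
  if (nrow(df)) {
    for (s in c("+", "-")) {
      d <- df[df$strand == s, , drop = FALSE]
      if (nrow(d) == 0L) next
      depth <- numeric(length(pos))
      for (i in seq_len(nrow(d))) {
        lo <- max(d$start[i], cluster$start) - cluster$start + 1L
        hi <- min(d$end[i], cluster$end) - cluster$start
        depth[lo:hi] <- depth[lo:hi] + d$copy_count[i]
      }
      out$depth[out$strand == s] <- depth
    }
  }
  out$log10_rpm <- log10_rpm(out$depth, total_mapped)
  out[, c("chrom", "pos", "strand", "depth", "log10_rpm")]
}

#' Write a coverage track as bedGraph
#' @param track output of [coverage_track()].
#' @param path output path.
#' @param strand which strand to emit ("+" or "-").
#' @param value column to write (default "log10_rpm").
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = "+", value = "log10_rpm") {
  t0 <- track[track$strand == strand, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%.6g", t0$chrom, t0$pos, t0$pos + 1L, t0[[value]])
  writeLines(c(sprintf("track type=bedGraph name=coverage_%s", strand), lines), path)
  invisible(path)
}

#' Write clusters as BED6+ / TSV
#' @param clusters cluster data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  df <- clusters
  strand6 <- if (!is.null(df$strand_call))
    c(plus = "+", minus = "-", bidirectional = ".")[df$strand_call] else rep(".", nrow(df))
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$cluster_id, score = df$total_reads %||% 0L,
                    strand = strand6,
                    size_fraction = round(df$size_fraction %||% NA_real_, 4),
                    plus_collapsed = df$plus_collapsed %||% NA_integer_,
                    minus_collapsed = df$minus_collapsed %||% NA_integer_,
                    strand_call = df$strand_call %||% NA_character_,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
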