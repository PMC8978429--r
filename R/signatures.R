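# piRNA biogenesis signatures: 1U/10A nucleotide biases, the ping-pong
# 10 nt 5'-overlap enrichment Z-score and the phasing 3'-5' distance
# Z-score.
#
# Ping-pong background = overlaps 1..30 excluding 10; phasing
# background = distances 2..50 excluding 1. Both windows are exposed as
# arguments.

#' 1U and 10A bias fractions
#'
#' Copy-weighted fraction of reads with T at position 1 (in read
#' orientation) and, among reads of length >= 10, with A at position
#' 10. Intended for reads in the 26-31 nt piRNA window; with
#' `check_range = TRUE` a warning is emitted when reads fall outside
#' it.
#' @param rs a ReadSet.
#' @param check_range warn when reads are outside 26-31 nt.
#' @return list(u1_fraction, a10_fraction, n_reads); fractions NA when
#'   the set is empty.
#' @export
u1_a10_bias <- function(rs, check_range = TRUE) {
  df <- rs$reads
  if (nrow(df) == 0L)
    return(list(u1_fraction = NA_real_, a10_fraction = NA_real_, n_reads = 0))
  if (check_range && any(df$length < 26L | df$length > 31L))
    warnf("u1_a10_bias: %d read(s) outside the 26-31 nt window",
          sum(df$length < 26L | df$length > 31L))
  w <- df$copy_count
  u1 <- sum(w[substr(df$sequence, 1, 1) == "T"]) / sum(w)
  long <- df$length >= 10L
  a10 <- if (any(long))
    sum(w[long][substr(df$sequence[long], 10, 10) == "A"]) / sum(w[long])
  else NA_real_
  list(u1_fraction = u1, a10_fraction = a10, n_reads = sum(w))
}

#' Ping-pong 5'-overlap histogram
#'
#' For every (+, -) read pair on the same chromosome whose 5' ends p
#' (+ read) and q (- read) satisfy q >= p, the overlap o = q - p + 1
#' (the number of bases the two 5' ends span) increments bin o for
#' o in 1..`max_overlap`. Pairs are weighted by the product of copy
#' counts (`weighting = "copy"`) or counted once per unique collapsed
#' pair (`weighting = "unique"`). Ping-pong amplification shows as
#' enrichment at o = 10.
#' @param rs a ReadSet.
#' @param max_overlap largest overlap binned.
#' @param weighting "copy" or "unique".
#' @return named numeric vector over 1:max_overlap.
#' @export
pingpong_overlap_histogram <- function(rs, max_overlap = 30L,
                                       weighting = c("copy", "unique")) {
  weighting <- match.arg(weighting)
  df <- collapse_reads(rs)$reads
  hist <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (nrow(df) == 0L) return(hist)
  w <- if (weighting == "copy") df$copy_count else rep(1, nrow(df))
  f5 <- ifelse(df$strand == "+", df$start, df$end - 1L)
  for (ch in unique(df$chrom)) {
    on <- df$chrom == ch
    plus <- on & df$strand == "+"
    minus <- on & df$strand == "-"
    if (!any(plus) || !any(minus)) next
    # aggregate weight per distinct 5' position, then convolve
    wp <- tapply(w[plus], f5[plus], sum)
    wm <- tapply(w[minus], f5[minus], sum)
    pp <- as.integer(names(wp)); qq <- as.integer(names(wm))
    for (o in seq_len(max_overlap)) {
      idx <- match(pp + o - 1L, qq)
      ok <- !is.na(idx)
      if (any(ok)) hist[o] <- hist[o] + sum(wp[ok] * wm[idx[ok]])
    }
  }
  hist
}

#' Ping-pong enrichment Z-score
#'
#' Z = (count at overlap `signal` - mean of background counts) /
#' background scale, background = all other overlaps in the histogram.
#' Histogram bins are count data, so the background scale is the
#' empirical sd floored at the Poisson value sqrt(mean): without the
#' floor, background draws that happen to be tight produce spuriously
#' extreme Z on null data. A flat histogram gives Z = 0; with no
#' background counts at all the score has no scale and is flagged NA.
#' @param overlap_hist output of [pingpong_overlap_histogram()].
#' @param signal the tested overlap (10 nt for ping-pong).
#' @return Z-score; NA (flagged undefined) when no background scale
#'   exists.
#' @export
pingpong_zscore <- function(overlap_hist, signal = 10L) {
  bg <- overlap_hist[-signal]
  s <- max(sd(bg), sqrt(mean(bg)), na.rm = TRUE)
  if (s == 0)
    return(if (unname(overlap_hist[signal]) == 0) 0 else NA_real_)
  unname((overlap_hist[signal] - mean(bg)) / s)
}

#' Phasing 3'-5' distance histogram
#'
#' Reads are grouped by (chrom, strand) and sorted by 5' position in
#' transcription direction. For each consecutive same-strand pair, the
#' distance d = (downstream 5' position) - (upstream 3' position) in
#' transcription direction is recorded when 1 <= d <= `max_dist`; d = 1
#' means perfect head-to-tail adjacency. Collapsed reads are used, one
#' count per consecutive pair.
#' @param rs a ReadSet.
#' @param max_dist largest distance binned.
#' @return named numeric vector over 1:max_dist.
#' @export
phasing_distance_histogram <- function(rs, max_dist = 50L) {
  df <- collapse_reads(rs)$reads
  hist <- setNames(numeric(max_dist), seq_len(max_dist))
  if (nrow(df) < 2L) return(hist)
  for (ch in unique(df$chrom)) for (s in c("+", "-")) {
    d0 <- df[df$chrom == ch & df$strand == s, , drop = FALSE]
    if (nrow(d0) < 2L) next
    if (s == "+") {
      o <- order(d0$start, d0$end)
      f5 <- d0$start[o]; f3 <- d0$end[o] - 1L
      dist <- f5[-1] - f3[-length(f3)]
    } else {
      # transcription runs right to left: sort by 5' (= end-1) descending
      o <- order(-(d0$end), -(d0$start))
      f5 <- d0$end[o] - 1L; f3 <- d0$start[o]
      dist <- f3[-length(f3)] - f5[-1]
    }
    dist <- dist[dist >= 1 & dist <= max_dist]
    if (length(dist)) {
      tt <- table(dist)
      hist[as.integer(names(tt))] <- hist[as.integer(names(tt))] + as.numeric(tt)
    }
  }
  hist
}

#' Phasing Z-score
#'
#' Z = (count at d = 1 - mean of counts at d in 2..max) / background
#' scale, where the scale is the empirical sd of the background counts
#' floored at the Poisson value sqrt(mean) (see [pingpong_zscore()] for
#' the rationale). The one-sided normal-tail p-value is attached as
#' attribute `p_value`.
#' @param distance_hist output of [phasing_distance_histogram()].
#' @return Z-score with attribute `p_value`; NA when no background
#'   scale exists.
#' @export
phasing_zscore <- function(distance_hist) {
  bg <- distance_hist[-1]
  s <- max(sd(bg), sqrt(mean(bg)), na.rm = TRUE)
  if (s == 0) {
    if (unname(distance_hist[1]) == 0) {
      z <- 0
      attr(z, "p_value") <- 0.5
      return(z)
    }
    return(NA_real_)
  }
  z <- unname((distance_hist[1] - mean(bg)) / s)
  attr(z, "p_value") <- pnorm(z, lower.tail = FALSE)
  z
}

#' All biogenesis signatures for one read set
#'
#' Computes 1U/10A fractions, the ping-pong overlap histogram and
#' Z-score, and the phasing distance histogram and Z-score for a read
#' set (typically the 26-31 nt putative piRNAs of one cluster or one
#' library). Z-scores are reported as NA below `min_reads` reads.
#' @param rs a ReadSet (26-31 nt putative piRNAs).
#' @param min_reads minimum copy-weighted reads for a defined Z.
#' @param max_overlap,max_dist histogram windows.
#' @return object of class `SignatureResult`.
#' @export
compute_signatures <- function(rs, min_reads = 50L, max_overlap = 30L,
                               max_dist = 50L) {
  bias <- u1_a10_bias(rs, check_range = FALSE)
  oh <- pingpong_overlap_histogram(rs, max_overlap = max_overlap)
  dh <- phasing_distance_histogram(rs, max_dist = max_dist)
  enough <- bias$n_reads >= min_reads
  res <- list(n_reads = bias$n_reads,
              u1_fraction = bias$u1_fraction,
              a10_fraction = bias$a10_fraction,
              overlap_hist = oh,
              pingpong_z = if (enough) pingpong_zscore(oh) else NA_real_,
              distance_hist = dh,
              phasing_z = if (enough) phasing_zscore(dh) else NA_real_,
              defined = enough)
  class(res) <- "SignatureResult"
  res
}

#' @export
print.SignatureResult <- function(x, ...) {
  cat(sprintf("SignatureResult (%d reads%s)\n", x$n_reads,
              if (x$defined) "" else "; below minimum, Z undefined"))
  cat(sprintf("  1U %.3f  10A %.3f  ping-pong Z %.2f  phasing Z %.2f\n",
              x$u1_fraction, x$a10_fraction,
              x$pingpong_z, as.numeric(x$phasing_z)))
  invisible(x)
}

#' Per-cluster signature table
#' @param clusters final cluster data.frame.
#' @param rs length-filtered putative piRNA ReadSet.
#' @param ... passed to [compute_signatures()].
#' @return data.frame with one row per cluster: n_reads, u1, a10,
#'   pingpong_z, phasing_z.
#' @export
cluster_signatures <- function(clusters, rs, ...) {
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    sel <- rs$reads$chrom == clusters$chrom[i] &
      rs$reads$start < clusters$end[i] & rs$reads$end > clusters$start[i]
    sig <- compute_signatures(subset_reads(rs, sel), ...)
    data.frame(cluster_id = clusters$cluster_id[i], n_reads = sig$n_reads,
               u1_fraction = sig$u1_fraction, a10_fraction = sig$a10_fraction,
               pingpong_z = sig$pingpong_z, phasing_z = as.numeric(sig$phasing_z),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), n_reads = numeric(),
                      u1_fraction = numeric(), a10_fraction = numeric(),
                      pingpong_z = numeric(), phasing_z = numeric()))
  }
  do.call(rbind, rows)
}
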