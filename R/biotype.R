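# Biotype profiling: read-length histograms, biotype proportion tables
# and positional nucleotide frequencies (the classic small-RNA library
# QC views).

BIOTYPE_PRECEDENCE <- c("rRNA", "tRNA", "pre_miRNA", "other_ncRNA", "mRNA")

#' Assign a biotype label to each read
#'
#' Labels follow the precedence ladder rRNA > tRNA > pre_miRNA >
#' other_ncRNA > mRNA > unannotated, using any-overlap on either strand
#' (a read antisense to a tRNA still reflects tRNA origin ambiguity;
#' strand-aware counting lives in the feature-targeting module). The
#' mRNA category is the union of exon and intron features of
#' protein-coding genes. TE overlap does not enter the ladder.
#'
#' @param rs a ReadSet.
#' @param annots an AnnotationSet.
#' @param ignore_strand overlap on either strand (default TRUE).
#' @return character vector of labels, one per alignment row.
#' @export
assign_biotype <- function(rs, annots, ignore_strand = TRUE) {
  nr <- nrow(rs$reads)
  if (nr == 0L) return(character(0))
  labels <- rep("unannotated", nr)
  feats <- annots$features
  if (nrow(feats) == 0L) return(labels)
  fb <- feats$biotype
  fb[fb %in% c("exon", "intron")] <- "mRNA"
  consider <- fb %in% BIOTYPE_PRECEDENCE
  if (!any(consider)) return(labels)
  fgr <- annots$gr[consider]
  fb <- fb[consider]
  hits <- GenomicRanges::findOverlaps(as_granges(rs), fgr,
                                      ignore.strand = ignore_strand)
  if (length(hits) == 0L) return(labels)
  qi <- S4Vectors::queryHits(hits)
  rank <- match(fb[S4Vectors::subjectHits(hits)], BIOTYPE_PRECEDENCE)
  best <- tapply(rank, qi, min)
  labels[as.integer(names(best))] <- BIOTYPE_PRECEDENCE[best]
  labels
}

#' Read length histogram
#'
#' Copy-weighted counts for every length in `[lo, hi]`; out-of-range
#' reads are excluded and their count reported as an attribute.
#' @param rs a ReadSet.
#' @param lo,hi length window in nt.
#' @return named integer vector over lo:hi with attribute
#'   `n_out_of_range`.
#' @export
length_histogram <- function(rs, lo = 13L, hi = 43L) {
  if (lo > hi) stopf("length_histogram: lo > hi")
  lens <- lo:hi
  counts <- integer(length(lens))
  names(counts) <- lens
  df <- rs$reads
  inr <- df$length >= lo & df$length <= hi
  if (any(inr)) {
    agg <- tapply(df$copy_count[inr], factor(df$length[inr], levels = lens), sum)
    agg[is.na(agg)] <- 0L
    counts[] <- as.integer(agg)
  }
  attr(counts, "n_out_of_range") <- sum(df$copy_count[!inr])
  counts
}

#' Biotype profile of a library
#'
#' The Fig-1A-style view: per-length counts, per-biotype fractions of
#' mapped reads, and the length x biotype matrix.
#' @param rs a ReadSet.
#' @param annots an AnnotationSet.
#' @param lo,hi length window in nt.
#' @return object of class `BiotypeProfile`: list with `length_counts`,
#'   `biotype_fractions` (sums to 1), `matrix` (length x biotype,
#'   copy-weighted counts) and `n_reads`.
#' @export
biotype_profile <- function(rs, annots, lo = 13L, hi = 43L) {
  labels <- assign_biotype(rs, annots)
  cats <- c(BIOTYPE_PRECEDENCE, "unannotated")
  df <- rs$reads
  inr <- df$length >= lo & df$length <= hi
  lens <- lo:hi
  m <- matrix(0, nrow = length(lens), ncol = length(cats),
              dimnames = list(lens, cats))
  if (any(inr)) {
    t2 <- tapply(df$copy_count[inr],
                 list(factor(df$length[inr], levels = lens),
                      factor(labels[inr], levels = cats)), sum)
    t2[is.na(t2)] <- 0
    m[] <- t2
  }
  total <- sum(m)
  fractions <- if (total > 0) colSums(m) / total else setNames(rep(NA_real_, length(cats)), cats)
  structure(list(length_counts = length_histogram(rs, lo, hi),
                 biotype_fractions = fractions,
                 matrix = m, n_reads = total),
            class = "BiotypeProfile")
}

#' @export
print.BiotypeProfile <- function(x, ...) {
  cat(sprintf("BiotypeProfile: %d reads in range\n", x$n_reads))
  print(round(x$biotype_fractions, 4))
  invisible(x)
}

#' Positional nucleotide frequencies
#'
#' Per-position base fractions in read (5'->3') orientation, computed
#' on reads whose length falls in `len_range` (default 26-31 nt, the
#' putative piRNA window). Position p uses only reads long enough to
#' have a base there; fractions at each position sum to 1 over A/C/G/T
#' (N excluded).
#' @param rs a ReadSet.
#' @param len_range length window, e.g. `c(26, 31)`.
#' @param max_pos last position profiled.
#' @return matrix positions x bases of fractions, with attribute
#'   `n_reads`; flagged `undefined = TRUE` when no reads qualify.
#' @export
nucleotide_frequency <- function(rs, len_range = c(26L, 31L), max_pos = 31L) {
  df <- rs$reads
  sel <- df$length >= len_range[1] & df$length <= len_range[2]
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_real_, nrow = max_pos, ncol = 4,
                dimnames = list(seq_len(max_pos), bases))
  if (!any(sel)) {
    attr(out, "undefined") <- TRUE
    attr(out, "n_reads") <- 0
    return(out)
  }
  seqs <- df$sequence[sel]
  w <- df$copy_count[sel]
  lens <- df$length[sel]
  for (p in seq_len(max_pos)) {
    long_enough <- lens >= p
    if (!any(long_enough)) next
    b <- substr(seqs[long_enough], p, p)
    wp <- w[long_enough]
    cnt <- vapply(bases, function(nt) sum(wp[b == nt]), numeric(1))
    tot <- sum(cnt)
    if (tot > 0) out[p, ] <- cnt / tot
  }
  attr(out, "undefined") <- FALSE
  attr(out, "n_reads") <- sum(w)
  out
}
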