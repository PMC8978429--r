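# Strand-aware counting of putative piRNAs over TEs, exons, introns
# and intergenic space; TE class/family tables; chi-squared tissue
# comparisons; differential antisense targeting.

#' Count putative piRNAs over genomic feature categories
#'
#' Each read is assigned to at most one feature by category precedence
#' (default TE > exon > intron); within the chosen category the feature
#' with the largest overlap wins. A read counts toward a feature only
#' when the overlap covers at least `min_overlap_frac` of the read
#' length. Orientation relative to the feature strand is recorded as
#' sense/antisense. Counts are copy-weighted totals.
#'
#' @param rs length- and ncRNA-filtered putative piRNA ReadSet.
#' @param annots an AnnotationSet.
#' @param categories biotype categories in precedence order.
#' @param min_overlap_frac minimum overlap as a fraction of read length.
#' @return object of class `TargetingTable`: data.frame feature_id,
#'   category, te_class, te_family, feature_strand, sense_count,
#'   antisense_count; attributes `n_total` (input reads) and
#'   `n_assigned`.
#' @export
count_feature_reads <- function(rs, annots,
                                categories = c("TE", "exon", "intron"),
                                min_overlap_frac = 0.5) {
  feats <- annots$features[annots$features$biotype %in% categories, , drop = FALSE]
  empty <- data.frame(feature_id = character(), category = character(),
                      te_class = character(), te_family = character(),
                      feature_strand = character(),
                      sense_count = numeric(), antisense_count = numeric(),
                      stringsAsFactors = FALSE)
  n_total <- sum(rs$reads$copy_count)
  if (nrow(feats) == 0L || nrow(rs$reads) == 0L) {
    attr(empty, "n_total") <- n_total
    attr(empty, "n_assigned") <- 0
    class(empty) <- c("TargetingTable", "data.frame")
    return(empty)
  }
  fgr <- GenomicRanges::GRanges(feats$chrom,
                                IRanges::IRanges(feats$start + 1L, feats$end))
  rgr <- as_granges(rs)
  hits <- GenomicRanges::findOverlaps(rgr, fgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ovw <- IRanges::width(IRanges::pintersect(IRanges::ranges(rgr)[qi],
                                            IRanges::ranges(fgr)[si]))
  frac_ok <- ovw >= min_overlap_frac * rs$reads$length[qi]
  qi <- qi[frac_ok]; si <- si[frac_ok]; ovw <- ovw[frac_ok]
  # pick one feature per read: best category rank, then largest overlap
  rank <- match(feats$biotype[si], categories)
  o <- order(qi, rank, -ovw)
  qi <- qi[o]; si <- si[o]
  first <- !duplicated(qi)
  qi <- qi[first]; si <- si[first]
  w <- rs$reads$copy_count[qi]
  sense <- rs$reads$strand[qi] == feats$strand[si]
  dt <- data.table(fi = si, w = w, sense = sense)
  agg <- dt[, list(sense_count = sum(w[sense]),
                   antisense_count = sum(w[!sense])), by = fi]
  out <- data.frame(feature_id = feats$feature_id,
                    category = feats$biotype,
                    te_class = feats$te_class,
                    te_family = feats$te_family,
                    feature_strand = feats$strand,
                    sense_count = 0, antisense_count = 0,
                    stringsAsFactors = FALSE)
  out$sense_count[agg$fi] <- agg$sense_count
  out$antisense_count[agg$fi] <- agg$antisense_count
  attr(out, "n_total") <- n_total
  attr(out, "n_assigned") <- sum(w)
  class(out) <- c("TargetingTable", "data.frame")
  out
}

#' @export
print.TargetingTable <- function(x, ...) {
  cat(sprintf("TargetingTable: %d features, %g/%g reads assigned\n",
              nrow(x), attr(x, "n_assigned"), attr(x, "n_total")))
  invisible(x)
}

#' Intergenic read count
#'
#' Putative piRNAs not assigned to any feature category: total minus
#' assigned, per the subtraction rule.
#' @param rs the ReadSet the table was computed from.
#' @param table a [count_feature_reads()] result.
#' @return non-negative count.
#' @export
intergenic_count <- function(rs, table) {
  out <- sum(rs$reads$copy_count) - attr(table, "n_assigned")
  if (out < 0) stopf("internal error: assigned reads exceed total (double counting)")
  out
}

#' TE family percentage table
#'
#' Percentage of TE-mapped putative piRNAs per TE family (sense +
#' antisense), the Table-1-style view. Percentages sum to 100 within
#' the tissue.
#' @param table a [count_feature_reads()] result for one tissue.
#' @return data.frame te_class, te_family, reads, percent.
#' @export
te_family_table <- function(table) {
  te <- table[table$category == "TE", , drop = FALSE]
  if (nrow(te) == 0L) {
    return(data.frame(te_class = character(), te_family = character(),
                      reads = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  dt <- as.data.table(data.frame(
    te_class = te$te_class, te_family = te$te_family,
    reads = te$sense_count + te$antisense_count, stringsAsFactors = FALSE))
  agg <- as.data.frame(dt[, list(reads = sum(reads)),
                          by = list(te_class, te_family)])
  agg <- agg[agg$reads > 0, , drop = FALSE]  # percentages over observed families
  rownames(agg) <- NULL
  tot <- sum(agg$reads)
  agg$percent <- if (tot > 0) 100 * agg$reads / tot else NA_real_
  agg[order(-agg$reads), , drop = FALSE]
}

#' Chi-squared comparison of TE class proportions between tissues
#'
#' Pearson chi-squared (no continuity correction) on the 2x2 table of
#' (class I, class II) read counts x (tissue A, tissue B).
#' @param tableA,tableB [count_feature_reads()] results for the two
#'   tissues.
#' @return list(statistic, df, p_value, table, low_expected) where
#'   `low_expected` flags any expected cell below 1.
#' @export
compare_class_proportions <- function(tableA, tableB) {
  class_counts <- function(tb) {
    te <- tb[tb$category == "TE" & !is.na(tb$te_class), , drop = FALSE]
    reads <- te$sense_count + te$antisense_count
    c(I = sum(reads[te$te_class == "I"]), II = sum(reads[te$te_class == "II"]))
  }
  m <- rbind(A = class_counts(tableA), B = class_counts(tableB))
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warnf("chi-squared: expected cell count below 1")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = m, low_expected = low)
}

#' Differentially targeted genes/TEs between two tissues
#'
#' Features with significantly more putative piRNAs mapping antisense
#' in one tissue than the other, using the package's conditioned NB
#' exact test with the standard DE thresholds on the antisense count
#' matrix.
#' @param antisense_counts matrix features x samples of antisense read
#'   counts.
#' @param groups tissue label per sample column.
#' @param pair character(2): the two tissues compared.
#' @param ... passed to [call_de()] (fdr_max, fc_min, min_count).
#' @return [call_de()] result; `table` rows are the candidate features
#'   ranked by fdr then fold change.
#' @export
differential_targeting <- function(antisense_counts, groups, pair, ...) {
  de <- call_de(antisense_counts, groups, pair, ...)
  tab <- de$table
  o <- order(!tab$DE, tab$fdr, -tab$fold_change)
  de$table <- tab[o, , drop = FALSE]
  de
}
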