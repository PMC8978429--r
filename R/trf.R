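# tRNA fragment (tRF) classification: reads are mapped onto mature
# tRNA coordinates and sorted into the five positional classes
# (5'/3' halves, 5'/3' tRFs, internal tRFs) by a concrete rule table:
# 5' start tolerance s <= 2, 3' terminus zone L-2..L (accommodating
# the CCA tail), anticodon loop window = anticodon start +/- 3.

#' Build the mature tRNA table from an AnnotationSet
#'
#' One row per tRNA gene: mature length (genomic width, CCA included
#' when present), 1-based anticodon start position and isodecoder
#' label (tRNA gene copies sharing an anticodon).
#' @param annots AnnotationSet whose tRNA features carry
#'   `anticodon_start` (0-based genomic-side offset) and `cca`.
#' @return data.frame trna_id, isodecoder, length, anticodon_start
#'   (1-based), has_CCA, chrom, start, end, strand.
#' @export
mature_trnas <- function(annots) {
  tr <- features_by_biotype(annots, "tRNA")
  if (nrow(tr) == 0L) {
    return(data.frame(trna_id = character(), isodecoder = character(),
                      length = integer(), anticodon_start = integer(),
                      has_CCA = logical(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(trna_id = tr$feature_id,
             isodecoder = ifelse(is.na(tr$isodecoder), tr$feature_id, tr$isodecoder),
             length = tr$end - tr$start,
             anticodon_start = tr$anticodon_start + 1L,
             has_CCA = ifelse(is.na(tr$cca), FALSE, tr$cca),
             chrom = tr$chrom, start = tr$start, end = tr$end,
             strand = tr$strand, stringsAsFactors = FALSE)
}

#' Map reads onto mature tRNA coordinates
#'
#' Converts genomic coordinates of reads overlapping one tRNA gene to
#' 1-based positions on the mature tRNA, strand-aware (reads on a
#' minus-strand tRNA are mirrored). Antisense reads are excluded (count
#' reported as attribute `n_antisense`); reads running at most 2 nt
#' past the mature 3' end are clipped to L (non-templated CCA-adjacent
#' additions), reads extending further, or past the 5' end, are
#' dropped.
#' @param rs a ReadSet.
#' @param trna one row of [mature_trnas()].
#' @return data.frame s, e (1-based inclusive mature coordinates),
#'   copy_count, read_row; attribute `n_antisense`.
#' @export
map_to_mature <- function(rs, trna) {
  df <- rs$reads
  ov <- df$chrom == trna$chrom & df$start < trna$end & df$end > trna$start
  anti <- ov & df$strand != trna$strand
  sense <- which(ov & df$strand == trna$strand)
  L <- trna$length
  if (trna$strand == "+") {
    s <- df$start[sense] - trna$start + 1L
    e <- df$end[sense] - trna$start
  } else {
    s <- trna$end - df$end[sense] + 1L
    e <- trna$end - df$start[sense]
  }
  keep <- s >= 1L & e <= L + 2L
  s <- s[keep]; e <- pmin(e[keep], L)
  out <- data.frame(s = s, e = e, copy_count = df$copy_count[sense][keep],
                    read_row = sense[keep])
  attr(out, "n_antisense") <- sum(df$copy_count[anti])
  out
}

#' Classify a tRNA fragment by mature-coordinate position
#'
#' With anticodon loop window W = [a - loop_halfwidth,
#' a + 2 + loop_halfwidth] and 3' terminus zone starting at L - 2, the
#' rules are applied in order: five_tRH iff s <= 2 and e in W;
#' three_tRH iff e >= L - 2 and s in W; five_tRF iff s <= 2 and e
#' before the terminus zone (and not in W); three_tRF iff e >= L - 2
#' (and s not in W); i_tRF otherwise. Total and mutually exclusive over
#' all valid (s, e). Vectorized over s/e.
#' @param s,e 1-based inclusive fragment coordinates on the mature tRNA.
#' @param L mature tRNA length.
#' @param anticodon_start 1-based anticodon first position a.
#' @param loop_halfwidth half-width of the anticodon loop window.
#' @return character vector of classes.
#' @export
classify_trf <- function(s, e, L, anticodon_start, loop_halfwidth = 3L) {
  a <- anticodon_start
  w_lo <- a - loop_halfwidth
  w_hi <- a + 2L + loop_halfwidth
  in_w <- function(x) x >= w_lo & x <= w_hi
  cls <- rep("i_tRF", length(s))
  cls[e >= L - 2L & !in_w(s)] <- "three_tRF"
  cls[s <= 2L & e < L - 2L & !in_w(e)] <- "five_tRF"
  cls[e >= L - 2L & in_w(s)] <- "three_tRH"
  cls[s <= 2L & in_w(e)] <- "five_tRH"
  cls
}

#' Classify all tRNA-derived reads of a library
#'
#' Maps reads onto every tRNA and classifies them; fragments are keyed
#' by (trna_id, s, e).
#' @param rs a ReadSet.
#' @param trnas [mature_trnas()] table.
#' @param loop_halfwidth passed to [classify_trf()].
#' @return data.frame trna_id, isodecoder, s, e, length, trf_class,
#'   copy_count (aggregated per key).
#' @export
classify_trfs <- function(rs, trnas, loop_halfwidth = 3L) {
  rows <- lapply(seq_len(nrow(trnas)), function(i) {
    tr <- trnas[i, ]
    m <- map_to_mature(rs, tr)
    if (nrow(m) == 0L) return(NULL)
    data.frame(trna_id = tr$trna_id, isodecoder = tr$isodecoder,
               s = m$s, e = m$e, length = m$e - m$s + 1L,
               trf_class = classify_trf(m$s, m$e, tr$length,
                                        tr$anticodon_start, loop_halfwidth),
               copy_count = m$copy_count, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(trna_id = character(), isodecoder = character(),
                      s = integer(), e = integer(), length = integer(),
                      trf_class = character(), copy_count = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  dt <- as.data.table(df)
  out <- as.data.frame(dt[, list(copy_count = sum(copy_count)),
                          by = list(trna_id, isodecoder, s, e, length, trf_class)])
  out[order(-out$copy_count), , drop = FALSE]
}

#' Cross-sample tRF abundance table
#'
#' tRFs keyed by (trna_id, s, e); per-sample proportions are normalized
#' within each sample's tRF total (columns sum to 1). The `top`
#' attribute ranks fragments by their maximum proportion across
#' samples.
#' @param readsets named list of ReadSets (one per sample).
#' @param trnas [mature_trnas()] table.
#' @param top_k how many fragments the top-k report keeps.
#' @return list(counts, proportions) of data.frames keyed by
#'   trna_id/isodecoder/s/e/trf_class with one column per sample, plus
#'   `top` (top_k rows of proportions by max abundance). Samples with
#'   zero tRFs keep an all-zero, `NA`-flagged column.
#' @export
trf_abundance_table <- function(readsets, trnas, top_k = 10L) {
  stopifnot(!is.null(names(readsets)))
  per <- lapply(readsets, classify_trfs, trnas = trnas)
  keys <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("trna_id", "isodecoder", "s", "e", "trf_class")])))
  if (is.null(keys) || nrow(keys) == 0L) {
    empty <- data.frame()
    return(list(counts = empty, proportions = empty, top = empty))
  }
  keys <- keys[order(keys$trna_id, keys$s, keys$e), , drop = FALSE]
  rownames(keys) <- NULL
  key_id <- function(d) paste(d$trna_id, d$s, d$e, sep = ":")
  kid <- key_id(keys)
  counts <- keys
  props <- keys
  for (sm in names(per)) {
    v <- numeric(nrow(keys))
    d <- per[[sm]]
    if (nrow(d)) v[match(key_id(d), kid)] <- d$copy_count
    counts[[sm]] <- v
    tot <- sum(v)
    props[[sm]] <- if (tot > 0) v / tot else rep(NA_real_, length(v))
  }
  samp_cols <- names(per)
  mx <- apply(as.matrix(props[, samp_cols, drop = FALSE]), 1,
              function(z) if (all(is.na(z))) 0 else max(z, na.rm = TRUE))
  top <- props[order(-mx), , drop = FALSE]
  top <- utils::head(top, top_k)
  list(counts = counts, proportions = props, top = top)
}

#' Per-position abundance map over a mature tRNA (isodecoder)
#'
#' Copy-weighted read depth at each mature-tRNA position, summed over
#' all gene copies of an isodecoder — the per-isodecoder positional
#' view of tRF production.
#' @param rs a ReadSet.
#' @param trnas [mature_trnas()] table.
#' @param isodecoder isodecoder label (e.g. "GlyGCC").
#' @return data.frame pos (1-based mature coordinate), depth.
#' @export
isodecoder_coverage <- function(rs, trnas, isodecoder) {
  tr <- trnas[trnas$isodecoder == isodecoder, , drop = FALSE]
  if (nrow(tr) == 0L) stopf("unknown isodecoder: %s", isodecoder)
  L <- max(tr$length)
  depth <- numeric(L)
  for (i in seq_len(nrow(tr))) {
    m <- map_to_mature(rs, tr[i, ])
    for (j in seq_len(nrow(m)))
      depth[m$s[j]:m$e[j]] <- depth[m$s[j]:m$e[j]] + m$copy_count[j]
  }
  data.frame(pos = seq_len(L), depth = depth)
}
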