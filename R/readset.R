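# ReadSet: the package's container for aligned small-RNA reads.
#
# Coordinates are 0-based half-open throughout the package; GFF3 and SAM
# I/O convert from/to their native 1-based conventions at the boundary.
# The 5' genomic position of a read is `start` on the + strand and
# `end - 1` on the - strand.

#' Construct a ReadSet
#'
#' A ReadSet holds one library's genome alignments of small-RNA reads
#' plus library metadata. Each row is one alignment: multi-mapped reads
#' appear once per reported alignment (`n_hits` records how many), and
#' `copy_count` carries the number of identical reads collapsed into the
#' row (1 before collapsing).
#'
#' @param reads data.frame with columns `read_id`, `sequence` (read
#'   orientation, T not U), `length`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand` ("+"/"-"), `n_hits`, `copy_count`.
#'   Missing `n_hits`/`copy_count` default to 1; `length` defaults to
#'   `end - start`.
#' @param sample_id,tissue library metadata labels.
#' @param total_mapped total mapped reads in the library; defaults to
#'   the sum of `copy_count`.
#' @return object of class `ReadSet`.
#' @export
ReadSet <- function(reads, sample_id = NA_character_, tissue = NA_character_,
                    total_mapped = NULL) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) {
    reads <- data.frame(read_id = character(), sequence = character(),
                        length = integer(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), n_hits = integer(),
                        copy_count = integer(), stringsAsFactors = FALSE)
  } else {
    if (is.null(reads$length)) reads$length <- reads$end - reads$start
    if (is.null(reads$n_hits)) reads$n_hits <- 1L
    if (is.null(reads$copy_count)) reads$copy_count <- 1L
    if (is.null(reads$read_id)) reads$read_id <- sprintf("r%06d", seq_len(nrow(reads)))
    need <- c("read_id", "sequence", "length", "chrom", "start", "end",
              "strand", "n_hits", "copy_count")
    miss <- setdiff(need, names(reads))
    if (length(miss)) stopf("ReadSet is missing columns: %s", paste(miss, collapse = ", "))
    reads <- reads[, need]
    bad <- which(reads$end - reads$start != reads$length)
    if (length(bad)) stopf("read %s: end - start != length", reads$read_id[bad[1]])
    if (!all(reads$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-'")
  }
  rownames(reads) <- NULL
  structure(list(reads = reads,
                 sample_id = sample_id,
                 tissue = tissue,
                 total_mapped = total_mapped %||% sum(reads$copy_count)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d alignments (%d reads), sample=%s tissue=%s\n",
              nrow(x$reads), sum(x$reads$copy_count),
              x$sample_id, x$tissue))
  if (nrow(x$reads)) {
    rng <- range(x$reads$length)
    cat(sprintf("  lengths %d-%d nt on %d sequence(s)\n",
                rng[1], rng[2], length(unique(x$reads$chrom))))
  }
  invisible(x)
}

#' @export
length.ReadSet <- function(x) nrow(x$reads)

#' Number of reads (copy-weighted) in a ReadSet
#' @param rs a ReadSet.
#' @return total read count (sum of `copy_count`).
#' @export
n_reads <- function(rs) sum(rs$reads$copy_count)

#' Subset a ReadSet by a logical or integer index over alignments
#' @param rs a ReadSet.
#' @param i logical or integer index on rows of `rs$reads`.
#' @return ReadSet with the same library metadata.
#' @export
subset_reads <- function(rs, i) {
  ReadSet(rs$reads[i, , drop = FALSE], sample_id = rs$sample_id,
          tissue = rs$tissue, total_mapped = rs$total_mapped)
}

#' 5' genomic position of each read
#'
#' `start` for + strand reads, `end - 1` for - strand reads (0-based).
#' @param rs a ReadSet.
#' @return integer vector.
#' @export
five_prime_pos <- function(rs) {
  ifelse(rs$reads$strand == "+", rs$reads$start, rs$reads$end - 1L)
}

#' 3' genomic position of each read
#' @param rs a ReadSet.
#' @return integer vector (`end - 1` on +, `start` on -; 0-based).
#' @export
three_prime_pos <- function(rs) {
  ifelse(rs$reads$strand == "+", rs$reads$end - 1L, rs$reads$start)
}

as_granges <- function(rs_or_df) {
  df <- if (inherits(rs_or_df, "ReadSet")) rs_or_df$reads else rs_or_df
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         strand = df$strand)
}

#' Read small-RNA alignments from SAM/BAM or tabular format
#'
#' Accepts coordinate-addressed alignments in SAM/BAM (via Rsamtools) or
#' the package's 7-column TSV (chrom, start, end, read_id, copy_count,
#' strand, sequence; 0-based half-open). Unmapped records are dropped,
#' records with no stored sequence are skipped (with a message), and
#' reads outside `[min_len, max_len]` are removed. `n_hits` is taken
#' from the NH tag when present, else 1. Alignments are assumed ungapped
#' (small RNAs map contiguously), so the reference span equals the read
#' length.
#'
#' @param path file path (.sam, .bam, .tsv/.txt/.bed).
#' @param min_len,max_len retained read length window in nt.
#' @param sample_id,tissue library metadata for the returned ReadSet.
#' @return ReadSet sorted by (chrom, start). `total_mapped` is the
#'   number of retained reads (copy-weighted).
#' @export
read_alignments <- function(path, min_len = 13L, max_len = 43L,
                            sample_id = NA_character_, tissue = NA_character_) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("sam", "bam")) {
    read_sam_bam(path)
  } else {
    read_alignment_tsv(path)
  }
  if (nrow(df)) {
    keep <- df$length >= min_len & df$length <= max_len
    df <- df[keep, , drop = FALSE]
    o <- order(df$chrom, df$start, df$end, df$strand)
    df <- df[o, , drop = FALSE]
  }
  ReadSet(df, sample_id = sample_id, tissue = tissue)
}

read_sam_bam <- function(path) {
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      length = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_hits = integer(),
                      copy_count = integer(), stringsAsFactors = FALSE))
  }
  seqs <- as.character(x$seq)
  has_seq <- !is.na(seqs) & seqs != "" & seqs != "*"
  if (any(!has_seq)) {
    message(sprintf("read_alignments: skipped %d record(s) without a stored sequence",
                    sum(!has_seq)))
  }
  strand <- as.character(x$strand)
  len <- nchar(seqs)
  # SAM stores the sequence in reference orientation; restore read orientation
  minus <- has_seq & strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(1L, n)
  nh[is.na(nh)] <- 1L
  df <- data.frame(read_id = x$qname, sequence = seqs, length = len,
                   chrom = as.character(x$rname),
                   start = x$pos - 1L, end = x$pos - 1L + len,
                   strand = strand, n_hits = as.integer(nh),
                   copy_count = 1L, stringsAsFactors = FALSE)
  df[has_seq, , drop = FALSE]
}

read_alignment_tsv <- function(path) {
  cols <- c("chrom", "start", "end", "read_id", "copy_count", "strand", "sequence")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      length = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_hits = integer(),
                      copy_count = integer(), stringsAsFactors = FALSE))
  }
  header <- startsWith(first, "chrom\t")
  classes <- c("character", "integer", "integer", "character",
               "integer", "character", "character")
  df <- tryCatch(
    if (header) read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = classes)
    else read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE, colClasses = classes),
    error = function(e) stopf("unparseable alignment table %s: %s", path, conditionMessage(e)))
  names(df) <- cols
  df$length <- df$end - df$start
  df$n_hits <- 1L
  bad <- which(nchar(df$sequence) != df$length)
  if (length(bad))
    stopf("record %d (%s): sequence length != end - start", bad[1], df$read_id[bad[1]])
  df[, c("read_id", "sequence", "length", "chrom", "start", "end",
         "strand", "n_hits", "copy_count")]
}

#' Write a ReadSet to the 7-column alignment TSV
#' @param rs a ReadSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(rs, path) {
  df <- rs$reads[, c("chrom", "start", "end", "read_id", "copy_count",
                     "strand", "sequence")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a ReadSet as SAM text
#'
#' Emits an unsorted-by-spec but coordinate-ordered SAM file with @SQ
#' header lines from `seqinfo` (named integer vector of sequence
#' lengths). Sequences are stored in reference orientation as the format
#' requires.
#' @param rs a ReadSet.
#' @param path output .sam path.
#' @param seqinfo named integer vector: sequence name -> length.
#' @return `path`, invisibly.
#' @export
write_sam <- function(rs, path, seqinfo) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo), as.integer(seqinfo)), con)
  df <- rs$reads
  if (nrow(df)) {
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    flag <- ifelse(df$strand == "-", 16L, 0L)
    seq_ref <- df$sequence
    minus <- df$strand == "-"
    seq_ref[minus] <- revcomp(seq_ref[minus])
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                     df$read_id, flag, df$chrom, df$start + 1L, df$length,
                     seq_ref, df$n_hits)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Collapse alignments to unique (sequence, locus) entries
#'
#' One output row per (sequence, chrom, start, strand); `copy_count`
#' sums the input multiplicities, so the total read count is conserved.
#' The key includes the locus, so per-strand cluster tallies stay
#' locus-resolved.
#' @param rs a ReadSet.
#' @return collapsed ReadSet; `total_mapped` is inherited.
#' @export
collapse_reads <- function(rs) {
  df <- rs$reads
  if (nrow(df) == 0L) return(rs)
  dt <- as.data.table(df)
  out <- dt[, list(read_id = read_id[1], length = length[1], end = end[1],
                   n_hits = n_hits[1], copy_count = sum(copy_count)),
            by = list(sequence, chrom, start, strand)]
  out <- as.data.frame(out)[, c("read_id", "sequence", "length", "chrom",
                                "start", "end", "strand", "n_hits", "copy_count")]
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  ReadSet(out, sample_id = rs$sample_id, tissue = rs$tissue,
          total_mapped = rs$total_mapped)
}

#' Reads-per-million normalization
#' @param count read count(s).
#' @param total_mapped library size (> 0).
#' @return `count * 1e6 / total_mapped`.
#' @export
rpm_normalize <- function(count, total_mapped) {
  if (length(total_mapped) != 1L || is.na(total_mapped) || total_mapped <= 0)
    stopf("rpm_normalize: total_mapped must be a single value > 0")
  count * 1e6 / total_mapped
}

#' log10(RPM + 1) track transform
#'
#' Pseudocount 1 so zero-coverage positions map to 0.
#' @inheritParams rpm_normalize
#' @return `log10(RPM + 1)`.
#' @export
log10_rpm <- function(count, total_mapped) {
  log10(rpm_normalize(count, total_mapped) + 1)
}

#' Read a sample sheet
#' @param path TSV with columns sample_id, tissue, replicate, path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "replicate", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet missing columns: %s", paste(miss, collapse = ", "))
  df
}
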