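# AnnotationSet: strand-aware interval index of genomic features by
# biotype, with introns derived from the gaps between each gene's exons.

GFF_TYPE_MAP <- c(
  rRNA = "rRNA", tRNA = "tRNA", pre_miRNA = "pre_miRNA",
  miRNA_primary_transcript = "pre_miRNA", ncRNA = "other_ncRNA",
  snoRNA = "other_ncRNA", snRNA = "other_ncRNA", lnc_RNA = "other_ncRNA",
  gene = "gene", exon = "exon", intron = "intron",
  transposable_element = "TE", repeat_region = "TE"
)

#' Construct an AnnotationSet from a feature table
#'
#' @param features data.frame with columns `feature_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `biotype` (one of
#'   rRNA, tRNA, pre_miRNA, other_ncRNA, gene, exon, intron, TE) and
#'   optional attribute columns `te_class`, `te_family`,
#'   `anticodon_start` (0-based offset within the tRNA), `cca`,
#'   `isodecoder`, `parent`.
#' @param derive_introns derive intron features as within-gene gaps
#'   between exons sharing a parent gene.
#' @return object of class `AnnotationSet`: a list with `features`
#'   (data.frame) and `gr` (GRanges mirror used for overlap queries).
#' @export
AnnotationSet <- function(features, derive_introns = TRUE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) == 0L) {
    features <- data.frame(feature_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), biotype = character(),
                           te_class = character(), te_family = character(),
                           anticodon_start = integer(), cca = logical(),
                           isodecoder = character(), parent = character(),
                           stringsAsFactors = FALSE)
  }
  for (col in c("te_class", "te_family", "isodecoder", "parent")) {
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  }
  if (is.null(features$anticodon_start)) features$anticodon_start <- NA_integer_
  if (is.null(features$cca)) features$cca <- NA
  if (nrow(features)) {
    bad <- which(features$end <= features$start)
    if (length(bad))
      stopf("feature %s: end <= start", features$feature_id[bad[1]])
    unknown <- !(features$biotype %in% c("rRNA", "tRNA", "pre_miRNA",
                                         "other_ncRNA", "gene", "exon",
                                         "intron", "TE"))
    if (any(unknown)) {
      warnf("%d feature(s) with unknown biotype categorized as other_ncRNA",
            sum(unknown))
      features$biotype[unknown] <- "other_ncRNA"
    }
    trna <- features$biotype == "tRNA"
    if (any(trna)) {
      a <- features$anticodon_start[trna]
      L <- features$end[trna] - features$start[trna]
      bad <- which(!is.na(a) & (a < 0L | a >= L))
      if (length(bad))
        stopf("tRNA %s: anticodon offset outside [0, length)",
              features$feature_id[which(trna)[bad[1]]])
    }
  }
  if (derive_introns && nrow(features)) {
    features <- rbind(features, derive_intron_features(features))
  }
  rownames(features) <- NULL
  gr <- if (nrow(features)) {
    GenomicRanges::GRanges(features$chrom,
                           IRanges::IRanges(features$start + 1L, features$end),
                           strand = features$strand)
  } else GenomicRanges::GRanges()
  structure(list(features = features, gr = gr), class = "AnnotationSet")
}

derive_intron_features <- function(features) {
  ex <- features[features$biotype == "exon" & !is.na(features$parent), , drop = FALSE]
  if (nrow(ex) == 0L) return(features[0, , drop = FALSE])
  out <- list()
  for (g in unique(ex$parent)) {
    e <- ex[ex$parent == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    istart <- e$end[-nrow(e)]
    iend <- e$start[-1]
    keep <- iend > istart
    if (!any(keep)) next
    out[[g]] <- data.frame(
      feature_id = sprintf("%s_intron%d", g, seq_len(sum(keep))),
      chrom = e$chrom[1], start = istart[keep], end = iend[keep],
      strand = e$strand[1], biotype = "intron",
      te_class = NA_character_, te_family = NA_character_,
      anticodon_start = NA_integer_, cca = NA,
      isodecoder = NA_character_, parent = g,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(features[0, , drop = FALSE])
  do.call(rbind, out)
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d features\n", nrow(x$features)))
  if (nrow(x$features)) print(table(x$features$biotype))
  invisible(x)
}

#' Read annotations from GFF3
#'
#' Imports a GFF3 file (via rtracklayer), maps feature types onto the
#' package's biotype vocabulary (rRNA, tRNA, pre_miRNA, other_ncRNA,
#' gene, exon, intron, TE; unknown types become other_ncRNA with a
#' warning) and derives introns from within-gene gaps between exons.
#' TE lines may carry `te_class=I|II;te_family=<name>` attributes; tRNA
#' lines `anticodon_start=<0-based offset>;cca=true|false;isodecoder=`.
#'
#' @param gff_path GFF3 file path.
#' @return AnnotationSet.
#' @export
read_annotations <- function(gff_path) {
  if (!file.exists(gff_path)) stopf("GFF file not found: %s", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0L) return(AnnotationSet(data.frame()))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  biotype <- unname(GFF_TYPE_MAP[type])
  biotype[is.na(biotype)] <- "unknown"
  get_attr <- function(name) {
    if (name %in% names(mc)) {
      v <- mc[[name]]
      if (is(v, "List") || is.list(v)) v <- vapply(v, function(z)
        if (length(z)) as.character(z[1]) else NA_character_, character(1))
      as.character(v)
    } else rep(NA_character_, length(gr))
  }
  id <- get_attr("ID")
  if (all(is.na(id))) id <- sprintf("feat%05d", seq_along(gr))
  id[is.na(id)] <- sprintf("feat%05d", which(is.na(id)))
  parent <- get_attr("Parent")
  cca <- tolower(get_attr("cca"))
  df <- data.frame(
    feature_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = ifelse(biotype == "unknown", "unknown_type", biotype),
    te_class = get_attr("te_class"),
    te_family = get_attr("te_family"),
    anticodon_start = suppressWarnings(as.integer(get_attr("anticodon_start"))),
    cca = ifelse(is.na(cca), NA, cca == "true"),
    isodecoder = get_attr("isodecoder"),
    parent = parent,
    stringsAsFactors = FALSE)
  df$strand[!(df$strand %in% c("+", "-"))] <- "+"
  unknown <- df$biotype == "unknown_type"
  if (any(unknown)) {
    warnf("%d GFF feature(s) of unrecognized type categorized as other_ncRNA",
          sum(unknown))
    df$biotype[unknown] <- "other_ncRNA"
  }
  AnnotationSet(df)
}

#' Write an AnnotationSet to GFF3
#' @param annots AnnotationSet.
#' @param path output path.
#' @param seqinfo optional named integer vector of sequence lengths for
#'   `##sequence-region` directives.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annots, path, seqinfo = NULL) {
  df <- annots$features
  df <- df[df$biotype != "intron", , drop = FALSE]  # introns are derived
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(seqinfo))
    writeLines(sprintf("##sequence-region %s 1 %d", names(seqinfo),
                       as.integer(seqinfo)), con)
  if (nrow(df)) {
    type <- c(rRNA = "rRNA", tRNA = "tRNA", pre_miRNA = "pre_miRNA",
              other_ncRNA = "ncRNA", gene = "gene", exon = "exon",
              TE = "transposable_element")[df$biotype]
    attrs <- sprintf("ID=%s", df$feature_id)
    has_parent <- !is.na(df$parent)
    attrs[has_parent] <- paste0(attrs[has_parent], ";Parent=", df$parent[has_parent])
    te <- df$biotype == "TE" & !is.na(df$te_class)
    attrs[te] <- paste0(attrs[te], ";te_class=", df$te_class[te],
                        ";te_family=", df$te_family[te])
    tr <- df$biotype == "tRNA" & !is.na(df$anticodon_start)
    attrs[tr] <- paste0(attrs[tr], ";anticodon_start=", df$anticodon_start[tr],
                        ";cca=", ifelse(df$cca[tr], "true", "false"),
                        ";isodecoder=", df$isodecoder[tr])
    lines <- sprintf("%s\tbeehive\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     df$chrom, type, df$start + 1L, df$end, df$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Subset features by biotype
#' @param annots AnnotationSet.
#' @param biotypes character vector of biotype labels.
#' @return data.frame of matching features.
#' @export
features_by_biotype <- function(annots, biotypes) {
  annots$features[annots$features$biotype %in% biotypes, , drop = FALSE]
}
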