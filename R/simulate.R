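# Synthetic data with planted truth: a toy genome with annotated
# features and designated piRNA cluster intervals, per-tissue read
# libraries with planted length/biotype mixtures, 1U/10A biases,
# ping-pong pairs and phased read trails, and NB count matrices with
# planted fold changes. Every planted quantity is recorded in a truth
# manifest so each pipeline stage can be checked by parameter
# recovery.
#
# Reads are placed exactly (no mismatch model): the analysis operates
# post-mapping, so exact placement suffices.

DEFAULT_TE_FAMILIES <- data.frame(
  te_family = c("R2", "Gypsy", "Copia", "Mariner/TC1", "PiggyBac"),
  te_class = c("I", "I", "I", "II", "II"),
  weight = c(0.25, 0.2, 0.15, 0.25, 0.15),
  stringsAsFactors = FALSE)

DEFAULT_ISODECODERS <- c("GlyGCC", "GlyGCC", "GlyGCC", "GluCTC", "LysCTT",
                         "AspGTC", "HisGTG", "ValAAC")

#' Default per-tissue small RNA mixture profiles
#'
#' Mixture weights over the four read sources (miRNA 21-23 nt, piRNA
#' 26-31 nt with mode 29, tRF 32-33 nt dominated, background 13-43 nt
#' rain). Semen is tRF-heavy, ovary/egg piRNA-heavy with the 29 nt
#' peak, testis/spermatheca miRNA-heavy — descriptive defaults only.
#' @return named list of weight vectors (mirna, pirna, trf, background).
#' @export
tissue_profiles <- function() {
  list(
    semen = c(mirna = 0.15, pirna = 0.15, trf = 0.60, background = 0.10),
    ovary = c(mirna = 0.15, pirna = 0.70, trf = 0.05, background = 0.10),
    egg = c(mirna = 0.20, pirna = 0.65, trf = 0.05, background = 0.10),
    testis = c(mirna = 0.55, pirna = 0.25, trf = 0.05, background = 0.15),
    spermatheca = c(mirna = 0.45, pirna = 0.30, trf = 0.15, background = 0.10)
  )
}

# rejection-sample n non-overlapping intervals with a buffer, given
# already-occupied intervals; returns data.frame(start, end)
place_intervals <- function(n, len_lo, len_hi, genome_length, occupied,
                            buffer = 200L, max_tries = 10000L) {
  placed <- occupied
  out_s <- integer(0); out_e <- integer(0)
  tries <- 0L
  while (length(out_s) < n && tries < max_tries) {
    tries <- tries + 1L
    len <- len_lo + sample.int(len_hi - len_lo + 1L, 1L) - 1L
    if (genome_length - len - 1L < 1L) next
    s <- sample.int(genome_length - len - 1L, 1L)
    e <- s + len
    clash <- any(s - buffer < placed$end & e + buffer > placed$start)
    if (!clash) {
      placed <- rbind(placed, data.frame(start = s, end = e))
      out_s <- c(out_s, s); out_e <- c(out_e, e)
    }
  }
  if (length(out_s) < n)
    stopf("could not place %d intervals of %d-%d bp in %d bp (placed %d); reduce feature density",
          n, len_lo, len_hi, genome_length, length(out_s))
  data.frame(start = out_s, end = out_e)
}

#' Generate a toy genome with annotated features and planted clusters
#'
#' Builds a random genome containing TE remnants (class I: R2, Gypsy,
#' Copia; class II: Mariner/TC1, PiggyBac), genes with exons/introns,
#' tRNA genes (mature length 75 nt incl. CCA, anticodon at position
#' 34), miRNA hairpins, rRNAs, other ncRNAs, and designated piRNA
#' cluster intervals (kept clear of ncRNA features, with TE remnants
#' planted inside). All planted truth is returned in `manifest`.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param genome_length genome size in bp.
#' @param chrom chromosome name.
#' @param n_clusters,cluster_size number and bp size range of planted
#'   piRNA clusters.
#' @param cluster_buffer minimum bp separating clusters from each
#'   other and from other features (keeps called clusters resolvable).
#' @param cluster_u1 planted 1U bias of cluster piRNAs (NA: positions
#'   sampled uniformly with no base conditioning).
#' @param cluster_pingpong planted fraction of cluster reads generated
#'   as ping-pong pairs.
#' @param cluster_phased planted fraction generated as phased trails.
#' @param strand_modes optional character vector recycling over
#'   clusters ("plus", "minus", "bidirectional"); default samples
#'   uni/bidirectional with most clusters unidirectional.
#' @param n_genes,n_te,n_trna,n_mirna,n_rrna,n_other feature counts.
#' @param te_in_cluster_frac fraction of TEs planted inside clusters.
#' @return object of class `ToyGenome`: list(seq (DNAStringSet),
#'   chars, seqinfo, annots, clusters, trnas, manifest).
#' @export
make_toy_genome <- function(seed = 1L, genome_length = 500000L,
                            chrom = "chrSim",
                            n_clusters = 10L, cluster_size = c(300L, 5000L),
                            cluster_buffer = 3000L,
                            cluster_u1 = 0.75, cluster_pingpong = 0.2,
                            cluster_phased = 0.2, strand_modes = NULL,
                            n_genes = 10L, n_te = 20L, n_trna = 8L,
                            n_mirna = 8L, n_rrna = 3L, n_other = 4L,
                            te_in_cluster_frac = 0.4) {
  set.seed(seed)
  occ <- data.frame(start = integer(0), end = integer(0))
  # clusters first (largest, with wide buffer)
  cl <- place_intervals(n_clusters, cluster_size[1], cluster_size[2],
                        genome_length, occ, buffer = cluster_buffer)
  occ <- rbind(occ, cl)
  if (is.null(strand_modes)) {
    strand_modes <- sample(c("plus", "minus", "bidirectional"), n_clusters,
                           replace = TRUE, prob = c(0.425, 0.425, 0.15))
  } else strand_modes <- rep(strand_modes, length.out = n_clusters)
  clusters <- data.frame(
    cluster_id = sprintf("truth_cl%02d", seq_len(n_clusters)),
    chrom = chrom, start = cl$start, end = cl$end,
    strand_mode = strand_modes,
    u1 = rep(cluster_u1, length.out = n_clusters),
    a10 = NA_real_,
    pingpong = rep(cluster_pingpong, length.out = n_clusters),
    phased = rep(cluster_phased, length.out = n_clusters),
    weight = 1, stringsAsFactors = FALSE)

  feats <- list()
  add_feats <- function(n, len_lo, len_hi, biotype, prefix, extra = NULL) {
    if (n == 0L) return(NULL)
    iv <- place_intervals(n, len_lo, len_hi, genome_length, occ)
    occ <<- rbind(occ, iv)
    df <- data.frame(feature_id = sprintf("%s%02d", prefix, seq_len(n)),
                     chrom = chrom, start = iv$start, end = iv$end,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     biotype = biotype, te_class = NA_character_,
                     te_family = NA_character_, anticodon_start = NA_integer_,
                     cca = NA, isodecoder = NA_character_,
                     parent = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    df
  }
  feats$rrna <- add_feats(n_rrna, 400L, 600L, "rRNA", "rrna")
  feats$mirna <- add_feats(n_mirna, 70L, 90L, "pre_miRNA", "mir")
  feats$other <- add_feats(n_other, 150L, 300L, "other_ncRNA", "nc")
  feats$trna <- add_feats(n_trna, 75L, 75L, "tRNA", "trna",
                          extra = list(anticodon_start = 33L, cca = TRUE,
                                       isodecoder = rep(DEFAULT_ISODECODERS,
                                                        length.out = n_trna)))
  # genes: exon/intron structure
  gene_rows <- list()
  for (i in seq_len(n_genes)) {
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(200:800, n_ex - 1L, replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    iv <- place_intervals(1L, glen, glen, genome_length, occ)
    occ <- rbind(occ, iv)
    gs <- iv$start; strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", i)
    rows <- data.frame(feature_id = gid, chrom = chrom, start = gs,
                       end = gs + glen, strand = strand, biotype = "gene",
                       te_class = NA_character_, te_family = NA_character_,
                       anticodon_start = NA_integer_, cca = NA,
                       isodecoder = NA_character_, parent = NA_character_,
                       stringsAsFactors = FALSE)
    pos <- gs
    for (j in seq_len(n_ex)) {
      rows <- rbind(rows, data.frame(
        feature_id = sprintf("%s_ex%d", gid, j), chrom = chrom,
        start = pos, end = pos + ex_len[j], strand = strand,
        biotype = "exon", te_class = NA_character_,
        te_family = NA_character_, anticodon_start = NA_integer_,
        cca = NA, isodecoder = NA_character_, parent = gid,
        stringsAsFactors = FALSE))
      pos <- pos + ex_len[j] + if (j < n_ex) in_len[j] else 0L
    }
    gene_rows[[i]] <- rows
  }
  feats$genes <- if (n_genes > 0) do.call(rbind, gene_rows) else NULL

  # TEs: a fraction inside cluster intervals (TE remnants), rest outside
  te_rows <- NULL
  if (n_te > 0) {
    fam <- DEFAULT_TE_FAMILIES[sample.int(nrow(DEFAULT_TE_FAMILIES), n_te,
                                          replace = TRUE,
                                          prob = DEFAULT_TE_FAMILIES$weight), ]
    n_in <- round(te_in_cluster_frac * n_te)
    s <- integer(n_te); e <- integer(n_te)
    cl_occ <- data.frame(start = integer(0), end = integer(0))
    for (i in seq_len(n_te)) {
      len <- sample(150:600, 1L)
      if (i <= n_in) {
        # nest inside a cluster wide enough, avoiding other in-cluster TEs
        ok_cl <- which(clusters$end - clusters$start > len + 40L)
        placed <- FALSE
        for (tries in 1:200) {
          ci <- sample(ok_cl, 1L)
          s0 <- clusters$start[ci] + sample.int(clusters$end[ci] - clusters$start[ci] - len, 1L)
          e0 <- s0 + len
          if (!any(s0 < cl_occ$end & e0 > cl_occ$start)) {
            s[i] <- s0; e[i] <- e0
            cl_occ <- rbind(cl_occ, data.frame(start = s0, end = e0))
            placed <- TRUE; break
          }
        }
        if (!placed) { i_out <- place_intervals(1L, len, len, genome_length, occ)
          occ <- rbind(occ, i_out); s[i] <- i_out$start; e[i] <- i_out$end }
      } else {
        iv <- place_intervals(1L, len, len, genome_length, occ)
        occ <- rbind(occ, iv); s[i] <- iv$start; e[i] <- iv$end
      }
    }
    te_rows <- data.frame(feature_id = sprintf("te%02d", seq_len(n_te)),
                          chrom = chrom, start = s, end = e,
                          strand = sample(c("+", "-"), n_te, replace = TRUE),
                          biotype = "TE", te_class = fam$te_class,
                          te_family = fam$te_family,
                          anticodon_start = NA_integer_, cca = NA,
                          isodecoder = NA_character_, parent = NA_character_,
                          stringsAsFactors = FALSE)
  }
  feats$te <- te_rows
  features <- do.call(rbind, feats[!vapply(feats, is.null, logical(1))])
  rownames(features) <- NULL
  annots <- AnnotationSet(features)

  seqchars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  seqstr <- paste(seqchars, collapse = "")
  seq <- Biostrings::DNAStringSet(setNames(seqstr, chrom))
  manifest <- list(
    seed = seed, genome_length = genome_length, chrom = chrom,
    feature_counts = as.list(table(features$biotype)),
    clusters = clusters,
    n_te_in_clusters = if (n_te > 0) sum(vapply(seq_len(nrow(te_rows)), function(i)
      any(te_rows$start[i] >= clusters$start & te_rows$end[i] <= clusters$end),
      logical(1))) else 0L)
  genome <- list(seq = seq, chars = setNames(list(seqchars), chrom),
                 seqstr = setNames(seqstr, chrom),
                 seqinfo = setNames(genome_length, chrom),
                 annots = annots, clusters = clusters,
                 trnas = mature_trnas(annots), manifest = manifest)
  class(genome) <- "ToyGenome"
  genome
}

#' @export
print.ToyGenome <- function(x, ...) {
  cat(sprintf("ToyGenome: %d bp (%s), %d features, %d planted clusters\n",
              x$manifest$genome_length, x$manifest$chrom,
              nrow(x$annots$features), nrow(x$clusters)))
  invisible(x)
}

#' Write a toy genome to disk (FASTA + GFF3 + tRNA table + manifest)
#' @param genome a ToyGenome.
#' @param dir output directory (created).
#' @return invisible named list of written paths.
#' @export
write_toy_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff = file.path(dir, "annotations.gff3"),
                trna = file.path(dir, "mature_trnas.tsv"),
                manifest = file.path(dir, "genome_manifest.json"))
  Biostrings::writeXStringSet(genome$seq, paths$fasta)
  write_annotations(genome$annots, paths$gff, seqinfo = genome$seqinfo)
  write.table(genome$trnas, paths$trna, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(genome$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Default tRF fragment catalog for a toy genome
#'
#' Fragment mixture on mature tRNA coordinates (L = 75, anticodon at
#' 34): a dominant 33 nt 5' half, a 32 nt 3' tRF, plus 5' tRF, 3' half
#' and internal fragments — the 32-33 nt classes carry most weight.
#' GlyGCC gene copies are up-weighted.
#' @param genome a ToyGenome.
#' @return data.frame trna_id, s, e, weight.
#' @export
default_trf_catalog <- function(genome) {
  tr <- genome$trnas
  if (nrow(tr) == 0L) return(data.frame())
  frag <- data.frame(s = c(1L, 1L, 20L, 31L, 44L),
                     e = c(33L, 18L, 52L, 75L, 75L),
                     w = c(0.45, 0.10, 0.15, 0.10, 0.20))
  out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    tw <- if (tr$isodecoder[i] == "GlyGCC") 4 else 1
    data.frame(trna_id = tr$trna_id[i], s = frag$s, e = pmin(frag$e, tr$length[i]),
               weight = frag$w * tw, stringsAsFactors = FALSE)
  }))
  out$weight <- out$weight / sum(out$weight)
  out
}

# sample n 5' positions inside [lo, hi] (0-based) on one strand with a
# planted 1U (and optionally 10A) bias; chars is the chromosome base
# vector. u1 = NA samples positions uniformly (no base conditioning).
# Falls back to unconstrained positions if a class is empty.
sample_biased_5p <- function(chars, lo, hi, strand, n, u1, a10 = NA_real_) {
  if (n == 0L) return(integer(0))
  f <- lo:hi
  if (is.na(u1)) return(f[sample.int(length(f), n, replace = TRUE)])
  base1 <- if (strand == "+") chars[f + 1L] == "T" else chars[f + 1L] == "A"
  pick <- function(pool, k) {
    if (length(pool) == 0L) pool <- f
    pool[sample.int(length(pool), k, replace = TRUE)]
  }
  if (is.na(a10)) {
    want1 <- runif(n) < u1
    out <- integer(n)
    out[want1] <- pick(f[base1], sum(want1))
    out[!want1] <- pick(f[!base1], sum(!want1))
    return(out)
  }
  base10 <- if (strand == "+") chars[f + 10L] == "A" else chars[f - 9L + 1L] == "T"
  want1 <- runif(n) < u1
  want10 <- runif(n) < a10
  out <- integer(n)
  for (c1 in c(TRUE, FALSE)) for (c10 in c(TRUE, FALSE)) {
    sel <- want1 == c1 & want10 == c10
    if (any(sel)) out[sel] <- pick(f[base1 == c1 & base10 == c10], sum(sel))
  }
  out
}

sample_pirna_lengths <- function(n) {
  sample(26:31, n, replace = TRUE, prob = c(0.05, 0.10, 0.15, 0.40, 0.20, 0.10))
}

#' Simulate one tissue library against a toy genome
#'
#' Draws reads from the tissue's mixture over {miRNA 21-23 nt, piRNA
#' 26-31 nt (mode 29), tRF (32-33 nt dominated), background rain
#' 13-43 nt}. piRNA reads are placed inside the genome's planted
#' cluster intervals with the cluster's 1U bias, ping-pong pair
#' fraction (opposite-strand partner, 5' ends offset by 9 so the
#' overlap is 10 nt; the partner's 10th base complements the primary's
#' first, giving the 10A bias) and phased trail fraction (head-to-tail,
#' distance 1). tRFs are drawn from the fragment catalog on tRNA genes
#' (sense strand); background rain is uniform. Alignments are exact by
#' construction. One RNG stream per library, derived from
#' (seed, sample_id).
#'
#' @param genome a ToyGenome.
#' @param sample_id,tissue library labels.
#' @param n_reads total reads to draw (> 0, or 0 for an empty library).
#' @param profile mixture weights (named: mirna, pirna, trf,
#'   background), summing to 1; default taken from [tissue_profiles()]
#'   by tissue name.
#' @param seed master seed; the library stream is derived from it and
#'   `sample_id`.
#' @param trf_catalog fragment catalog (default
#'   [default_trf_catalog()]).
#' @param cluster_overrides optional data.frame replacing the genome's
#'   per-cluster parameters (same columns as `genome$clusters`).
#' @return ReadSet with attribute `manifest`: list(category_counts,
#'   per_read (data.frame category, cluster_id, trna_id, s, e),
#'   cluster_alloc, trf_alloc, profile).
#' @export
simulate_tissue_library <- function(genome, sample_id, tissue, n_reads,
                                    profile = NULL, seed = 1L,
                                    trf_catalog = NULL,
                                    cluster_overrides = NULL) {
  if (n_reads < 0) stopf("n_reads must be >= 0")
  if (is.null(profile)) {
    profile <- tissue_profiles()[[tissue]]
    if (is.null(profile)) stopf("no default profile for tissue '%s'", tissue)
  }
  if (abs(sum(profile) - 1) > 1e-8) stopf("profile weights must sum to 1")
  clusters <- cluster_overrides %||% genome$clusters
  set.seed(derive_seed(seed, sample_id))
  chrom <- genome$manifest$chrom
  chars <- genome$chars[[chrom]]
  glen <- genome$manifest$genome_length
  if (n_reads == 0L) {
    rs <- ReadSet(data.frame(), sample_id = sample_id, tissue = tissue)
    attr(rs, "manifest") <- list(category_counts = c(mirna = 0, pirna = 0,
                                                     trf = 0, background = 0),
                                 per_read = data.frame(), profile = profile)
    return(rs)
  }
  nk <- as.vector(stats::rmultinom(1, n_reads,
                                   profile[c("mirna", "pirna", "trf", "background")]))
  names(nk) <- c("mirna", "pirna", "trf", "background")

  rows <- list()
  meta <- list()

  # --- miRNA reads: sense within pre-miRNA hairpins
  if (nk["mirna"] > 0) {
    mirs <- features_by_biotype(genome$annots, "pre_miRNA")
    if (nrow(mirs) == 0L) stopf("profile requests miRNA reads but genome has no pre_miRNA")
    fi <- sample.int(nrow(mirs), nk["mirna"], replace = TRUE)
    len <- sample(21:23, nk["mirna"], replace = TRUE)
    maxoff <- (mirs$end[fi] - mirs$start[fi]) - len
    off <- floor(runif(nk["mirna"]) * (maxoff + 1))
    st <- mirs$start[fi] + as.integer(off)
    rows$mirna <- data.frame(chrom = chrom, start = st, end = st + len,
                             strand = mirs$strand[fi], stringsAsFactors = FALSE)
    meta$mirna <- data.frame(category = "mirna", cluster_id = NA_character_,
                             trna_id = NA_character_, s = NA_integer_,
                             e = NA_integer_, stringsAsFactors = FALSE)
  }

  # --- tRF reads: fragment catalog on tRNA genes, sense strand
  trf_alloc <- NULL
  if (nk["trf"] > 0) {
    cat <- trf_catalog %||% default_trf_catalog(genome)
    if (nrow(cat) == 0L) stopf("profile requests tRF reads but genome has no tRNAs")
    ci <- sample.int(nrow(cat), nk["trf"], replace = TRUE, prob = cat$weight)
    tr <- genome$trnas[match(cat$trna_id[ci], genome$trnas$trna_id), ]
    s <- cat$s[ci]; e <- cat$e[ci]
    plus <- tr$strand == "+"
    st <- ifelse(plus, tr$start + s - 1L, tr$end - e)
    en <- ifelse(plus, tr$start + e, tr$end - s + 1L)
    rows$trf <- data.frame(chrom = chrom, start = as.integer(st),
                           end = as.integer(en), strand = tr$strand,
                           stringsAsFactors = FALSE)
    meta$trf <- data.frame(category = "trf", cluster_id = NA_character_,
                           trna_id = cat$trna_id[ci], s = s, e = e,
                           stringsAsFactors = FALSE)
    tdt <- as.data.table(meta$trf)
    trf_alloc <- as.data.frame(tdt[, list(n = .N), by = list(trna_id, s, e)])
  }

  # --- piRNA reads: planted clusters
  cluster_alloc <- NULL
  if (nk["pirna"] > 0) {
    if (nrow(clusters) == 0L) stopf("profile requests piRNA reads but genome has no clusters")
    alloc <- as.vector(stats::rmultinom(1, nk["pirna"],
                                        clusters$weight / sum(clusters$weight)))
    cluster_alloc <- data.frame(cluster_id = clusters$cluster_id, n = alloc,
                                stringsAsFactors = FALSE)
    pir <- list()
    for (ci in seq_len(nrow(clusters))) {
      n_c <- alloc[ci]
      if (n_c == 0L) next
      cs <- clusters$start[ci]; ce <- clusters$end[ci]
      mode <- clusters$strand_mode[ci]
      main <- if (mode == "minus") "-" else "+"
      p_main <- if (mode == "bidirectional") 0.5 else 0.9
      u1 <- clusters$u1[ci]; a10 <- clusters$a10[ci]
      n_pp <- 2L * floor(clusters$pingpong[ci] * n_c / 2)
      n_ph <- floor(clusters$phased[ci] * (n_c - n_pp))
      n_ind <- n_c - n_pp - n_ph
      part <- list()
      if (n_ind > 0) {
        strands <- ifelse(runif(n_ind) < p_main, main,
                          if (main == "+") "-" else "+")
        st <- integer(n_ind); en <- integer(n_ind)
        len <- sample_pirna_lengths(n_ind)
        for (s0 in c("+", "-")) {
          k <- which(strands == s0)
          if (!length(k)) next
          if (s0 == "+") {
            f <- sample_biased_5p(chars, cs, ce - 32L, "+", length(k), u1, a10)
            st[k] <- f; en[k] <- f + len[k]
          } else {
            f <- sample_biased_5p(chars, cs + 32L, ce - 1L, "-", length(k), u1, a10)
            en[k] <- f + 1L; st[k] <- f + 1L - len[k]
          }
        }
        part$ind <- data.frame(chrom = chrom, start = st, end = en,
                               strand = strands, stringsAsFactors = FALSE)
      }
      if (n_pp > 0) {
        npair <- n_pp %/% 2L
        plen <- sample_pirna_lengths(npair)
        qlen <- sample_pirna_lengths(npair)
        if (main == "+") {
          p <- sample_biased_5p(chars, cs + 10L, ce - 42L, "+", npair, u1, a10)
          prim <- data.frame(chrom = chrom, start = p, end = p + plen,
                             strand = "+", stringsAsFactors = FALSE)
          q <- p + 9L
          partn <- data.frame(chrom = chrom, start = q + 1L - qlen, end = q + 1L,
                              strand = "-", stringsAsFactors = FALSE)
        } else {
          q <- sample_biased_5p(chars, cs + 42L, ce - 10L, "-", npair, u1, a10)
          prim <- data.frame(chrom = chrom, start = q + 1L - plen, end = q + 1L,
                             strand = "-", stringsAsFactors = FALSE)
          p <- q - 9L
          partn <- data.frame(chrom = chrom, start = p, end = p + qlen,
                              strand = "+", stringsAsFactors = FALSE)
        }
        part$pp <- rbind(prim, partn)
      }
      if (n_ph > 0) {
        st <- integer(0); en <- integer(0); sr <- character(0)
        remaining <- n_ph
        while (remaining > 0) {
          k <- min(remaining, sample(3:8, 1L))
          lens <- sample_pirna_lengths(k)
          s0 <- if (runif(1) < p_main) main else if (main == "+") "-" else "+"
          span <- sum(lens)
          if (s0 == "+") {
            f <- cs + sample.int(max(1L, ce - cs - span - 1L), 1L) - 1L
            starts <- f + c(0L, cumsum(lens[-k]))
            st <- c(st, starts); en <- c(en, starts + lens)
          } else {
            f <- ce - sample.int(max(1L, ce - cs - span - 1L), 1L)
            ends <- f - c(0L, cumsum(lens[-k]))
            st <- c(st, ends - lens); en <- c(en, ends)
          }
          sr <- c(sr, rep(s0, k))
          remaining <- remaining - k
        }
        part$ph <- data.frame(chrom = chrom, start = st, end = en,
                              strand = sr, stringsAsFactors = FALSE)
      }
      dfc <- do.call(rbind, part)
      dfc$cluster_id <- clusters$cluster_id[ci]
      pir[[ci]] <- dfc
    }
    pirdf <- do.call(rbind, pir)
    rows$pirna <- pirdf[, c("chrom", "start", "end", "strand")]
    meta$pirna <- data.frame(category = "pirna", cluster_id = pirdf$cluster_id,
                             trna_id = NA_character_, s = NA_integer_,
                             e = NA_integer_, stringsAsFactors = FALSE)
  }

  # --- background rain
  if (nk["background"] > 0) {
    len <- sample(13:43, nk["background"], replace = TRUE)
    st <- floor(runif(nk["background"]) * (glen - len)) |> as.integer()
    rows$background <- data.frame(chrom = chrom, start = st, end = st + len,
                                  strand = sample(c("+", "-"), nk["background"],
                                                  replace = TRUE),
                                  stringsAsFactors = FALSE)
    meta$background <- data.frame(category = "background",
                                  cluster_id = NA_character_,
                                  trna_id = NA_character_, s = NA_integer_,
                                  e = NA_integer_, stringsAsFactors = FALSE)
  }

  ord <- c("mirna", "pirna", "trf", "background")
  df <- do.call(rbind, rows[ord[ord %in% names(rows)]])
  md <- do.call(rbind, lapply(ord[ord %in% names(meta)], function(k) {
    m <- meta[[k]]
    if (nrow(m) == 1L && k != "pirna") m[rep(1L, nrow(rows[[k]])), , drop = FALSE] else m
  }))
  rownames(df) <- rownames(md) <- NULL
  seqstr <- if (!is.null(genome$seqstr)) genome$seqstr[[chrom]] else
    paste(chars, collapse = "")
  seqs <- substring(seqstr, df$start + 1L, df$end)
  minus <- df$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  df$sequence <- seqs
  df$read_id <- sprintf("%s_r%06d", sample_id, seq_len(nrow(df)))
  rs <- ReadSet(df, sample_id = sample_id, tissue = tissue)
  attr(rs, "manifest") <- list(
    category_counts = nk,
    per_read = md,
    cluster_alloc = cluster_alloc,
    trf_alloc = trf_alloc,
    profile = profile)
  rs
}

#' Write a library as FASTQ text
#' @param rs a ReadSet.
#' @param path output .fastq path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  df <- rs$reads
  lines <- as.vector(rbind(paste0("@", df$read_id), df$sequence, "+",
                           strrep("I", df$length)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an NB count matrix with planted fold effects
#'
#' Per-feature base means are drawn log-uniformly over
#' `base_mean_range`; counts per sample are negative binomial with
#' common dispersion `phi` (Poisson when phi = 0). Planted effects
#' multiply the mean of designated features in one group.
#' @param n_features number of features.
#' @param groups group label per sample (e.g. `rep(c("A","B"), each=3)`).
#' @param phi common dispersion >= 0.
#' @param effects data.frame(feature, group, fold): feature row
#'   indices whose mean is multiplied by `fold` in `group`.
#' @param base_mean_range range of per-feature base means.
#' @param seed integer seed.
#' @return list(counts (matrix, rownames f00001...), groups, truth =
#'   list(base_mean, effects)).
#' @export
simulate_count_matrix <- function(n_features = 2000L,
                                  groups = rep(c("A", "B"), each = 3L),
                                  phi = 0.1, effects = NULL,
                                  base_mean_range = c(10, 200), seed = 1L) {
  stopifnot(phi >= 0)
  set.seed(derive_seed(seed, "counts"))
  mu0 <- exp(runif(n_features, log(base_mean_range[1]), log(base_mean_range[2])))
  mu <- matrix(mu0, nrow = n_features, ncol = length(groups))
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      cols <- which(groups == effects$group[i])
      mu[effects$feature[i], cols] <- mu[effects$feature[i], cols] * effects$fold[i]
    }
  }
  counts <- matrix(0L, n_features, length(groups))
  for (j in seq_along(groups)) {
    counts[, j] <- if (phi == 0) rpois(n_features, mu[, j])
    else rnbinom(n_features, size = 1 / phi, mu = mu[, j])
  }
  rownames(counts) <- sprintf("f%05d", seq_len(n_features))
  colnames(counts) <- sprintf("%s_%d", groups, stats::ave(seq_along(groups),
                                                          groups, FUN = seq_along))
  list(counts = counts, groups = groups,
       truth = list(base_mean = mu0, effects = effects))
}
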