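# End-to-end orchestration: simulate -> profile -> clusters ->
# signatures -> tRF -> targeting -> DE, with a resolved-config run
# record. Deterministic under a fixed seed; re-running a config
# rewrites identical stage outputs.

PIPELINE_CONFIG_KEYS <- c("seed", "out_dir", "genome", "tissues", "pairs",
                          "de", "cluster", "write_alignments")
GENOME_CONFIG_KEYS <- c("genome_length", "n_clusters", "cluster_size",
                        "n_genes", "n_te", "n_trna", "n_mirna", "n_rrna",
                        "n_other", "cluster_u1", "cluster_pingpong",
                        "cluster_phased", "cluster_buffer")
TISSUE_CONFIG_KEYS <- c("n_reads", "n_replicates", "profile")

#' Default pipeline configuration
#'
#' A small two-tissue (ovary-like, semen-like) demo configuration that
#' runs end to end in well under a minute.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return named config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 42L, out_dir = tempfile("sRNA_run_")) {
  # genome sized so background rain stays well below the cluster
  # caller's density criterion, as in real libraries
  list(seed = seed, out_dir = out_dir,
       genome = list(genome_length = 1500000L, n_clusters = 6L,
                     cluster_size = c(1000L, 4000L)),
       tissues = list(
         ovary = list(n_reads = 5000L, n_replicates = 2L),
         semen = list(n_reads = 5000L, n_replicates = 2L)),
       pairs = list(c("ovary", "semen")),
       de = list(fdr_max = 0.01, fc_min = 5, min_count = 5),
       cluster = list(max_gap = 1000L, min_reads = 35L, min_density = 10,
                      merge_dist = 1000L, min_len = 200L),
       write_alignments = TRUE)
}

validate_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$seed) || is.null(config$tissues))
    stopf("config requires 'seed' and 'tissues'")
  unknown <- setdiff(names(config$genome), GENOME_CONFIG_KEYS)
  if (length(unknown))
    stopf("unknown config key(s) under genome: %s", paste(unknown, collapse = ", "))
  for (tn in names(config$tissues)) {
    unknown <- setdiff(names(config$tissues[[tn]]), TISSUE_CONFIG_KEYS)
    if (length(unknown))
      stopf("unknown config key(s) under tissues$%s: %s", tn,
            paste(unknown, collapse = ", "))
  }
  invisible(config)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$pairs)) cfg$pairs <- lapply(cfg$pairs, unlist)
  if (!is.null(cfg$genome$cluster_size))
    cfg$genome$cluster_size <- as.integer(unlist(cfg$genome$cluster_size))
  validate_config(cfg)
}

stage_header <- function(stage, params) {
  sprintf("# stage=%s %s", stage,
          paste(sprintf("%s=%s", names(params), unlist(params)), collapse = " "))
}

write_stage_tsv <- function(df, path, stage, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(stage, params), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> biotype profiles -> per-tissue cluster calling
#' -> cross-tissue overlap sets -> per-library signatures -> tRF
#' abundance table -> feature targeting -> pairwise DE on tRF counts,
#' writing one TSV per stage (with a header naming the producing stage
#' and parameters) plus a JSON run record embedding the resolved
#' config and package version. Fully deterministic under
#' `config$seed`.
#'
#' @param config config list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @return invisible list of in-memory stage results (genome,
#'   libraries, profiles, clusters, overlap, signatures, trf,
#'   targeting, de, paths).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  out <- config$out_dir %||% tempfile("sRNA_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  genome <- do.call(make_toy_genome, c(list(seed = seed), config$genome))
  gpaths <- write_toy_genome(genome, file.path(out, "genome"))

  # --- libraries
  libs <- list()
  for (tn in names(config$tissues)) {
    tc <- config$tissues[[tn]]
    nrep <- tc$n_replicates %||% 1L
    for (r in seq_len(nrep)) {
      sid <- sprintf("%s_rep%d", tn, r)
      libs[[sid]] <- simulate_tissue_library(
        genome, sample_id = sid, tissue = tn, n_reads = tc$n_reads,
        profile = if (!is.null(tc$profile)) unlist(tc$profile) else NULL,
        seed = seed)
      if (isTRUE(config$write_alignments %||% TRUE)) {
        write_sam(libs[[sid]], file.path(out, paste0(sid, ".sam")),
                  genome$seqinfo)
        write_alignment_tsv(libs[[sid]], file.path(out, paste0(sid, ".tsv")))
      }
    }
  }

  # --- biotype profiles
  profiles <- lapply(libs, biotype_profile, annots = genome$annots)
  prof_df <- do.call(rbind, lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    data.frame(sample_id = sid, biotype = names(p$biotype_fractions),
               fraction = as.numeric(p$biotype_fractions),
               stringsAsFactors = FALSE)
  }))
  write_stage_tsv(prof_df, file.path(out, "biotype_profiles.tsv"),
                  "biotype_profiler", list(seed = seed))

  # --- clusters per tissue (replicate libraries pooled)
  ccfg <- config$cluster %||% list()
  tissues <- unique(vapply(libs, function(l) l$tissue, character(1)))
  clusters <- list()
  putative <- list()
  for (tn in tissues) {
    pool <- do.call(rbind, lapply(libs[vapply(libs, function(l) l$tissue,
                                              character(1)) == tn],
                                  function(l) l$reads))
    rs <- ReadSet(pool, sample_id = tn, tissue = tn)
    cl <- find_pirna_clusters(rs, genome$annots,
                              max_gap = ccfg$max_gap %||% 1000L,
                              min_reads = ccfg$min_reads %||% 35L,
                              min_density = ccfg$min_density %||% 10,
                              merge_dist = ccfg$merge_dist %||% 1000L,
                              min_len = ccfg$min_len %||% 200L)
    clusters[[tn]] <- cl
    putative[[tn]] <- filter_putative_pirnas(attr(cl, "putative"),
                                             genome$annots,
                                             length_filter = TRUE)
    write_clusters(cl, file.path(out, sprintf("clusters_%s.tsv", tn)))
  }
  overlap <- cluster_overlap_sets(clusters,
                                  merge_dist = ccfg$merge_dist %||% 1000L)
  write_stage_tsv(overlap, file.path(out, "cluster_overlap_sets.tsv"),
                  "pirna_pipeline", list(merge_dist = ccfg$merge_dist %||% 1000L))

  # --- signatures per tissue
  sig_df <- do.call(rbind, lapply(tissues, function(tn) {
    sig <- compute_signatures(putative[[tn]])
    data.frame(tissue = tn, n_reads = sig$n_reads, u1 = sig$u1_fraction,
               a10 = sig$a10_fraction, pingpong_z = sig$pingpong_z,
               phasing_z = as.numeric(sig$phasing_z), stringsAsFactors = FALSE)
  }))
  write_stage_tsv(sig_df, file.path(out, "signatures.tsv"), "pirna_signatures",
                  list(seed = seed))

  # --- tRF abundance
  trf <- trf_abundance_table(libs, genome$trnas)
  if (nrow(trf$proportions))
    write_stage_tsv(trf$proportions, file.path(out, "trf_proportions.tsv"),
                    "trf_classifier", list(seed = seed))

  # --- feature targeting per tissue
  targ <- lapply(tissues, function(tn)
    count_feature_reads(putative[[tn]], genome$annots))
  names(targ) <- tissues
  fam_df <- do.call(rbind, lapply(tissues, function(tn) {
    ft <- te_family_table(targ[[tn]])
    if (nrow(ft)) cbind(tissue = tn, ft) else NULL
  }))
  if (!is.null(fam_df))
    write_stage_tsv(fam_df, file.path(out, "te_family_percent.tsv"),
                    "feature_targeting", list(seed = seed))

  # --- DE on tRF counts across samples
  de_results <- list()
  if (length(config$pairs %||% list())) {
    cnt <- trf$counts
    if (nrow(cnt)) {
      samp_cols <- names(libs)
      m <- as.matrix(cnt[, samp_cols, drop = FALSE])
      rownames(m) <- paste(cnt$trna_id, cnt$s, cnt$e, sep = ":")
      groups <- vapply(libs, function(l) l$tissue, character(1))
      decfg <- config$de %||% list()
      for (pr in config$pairs) {
        key <- paste(pr, collapse = "_vs_")
        de_results[[key]] <- call_de(m, groups, pr,
                                     fdr_max = decfg$fdr_max %||% 0.01,
                                     fc_min = decfg$fc_min %||% 5,
                                     min_count = decfg$min_count %||% 5)
        write_stage_tsv(de_results[[key]]$table,
                        file.path(out, sprintf("de_trf_%s.tsv", key)),
                        "diffexp", decfg)
      }
    }
  }

  record <- list(package = "beehive",
                 version = as.character(packageVersion("beehive")),
                 config = config)
  jsonlite::write_json(record, file.path(out, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, libraries = libs, profiles = profiles,
                 clusters = clusters, putative = putative, overlap = overlap,
                 signatures = sig_df, trf = trf, targeting = targ,
                 de = de_results, out_dir = out, paths = gpaths))
}
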