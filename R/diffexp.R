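# Differential small-RNA expression between tissue pairs: library-size
# normalization, moment-estimated common dispersion, a conditioned
# negative-binomial exact test (Robinson-Smyth style), BH FDR, and the
# threshold-based DE / uniquely-expressed calls (FDR < 0.01, fold
# change > 5, >= 5 counts in at least one tissue).

#' Library-size scaling factors
#'
#' factor_j = total_j / geometric mean of totals; normalized count =
#' count / factor. Equal library sizes give factors of 1.
#' @param counts matrix features x samples of non-negative integers.
#' @return named numeric vector of per-sample factors.
#' @export
normalize_libsize <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stopf("normalize_libsize: sample with zero total count")
  totals / geometric_mean(totals)
}

#' Moment estimate of the common NB dispersion
#'
#' Within each group with >= 2 replicates, per-feature mean m and
#' variance s^2 of normalized counts give (s^2 - m) / m^2, whose NB
#' expectation is the dispersion phi; the estimate is the mean over all
#' (feature, group) values with m > 0, floored at 0. With no replicated
#' group, returns 0 with a warning.
#' @param counts matrix features x samples.
#' @param groups group label per sample column.
#' @return dispersion phi >= 0.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  factors <- normalize_libsize(counts)
  norm <- sweep(counts, 2, factors, "/")
  vals <- c()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1, stats::var)
    ok <- m > 0
    vals <- c(vals, (v[ok] - m[ok]) / m[ok]^2)
  }
  if (!length(vals)) {
    warnf("no group with >= 2 replicates; dispersion set to 0")
    return(0)
  }
  max(0, mean(vals))
}

#' Conditioned negative-binomial exact test
#'
#' Tests equal per-replicate abundance between two groups of counts.
#' Counts are scaled to effective equal library sizes (divide by the
#' per-sample factors, round the group sums), then the test conditions
#' on the feature's total t = a + b: under a common dispersion phi the
#' split a | t follows the conditional of two negative binomials with
#' sizes nA/phi and nB/phi (a binomial split with probability
#' nA/(nA+nB) when phi = 0). The two-sided p-value is the sum of the
#' conditional probabilities of all splits at most as probable as the
#' observed one. t = 0 gives p = 1.
#'
#' @param countsA,countsB raw counts for the feature in each group.
#' @param phi common dispersion (>= 0).
#' @param factorsA,factorsB per-sample scaling factors (default 1).
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(countsA, countsB, phi = 0,
                          factorsA = rep(1, length(countsA)),
                          factorsB = rep(1, length(countsB))) {
  a <- round(sum(countsA / factorsA))
  b <- round(sum(countsB / factorsB))
  t <- a + b
  if (t == 0) return(1)
  nA <- length(countsA); nB <- length(countsB)
  k <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(k, t, nA / (nA + nB), log = TRUE)
  } else {
    # conditional NB split is free of the mean: only the size parameters
    # (group replicates / phi) enter, via the negative-hypergeometric weights
    sA <- nA / phi; sB <- nB / phi
    logw <- lgamma(k + sA) - lgamma(k + 1) +
      lgamma(t - k + sB) - lgamma(t - k + 1)
    logp <- logw - max(logw)
    logp <- logp - log(sum(exp(logp)))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[a + 1]
  min(1, sum(p[p <= obs * (1 + 1e-8)]))
}

#' Benjamini-Hochberg FDR
#' @param p_values vector of p-values.
#' @return BH-adjusted values (step-up with monotonicity).
#' @export
bh_fdr <- function(p_values) p.adjust(p_values, method = "BH")

#' Threshold-based differential expression calls for a tissue pair
#'
#' For every feature: normalized tissue means, fold change (larger
#' mean over smaller, >= 1, with direction), conditioned NB exact test
#' p-value at the common dispersion, BH FDR. A feature is DE iff
#' fdr < `fdr_max` AND fold change > `fc_min` AND its larger
#' tissue-mean *raw* count is >= `min_count`. A feature is unique to a
#' tissue iff its mean normalized count there is >= `min_count` and
#' its raw count is 0 in every sample of the other tissue; the summary
#' reports unique counts within the DE up-regulated sets, and
#' up-regulated-not-unique separately, Table-2 style.
#'
#' @param counts matrix features x samples (rownames = feature ids).
#' @param groups tissue label per sample column.
#' @param pair character(2): tissues T1, T2 to compare.
#' @param fdr_max,fc_min,min_count the DE thresholds.
#' @param phi optional common dispersion; estimated from the pair's
#'   samples when NULL.
#' @return object of class `DEResult`: list(table, summary, phi, pair).
#'   `table` has mean_norm_T1/T2, mean_raw_T1/T2, fold_change,
#'   direction, p_value, fdr, DE, up_T1, up_T2, unique_T1, unique_T2.
#' @export
call_de <- function(counts, groups, pair, fdr_max = 0.01, fc_min = 5,
                    min_count = 5, phi = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%05d", seq_len(nrow(counts)))
  stopifnot(length(groups) == ncol(counts), length(pair) == 2)
  if (!all(pair %in% groups)) stopf("pair tissues not present in groups")
  colsA <- which(groups == pair[1]); colsB <- which(groups == pair[2])
  sub <- counts[, c(colsA, colsB), drop = FALSE]
  keep_any <- rowSums(sub) > 0
  factors <- normalize_libsize(sub)
  if (is.null(phi))
    phi <- estimate_common_dispersion(sub, c(rep("A", length(colsA)),
                                             rep("B", length(colsB))))
  fA <- factors[seq_along(colsA)]
  fB <- factors[length(colsA) + seq_along(colsB)]
  A <- counts[, colsA, drop = FALSE]; B <- counts[, colsB, drop = FALSE]
  normA <- sweep(A, 2, fA, "/"); normB <- sweep(B, 2, fB, "/")
  m1 <- rowMeans(normA); m2 <- rowMeans(normB)
  r1 <- rowMeans(A); r2 <- rowMeans(B)
  fc <- ifelse(pmin(m1, m2) > 0, pmax(m1, m2) / pmin(m1, m2),
               ifelse(pmax(m1, m2) > 0, Inf, 1))
  p <- rep(1, nrow(counts))
  idx <- which(keep_any)
  p[idx] <- vapply(idx, function(i)
    nb_exact_test(A[i, ], B[i, ], phi = phi, factorsA = fA, factorsB = fB),
    numeric(1))
  fdr <- bh_fdr(p)
  de <- fdr < fdr_max & fc > fc_min & pmax(r1, r2) >= min_count
  up1 <- de & m1 > m2
  up2 <- de & m2 > m1
  uniq1 <- m1 >= min_count & rowSums(B) == 0
  uniq2 <- m2 >= min_count & rowSums(A) == 0
  table <- data.frame(feature = rownames(counts),
                      mean_norm_T1 = m1, mean_norm_T2 = m2,
                      mean_raw_T1 = r1, mean_raw_T2 = r2,
                      fold_change = fc,
                      direction = ifelse(m1 > m2, pair[1],
                                         ifelse(m2 > m1, pair[2], "none")),
                      p_value = p, fdr = fdr, DE = de,
                      up_T1 = up1, up_T2 = up2,
                      unique_T1 = uniq1, unique_T2 = uniq2,
                      stringsAsFactors = FALSE, row.names = NULL)
  summary <- list(n_DE = sum(de),
                  n_up_T1 = sum(up1), n_up_T2 = sum(up2),
                  n_unique_T1 = sum(up1 & uniq1),
                  n_unique_T2 = sum(up2 & uniq2))
  structure(list(table = table, summary = summary, phi = phi, pair = pair),
            class = "DEResult")
}

#' @export
print.DEResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("DEResult %s vs %s (phi = %.3g)\n", x$pair[1], x$pair[2], x$phi))
  cat(sprintf("  DE: %d (up %s: %d [%d unique], up %s: %d [%d unique])\n",
              s$n_DE, x$pair[1], s$n_up_T1, s$n_unique_T1,
              x$pair[2], s$n_up_T2, s$n_unique_T2))
  invisible(x)
}

#' Sample coordinates from small-RNA profile PCA
#'
#' log2(CPM + 1) transform, feature centering, then PCA over samples.
#' Deterministic up to component sign.
#' @param counts matrix features x samples (>= 3 samples).
#' @return data.frame sample, PC1, PC2 with attribute
#'   `var_explained`.
#' @export
pca_profiles <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stopf("pca_profiles needs >= 3 samples")
  totals <- colSums(counts)
  if (any(totals <= 0)) stopf("sample with zero total count")
  x <- log2(sweep(counts, 2, totals, "/") * 1e6 + 1)
  xc <- x - rowMeans(x)
  pc <- prcomp(t(xc), center = FALSE)
  k <- min(2L, ncol(pc$x))
  out <- data.frame(sample = colnames(counts) %||% sprintf("s%d", seq_len(ncol(counts))),
                    PC1 = pc$x[, 1],
                    PC2 = if (k >= 2) pc$x[, 2] else 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(k)]
  out
}
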