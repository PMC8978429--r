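test_that("library-size factors are geometric-mean scaled", {
  m <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(unname(normalize_libsize(m)), c(1, 1))
  m2 <- rbind(c(1e6, 4e6))
  expect_equal(unname(normalize_libsize(m2)), c(0.5, 2.0))
  expect_error(normalize_libsize(cbind(c(1, 2), c(0, 0))), "zero total")
})

test_that("normalization leaves proportional features at fold change 1", {
  set.seed(51)
  base <- rpois(100, 50) + 1
  counts <- cbind(A1 = base, A2 = base * 2L, B1 = base * 3L, B2 = base)
  res <- call_de(counts, c("A", "A", "B", "B"), c("A", "B"), phi = 0)
  expect_true(all(abs(res$table$fold_change - 1) < 1e-9))
  expect_equal(sum(res$table$DE), 0)
})

test_that("common dispersion estimates recover the simulation truth", {
  sim0 <- simulate_count_matrix(n_features = 2000, phi = 0, seed = 15)
  phi0 <- estimate_common_dispersion(sim0$counts, sim0$groups)
  expect_gte(phi0, 0)
  expect_lte(phi0, 0.05)

  sim2 <- simulate_count_matrix(n_features = 2000, phi = 0.2, seed = 16)
  phi2 <- estimate_common_dispersion(sim2$counts, sim2$groups)
  expect_gte(phi2, 0.1)
  expect_lte(phi2, 0.3)

  ident <- cbind(c(5, 9, 14), c(5, 9, 14), c(5, 9, 14))
  expect_equal(estimate_common_dispersion(ident, rep("A", 3)), 0)
  expect_warning(phi_nr <- estimate_common_dispersion(cbind(c(5, 9)), "A"),
                 "replicates")
  expect_equal(phi_nr, 0)
})

test_that("the exact test matches closed forms and the enumeration oracle", {
  # A=5, B=0, equal sizes, phi=0: p = 2 * 0.5^5
  expect_equal(nb_exact_test(5, 0, phi = 0), 0.0625, tolerance = 1e-12)
  # symmetric split is the mode -> p = 1
  expect_equal(nb_exact_test(7, 7, phi = 0), 1)
  expect_equal(nb_exact_test(0, 0, phi = 0.3), 1)

  # all totals <= 30, with and without dispersion, vs the conditional
  # enumeration oracle (which also verifies mean-independence)
  for (phi in c(0, 0.15, 0.6)) {
    for (ab in list(c(0, 7), c(3, 9), c(12, 12), c(1, 29), c(15, 5))) {
      got <- nb_exact_test(ab[1], ab[2], phi = phi)
      want1 <- oracle_exact_p(ab[1], ab[2], phi = phi, mu = 3.1)
      want2 <- oracle_exact_p(ab[1], ab[2], phi = phi, mu = 40)
      expect_equal(want1, want2, tolerance = 1e-10)
      expect_equal(got, want1, tolerance = 1e-10)
    }
  }
  # unequal replicate numbers condition on group sizes
  got <- nb_exact_test(c(4, 3), c(2), phi = 0)
  want <- oracle_exact_p(7, 2, nA = 2, nB = 1, phi = 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("BH correction equals the independent step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(52)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DE and unique calls follow the three-threshold rule", {
  counts <- rbind(uniqT2 = c(0, 0, 0, 10, 12, 8),
                  flat = c(100, 110, 105, 95, 105, 100),
                  both0 = c(0, 0, 0, 0, 0, 0))
  groups <- rep(c("T1", "T2"), each = 3)
  res <- call_de(counts, groups, c("T1", "T2"), phi = 0)
  t <- res$table
  expect_true(t$unique_T2[t$feature == "uniqT2"])
  expect_true(t$DE[t$feature == "uniqT2"])
  expect_true(t$up_T2[t$feature == "uniqT2"])
  expect_false(t$DE[t$feature == "flat"])
  expect_false(t$DE[t$feature == "both0"])
  expect_false(t$unique_T1[t$feature == "both0"] || t$unique_T2[t$feature == "both0"])
  # unique flags are mutually exclusive by construction
  expect_false(any(t$unique_T1 & t$unique_T2))
})

test_that("tissue label swap maps up/unique flags antisymmetrically", {
  sim <- simulate_count_matrix(n_features = 300, phi = 0.1,
                               effects = data.frame(feature = 1:20,
                                                    group = "A", fold = 8),
                               seed = 53)
  r1 <- call_de(sim$counts, sim$groups, c("A", "B"))
  r2 <- call_de(sim$counts, sim$groups, c("B", "A"))
  expect_equal(r1$summary$n_up_T1, r2$summary$n_up_T2)
  expect_equal(r1$summary$n_unique_T1, r2$summary$n_unique_T2)
  expect_equal(r1$table$DE, r2$table$DE)
})

test_that("raising the fold-change threshold never enlarges the DE set", {
  sim <- simulate_count_matrix(n_features = 500, phi = 0.1,
                               effects = data.frame(feature = 1:40,
                                                    group = "A",
                                                    fold = rep(c(3, 6, 12, 30), 10)),
                               seed = 54)
  des <- lapply(c(2, 5, 10, 20), function(fc)
    which(call_de(sim$counts, sim$groups, c("A", "B"), fc_min = fc)$table$DE))
  for (i in seq_len(length(des) - 1))
    expect_true(all(des[[i + 1]] %in% des[[i]]))
})

test_that("planted fold changes are detected with controlled false discoveries", {
  effects <- data.frame(feature = 1:100, group = "A", fold = 10)
  sim <- simulate_count_matrix(n_features = 2000, phi = 0.1,
                               effects = effects, seed = 17)
  res <- call_de(sim$counts, sim$groups, c("A", "B"))
  called <- which(res$table$DE)
  sens <- mean(1:100 %in% called)
  fdp <- if (length(called)) mean(!(called %in% 1:100)) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.05)
})

test_that("PCA separates planted profiles and ignores feature order", {
  sim <- simulate_count_matrix(n_features = 400, phi = 0.05,
                               effects = data.frame(feature = 1:80,
                                                    group = "A", fold = 6),
                               seed = 18)
  pc <- pca_profiles(sim$counts)
  grpA <- sim$groups == "A"
  # first component separates the groups (positive silhouette-like gap)
  gap <- abs(mean(pc$PC1[grpA]) - mean(pc$PC1[!grpA]))
  spread <- max(stats::sd(pc$PC1[grpA]), stats::sd(pc$PC1[!grpA]))
  expect_gt(gap, spread)

  perm <- sample.int(nrow(sim$counts))
  pc2 <- pca_profiles(sim$counts[perm, ])
  expect_equal(abs(pc2$PC1), abs(pc$PC1), tolerance = 1e-8)

  # identical samples land on identical coordinates
  same <- cbind(a = c(5, 8, 2), b = c(5, 8, 2), c = c(9, 1, 4))
  pcs <- pca_profiles(same)
  expect_equal(pcs$PC1[1], pcs$PC1[2], tolerance = 1e-10)
  expect_equal(pcs$PC2[1], pcs$PC2[2], tolerance = 1e-10)
  expect_error(pca_profiles(cbind(c(1, 2), c(2, 3))), ">= 3 samples")
})
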