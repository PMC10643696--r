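test_that("K = 1 collapses to pooled frequencies with the closed-form likelihood", {
  set.seed(111)
  geno <- hwe_genotypes(15, runif(200, 0.2, 0.8))
  fit <- admixture_fit(geno, 1, seed = 1, n_restarts = 1, max_iter = 200)
  expect_true(all(abs(fit$Q - 1) < 1e-9))
  p_pool <- alt_allele_freq(geno)
  expect_equal(unname(fit$F[1, ]), unname(p_pool), tolerance = 1e-4)
  ll_closed <- sum(dbinom(geno, 2, rep(p_pool, each = nrow(geno)),
                          log = TRUE))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 800,
                    fst = 0.2, missing_rate = 0.05,
                    genotype_error_rate = 0.001, seed = 113)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  q <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE))
  ad <- make_admixed(cfg, freqs, q, map)
  fit <- admixture_fit(ad$geno, 2, seed = 3, n_restarts = 2, max_iter = 400)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("ancestry fractions are recovered for diverged populations and hybrids", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                    n_variants = 2500, fst = 0.2, missing_rate = 0.02,
                    genotype_error_rate = 0.001, seed = 127)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  # 12 + 12 purebred founders and 6 F1 crosses (true q exactly 0.5)
  ped <- pedigree_table(
    id = c(paste0("a", 1:12), paste0("b", 1:12), paste0("f1_", 1:6)),
    sire = c(rep(NA, 24), paste0("a", 1:6)),
    dam = c(rep(NA, 24), paste0("b", 1:6)),
    pop = c(rep("pop1", 12), rep("pop2", 12), rep(NA, 6)))
  dd <- gene_drop(cfg, freqs, ped, map,
                  truth_pairs = matrix(c("a1", "b1"), ncol = 2))
  fit <- admixture_fit(dd$geno, 2, seed = 5, n_restarts = 3, max_iter = 600)
  labels <- c(rep("pop1", 12), rep("pop2", 12), rep("zmix", 6))
  mapping <- align_clusters(fit, labels)
  # reorder fitted columns to (pop1, pop2)
  ord <- match(c("pop1", "pop2"), mapping)
  q_hat <- fit$Q[, ord]
  expect_lt(mean(abs(q_hat - dd$truth$q)), 0.05)
  # F1 hybrids sit near 50:50
  expect_true(all(abs(q_hat[25:30, 1] - 0.5) < 0.05))
  expect_equal(unname(dd$truth$q[25:30, "pop1"]), rep(0.5, 6))
})

test_that("cross-validation error prefers the true number of clusters", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 1200,
                    fst = 0.2, missing_rate = 0.02,
                    genotype_error_rate = 0, seed = 131)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  q <- rbind(matrix(rep(c(1, 0), 12), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 12), ncol = 2, byrow = TRUE))
  ad <- make_admixed(cfg, freqs, q, map)
  sweep2 <- admixture_cv_sweep(ad$geno, 1:2, folds = 3, seed = 9,
                               max_iter = 300)
  expect_lt(sweep2$cv_error[2], sweep2$cv_error[1])
  expect_equal(attr(sweep2, "best_K"), 2L)

  # single-population data: K = 1 wins over K in {1,2,3}
  set.seed(137)
  g1 <- hwe_genotypes(24, runif(800, 0.2, 0.8))
  sweep1 <- admixture_cv_sweep(g1, 1:3, folds = 3, seed = 11,
                               max_iter = 200)
  expect_equal(attr(sweep1, "best_K"), 1L)

  # determinism: identical seed, identical error
  e1 <- admixture_cv(g1, 2, folds = 3, seed = 17, max_iter = 100)
  e2 <- admixture_cv(g1, 2, folds = 3, seed = 17, max_iter = 100)
  expect_identical(e1, e2)
})

test_that("cluster alignment recovers a known permutation", {
  Q <- rbind(c(0.9, 0.05, 0.05), c(0.8, 0.1, 0.1),
             c(0.05, 0.9, 0.05), c(0.1, 0.85, 0.05),
             c(0.02, 0.08, 0.9), c(0.05, 0.05, 0.9))
  colnames(Q) <- c("K1", "K2", "K3")
  labels <- c("a", "a", "b", "b", "c", "c")
  perm <- c(3, 1, 2)
  Qp <- Q[, perm]
  colnames(Qp) <- c("K1", "K2", "K3")
  mapping <- align_clusters(Qp, labels)
  expect_equal(unname(mapping), c("c", "a", "b"))
  # bijective when K equals the label count
  expect_equal(sort(unname(mapping)), c("a", "b", "c"))
})

test_that("purity classification applies the tolerance and admixture flag", {
  calls <- classify_purity(rbind(c(0.9995, 0.0005),
                                 c(0.55, 0.45),
                                 c(0.93, 0.07)))
  expect_equal(calls$purity_class,
               c("purebred", "admixed", "low_admixture"))
  expect_equal(calls$dominant_fraction, c(0.9995, 0.55, 0.93))
  expect_error(classify_purity(c(0.7, 0.2)), "sum to 1")
})

test_that("fit is invariant to sample order up to column permutation", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 800,
                    fst = 0.25, missing_rate = 0, genotype_error_rate = 0,
                    seed = 139)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  q <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE))
  ad <- make_admixed(cfg, freqs, q, map)
  fit_a <- admixture_fit(ad$geno, 2, seed = 7, n_restarts = 2,
                         max_iter = 400)
  perm <- c(11:20, 1:10)
  fit_b <- admixture_fit(ad$geno[perm, ], 2, seed = 7, n_restarts = 2,
                         max_iter = 400)
  qa <- fit_a$Q[perm, ]
  qb <- fit_b$Q
  # align columns by correlation of the first sample block
  flip <- cor(qa[, 1], qb[, 1]) < 0
  if (flip) qb <- qb[, 2:1]
  expect_lt(mean(abs(qa - qb)), 0.05)
})
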