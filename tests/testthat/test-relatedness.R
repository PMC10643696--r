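test_that("IBS counting follows the definition locus by locus", {
  expect_equal(unname(ibs_counts(0L, 2L)), c(1, 0, 0))
  expect_equal(unname(ibs_counts(1L, 1L)), c(0, 0, 1))
  expect_equal(unname(ibs_counts(0L, 1L)), c(0, 1, 0))
  expect_equal(unname(ibs_counts(c(0L, 1L, 2L), c(2L, 1L, 0L))), c(2, 0, 1))
  x <- rep(c(0L, 1L, 2L), length.out = 100)
  expect_equal(ibs_counts(x, x)[["n_ibs2"]], 100)
  # missing loci are dropped from the counts
  expect_equal(sum(ibs_counts(c(0L, NA, 2L), c(0L, 1L, NA))), 1)
  expect_error(ibs_counts(NA_integer_, 1L), "no loci")
})

test_that("a duplicated sample yields pi_hat near 1 and class duplicate_or_twin", {
  set.seed(71)
  geno <- hwe_genotypes(20, runif(2000, 0.2, 0.8))
  geno <- rbind(geno, dup = geno[1, ])
  rel <- snp_relatedness(geno, pairs = cbind("S1", "dup"))
  expect_gte(rel$pi_hat, 0.99)
  expect_equal(as.character(rel$rel_class), "duplicate_or_twin")
})

test_that("relationship classes honor the printed boundaries exactly", {
  th <- relationship_thresholds()
  got <- classify_relationship(
    c(0.96, 0.95, 0.40, 0.39, 0.20, 0.19, 0.10, 0.09), th)
  expect_equal(as.character(got),
               c("duplicate_or_twin", "first_degree", "first_degree",
                 "second_degree", "second_degree", "third_degree",
                 "third_degree", "unrelated"))
  expect_error(classify_relationship(1.2), "\\[0, 1\\]")
  expect_error(relationship_thresholds(first = 0.96), "decreasing")
})

test_that("IBD estimates stay on the simplex and are symmetric in pair order", {
  set.seed(73)
  geno <- hwe_genotypes(15, runif(800, 0.2, 0.8))
  geno[sample(length(geno), 300)] <- NA
  rel_ab <- snp_relatedness(geno)
  for (k in seq_len(nrow(rel_ab))) {
    z <- unlist(rel_ab[k, c("z0", "z1", "z2")])
    expect_true(all(z >= 0 & z <= 1))
    expect_equal(sum(z), 1, tolerance = 1e-9)
    expect_true(rel_ab$pi_hat[k] >= 0 && rel_ab$pi_hat[k] <= 1)
  }
  rel_ba <- snp_relatedness(geno, pairs = cbind(rel_ab$id2, rel_ab$id1))
  expect_equal(rel_ba$pi_hat, rel_ab$pi_hat, tolerance = 1e-12)
})

test_that("ibd_moments recovers z2 = 1 for identical genotype vectors", {
  set.seed(79)
  p <- runif(5000, 0.2, 0.8)
  x <- vapply(p, function(pp) rbinom(1, 2, pp), integer(1))
  cnt <- ibs_counts(x, x)
  z <- ibd_moments(cnt, p)
  expect_gte(z[["pi_hat"]], 0.99)
  expect_error(ibd_moments(c(n_ibs0 = 0, n_ibs1 = 0, n_ibs2 = 10),
                           rep(0, 10)), "monomorphic")
})

test_that("classical MDS embeds a metric triangle exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  xy <- mds_embed(d, 2)
  got <- as.matrix(dist(xy))
  expect_equal(unname(got), unname(d), tolerance = 1e-9)
  # sign convention: first nonzero loading on each axis is positive
  for (c in 1:2) {
    nz <- which(abs(xy[, c]) > 1e-12)
    expect_gt(xy[nz[1], c], 0)
  }
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("mds_embed agrees with cmdscale up to sign", {
  set.seed(83)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(x))
  a <- mds_embed(d, 2)
  b <- stats::cmdscale(d, k = 2)
  for (c in 1:2) {
    expect_equal(unname(abs(a[, c])), unname(abs(b[, c])), tolerance = 1e-8)
  }
})

test_that("duplicate samples land on identical MDS coordinates", {
  set.seed(89)
  geno <- hwe_genotypes(10, runif(500, 0.2, 0.8))
  geno <- rbind(geno, dup = geno[1, ])
  xy <- mds_embed(ibs_distance(geno), 2)
  expect_equal(xy["S1", ], xy["dup", ], tolerance = 1e-9)
})

test_that("two diverged subspecies separate along MDS dimension 1", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 2000,
                    fst = 0.2, missing_rate = 0.02,
                    genotype_error_rate = 0, seed = 97)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  q <- rbind(matrix(rep(c(1, 0), 15), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 15), ncol = 2, byrow = TRUE))
  ad <- make_admixed(cfg, freqs, q, map)
  xy <- mds_embed(ibs_distance(ad$geno), 2)
  g1 <- xy[1:15, 1]
  g2 <- xy[16:30, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("pedigree pairs are recovered from simulated genotypes", {
  # parent-offspring and unrelated pairs at ~4000 spread-out markers
  cfg <- sim_config(chrom_lengths = setNames(rep(2.5e7, 8),
                                             paste0("chr", 1:8)),
                    n_variants = 4000, fst = 0.2, missing_rate = 0.02,
                    genotype_error_rate = 0.001, seed = 101)
  map <- sim_map(cfg)
  freqs <- draw_subpop_frequencies(cfg, nrow(map))
  peds <- lapply(1:15, function(k) {
    pre <- paste0("t", k, "_")
    pedigree_table(id = paste0(pre, c("sire", "dam", "kid")),
                   sire = c(NA, NA, paste0(pre, "sire")),
                   dam = c(NA, NA, paste0(pre, "dam")),
                   pop = "pop1")
  })
  dd <- gene_drop(cfg, freqs, do.call(rbind, peds), map,
                  truth_pairs = matrix(c("t1_sire", "t1_dam"), ncol = 2))
  po <- cbind(paste0("t", 1:15, "_sire"), paste0("t", 1:15, "_kid"))
  un <- cbind(paste0("t", 1:15, "_sire"), paste0("t", 1:15, "_dam"))
  rel_po <- snp_relatedness(dd$geno, pairs = po)
  rel_un <- snp_relatedness(dd$geno, pairs = un)
  expect_lt(abs(mean(rel_po$pi_hat) - 0.5), 0.05)
  expect_gt(mean(rel_po$z1), 0.8)
  expect_lte(mean(rel_un$pi_hat), 0.05)
})

test_that("heatmap export is males x females in percent, deterministically ordered", {
  set.seed(103)
  geno <- hwe_genotypes(6, runif(300, 0.3, 0.7),
                        ids = c("m1", "m2", "m3", "f1", "f2", "f3"))
  md <- data.frame(sample_id = rownames(geno),
                   sex = rep(c("male", "female"), each = 3),
                   subpopulation = rep(c("B", "A"), 3))
  rel <- snp_relatedness(geno)
  hm <- pihat_heatmap_matrix(rel, md)
  expect_equal(dim(hm), c(3L, 3L))
  # ordered by (subpopulation, id): subpop A males first
  expect_equal(rownames(hm), c("m2", "m1", "m3"))
  k <- rel$pi_hat[rel$id1 == "f1" & rel$id2 == "m1" |
                  rel$id1 == "m1" & rel$id2 == "f1"]
  expect_equal(hm["m1", "f1"], 100 * k)
})
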