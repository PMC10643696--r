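test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(n_variants = 300, seed = 201)
  expect_identical(sim_map(cfg), sim_map(cfg))
  expect_identical(draw_subpop_frequencies(cfg, 300),
                   draw_subpop_frequencies(cfg, 300))
  ped <- pedigree_table(id = c("a", "b", "c"), sire = c(NA, NA, "a"),
                        dam = c(NA, NA, "b"), pop = "pop1")
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  expect_identical(gene_drop(cfg, f, ped, map)$geno,
                   gene_drop(cfg, f, ped, map)$geno)
  expect_error(sim_config(n_variants = 10), "seed")
  expect_error(sim_config(fst = 0, seed = 1), "fst")
})

test_that("Balding-Nichols frequencies behave at small and moderate divergence", {
  cfg_small <- sim_config(n_variants = 3000, fst = 0.001, seed = 203)
  f <- draw_subpop_frequencies(cfg_small, 3000)
  close1 <- mean(abs(f[, "pop1"] - f[, "ancestral"]) <= 0.05)
  expect_gte(close1, 0.99)

  # Hudson-style FST estimate on simulated truth frequencies
  cfg <- sim_config(n_variants = 10000, fst = 0.2, seed = 207)
  fr <- draw_subpop_frequencies(cfg, 10000)
  p1 <- fr[, "pop1"]; p2 <- fr[, "pop2"]
  fst_hat <- mean((p1 - p2)^2) /
    mean((p1 - p2)^2 + 2 * (p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  expect_lt(abs(fst_hat - 0.2), 0.02)
})

test_that("parent-offspring pairs have realized z1 = 1 exactly", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 500,
                    missing_rate = 0, genotype_error_rate = 0, seed = 211)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  ped <- pedigree_table(id = c("p1", "p2", "kid"),
                        sire = c(NA, NA, "p1"), dam = c(NA, NA, "p2"),
                        pop = "pop1")
  tr <- gene_drop(cfg, f, ped, map)$truth$pairs
  po <- tr[tr$id1 == "p1" & tr$id2 == "kid", ]
  expect_equal(po$z1, 1)
  expect_equal(po$pi_hat, 0.5)
})

test_that("full-sib realized IBD averages to (0.25, 0.5, 0.25)", {
  # 100 sib pairs over 10 chromosomes
  cfg <- sim_config(chrom_lengths = setNames(rep(2.5e7, 10),
                                             paste0("chr", 1:10)),
                    n_variants = 2000, missing_rate = 0,
                    genotype_error_rate = 0, seed = 213)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  peds <- lapply(1:100, function(k) {
    pre <- paste0("fam", k, "_")
    pedigree_table(id = paste0(pre, c("s", "d", "k1", "k2")),
                   sire = c(NA, NA, pre %+% "s", pre %+% "s"),
                   dam = c(NA, NA, pre %+% "d", pre %+% "d"),
                   pop = "pop1")
  })
  sib_pairs <- cbind(paste0("fam", 1:100, "_k1"),
                     paste0("fam", 1:100, "_k2"))
  dd <- gene_drop(cfg, f, do.call(rbind, peds), map,
                  truth_pairs = sib_pairs)
  z <- colMeans(dd$truth$pairs[, c("z0", "z1", "z2")])
  expect_lt(abs(z[1] - 0.25), 0.03)
  expect_lt(abs(z[2] - 0.50), 0.03)
  expect_lt(abs(z[3] - 0.25), 0.03)
})

test_that("full-sib-mating offspring are about one quarter autozygous", {
  cfg <- sim_config(chrom_lengths = setNames(rep(2.5e7, 8),
                                             paste0("chr", 1:8)),
                    n_variants = 2000, missing_rate = 0,
                    genotype_error_rate = 0, seed = 217)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  peds <- lapply(1:20, function(k) {
    pre <- paste0("fam", k, "_")
    pedigree_table(
      id = paste0(pre, c("s", "d", "b1", "b2", "off")),
      sire = c(NA, NA, pre %+% "s", pre %+% "s", pre %+% "b1"),
      dam = c(NA, NA, pre %+% "d", pre %+% "d", pre %+% "b2"),
      pop = "pop1")
  })
  dd <- gene_drop(cfg, f, do.call(rbind, peds), map,
                  truth_pairs = matrix(c("fam1_s", "fam1_d"), ncol = 2))
  off <- grepl("_off$", names(dd$truth$autozygous_fraction))
  expect_lt(abs(mean(dd$truth$autozygous_fraction[off]) - 0.25), 0.05)
})

test_that("admixed samples realize their target ancestry", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                    n_variants = 5000, missing_rate = 0,
                    genotype_error_rate = 0, seed = 219)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  q <- rbind(c(1, 0), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  ad <- make_admixed(cfg, f, q, map)
  expect_equal(unname(ad$true_q[1, "pop1"]), 1)
  expect_lt(max(abs(ad$true_q[2:5, "pop1"] - 0.5)), 0.2)
  expect_lt(abs(mean(ad$true_q[2:5, "pop1"]) - 0.5), 0.1)
  expect_error(make_admixed(cfg, f, rbind(c(0.7, 0.6)), map), "sum to 1")
})

test_that("truth export round-trips coordinates and conserves lengths", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2.5e7), n_variants = 1000,
                    missing_rate = 0, genotype_error_rate = 0, seed = 223)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  ped <- pedigree_table(
    id = c("s", "d", "b1", "b2", "off"),
    sire = c(NA, NA, "s", "s", "b1"),
    dam = c(NA, NA, "d", "d", "b2"), pop = "pop1")
  dd <- gene_drop(cfg, f, ped, map)
  dir <- tempfile()
  export_truth(dd$truth, dir)
  bed <- read_truth_bed(file.path(dir, "truth_autozygous.bed"))
  expect_equal(bed$start_pos, dd$truth$autozygous$start_pos)
  expect_equal(bed$end_pos, dd$truth$autozygous$end_pos)
  # summed truth segment lengths match the recorded autozygous fractions
  ext <- max(map$pos) - min(map$pos)
  for (s in unique(dd$truth$autozygous$sample_id)) {
    seg <- dd$truth$autozygous[dd$truth$autozygous$sample_id == s, ]
    expect_equal(sum(seg$end_pos - seg$start_pos) / ext,
                 unname(dd$truth$autozygous_fraction[s]))
  }
  # empty pedigree of founders only: pair file still written with header
  ped0 <- pedigree_table(id = c("x", "y"), pop = "pop1")
  dd0 <- gene_drop(cfg, f, ped0, map,
                   truth_pairs = matrix(character(0), ncol = 2))
  dir0 <- tempfile()
  export_truth(dd0$truth, dir0)
  lines <- readLines(file.path(dir0, "truth_pairs.tsv"))
  expect_equal(length(lines), 1L)
  expect_match(lines[1], "id1")
})

test_that("genotype noise matches the configured rates", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_variants = 5000,
                    missing_rate = 0.05, genotype_error_rate = 0.01,
                    seed = 227)
  map <- sim_map(cfg)
  f <- draw_subpop_frequencies(cfg, nrow(map))
  ped <- pedigree_table(id = paste0("f", 1:10), pop = "pop1")
  dd <- gene_drop(cfg, f, ped, map)
  expect_lt(abs(mean(is.na(dd$geno)) - 0.05), 0.01)
  ok <- !is.na(dd$geno)
  expect_lt(abs(mean(dd$geno[ok] != dd$geno_clean[ok]) - 0.01), 0.005)
})
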