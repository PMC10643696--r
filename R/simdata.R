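#' Simulation configuration
#'
#' Defines the synthetic study design: a SNP map over one or more
#' chromosomes, two subpopulations diverged under the Balding-Nichols model,
#' recombination for gene dropping, and genotyping noise. The default noise
#' levels are typical of filtered RADseq call sets (a few percent missing
#' calls, ~0.1% genotype errors).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_variants total SNP count, distributed over chromosomes in
#'   proportion to length.
#' @param spacing "poisson" (uniform random positions, i.e. a Poisson
#'   process conditioned on the count) or "uniform" (evenly spaced).
#' @param fst divergence between the two subpopulations, in (0, 1).
#' @param ancestral_range range of ancestral allele frequencies
#'   (default 0.05-0.95).
#' @param recomb_rate recombination rate in cM/Mb (default 1.04).
#' @param missing_rate per-genotype missing-call probability (default 0.05,
#'   below the per-variant and per-sample filter thresholds).
#' @param genotype_error_rate per-genotype error probability
#'   (default 0.001).
#' @param seed random seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                       n_variants = 2000L, spacing = c("poisson", "uniform"),
                       fst = 0.2, ancestral_range = c(0.05, 0.95),
                       recomb_rate = 1.04, missing_rate = 0.05,
                       genotype_error_rate = 0.001, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  spacing <- match.arg(spacing)
  if (!(fst > 0 && fst < 1)) stop("fst must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1 ||
      genotype_error_rate < 0 || genotype_error_rate >= 1) {
    stop("rates must be in [0, 1)")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_variants = as.integer(n_variants), spacing = spacing,
                 fst = fst, ancestral_range = ancestral_range,
                 recomb_rate = recomb_rate, missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the SNP map
#'
#' @param config a [sim_config()] object; uses its seed.
#' @return variant table (chrom, pos, ref, alt, vid) sorted by
#'   (chromosome, position).
#' @export
sim_map <- function(config) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  n_per <- pmax(round(config$n_variants * lens / sum(lens)), 1L)
  out <- lapply(names(lens), function(chr) {
    n <- n_per[[chr]]
    pos <- if (config$spacing == "uniform") {
      round(seq(1, lens[[chr]], length.out = n))
    } else {
      sort(sample.int(lens[[chr]], n))
    }
    data.frame(chrom = chr, pos = as.integer(pos), ref = "A", alt = "G",
               vid = paste0(chr, ":", pos), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Draw diverged subpopulation allele frequencies
#'
#' Balding-Nichols model: an ancestral frequency p is drawn uniformly from
#' the configured range, then each subpopulation's frequency is
#' Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst).
#'
#' @param config a [sim_config()] object.
#' @param n_variants number of variants (defaults to `config$n_variants`).
#' @return matrix with columns `ancestral`, `pop1`, `pop2`.
#' @export
draw_subpop_frequencies <- function(config, n_variants = config$n_variants) {
  set.seed(config$seed + 1L)
  rng <- config$ancestral_range
  p <- runif(n_variants, rng[1L], rng[2L])
  a <- p * (1 - config$fst) / config$fst
  b <- (1 - p) * (1 - config$fst) / config$fst
  f1 <- rbeta(n_variants, a, b)
  f2 <- rbeta(n_variants, a, b)
  eps <- 1e-6
  cbind(ancestral = p, pop1 = pmin(pmax(f1, eps), 1 - eps),
        pop2 = pmin(pmax(f2, eps), 1 - eps))
}

#' Construct a pedigree table
#'
#' @param id sample identifiers.
#' @param sire,dam parent ids (`NA` for founders).
#' @param pop founder subpopulation ("pop1"/"pop2"; ignored, may be NA, for
#'   non-founders).
#' @param sex optional sex per individual ("male"/"female"/"unknown").
#' @return validated pedigree data.frame (founders before offspring).
#' @export
pedigree_table <- function(id, sire = NA, dam = NA, pop = "pop1",
                           sex = "unknown") {
  ped <- data.frame(id = as.character(id),
                    sire = as.character(rep_len(sire, length(id))),
                    dam = as.character(rep_len(dam, length(id))),
                    pop = as.character(rep_len(pop, length(id))),
                    sex = as.character(rep_len(sex, length(id))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate pedigree id")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(par) && !(par %in% seen)) {
        stop("pedigree references unknown (or later-defined) parent: ", par)
      }
    }
    seen <- c(seen, ped$id[i])
  }
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(!founder & (is.na(ped$sire) | is.na(ped$dam)))) {
    stop("individuals must have either two parents or none")
  }
  if (any(founder & !(ped$pop %in% c("pop1", "pop2")))) {
    stop("founders must have pop 'pop1' or 'pop2'")
  }
  ped
}

# one meiosis on one chromosome: returns locus-wise index (1 or 2) of the
# parental haplotype transmitted, under a Poisson crossover process
meiosis_phase <- function(pos, chrom_len, recomb_rate) {
  rate_per_bp <- recomb_rate / 1e8   # cM/Mb -> Morgans/bp
  n_xo <- rpois(1L, chrom_len * rate_per_bp)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) return(rep(start, length(pos)))
  xo <- sort(runif(n_xo, 0, chrom_len))
  ((start - 1L + findInterval(pos, xo)) %% 2L) + 1L
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn from their subpopulation's allele
#' frequencies; transmission places crossovers as a Poisson process at the
#' configured recombination rate. Each founder haplotype carries a unique
#' label that is copied along with the alleles, so realized identity by
#' descent (pairwise Z0/Z1/Z2 and Pi-Hat), per-individual autozygous
#' segments (both haplotypes carrying the same founder-allele label), and
#' realized ancestry fractions are all recorded exactly. Genotype errors and
#' missing calls are applied last, to the genotype matrix only.
#'
#' @param config a [sim_config()] object.
#' @param freqs frequency matrix from [draw_subpop_frequencies()], rows
#'   aligned with `map`.
#' @param pedigree data.frame from [pedigree_table()].
#' @param map variant table from [sim_map()].
#' @param truth_pairs optional 2-column matrix of id pairs for which
#'   realized IBD is recorded; default all pairs.
#' @return list with `geno` (noisy), `geno_clean`, `variants`, `samples`
#'   (sample_id, sex, subpopulation = founder pop or "pedigree"), and
#'   `truth` (list: `pairs`, `autozygous` segments, `autozygous_fraction`,
#'   `q` realized ancestry fractions).
#' @export
gene_drop <- function(config, freqs, pedigree, map = sim_map(config),
                      truth_pairs = NULL) {
  set.seed(config$seed + 2L)
  stopifnot(nrow(freqs) == nrow(map))
  n <- nrow(pedigree)
  ids <- pedigree$id
  founder <- is.na(pedigree$sire)
  # founder-allele labels: founder k carries labels 2k-1 and 2k
  lab_of <- setNames(seq_len(n), ids)
  # label -> founder pop, for realized ancestry
  lab_pop <- rep(NA_character_, 2L * n)
  lab_pop[2L * which(founder) - 1L] <- pedigree$pop[founder]
  lab_pop[2L * which(founder)] <- pedigree$pop[founder]

  chroms <- unique(map$chrom)
  hapA <- hapB <- labA <- labB <- list()
  for (chr in chroms) {
    jj <- which(map$chrom == chr)
    nv <- length(jj)
    len <- config$chrom_lengths[[chr]]
    pos <- map$pos[jj]
    hA <- hB <- lA <- lB <- matrix(0L, n, nv)
    for (i in seq_len(n)) {
      if (founder[i]) {
        f <- freqs[jj, pedigree$pop[i]]
        hA[i, ] <- rbinom(nv, 1L, f)
        hB[i, ] <- rbinom(nv, 1L, f)
        lA[i, ] <- 2L * i - 1L
        lB[i, ] <- 2L * i
      } else {
        si <- lab_of[[pedigree$sire[i]]]
        di <- lab_of[[pedigree$dam[i]]]
        ph_s <- meiosis_phase(pos, len, config$recomb_rate)
        ph_d <- meiosis_phase(pos, len, config$recomb_rate)
        hA[i, ] <- ifelse(ph_s == 1L, hA[si, ], hB[si, ])
        lA[i, ] <- ifelse(ph_s == 1L, lA[si, ], lB[si, ])
        hB[i, ] <- ifelse(ph_d == 1L, hA[di, ], hB[di, ])
        lB[i, ] <- ifelse(ph_d == 1L, lA[di, ], lB[di, ])
      }
    }
    hapA[[chr]] <- hA; hapB[[chr]] <- hB
    labA[[chr]] <- lA; labB[[chr]] <- lB
  }
  hA <- do.call(cbind, hapA); hB <- do.call(cbind, hapB)
  lA <- do.call(cbind, labA); lB <- do.call(cbind, labB)
  geno_clean <- hA + hB
  storage.mode(geno_clean) <- "integer"
  dimnames(geno_clean) <- list(ids, map$vid)

  # realized pairwise IBD from founder-allele labels (locus fractions)
  if (is.null(truth_pairs)) {
    truth_pairs <- if (n >= 2L) t(utils::combn(ids, 2L)) else
      matrix(character(0), ncol = 2L)
  }
  pair_rows <- lapply(seq_len(nrow(truth_pairs)), function(k) {
    i <- lab_of[[truth_pairs[k, 1L]]]
    j <- lab_of[[truth_pairs[k, 2L]]]
    two <- (lA[i, ] == lA[j, ] & lB[i, ] == lB[j, ]) |
           (lA[i, ] == lB[j, ] & lB[i, ] == lA[j, ])
    any_share <- lA[i, ] == lA[j, ] | lA[i, ] == lB[j, ] |
                 lB[i, ] == lA[j, ] | lB[i, ] == lB[j, ]
    z2 <- mean(two)
    z1 <- mean(any_share & !two)
    data.frame(id1 = truth_pairs[k, 1L], id2 = truth_pairs[k, 2L],
               z0 = 1 - z1 - z2, z1 = z1, z2 = z2,
               pi_hat = z2 + z1 / 2, stringsAsFactors = FALSE)
  })
  truth_pair_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(id1 = character(), id2 = character(), z0 = numeric(),
               z1 = numeric(), z2 = numeric(), pi_hat = numeric(),
               stringsAsFactors = FALSE)

  # autozygous segments: runs of loci with both labels equal
  auto_rows <- list()
  for (chr in chroms) {
    jj <- which(map$chrom == chr)
    pos <- map$pos[jj]
    for (i in seq_len(n)) {
      auto <- labA[[chr]][i, ] == labB[[chr]][i, ]
      if (!any(auto)) next
      r <- rle(auto)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        auto_rows[[length(auto_rows) + 1L]] <- data.frame(
          sample_id = ids[i], chrom = chr,
          start_pos = pos[starts[k]], end_pos = pos[ends[k]],
          n_loci = r$lengths[k], stringsAsFactors = FALSE)
      }
    }
  }
  autozygous <- if (length(auto_rows)) do.call(rbind, auto_rows) else
    data.frame(sample_id = character(), chrom = character(),
               start_pos = integer(), end_pos = integer(),
               n_loci = integer(), stringsAsFactors = FALSE)
  map_extent <- sum(tapply(map$pos, map$chrom,
                           function(p) max(p) - min(p)))
  auto_frac <- vapply(ids, function(s) {
    sum(autozygous$end_pos[autozygous$sample_id == s] -
        autozygous$start_pos[autozygous$sample_id == s]) / map_extent
  }, numeric(1))

  # realized ancestry fractions from founder-allele origin
  q_true <- t(vapply(seq_len(n), function(i) {
    pops <- c(lab_pop[lA[i, ]], lab_pop[lB[i, ]])
    c(pop1 = mean(pops == "pop1"), pop2 = mean(pops == "pop2"))
  }, numeric(2)))
  rownames(q_true) <- ids

  geno <- add_genotype_noise(geno_clean, config)
  samples <- data.frame(
    sample_id = ids,
    sex = pedigree$sex,
    subpopulation = ifelse(founder, pedigree$pop, "pedigree"),
    organization = "sim",
    stringsAsFactors = FALSE
  )
  list(geno = geno, geno_clean = geno_clean, variants = map,
       samples = samples,
       truth = list(pairs = truth_pair_df, autozygous = autozygous,
                    autozygous_fraction = auto_frac, q = q_true))
}

# genotype errors (replace with one of the other two values), then missing
add_genotype_noise <- function(geno, config) {
  n <- length(geno)
  if (config$genotype_error_rate > 0) {
    err <- which(runif(n) < config$genotype_error_rate & !is.na(geno))
    if (length(err)) {
      cur <- geno[err]
      shift <- sample.int(2L, length(err), replace = TRUE)
      geno[err] <- (cur + shift) %% 3L
    }
  }
  if (config$missing_rate > 0) {
    geno[runif(n) < config$missing_rate] <- NA_integer_
  }
  geno
}

#' Simulate admixed individuals with known ancestry
#'
#' Each haplotype of each sample is partitioned into segments by a Poisson
#' breakpoint process at the configured recombination rate; each segment's
#' ancestry is drawn independently from the target ancestry fractions, and
#' alleles are then drawn from that ancestry's allele frequencies. The
#' realized (not just target) ancestry fraction is recorded per sample.
#'
#' @param config a [sim_config()] object.
#' @param freqs frequency matrix from [draw_subpop_frequencies()].
#' @param q_target matrix with one row per sample and columns (pop1, pop2);
#'   rows must sum to one.
#' @param map variant table from [sim_map()].
#' @param ids sample identifiers (default adm1, adm2, ...).
#' @return list with `geno` (noisy), `geno_clean`, `variants`, `samples`,
#'   and `true_q` (realized ancestry fractions, samples x 2).
#' @export
make_admixed <- function(config, freqs, q_target, map = sim_map(config),
                         ids = NULL) {
  q_target <- as.matrix(q_target)
  if (any(q_target < 0) || any(abs(rowSums(q_target) - 1) > 1e-8)) {
    stop("q_target rows must be non-negative and sum to 1")
  }
  set.seed(config$seed + 3L)
  n <- nrow(q_target)
  if (is.null(ids)) ids <- paste0("adm", seq_len(n))
  nv <- nrow(map)
  geno_clean <- matrix(0L, n, nv, dimnames = list(ids, map$vid))
  anc_count <- matrix(0, n, 2L)  # allele draws per ancestry
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    pos <- map$pos[jj]
    len <- config$chrom_lengths[[chr]]
    rate_per_bp <- config$recomb_rate / 1e8
    for (i in seq_len(n)) {
      g <- integer(length(jj))
      for (h in 1:2) {
        n_bk <- rpois(1L, len * rate_per_bp)
        bk <- sort(runif(n_bk, 0, len))
        seg <- findInterval(pos, bk) + 1L
        seg_anc <- sample.int(2L, max(seg), replace = TRUE,
                              prob = q_target[i, ])
        anc <- seg_anc[seg]
        f <- ifelse(anc == 1L, freqs[jj, "pop1"], freqs[jj, "pop2"])
        g <- g + rbinom(length(jj), 1L, f)
        anc_count[i, 1L] <- anc_count[i, 1L] + sum(anc == 1L)
        anc_count[i, 2L] <- anc_count[i, 2L] + sum(anc == 2L)
      }
      geno_clean[i, jj] <- g
    }
  }
  true_q <- anc_count / rowSums(anc_count)
  colnames(true_q) <- c("pop1", "pop2")
  rownames(true_q) <- ids
  geno <- add_genotype_noise(geno_clean, config)
  samples <- data.frame(sample_id = ids, sex = "unknown",
                        subpopulation = "admixed", organization = "sim",
                        stringsAsFactors = FALSE)
  list(geno = geno, geno_clean = geno_clean, variants = map,
       samples = samples, true_q = true_q)
}

#' Export simulation ground truth as plain-text files
#'
#' Writes `truth_q.tsv`, `truth_pairs.tsv` and `truth_autozygous.bed`
#' (BED: 0-based half-open coordinates, converted from the internal 1-based
#' inclusive segments).
#'
#' @param truth truth list from [gene_drop()] (optionally with `q` replaced
#'   or augmented).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q_path <- file.path(dir, "truth_q.tsv")
  q <- truth$q
  qdf <- data.frame(sample_id = rownames(q), as.data.frame(q),
                    stringsAsFactors = FALSE, row.names = NULL)
  write_report_tsv(qdf, q_path)
  p_path <- file.path(dir, "truth_pairs.tsv")
  write_report_tsv(truth$pairs, p_path)
  b_path <- file.path(dir, "truth_autozygous.bed")
  bed <- truth$autozygous
  bed_out <- data.frame(chrom = bed$chrom, start = bed$start_pos - 1L,
                        end = bed$end_pos, name = bed$sample_id)
  write.table(bed_out, b_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(q_path, p_path, b_path))
}

#' Read a truth BED back as 1-based inclusive segments
#'
#' @param path BED file written by [export_truth()].
#' @return data.frame with sample_id, chrom, start_pos, end_pos.
#' @export
read_truth_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(sample_id = b$V4, chrom = b$V1, start_pos = b$V2 + 1L,
             end_pos = b$V3, stringsAsFactors = FALSE)
}

#' A ready-made study-like scenario
#'
#' Builds a small cohort that mirrors the structure of a two-subspecies
#' captive program: an inbred herd founded by three individuals with
#' full-sib matings over two generations ("SEDlike"), an outbred herd from
#' eleven founders ("BEDlike"), and a few F1 hybrids between the herds.
#'
#' @param seed random seed.
#' @param n_variants SNP count (default 2000 over two 50 Mb chromosomes).
#' @return a [gene_drop()] result whose `samples` table carries herd labels
#'   and sexes usable by the downstream stages.
#' @export
sim_study_scenario <- function(seed, n_variants = 2000L) {
  config <- sim_config(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                       n_variants = n_variants, fst = 0.2,
                       missing_rate = 0.03, genotype_error_rate = 0.001,
                       seed = seed)
  map <- sim_map(config)
  freqs <- draw_subpop_frequencies(config, nrow(map))
  sed_f <- paste0("SED_F", 1:3)
  bed_f <- paste0("BED_F", 1:11)
  ped <- pedigree_table(
    id = c(sed_f, bed_f,
           "SED_G1a", "SED_G1b", "SED_G2a", "SED_G2b", "SED_G2c",
           "BED_G1a", "BED_G1b", "BED_G1c", "BED_G1d",
           "HYB_F1a", "HYB_F1b"),
    sire = c(rep(NA, 14),
             "SED_F1", "SED_F1", "SED_G1a", "SED_G1a", "SED_G1a",
             "BED_F1", "BED_F3", "BED_F5", "BED_F7",
             "SED_F3", "BED_F9"),
    dam = c(rep(NA, 14),
            "SED_F2", "SED_F2", "SED_G1b", "SED_G1b", "SED_G1b",
            "BED_F2", "BED_F4", "BED_F6", "BED_F8",
            "BED_F10", "SED_F2"),
    pop = c(rep("pop1", 3), rep("pop2", 11), rep(NA, 11)),
    sex = c("male", "female", "male",
            rep(c("male", "female"), length.out = 11),
            "male", "female", "male", "female", "male",
            "male", "female", "male", "female",
            "male", "female")
  )
  dd <- gene_drop(config, freqs, ped, map)
  herd <- ifelse(grepl("^SED", dd$samples$sample_id), "SEDlike",
                 ifelse(grepl("^BED", dd$samples$sample_id), "BEDlike",
                        "hybrid"))
  dd$samples$subpopulation <- herd
  dd$config <- config
  dd
}
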