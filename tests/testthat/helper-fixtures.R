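# shared fixtures and independent oracles

`%+%` <- function(a, b) paste0(a, b)

# write a small VCF text file; gt is a character matrix samples x variants
write_vcf_text <- function(path, chrom, pos, ref, alt, gt,
                           sample_ids = paste0("S", seq_len(nrow(gt)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(j) {
    paste(c(chrom[j], pos[j], ".", ref[j], alt[j], ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# independent HWE oracle: closed-form Levene/Haldane probabilities via
# lgamma, enumerated over all heterozygote counts (no recurrence)
oracle_hwe_all <- function(R, N) {
  h <- seq.int(R %% 2L, R, by = 2L)
  logp <- h * log(2) + lgamma(N + 1) - lgamma((R - h) / 2 + 1) -
    lgamma(h + 1) - lgamma(N - (R + h) / 2 + 1) +
    lgamma(R + 1) + lgamma(2 * N - R + 1) - lgamma(2 * N + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pv <- vapply(seq_along(h), function(i) {
    sum(p[p <= p[i] * (1 + 1e-12)])
  }, numeric(1))
  list(het = h, pvalue = pmin(pv, 1))
}

oracle_hwe <- function(n_AA, n_AB, n_BB) {
  N <- n_AA + n_AB + n_BB
  nA <- 2L * n_AA + n_AB
  R <- min(nA, 2L * N - nA)
  o <- oracle_hwe_all(R, N)
  o$pvalue[match(n_AB, o$het)]
}

# a genotype matrix drawn under HWE at given allele frequencies
hwe_genotypes <- function(n_samples, freqs, ids = paste0("S", seq_len(n_samples))) {
  g <- vapply(freqs, function(p) rbinom(n_samples, 2L, p), integer(n_samples))
  g <- matrix(as.integer(g), nrow = n_samples,
              dimnames = list(ids, NULL))
  g
}

# uniformly spaced map on one or more chromosomes
simple_map <- function(n_per_chrom, spacing_bp = 10000L,
                       chroms = paste0("chr", seq_along(n_per_chrom))) {
  do.call(rbind, lapply(seq_along(n_per_chrom), function(k) {
    pos <- seq.int(spacing_bp, by = spacing_bp,
                   length.out = n_per_chrom[k])
    data.frame(chrom = chroms[k], pos = pos, ref = "A", alt = "G",
               vid = paste0(chroms[k], ":", pos), stringsAsFactors = FALSE)
  }))
}

# total overlap (bp) between one segment set and another, per the
# 1-based inclusive convention
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  tot <- 0
  for (i in seq_along(a_start)) {
    o <- pmin(a_end[i], b_end) - pmax(a_start[i], b_start)
    tot <- tot + sum(pmax(o, 0))
  }
  tot
}
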