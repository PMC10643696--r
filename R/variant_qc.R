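#' Quality-control filter parameters
#'
#' Defaults follow the common RADseq practice for population-structure work:
#' drop variants with more than 10% missing calls, minor allele frequency
#' below 0.05 or Hardy-Weinberg exact-test p below 0.01, and drop samples
#' with 15% or more missing calls.
#'
#' @param max_variant_missing exclude a variant if its missing fraction is
#'   strictly greater than this (default 0.10).
#' @param min_maf exclude a variant if MAF is strictly below this
#'   (default 0.05).
#' @param hwe_alpha exclude a variant if the HWE exact p-value is strictly
#'   below this (default 0.01).
#' @param max_sample_missing exclude a sample if its missing fraction is
#'   greater than or equal to this (default 0.15).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(max_variant_missing = 0.10, min_maf = 0.05,
                          hwe_alpha = 0.01, max_sample_missing = 0.15) {
  p <- list(max_variant_missing = max_variant_missing, min_maf = min_maf,
            hwe_alpha = hwe_alpha, max_sample_missing = max_sample_missing)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0 || p[[nm]] > 1) {
      stop("filter parameter '", nm, "' must be a single value in [0, 1]")
    }
  }
  structure(p, class = "filter_params")
}

#' Per-variant missing-call fraction
#'
#' @param geno genotype matrix, samples x variants (`NA` = missing).
#' @return numeric vector, one fraction in \[0, 1\] per variant.
#' @export
variant_missingness <- function(geno) {
  stopifnot(nrow(geno) >= 1L)
  colMeans(is.na(geno))
}

#' Per-sample missing-call fraction
#'
#' @inheritParams variant_missingness
#' @return numeric vector, one fraction per sample.
#' @export
sample_missingness <- function(geno) {
  stopifnot(ncol(geno) >= 1L)
  rowMeans(is.na(geno))
}

#' Per-variant alternate-allele frequency and minor allele frequency
#'
#' The alternate-allele frequency is the alternate allele count over twice
#' the number of non-missing samples; MAF folds it onto \[0, 0.5\]. A variant
#' with no non-missing calls has undefined (NA) frequency and fails any MAF
#' filter.
#'
#' @inheritParams variant_missingness
#' @return for [alt_allele_freq()] the alternate frequency p; for
#'   [minor_allele_freq()] min(p, 1 - p).
#' @export
alt_allele_freq <- function(geno) {
  n_obs <- colSums(!is.na(geno))
  p <- colSums(geno, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0L] <- NA_real_
  p
}

#' @rdname alt_allele_freq
#' @export
minor_allele_freq <- function(geno) {
  p <- alt_allele_freq(geno)
  pmin(p, 1 - p)
}

# Log-probabilities of every possible heterozygote count given the rare
# allele count R and the number of diploid genotypes N, conditional on the
# allele counts (Levene/Haldane distribution). Computed by a log-space
# recurrence from the smallest feasible heterozygote count upward, then
# normalized. Returns list(het = feasible counts, logp = normalized logs).
hwe_het_logprobs <- function(R, N) {
  stopifnot(R >= 0L, R <= N * 2L - R)
  h_min <- if (R %% 2L == 0L) 0L else 1L
  h <- seq.int(h_min, R, by = 2L)
  logp <- numeric(length(h))
  if (length(h) > 1L) {
    for (i in seq_len(length(h) - 1L)) {
      hh <- h[i]
      n_aa <- (R - hh) / 2          # rare-allele homozygotes at hh
      n_bb <- N - (R + hh) / 2      # common-allele homozygotes at hh
      # P(h+2)/P(h) = 4 n_aa n_bb / ((h+2)(h+1))
      logp[i + 1L] <- logp[i] + log(4 * n_aa * n_bb) -
        log((hh + 2) * (hh + 1))
    }
  }
  m <- max(logp)
  logp <- logp - (m + log(sum(exp(logp - m))))
  list(het = h, logp = logp)
}

# Exact p-values for all feasible heterozygote counts at (R, N):
# p(h_obs) = sum of P(h') over h' with P(h') <= P(h_obs).
hwe_pvalues_all <- function(R, N) {
  d <- hwe_het_logprobs(R, N)
  p <- exp(d$logp)
  ord <- order(p)
  cum <- cumsum(p[ord])
  # ties share the cumulative mass of the last tied element
  pv <- numeric(length(p))
  i <- 1L
  n <- length(p)
  while (i <= n) {
    j <- i
    while (j < n && p[ord[j + 1L]] <= p[ord[i]] * (1 + 1e-12)) j <- j + 1L
    pv[ord[i:j]] <- cum[j]
    i <- j + 1L
  }
  list(het = d$het, pvalue = pmin(pv, 1))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions, conditional
#' on the observed allele counts: the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Probabilities are computed by a log-space recurrence,
#' stable for totals up to at least 10^4.
#'
#' @param n_AA,n_AB,n_BB genotype counts (vectors are recycled to a common
#'   length and tested element-wise).
#' @return exact p-value(s) in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  n <- max(length(n_AA), length(n_AB), length(n_BB))
  n_AA <- rep_len(as.integer(n_AA), n)
  n_AB <- rep_len(as.integer(n_AB), n)
  n_BB <- rep_len(as.integer(n_BB), n)
  if (any(is.na(n_AA) | is.na(n_AB) | is.na(n_BB))) {
    stop("genotype counts must be non-missing")
  }
  if (any(n_AA < 0L | n_AB < 0L | n_BB < 0L)) {
    stop("genotype counts must be non-negative")
  }
  if (any(n_AA + n_AB + n_BB < 1L)) stop("total genotype count must be >= 1")
  vapply(seq_len(n), function(i) {
    N <- n_AA[i] + n_AB[i] + n_BB[i]
    nA <- 2L * n_AA[i] + n_AB[i]
    R <- min(nA, 2L * N - nA)
    pv <- hwe_pvalues_all(R, N)
    pv$pvalue[match(n_AB[i], pv$het)]
  }, numeric(1))
}

#' Per-variant HWE exact p-values for a genotype matrix
#'
#' @inheritParams variant_missingness
#' @return numeric vector of p-values; NA for variants with no observed
#'   genotypes.
#' @export
variant_hwe_pvalues <- function(geno) {
  vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
}

#' Apply variant and sample quality-control filters
#'
#' Filter order is fixed: (1) samples with missing fraction at or above
#' `max_sample_missing` are dropped; (2) variant statistics are recomputed on
#' the remaining samples; (3) variants failing missingness (strictly above
#' threshold), MAF (strictly below threshold) or the HWE exact test
#' (p strictly below `hwe_alpha`) are dropped. Every exclusion and its reason
#' is recorded in the report.
#'
#' @param geno genotype matrix, samples x variants.
#' @param variants variant table aligned with `geno` columns.
#' @param params a [filter_params()] object.
#' @return list with elements `geno`, `variants` (filtered), and `report`
#'   (list of data.frames `samples` and `variants`, one row per input sample
#'   and variant with the computed statistics and pass/fail reason).
#' @export
apply_filters <- function(geno, variants, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"),
            ncol(geno) == nrow(variants))
  smiss <- sample_missingness(geno)
  s_pass <- smiss < params$max_sample_missing
  sample_report <- data.frame(
    sample_id = rownames(geno),
    missing_fraction = smiss,
    pass = s_pass,
    reason = ifelse(s_pass, "", "sample_missingness"),
    stringsAsFactors = FALSE
  )
  if (!any(s_pass)) {
    stop("all ", nrow(geno), " samples removed by the sample missingness filter")
  }
  g2 <- geno[s_pass, , drop = FALSE]

  vmiss <- variant_missingness(g2)
  maf <- minor_allele_freq(g2)
  hwe <- variant_hwe_pvalues(g2)
  reason <- character(ncol(g2))
  reason[!is.na(hwe) & hwe < params$hwe_alpha] <- "hwe"
  reason[is.na(maf) | maf < params$min_maf] <- "maf"
  reason[vmiss > params$max_variant_missing] <- "missingness"
  v_pass <- reason == ""
  variant_report <- data.frame(
    vid = variants$vid,
    missing_fraction = vmiss,
    maf = maf,
    hwe_p = hwe,
    pass = v_pass,
    reason = reason,
    stringsAsFactors = FALSE
  )
  if (!any(v_pass)) {
    stop("all ", ncol(g2), " variants removed by the variant filters ",
         "(missingness: ", sum(reason == "missingness"),
         ", maf: ", sum(reason == "maf"),
         ", hwe: ", sum(reason == "hwe"), ")")
  }
  list(
    geno = g2[, v_pass, drop = FALSE],
    variants = {
      v <- variants[v_pass, , drop = FALSE]
      rownames(v) <- NULL
      v
    },
    report = list(samples = sample_report, variants = variant_report)
  )
}
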