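#' Per-sample heterozygosity rate
#'
#' Fraction of a sample's non-missing genotypes that are heterozygous.
#'
#' @param geno genotype matrix, samples x variants.
#' @return numeric vector, one rate in \[0, 1\] per sample.
#' @export
het_rate <- function(geno) {
  n_obs <- rowSums(!is.na(geno))
  if (any(n_obs == 0L)) {
    stop("sample(s) with no observed genotypes: ",
         paste(rownames(geno)[n_obs == 0L], collapse = ", "))
  }
  rowSums(geno == 1L, na.rm = TRUE) / n_obs
}

#' Method-of-moments genomic inbreeding coefficient
#'
#' For each sample, F-hat = (O_hom - E_hom) / (L - E_hom), where O_hom is
#' the observed homozygote count over that sample's L non-missing variants
#' and E_hom sums, over the same variants, the Hardy-Weinberg expected
#' homozygosity 1 - 2 p q * 2n/(2n - 1) at cohort alternate-allele frequency
#' p (q = 1 - p) with n non-missing samples at the variant; the 2n/(2n-1)
#' factor removes the small-sample downward bias of expected
#' heterozygosity. Negative values indicate heterozygosity excess.
#'
#' @param geno genotype matrix, samples x variants; allele frequencies are
#'   taken from this cohort.
#' @return numeric vector of F-hat, one per sample; NA where the estimator
#'   is degenerate (L equals E_hom, e.g. an all-monomorphic panel).
#' @export
inbreeding_f <- function(geno) {
  n_obs_var <- colSums(!is.na(geno))
  p <- alt_allele_freq(geno)
  q <- 1 - p
  corr <- ifelse(n_obs_var > 0L, 2 * n_obs_var / (2 * n_obs_var - 1), NA_real_)
  e_hom_var <- 1 - 2 * p * q * corr   # per-variant expected homozygosity
  obs <- !is.na(geno)
  hom <- obs & geno != 1L
  o_hom <- rowSums(hom)
  e_hom <- as.numeric(obs %*% ifelse(is.na(e_hom_var), 0, e_hom_var))
  l_used <- rowSums(obs)
  denom <- l_used - e_hom
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (o_hom - e_hom) / denom)
  names(f) <- rownames(geno)
  f
}

#' Per-sample genetic-diversity records
#'
#' @param geno genotype matrix, samples x variants.
#' @return data.frame with columns sample_id, n_used, het_rate, o_hom,
#'   e_hom, f_hat.
#' @export
diversity_table <- function(geno) {
  obs <- !is.na(geno)
  n_obs_var <- colSums(obs)
  p <- alt_allele_freq(geno)
  e_hom_var <- 1 - 2 * p * (1 - p) *
    ifelse(n_obs_var > 0L, 2 * n_obs_var / (2 * n_obs_var - 1), NA_real_)
  data.frame(
    sample_id = rownames(geno),
    n_used = rowSums(obs),
    het_rate = het_rate(geno),
    o_hom = rowSums(obs & geno != 1L),
    e_hom = as.numeric(obs %*% ifelse(is.na(e_hom_var), 0, e_hom_var)),
    f_hat = inbreeding_f(geno),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Subpopulation summaries with pairwise tests
#'
#' Mean, sample SD (n - 1 denominator), min and max of a per-sample
#' statistic by subpopulation, plus two-sided pairwise Welch t-tests
#' (headline p-value) and Mann-Whitney U tests. Groups of fewer than two
#' samples are summarised but excluded from testing, with a warning.
#'
#' @param values named numeric vector or a column of [diversity_table()]
#'   aligned with `metadata`.
#' @param metadata sample table with columns sample_id and subpopulation.
#' @param statistic label used in the output (e.g. "het_rate").
#' @return list with data.frames `summary` (subpopulation, n, mean, sd,
#'   min, max) and `tests` (group1, group2, welch_p, mannwhitney_p).
#' @export
subpop_summary <- function(values, metadata, statistic = "value") {
  stopifnot(length(values) == nrow(metadata))
  grp <- split(values, metadata$subpopulation)
  summ <- data.frame(
    subpopulation = names(grp),
    statistic = statistic,
    n = vapply(grp, length, integer(1)),
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, sd, numeric(1)),
    min = vapply(grp, min, numeric(1)),
    max = vapply(grp, max, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  testable <- names(grp)[vapply(grp, length, integer(1)) >= 2L]
  if (length(testable) < length(grp)) {
    warning("group(s) of size < 2 excluded from pairwise tests: ",
            paste(setdiff(names(grp), testable), collapse = ", "))
  }
  tests <- NULL
  if (length(testable) >= 2L) {
    pairs <- utils::combn(sort(testable), 2L)
    tests <- data.frame(
      group1 = pairs[1L, ],
      group2 = pairs[2L, ],
      welch_p = apply(pairs, 2L, function(pr) {
        x <- grp[[pr[1L]]]; y <- grp[[pr[2L]]]
        if (sd(c(x, y)) == 0) return(1)  # identical constant groups
        tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
      }),
      mannwhitney_p = apply(pairs, 2L, function(pr) {
        suppressWarnings(wilcox.test(grp[[pr[1L]]], grp[[pr[2L]]])$p.value)
      }),
      stringsAsFactors = FALSE
    )
  }
  list(summary = summ, tests = tests)
}
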