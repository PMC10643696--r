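#' LD-pruning parameters
#'
#' Windowed pairwise-r2 pruning in the style of the common
#' `--indep-pairwise 50 5 0.5` idiom: windows of `window_size` SNPs advanced
#' by `step` SNPs, removing one SNP of any pair with genotype r2 above
#' `r2_threshold`.
#'
#' @param window_size window width in SNPs (default 50).
#' @param step window advance in SNPs (default 5).
#' @param r2_threshold r2 above which one SNP of a pair is removed
#'   (default 0.5).
#' @return object of class `prune_params`.
#' @export
prune_params <- function(window_size = 50L, step = 5L, r2_threshold = 0.5) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (!(window_size > step && step >= 1L)) {
    stop("require window_size > step >= 1")
  }
  if (!(r2_threshold > 0 && r2_threshold <= 1)) {
    stop("r2_threshold must be in (0, 1]")
  }
  structure(list(window_size = window_size, step = step,
                 r2_threshold = r2_threshold), class = "prune_params")
}

#' Squared genotype correlation between two variants
#'
#' Composite-LD r2: the squared Pearson correlation of alternate-allele
#' counts over samples where both genotypes are observed. If fewer than two
#' complete pairs remain, or either vector has zero variance after pair
#' deletion, r2 is undefined and 0 is returned (such pairs never trigger
#' pruning).
#'
#' @param x,y integer genotype vectors of equal length (`NA` = missing).
#' @return r2 in \[0, 1\].
#' @export
genotype_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

# r2 matrix for a window of genotype columns; undefined entries -> 0
window_r2 <- function(gw) {
  suppressWarnings(r <- cor(gw, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Prune variants by windowed pairwise LD
#'
#' Within each sliding window on each chromosome, while any pair of kept
#' variants has r2 above the threshold the later variant (higher position)
#' of the pair is removed; the window then advances by `step` SNPs. The
#' procedure is deterministic and its result contains no intra-window pair
#' exceeding the threshold.
#'
#' @param geno genotype matrix, samples x variants, columns sorted by
#'   (chromosome, position).
#' @param variants variant table aligned with `geno` columns.
#' @param params a [prune_params()] object.
#' @return integer vector of kept variant column indices (sorted).
#' @export
ld_prune <- function(geno, variants, params = prune_params()) {
  stopifnot(inherits(params, "prune_params"),
            ncol(geno) == nrow(variants))
  if (is.unsorted(chrom_rank(variants$chrom) * (max(variants$pos) + 1) +
                  variants$pos)) {
    stop("variants must be sorted by (chromosome, position)")
  }
  keep <- rep(TRUE, ncol(geno))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    nv <- length(idx)
    w <- params$window_size
    starts <- if (nv <= w) 0L else seq.int(0L, nv - w, by = params$step)
    for (s in starts) {
      win <- idx[(s + 1L):min(s + w, nv)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- window_r2(geno[, win, drop = FALSE])
      m <- length(win)
      for (i in seq_len(m - 1L)) {
        if (!keep[win[i]]) next
        for (j in (i + 1L):m) {
          if (keep[win[j]] && r2[i, j] > params$r2_threshold) {
            keep[win[j]] <- FALSE
          }
        }
      }
    }
  }
  which(keep)
}
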