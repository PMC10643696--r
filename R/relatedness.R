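#' Relationship-class thresholds on Pi-Hat
#'
#' The five-class criteria: strictly above `duplicate` is a duplicate or
#' identical twin; at or above `first`, `second`, `third` are first-, second-
#' and third-degree relationships; below `third` is unrelated.
#'
#' @param duplicate,first,second,third Pi-Hat cut points (defaults 0.95,
#'   0.40, 0.20, 0.10); must be strictly decreasing.
#' @return object of class `relationship_thresholds`.
#' @export
relationship_thresholds <- function(duplicate = 0.95, first = 0.40,
                                    second = 0.20, third = 0.10) {
  v <- c(duplicate, first, second, third)
  if (any(diff(v) >= 0)) stop("thresholds must be strictly decreasing")
  structure(list(duplicate = duplicate, first = first, second = second,
                 third = third), class = "relationship_thresholds")
}

#' Classify a pair's relationship from Pi-Hat
#'
#' @param pi_hat numeric vector of Pi-Hat values in \[0, 1\].
#' @param thresholds a [relationship_thresholds()] object.
#' @return factor with levels duplicate_or_twin, first_degree,
#'   second_degree, third_degree, unrelated.
#' @export
classify_relationship <- function(pi_hat,
                                  thresholds = relationship_thresholds()) {
  if (any(is.na(pi_hat) | pi_hat < 0 | pi_hat > 1)) {
    stop("pi_hat values must lie in [0, 1]")
  }
  lv <- c("duplicate_or_twin", "first_degree", "second_degree",
          "third_degree", "unrelated")
  out <- rep("unrelated", length(pi_hat))
  out[pi_hat >= thresholds$third] <- "third_degree"
  out[pi_hat >= thresholds$second] <- "second_degree"
  out[pi_hat >= thresholds$first] <- "first_degree"
  out[pi_hat > thresholds$duplicate] <- "duplicate_or_twin"
  factor(out, levels = lv)
}

#' Identity-by-state counts for a pair of genotype vectors
#'
#' Loci with either genotype missing are excluded. IBS2 when genotypes are
#' equal, IBS0 when they are opposite homozygotes (0 vs 2), IBS1 otherwise.
#'
#' @param x,y integer genotype vectors of equal length.
#' @return named integer vector (n_ibs0, n_ibs1, n_ibs2).
#' @export
ibs_counts <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no loci with complete genotypes for the pair")
  x <- x[ok]; y <- y[ok]
  n2 <- sum(x == y)
  n0 <- sum(abs(x - y) == 2L)
  c(n_ibs0 = n0, n_ibs1 = length(x) - n0 - n2, n_ibs2 = n2)
}

# Per-locus expected IBS-state probabilities conditional on IBD state, at
# alternate-allele frequency p. Columns: e0_z0, e1_z0, e2_z0, e1_z1, e2_z1.
ibs_state_expectations <- function(p) {
  q <- 1 - p
  cbind(
    e0_z0 = 2 * p^2 * q^2,
    e1_z0 = 4 * p^3 * q + 4 * p * q^3,
    e2_z0 = p^4 + q^4 + 4 * p^2 * q^2,
    e1_z1 = 2 * p^2 * q + 2 * p * q^2,
    e2_z1 = p^3 + q^3 + p^2 * q + p * q^2
  )
}

#' Method-of-moments IBD estimates from IBS counts
#'
#' Solves the moments equations relating observed IBS-state counts to the
#' IBD-state proportions (Z0, Z1, Z2), using expected per-locus IBS-state
#' probabilities at the supplied cohort allele frequencies, summed over the
#' loci complete for the pair. Estimates are clamped to \[0, 1\] and
#' renormalized to sum to one; Pi-Hat = Z2 + Z1/2.
#'
#' @param counts named vector from [ibs_counts()].
#' @param p alternate-allele frequencies of the loci complete for the pair.
#' @return named numeric vector (z0, z1, z2, pi_hat).
#' @export
ibd_moments <- function(counts, p) {
  e <- ibs_state_expectations(p)
  s <- colSums(e)
  n_loci <- sum(counts)
  if (any(s[c("e0_z0", "e1_z1")] <= 0) || n_loci <= 0) {
    stop("degenerate IBS expectations (all loci monomorphic?): ",
         paste(sprintf("%s=%.3g", names(s), s), collapse = ", "))
  }
  z0 <- counts[["n_ibs0"]] / s[["e0_z0"]]
  z1 <- (counts[["n_ibs1"]] - z0 * s[["e1_z0"]]) / s[["e1_z1"]]
  z2 <- (counts[["n_ibs2"]] - z0 * s[["e2_z0"]] - z1 * s[["e2_z1"]]) / n_loci
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  if (sum(z) <= 0) z <- c(1, 0, 0) else z <- z / sum(z)
  c(z0 = z[1L], z1 = z[2L], z2 = z[3L], pi_hat = z[3L] + z[2L] / 2)
}

#' Pairwise IBD relatedness over a genotype matrix
#'
#' Computes IBS counts, moments IBD estimates, Pi-Hat and the relationship
#' class for sample pairs, using cohort alternate-allele frequencies.
#' Intended for the post-QC, LD-pruned marker set.
#'
#' @param geno genotype matrix, samples x variants.
#' @param pairs optional 2-column matrix/data.frame of sample ids (or row
#'   indices) restricting computation; default all unordered pairs.
#' @param thresholds a [relationship_thresholds()] object.
#' @return data.frame, one row per pair: id1, id2, n_ibs0, n_ibs1, n_ibs2,
#'   z0, z1, z2, pi_hat, rel_class.
#' @export
snp_relatedness <- function(geno, pairs = NULL,
                            thresholds = relationship_thresholds()) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nrow(geno), 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (!is.numeric(pairs)) {
      pairs <- matrix(match(pairs, ids), ncol = 2L)
      if (anyNA(pairs)) stop("pair sample id not found in genotype matrix")
    }
    storage.mode(pairs) <- "integer"
  }
  p_all <- alt_allele_freq(geno)
  e_all <- ibs_state_expectations(p_all)
  e_all[is.na(e_all)] <- 0
  s_tot <- colSums(e_all)
  miss_idx <- lapply(seq_len(nrow(geno)),
                     function(i) which(is.na(geno[i, ])))

  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    cnt <- ibs_counts(geno[i, ], geno[j, ])
    drop <- union(miss_idx[[i]], miss_idx[[j]])
    s <- if (length(drop)) {
      s_tot - colSums(e_all[drop, , drop = FALSE])
    } else s_tot
    n_loci <- sum(cnt)
    if (s[["e0_z0"]] <= 0 || s[["e1_z1"]] <= 0) {
      stop("degenerate IBS expectations for pair ", ids[i], "/", ids[j])
    }
    z0 <- cnt[["n_ibs0"]] / s[["e0_z0"]]
    z1 <- (cnt[["n_ibs1"]] - z0 * s[["e1_z0"]]) / s[["e1_z1"]]
    z2 <- (cnt[["n_ibs2"]] - z0 * s[["e2_z0"]] - z1 * s[["e2_z1"]]) / n_loci
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    if (sum(z) <= 0) z <- c(1, 0, 0) else z <- z / sum(z)
    out[[k]] <- c(cnt, z0 = z[1L], z1 = z[2L], z2 = z[3L],
                  pi_hat = z[3L] + z[2L] / 2)
  }
  res <- as.data.frame(do.call(rbind, out))
  res <- cbind(data.frame(id1 = ids[pairs[, 1L]], id2 = ids[pairs[, 2L]],
                          stringsAsFactors = FALSE), res)
  res$rel_class <- classify_relationship(res$pi_hat, thresholds)
  res
}

#' IBS-sharing distance matrix
#'
#' D_ij = 1 - (n_ibs2 + 0.5 n_ibs1) / N_ij over the loci complete for each
#' pair; the diagonal is zero.
#'
#' @param geno genotype matrix, samples x variants.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(geno) {
  obs <- !is.na(geno)
  m0 <- obs & geno == 0L
  m1 <- obs & geno == 1L
  m2 <- obs & geno == 2L
  storage.mode(m0) <- storage.mode(m1) <- storage.mode(m2) <-
    storage.mode(obs) <- "double"
  n_pair <- obs %*% t(obs)
  ibs2 <- m0 %*% t(m0) + m1 %*% t(m1) + m2 %*% t(m2)
  ibs0 <- m0 %*% t(m2) + m2 %*% t(m0)
  ibs1 <- n_pair - ibs2 - ibs0
  d <- 1 - (ibs2 + 0.5 * ibs1) / n_pair
  diag(d) <- 0
  dimnames(d) <- list(rownames(geno), rownames(geno))
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -D^2/2, eigendecomposes, and returns the leading
#' coordinates scaled by the square root of their eigenvalues. The sign of
#' each axis is fixed so that its first nonzero loading is positive.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of dimensions (default 2).
#' @return numeric matrix, points x k, rownames from `d`.
#' @export
mds_embed <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  k <- min(k, n - 1L)
  lam <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  for (c in seq_len(k)) {
    nz <- which(abs(coords[, c]) > 1e-12)
    if (length(nz) && coords[nz[1L], c] < 0) coords[, c] <- -coords[, c]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(k))
  coords
}

#' Pi-Hat heatmap matrix by sex
#'
#' Builds the males x females matrix of Pi-Hat values (as percentages),
#' rows and columns ordered by (subpopulation, sample_id) for deterministic
#' output.
#'
#' @param pairs data.frame from [snp_relatedness()].
#' @param metadata sample table with sample_id, sex, subpopulation.
#' @return numeric matrix (percent Pi-Hat), males as rows, females as
#'   columns.
#' @export
pihat_heatmap_matrix <- function(pairs, metadata) {
  ord <- order(metadata$subpopulation, metadata$sample_id)
  md <- metadata[ord, , drop = FALSE]
  males <- md$sample_id[md$sex == "male"]
  females <- md$sample_id[md$sex == "female"]
  m <- matrix(NA_real_, length(males), length(females),
              dimnames = list(males, females))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- setNames(pairs$pi_hat, key(pairs$id1, pairs$id2))
  for (i in seq_along(males)) {
    kk <- key(rep(males[i], length(females)), females)
    m[i, ] <- 100 * unname(lut[kk])
  }
  m
}
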