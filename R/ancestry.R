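ADMIX_EPS <- 1e-6

# binomial log-likelihood of genotype matrix G (0/1/2, NA skipped) at
# per-entry alternate dosage probabilities P = Q %*% F, with the binomial
# coefficient included so K = 1 matches the closed-form binomial likelihood
admix_loglik <- function(G, P) {
  obs <- !is.na(G)
  g <- G[obs]
  p <- P[obs]
  sum(log(choose(2, g)) + g * log(p) + (2 - g) * log(1 - p))
}

admix_init <- function(n, L, K, seed) {
  set.seed(seed)
  q <- matrix(runif(n * K, 0.1, 1), n, K)
  q <- q / rowSums(q)
  f <- matrix(runif(K * L, 0.05, 0.95), K, L)
  list(q = q, f = f)
}

# one EM sweep; returns updated q, f
admix_em_step <- function(G, q, f, obs, L_i) {
  K <- ncol(q)
  P <- q %*% f
  P <- pmin(pmax(P, ADMIX_EPS), 1 - ADMIX_EPS)
  Gn <- G
  Gn[!obs] <- 0
  W1 <- Gn / P          # g / p, zero where missing
  W0 <- (2 - Gn) / (1 - P)
  W0[!obs] <- 0
  q_new <- matrix(0, nrow(q), K)
  f_num <- matrix(0, K, ncol(f))
  f_den <- matrix(0, K, ncol(f))
  for (k in seq_len(K)) {
    ak <- W1 * outer(q[, k], f[k, ])        # g * a_ilk
    bk <- W0 * outer(q[, k], 1 - f[k, ])    # (2-g) * b_ilk
    q_new[, k] <- rowSums(ak + bk) / (2 * L_i)
    f_num[k, ] <- colSums(ak)
    f_den[k, ] <- colSums(ak + bk)
  }
  f_new <- ifelse(f_den > 0, f_num / f_den, f)  # no data: keep current value
  f_new <- pmin(pmax(f_new, ADMIX_EPS), 1 - ADMIX_EPS)
  q_new <- pmin(pmax(q_new, ADMIX_EPS), 1 - ADMIX_EPS)
  q_new <- q_new / rowSums(q_new)
  list(q = q_new, f = f_new)
}

admix_em_run <- function(G, K, seed, tol, max_iter) {
  n <- nrow(G); L <- ncol(G)
  obs <- !is.na(G)
  L_i <- rowSums(obs)
  init <- admix_init(n, L, K, seed)
  q <- init$q; f <- init$f
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    st <- admix_em_step(G, q, f, obs, L_i)
    q <- st$q; f <- st$f
    ll <- admix_loglik(G, pmin(pmax(q %*% f, ADMIX_EPS), 1 - ADMIX_EPS))
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at EM iteration ", it)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
  }
  list(q = q, f = f, loglik = trace[length(trace)], trace = trace,
       n_iter = length(trace))
}

#' Fit the admixture model by expectation-maximization
#'
#' Models each genotype as Binomial(2, p_il) with p_il = sum_k q_ik f_kl:
#' q_ik are per-sample ancestry fractions over K clusters and f_kl per-
#' cluster alternate-allele frequencies. Plain EM updates are iterated until
#' the log-likelihood gain falls below `tol`; the log-likelihood is
#' non-decreasing across iterations. Several seeded restarts are run and the
#' best final log-likelihood kept. Missing genotypes are skipped in all
#' sums; parameters are kept in the open interval by clipping to
#' \[1e-6, 1 - 1e-6\].
#'
#' @param geno genotype matrix, samples x variants (post-QC, LD-pruned).
#' @param K number of ancestry clusters (1 to the sample count).
#' @param seed base random seed; restart r uses seed + r - 1.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter iteration cap per restart (default 2000).
#' @param n_restarts number of seeded restarts (default 5).
#' @return object of class `admixture_fit` with elements `K`, `Q`
#'   (samples x K), `F` (K x variants), `loglik`, `loglik_trace`, `n_iter`,
#'   `seed`, `seeds`, `cv_error` (NULL until [admixture_cv()] fills it).
#' @export
admixture_fit <- function(geno, K, seed = 1L, tol = 1e-6, max_iter = 2000L,
                          n_restarts = 5L) {
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(geno)) stop("K (", K, ") exceeds the sample count (",
                           nrow(geno), ")")
  seeds <- seed + seq_len(n_restarts) - 1L
  best <- NULL
  for (s in seeds) {
    run <- admix_em_run(geno, K, s, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best$seed_used <- s
    }
  }
  rownames(best$q) <- rownames(geno)
  colnames(best$q) <- paste0("K", seq_len(K))
  rownames(best$f) <- paste0("K", seq_len(K))
  structure(list(K = K, Q = best$q, F = best$f, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 seed = seed, seeds = seeds, seed_used = best$seed_used,
                 cv_error = NULL),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Admixture model fit (EM)\n")
  cat("  samples:", nrow(x$Q), "  variants:", ncol(x$F),
      "  clusters K:", x$K, "\n")
  cat("  log-likelihood:", format(x$loglik), "after", x$n_iter,
      "iterations (best of", length(x$seeds), "restarts)\n")
  if (!is.null(x$cv_error)) cat("  CV error:", format(x$cv_error), "\n")
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  dom <- apply(object$Q, 1L, max)
  cat("Admixture fit: K =", object$K, ", loglik =", format(object$loglik),
      "\nDominant ancestry fraction per sample:\n")
  print(summary(dom))
  invisible(list(dominant_fraction = dom))
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = nrow(object$Q) * (object$K - 1) + object$K * ncol(object$F),
            class = "logLik")
}

#' @export
predict.admixture_fit <- function(object, ...) {
  2 * object$Q %*% object$F  # expected alternate-allele dosage
}

#' Cross-validated prediction error for choosing K
#'
#' Non-missing genotype entries are partitioned at random into `folds`
#' folds. Each fold is masked in turn, the model refit on the rest, and the
#' masked genotypes predicted as Binomial(2, p_il); the error is the mean
#' binomial deviance over masked entries, averaged over folds. Masked
#' entries of a variant left with no training observations in a fold are
#' skipped with a warning. Deterministic given `seed`.
#'
#' @inheritParams admixture_fit
#' @param folds number of folds (default 5).
#' @param n_restarts restarts per fold fit (default 1; CV compares K values,
#'   not restart noise).
#' @return mean cross-validated deviance (a single number).
#' @export
admixture_cv <- function(geno, K, folds = 5L, seed = 1L, tol = 1e-5,
                         max_iter = 500L, n_restarts = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  obs_idx <- which(!is.na(geno))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
  fold_means <- numeric(folds)
  for (fd in seq_len(folds)) {
    masked <- obs_idx[fold_of == fd]
    g_train <- geno
    g_train[masked] <- NA_integer_
    empty_var <- colSums(!is.na(g_train)) == 0L
    fit <- admixture_fit(g_train, K, seed = seed + fd, tol = tol,
                         max_iter = max_iter, n_restarts = n_restarts)
    # held-out predictions are smoothed away from 0/1 (at 1/(2N + 2), the
    # Laplace pseudocount scale) so a single unseen allele cannot dominate
    # the deviance
    clip <- 1 / (2 * nrow(geno) + 2)
    P <- pmin(pmax(fit$Q %*% fit$F, clip), 1 - clip)
    if (any(empty_var)) {
      warning(sum(empty_var), " variant(s) with no training observations ",
              "in fold ", fd, "; their masked entries skipped")
      masked_col <- ((masked - 1L) %/% nrow(geno)) + 1L
      keep <- !(masked_col %in% which(empty_var))
      masked <- masked[keep]
    }
    g <- geno[masked]
    p <- P[masked]
    p_sat <- pmin(pmax(g / 2, clip), 1 - clip)
    dev <- -2 * ((g * log(p) + (2 - g) * log(1 - p)) -
                 (g * log(p_sat) + (2 - g) * log(1 - p_sat)))
    fold_means[fd] <- mean(dev)
  }
  mean(fold_means)
}

#' Sweep K over a range by cross-validation
#'
#' @param geno genotype matrix.
#' @param k_values integer vector of K values to evaluate.
#' @param ... passed to [admixture_cv()].
#' @return data.frame with columns K and cv_error, plus attribute
#'   `best_K` (the K with smallest error).
#' @export
admixture_cv_sweep <- function(geno, k_values, ...) {
  err <- vapply(k_values, function(K) admixture_cv(geno, K, ...), numeric(1))
  out <- data.frame(K = k_values, cv_error = err)
  attr(out, "best_K") <- k_values[which.min(err)]
  out
}

#' Map fitted clusters to reference labels
#'
#' Greedy assignment: repeatedly pair the (cluster, label) combination with
#' the highest mean ancestry fraction of that cluster among samples carrying
#' that label. Bijective when K equals the number of labels; ties are broken
#' by label sort order with a warning.
#'
#' @param fit an `admixture_fit` object (or a Q matrix).
#' @param labels character vector of reference labels, one per sample.
#' @return named character vector mapping cluster names to labels.
#' @export
align_clusters <- function(fit, labels) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  stopifnot(nrow(Q) == length(labels))
  labs <- sort(unique(labels))
  means <- vapply(labs, function(l) colMeans(Q[labels == l, , drop = FALSE]),
                  numeric(ncol(Q)))
  means <- matrix(means, nrow = ncol(Q), dimnames = list(colnames(Q), labs))
  mapping <- setNames(rep(NA_character_, ncol(Q)), colnames(Q))
  free_k <- colnames(Q)
  free_l <- labs
  while (length(free_k) && length(free_l)) {
    sub <- means[free_k, free_l, drop = FALSE]
    mx <- max(sub)
    hits <- which(sub == mx, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      warning("tie while aligning clusters; resolved by label sort order")
      hits <- hits[order(colnames(sub)[hits[, 2L]],
                         rownames(sub)[hits[, 1L]]), , drop = FALSE]
    }
    k <- rownames(sub)[hits[1L, 1L]]
    l <- colnames(sub)[hits[1L, 2L]]
    mapping[k] <- l
    free_k <- setdiff(free_k, k)
    free_l <- setdiff(free_l, l)
  }
  mapping
}

#' Classify genetic purity from ancestry fractions
#'
#' A sample is purebred when its dominant ancestry fraction is at least
#' 1 - `purity_tol` (the operational reading of "100% ancestry" under
#' interior-point clipping), admixed when any non-dominant fraction exceeds
#' `admix_flag`, and low_admixture otherwise.
#'
#' @param Q ancestry-fraction matrix (samples x K) or a single row.
#' @param purity_tol tolerance on the dominant fraction (default 0.001).
#' @param admix_flag non-dominant fraction above which a sample is called
#'   admixed (default 0.40).
#' @return data.frame: sample_id, dominant_cluster, dominant_fraction,
#'   purity_class.
#' @export
classify_purity <- function(Q, purity_tol = 0.001, admix_flag = 0.40) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L,
                                   dimnames = list("sample1",
                                                   names(Q)))
  if (any(abs(rowSums(Q) - 1) > 1e-6)) {
    stop("ancestry rows must sum to 1")
  }
  if (is.null(colnames(Q))) colnames(Q) <- paste0("K", seq_len(ncol(Q)))
  dom_k <- max.col(Q, ties.method = "first")
  dom <- Q[cbind(seq_len(nrow(Q)), dom_k)]
  other_max <- apply(Q, 1L, function(r) {
    if (length(r) == 1L) 0 else max(r[-which.max(r)])
  })
  cls <- ifelse(dom >= 1 - purity_tol, "purebred",
                ifelse(other_max > admix_flag, "admixed", "low_admixture"))
  data.frame(
    sample_id = if (is.null(rownames(Q))) as.character(seq_len(nrow(Q)))
                else rownames(Q),
    dominant_cluster = colnames(Q)[dom_k],
    dominant_fraction = dom,
    purity_class = cls,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
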