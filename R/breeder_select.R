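#' Build candidate and mate pools for breeder selection
#'
#' Candidates and mates are opposite-sex subsets of the cohort, optionally
#' gated to purebred individuals. Unknown-sex individuals are excluded from
#' both pools with a warning.
#'
#' @param metadata sample table with sample_id and sex.
#' @param purity data.frame from [classify_purity()] (required when a gate
#'   is on).
#' @param candidate_sex,mate_sex "male" or "female".
#' @param gate_candidates,gate_mates restrict the respective side to
#'   purebred individuals (default TRUE).
#' @return list with character vectors `candidates` and `mates`.
#' @export
build_mate_pool <- function(metadata, purity = NULL,
                            candidate_sex = "male", mate_sex = "female",
                            gate_candidates = TRUE, gate_mates = TRUE) {
  stopifnot(candidate_sex != mate_sex)
  unk <- metadata$sample_id[metadata$sex == "unknown"]
  if (length(unk)) {
    warning("unknown-sex individual(s) excluded from pools: ",
            paste(unk, collapse = ", "))
  }
  pure_ids <- if (!is.null(purity)) {
    purity$sample_id[purity$purity_class == "purebred"]
  } else character(0)
  pick <- function(sex, gate) {
    ids <- metadata$sample_id[metadata$sex == sex]
    if (gate) {
      if (is.null(purity)) stop("purity calls required when gating is on")
      ids <- intersect(ids, pure_ids)
    }
    ids
  }
  cands <- pick(candidate_sex, gate_candidates)
  mates <- pick(mate_sex, gate_mates)
  if (!length(cands) || !length(mates)) {
    warning("empty pool after gating (candidates: ", length(cands),
            ", mates: ", length(mates), ")")
  }
  list(candidates = cands, mates = mates)
}

#' Rank breeder candidates by unrelated-mate counts
#'
#' For each candidate, counts mates classified unrelated (Pi-Hat below the
#' unrelated boundary) and assigns a tier: `unrelated_to_all` when the count
#' equals the mate-pool size, `unrelated_to_more_than_10` when it exceeds
#' `tier_cutoff`, otherwise `other`. The report is sorted by count
#' (descending) then sample id.
#'
#' @param pairs data.frame from [snp_relatedness()]; must contain a record
#'   for every candidate x mate pair.
#' @param pools list from [build_mate_pool()].
#' @param tier_cutoff count above which the middle tier applies
#'   (default 10).
#' @return data.frame: sample_id, n_unrelated_mates, unrelated_mate_ids
#'   (comma-separated), tier.
#' @export
recommend_breeders <- function(pairs, pools, tier_cutoff = 10L) {
  cands <- pools$candidates
  mates <- pools$mates
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- setNames(as.character(pairs$rel_class), key(pairs$id1, pairs$id2))
  rows <- lapply(cands, function(cand) {
    kk <- key(rep(cand, length(mates)), mates)
    cls <- lut[kk]
    if (anyNA(cls)) {
      stop("missing relatedness record for pair ", cand, " x ",
           mates[which(is.na(cls))[1L]])
    }
    unrel <- mates[cls == "unrelated"]
    n <- length(unrel)
    data.frame(
      sample_id = cand,
      n_unrelated_mates = n,
      unrelated_mate_ids = paste(unrel, collapse = ","),
      tier = if (n == length(mates) && n > 0L) "unrelated_to_all"
             else if (n > tier_cutoff) "unrelated_to_more_than_10"
             else "other",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(sample_id = character(), n_unrelated_mates = integer(),
                      unrelated_mate_ids = character(), tier = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$n_unrelated_mates, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
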