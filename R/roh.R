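#' Sliding-window ROH detection parameters
#'
#' Defaults are the parameter set commonly used for medium-density SNP data:
#' 15-SNP windows, a window-proportion threshold of 0.05, at most one
#' heterozygous and one missing call per window, runs of at least 20 SNPs and
#' 250 kb, a maximum inter-SNP gap of 1 Mb, and a minimum density of one SNP
#' per Mb of run length.
#'
#' @param window_size window width in SNPs (default 15).
#' @param threshold minimum proportion of homozygous windows covering a SNP
#'   for it to be called in-run (default 0.05; the SNP is in-run when the
#'   proportion is strictly greater).
#' @param min_snp minimum SNPs per run (default 20).
#' @param max_opp_window maximum heterozygous calls per homozygous window
#'   (default 1).
#' @param max_miss_window maximum missing calls per homozygous window
#'   (default 1).
#' @param max_gap maximum adjacent-SNP spacing inside a run, bp
#'   (default 1e6).
#' @param min_length_bps minimum run length, bp (default 250000).
#' @param min_density minimum SNPs per kb of run length (default 1/1000,
#'   i.e. one SNP per Mb).
#' @return object of class `roh_params`.
#' @export
roh_params <- function(window_size = 15L, threshold = 0.05, min_snp = 20L,
                       max_opp_window = 1L, max_miss_window = 1L,
                       max_gap = 1e6, min_length_bps = 250000,
                       min_density = 1 / 1000) {
  p <- list(window_size = as.integer(window_size), threshold = threshold,
            min_snp = as.integer(min_snp),
            max_opp_window = as.integer(max_opp_window),
            max_miss_window = as.integer(max_miss_window),
            max_gap = max_gap, min_length_bps = min_length_bps,
            min_density = min_density)
  if (p$window_size < 1L || any(unlist(p) < 0)) {
    stop("ROH parameters must be non-negative with window_size >= 1")
  }
  structure(p, class = "roh_params")
}

# rolling sum over windows of width w (length(x) - w + 1 values)
roll_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

# run detection for one sample on one chromosome
detect_roh_chrom <- function(g, pos, params) {
  nv <- length(g)
  w <- params$window_size
  if (nv < w) {
    warning("chromosome with fewer SNPs (", nv, ") than the window size; ",
            "no runs detected")
    return(NULL)
  }
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom_win <- roll_sum(as.numeric(het), w) <= params$max_opp_window &
    roll_sum(as.numeric(mis), w) <= params$max_miss_window
  # proportion of full windows covering SNP i that are homozygous
  n_win <- nv - w + 1L
  cs <- cumsum(c(0, as.numeric(hom_win)))
  i <- seq_len(nv)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n_win)
  prop <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  in_run <- prop > params$threshold

  if (!any(in_run)) return(NULL)
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split where adjacent spacing exceeds max_gap
    gap_break <- which(diff(pos[idx]) > params$max_gap)
    piece_start <- c(1L, gap_break + 1L)
    piece_end <- c(gap_break, length(idx))
    for (m in seq_along(piece_start)) {
      ii <- idx[piece_start[m]:piece_end[m]]
      n_snps <- length(ii)
      len <- pos[ii[n_snps]] - pos[ii[1L]]
      if (n_snps >= params$min_snp && len >= params$min_length_bps &&
          n_snps / (len / 1000) >= params$min_density) {
        segs[[length(segs) + 1L]] <-
          c(start_pos = pos[ii[1L]], end_pos = pos[ii[n_snps]],
            n_snps = n_snps, length_bp = len)
      }
    }
  }
  if (!length(segs)) return(NULL)
  as.data.frame(do.call(rbind, segs))
}

#' Detect runs of homozygosity by sliding windows
#'
#' Per chromosome and sample: (1) a window of `window_size` consecutive SNPs
#' slides one SNP at a time and is called homozygous when it contains at
#' most `max_opp_window` heterozygous and `max_miss_window` missing calls;
#' (2) a SNP is in-run when the proportion of full windows covering it that
#' are homozygous exceeds `threshold`; (3) maximal stretches of consecutive
#' in-run SNPs are split wherever adjacent SNPs are more than `max_gap`
#' apart; (4) candidate runs are kept when they have at least `min_snp`
#' SNPs, span at least `min_length_bps` (end minus start position) and have
#' SNP density at least `min_density` per kb.
#'
#' @param geno genotype matrix, samples x variants (or a single sample's
#'   vector).
#' @param variants variant table aligned with the genotype columns, sorted
#'   by (chromosome, position).
#' @param params a [roh_params()] object.
#' @return data.frame of segments: sample_id, chrom, start_pos, end_pos,
#'   n_snps, length_bp, length_class, g_estimate (generations to the common
#'   ancestor from [generations_to_ancestor()]).
#' @export
detect_roh <- function(geno, variants, params = roh_params()) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                         dimnames = list("sample1", NULL))
  stopifnot(ncol(geno) == nrow(variants))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  chroms <- unique(variants$chrom)
  out <- list()
  for (chr in chroms) {
    jj <- which(variants$chrom == chr)
    pos <- variants$pos[jj]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions not strictly increasing on ", chr)
    }
    for (s in seq_len(nrow(geno))) {
      segs <- detect_roh_chrom(geno[s, jj], pos, params)
      if (!is.null(segs)) {
        segs$sample_id <- ids[s]
        segs$chrom <- chr
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start_pos = numeric(), end_pos = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = factor(character(),
                                            levels = roh_class_levels()),
                      g_estimate = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "chrom", "start_pos", "end_pos", "n_snps",
                 "length_bp")]
  res$length_class <- bin_length_classes(res$length_bp)
  res$g_estimate <- generations_to_ancestor(res$length_bp / 1e6)
  rownames(res) <- NULL
  res
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH is the summed ROH length divided by the SNP-covered map extent
#' (per chromosome, last minus first SNP position, summed over
#' chromosomes). A genome-length override may be supplied instead.
#'
#' @param segments data.frame from [detect_roh()] (possibly several
#'   samples).
#' @param variants variant table defining the map.
#' @param sample_ids samples to report; defaults to those present in
#'   `segments`.
#' @param genome_length optional denominator in bp overriding the map
#'   extent.
#' @return named numeric vector of F_ROH per sample.
#' @export
f_roh <- function(segments, variants, sample_ids = NULL,
                  genome_length = NULL) {
  if (is.null(genome_length)) {
    if (nrow(variants) == 0L) stop("empty variant map")
    ext <- tapply(variants$pos, variants$chrom, function(p) max(p) - min(p))
    genome_length <- sum(ext)
  }
  if (genome_length <= 0) stop("map extent is zero; cannot compute F_ROH")
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  v <- vapply(sample_ids, function(s) {
    sum(segments$length_bp[segments$sample_id == s]) / genome_length
  }, numeric(1))
  setNames(v, sample_ids)
}

roh_class_levels <- function() {
  c("0-6", "6-12", "12-24", "24-48", ">48")
}

#' Bin ROH lengths into the five tract-length classes
#'
#' Half-open classes in Mb: \[0, 6), \[6, 12), \[12, 24), \[24, 48) and
#' \[48, Inf).
#'
#' @param length_bp segment lengths in bp.
#' @return factor with levels "0-6", "6-12", "12-24", "24-48", ">48".
#' @export
bin_length_classes <- function(length_bp) {
  stopifnot(all(length_bp > 0))
  cut(length_bp / 1e6, breaks = c(0, 6, 12, 24, 48, Inf),
      labels = roh_class_levels(), right = FALSE, include.lowest = TRUE)
}

#' Recombination model for dating autozygous tracts
#'
#' @param r recombination rate in cM/Mb (default 1.04, a deer genome-wide
#'   average).
#' @return object of class `generation_model`.
#' @export
generation_model <- function(r = 1.04) {
  if (!is.numeric(r) || r <= 0) stop("recombination rate must be positive")
  structure(list(r = r), class = "generation_model")
}

#' Generations to the most recent common ancestor of an ROH
#'
#' g = 100 / (2 r L) with L the tract length in Mb and r the recombination
#' rate in cM/Mb: longer tracts imply more recent shared ancestry.
#'
#' @param length_mb tract length(s) in Mb; must be positive.
#' @param model a [generation_model()] object.
#' @return estimated generations (strictly decreasing in length).
#' @export
generations_to_ancestor <- function(length_mb, model = generation_model()) {
  if (any(is.na(length_mb) | length_mb <= 0)) {
    stop("tract length must be positive")
  }
  100 / (2 * model$r * length_mb)
}

#' ROH class counts per subpopulation
#'
#' @param segments data.frame from [detect_roh()].
#' @param metadata sample table with sample_id and subpopulation.
#' @return data.frame of counts, one row per (subpopulation, length_class).
#' @export
roh_class_counts <- function(segments, metadata) {
  sub <- metadata$subpopulation[match(segments$sample_id,
                                      metadata$sample_id)]
  tab <- table(subpopulation = sub,
               length_class = segments$length_class)
  as.data.frame(tab, stringsAsFactors = FALSE)
}
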