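#' Pipeline run configuration
#'
#' Bundles and validates the stage parameters for [run_pipeline()]. The
#' resolved configuration is echoed to the output directory as
#' `config.yaml` so a run is fully reproducible from its artifacts.
#'
#' @param vcf path to the input VCF.
#' @param metadata path to the sample metadata TSV.
#' @param out_dir output directory.
#' @param filter a [filter_params()] object.
#' @param prune a [prune_params()] object.
#' @param roh a [roh_params()] object.
#' @param thresholds a [relationship_thresholds()] object.
#' @param K number of ancestry clusters, or an integer vector to sweep by
#'   cross-validation.
#' @param folds CV folds used when `K` is a range.
#' @param admix_restarts,admix_max_iter,admix_tol EM control for the
#'   admixture stage (see [admixture_fit()]).
#' @param purity_tol,admix_flag purity-classification parameters (see
#'   [classify_purity()]).
#' @param tier_cutoff breeder-tier cutoff (see [recommend_breeders()]).
#' @param seed master seed for every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(vcf, metadata, out_dir,
                       filter = filter_params(), prune = prune_params(),
                       roh = roh_params(),
                       thresholds = relationship_thresholds(),
                       K = 2L, folds = 3L, admix_restarts = 3L,
                       admix_max_iter = 500L, admix_tol = 1e-5,
                       purity_tol = 0.001,
                       admix_flag = 0.40, tier_cutoff = 10L, seed = 1L) {
  stopifnot(inherits(filter, "filter_params"),
            inherits(prune, "prune_params"),
            inherits(roh, "roh_params"),
            inherits(thresholds, "relationship_thresholds"))
  if (any(K < 1L)) stop("K values must be >= 1")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(vcf = vcf, metadata = metadata, out_dir = out_dir,
                 filter = filter, prune = prune, roh = roh,
                 thresholds = thresholds, K = as.integer(K),
                 folds = as.integer(folds),
                 admix_restarts = as.integer(admix_restarts),
                 admix_max_iter = as.integer(admix_max_iter),
                 admix_tol = admix_tol, purity_tol = purity_tol,
                 admix_flag = admix_flag, tier_cutoff = as.integer(tier_cutoff),
                 seed = as.integer(seed)),
            class = "run_config")
}

manifest_add <- function(manifest, path) {
  n_rows <- length(readLines(path, warn = FALSE))
  rbind(manifest, data.frame(file = basename(path), rows = n_rows,
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: read input, QC (sample then variant filters), LD
#' pruning, diversity, pairwise IBD relatedness and MDS, ROH with F_ROH,
#' admixture with purity calls, and breeder recommendation. Every artifact
#' is a TSV in `out_dir` and is recorded in `manifest.tsv` (file, rows,
#' md5). Rerunning with an identical configuration reproduces identical
#' files.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), rows = integer(),
                         md5 = character(), stringsAsFactors = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  cfg_lines <- list(
    vcf = config$vcf, metadata = config$metadata,
    filter = unclass(config$filter), prune = unclass(config$prune),
    roh = unclass(config$roh), thresholds = unclass(config$thresholds),
    K = config$K, folds = config$folds, purity_tol = config$purity_tol,
    admix_flag = config$admix_flag, tier_cutoff = config$tier_cutoff,
    seed = config$seed)
  yaml::write_yaml(cfg_lines, out("config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## input
  dat <- stage("input", {
    d <- read_vcf(config$vcf)
    md <- read_metadata(config$metadata)
    d$samples <- match_metadata(d$samples, md)
    d
  })

  ## qc
  qc <- stage("qc", apply_filters(dat$geno, dat$variants, config$filter))
  write_report_tsv(qc$report$variants, out("variants.qc.tsv"))
  write_report_tsv(qc$report$samples, out("samples.qc.tsv"))
  meta <- dat$samples[match(rownames(qc$geno), dat$samples$sample_id), ,
                      drop = FALSE]

  ## prune
  kept <- stage("prune", ld_prune(qc$geno, qc$variants, config$prune))
  geno_p <- qc$geno[, kept, drop = FALSE]
  var_p <- qc$variants[kept, , drop = FALSE]
  writeLines(var_p$vid, out("pruned.keep.txt"))
  write_vcf(out("pruned.vcf"), var_p, meta, geno_p)

  ## diversity
  div <- stage("diversity", diversity_table(geno_p))
  write_report_tsv(div, out("diversity.tsv"))
  ds <- stage("diversity", {
    hs <- subpop_summary(div$het_rate, meta, "het_rate")
    fs <- subpop_summary(div$f_hat, meta, "f_hat")
    list(summary = rbind(hs$summary, fs$summary),
         tests = rbind(cbind(statistic = "het_rate", hs$tests),
                       cbind(statistic = "f_hat", fs$tests)))
  })
  write_report_tsv(ds$summary, out("diversity_summary.tsv"))
  if (!is.null(ds$tests)) {
    write_report_tsv(ds$tests, out("diversity_tests.tsv"))
  }

  ## relatedness + MDS
  pairs <- stage("relatedness",
                 snp_relatedness(geno_p, thresholds = config$thresholds))
  write_report_tsv(pairs, out("ibd_pairs.tsv"))
  mds <- stage("mds", mds_embed(ibs_distance(geno_p), 2L))
  write_report_tsv(data.frame(sample_id = rownames(mds), mds,
                              stringsAsFactors = FALSE, row.names = NULL),
                   out("mds.tsv"))
  hm <- pihat_heatmap_matrix(pairs, meta)
  write_report_tsv(data.frame(male = rownames(hm), hm, check.names = FALSE,
                              stringsAsFactors = FALSE, row.names = NULL),
                   out("pihat_heatmap.tsv"))

  ## ROH on the post-QC (un-pruned) set: run detection wants dense maps
  segs <- stage("roh", detect_roh(qc$geno, qc$variants, config$roh))
  write_report_tsv(segs, out("roh_segments.tsv"))
  fr <- f_roh(segs, qc$variants, sample_ids = rownames(qc$geno))
  write_report_tsv(data.frame(sample_id = names(fr), f_roh = fr,
                              stringsAsFactors = FALSE, row.names = NULL),
                   out("froh.tsv"))
  write_report_tsv(roh_class_counts(segs, meta), out("class_counts.tsv"))

  ## admixture
  adm <- stage("admixture", {
    kk <- config$K
    if (length(kk) > 1L) {
      sweep <- admixture_cv_sweep(qc$geno[, kept, drop = FALSE], kk,
                                  folds = config$folds, seed = config$seed)
      write_report_tsv(sweep, out("cv_errors.tsv"))
      kk <- attr(sweep, "best_K")
    }
    admixture_fit(geno_p, kk, seed = config$seed,
                  tol = config$admix_tol, max_iter = config$admix_max_iter,
                  n_restarts = config$admix_restarts)
  })
  write.table(format(adm$Q, digits = 6), out("ancestry.Q"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(format(t(adm$F), digits = 6), out("ancestry.P"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  purity <- classify_purity(adm$Q, config$purity_tol, config$admix_flag)
  mapping <- align_clusters(adm, meta$subpopulation)
  purity$dominant_label <- unname(mapping[purity$dominant_cluster])
  write_report_tsv(purity, out("purity.tsv"))

  ## breeder selection (male- and female-centric)
  breeders <- stage("selection", {
    male_pool <- build_mate_pool(meta, purity, "male", "female")
    female_pool <- build_mate_pool(meta, purity, "female", "male")
    rbind(cbind(candidate_sex = "male",
                recommend_breeders(pairs, male_pool, config$tier_cutoff)),
          cbind(candidate_sex = "female",
                recommend_breeders(pairs, female_pool, config$tier_cutoff)))
  })
  write_report_tsv(breeders, out("breeders.tsv"))

  for (f in c("config.yaml", "variants.qc.tsv", "samples.qc.tsv",
              "pruned.keep.txt", "pruned.vcf", "diversity.tsv",
              "diversity_summary.tsv", "ibd_pairs.tsv", "mds.tsv",
              "pihat_heatmap.tsv", "roh_segments.tsv", "froh.tsv",
              "class_counts.tsv", "ancestry.Q", "ancestry.P", "purity.tsv",
              "breeders.tsv")) {
    if (file.exists(out(f))) manifest <- manifest_add(manifest, out(f))
  }
  write_report_tsv(manifest, out("manifest.tsv"))
  invisible(list(qc = qc, kept = kept, diversity = div, pairs = pairs,
                 mds = mds, roh = segs, f_roh = fr, admixture = adm,
                 purity = purity, breeders = breeders, manifest = manifest))
}
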