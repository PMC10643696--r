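#' @importFrom stats cor dbinom rbeta rbinom rnorm rpois runif setNames t.test
#'   wilcox.test p.adjust sd var qbinom
#' @importFrom utils read.delim write.table head
NULL

MISSING_GT <- NA_integer_

#' Natural order of chromosome labels
#'
#' Orders labels so that numeric suffixes sort numerically (chr2 before
#' chr10); purely lexical labels sort alphabetically after numeric ones.
#'
#' @param chrom character vector of chromosome labels.
#' @return integer ranks usable with `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^(chr|Chr|CHR)", "", u)))
  match(chrom, u[order(is.na(num), num, u)])
}

#' Read genotypes from a multi-sample VCF
#'
#' Parses a VCF 4.x file, keeps only biallelic SNP records, and encodes
#' genotypes as alternate-allele counts. Missing calls (`./.` or `.`) and
#' half-calls (`0/.`) become `NA`. Phased and unphased genotypes are treated
#' identically. Records are returned sorted by (chromosome, position) using a
#' natural chromosome order.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param region_filter optional character vector of chromosome labels to
#'   retain.
#' @return a list with elements
#'   \item{variants}{data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'     `vid` (one row per retained biallelic SNP)}
#'   \item{samples}{data.frame stub with column `sample_id`}
#'   \item{geno}{integer matrix, samples x variants, values 0/1/2/`NA`}
#'   \item{n_skipped}{number of records dropped as non-biallelic or non-SNP}
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) {
    stop("cannot read VCF file: ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_field <- v@gt
  if (is.null(gt_field) || ncol(gt_field) < 2L) {
    stop("VCF contains no sample genotype columns: ", path)
  }
  sample_ids <- colnames(gt_field)[-1L]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!is.null(region_filter)) {
    keep <- keep & fix[, "CHROM"] %in% region_filter
  }
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)

  fix <- fix[keep, , drop = FALSE]
  gt_field <- gt_field[keep, , drop = FALSE]

  fmt <- gt_field[, 1L]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) {
    i <- match("GT", f)
    if (is.na(i)) stop("VCF record without GT in FORMAT")
    i
  }, integer(1))

  geno <- matrix(NA_integer_, nrow = length(sample_ids), ncol = nrow(fix),
                 dimnames = list(sample_ids, NULL))
  for (j in seq_len(nrow(fix))) {
    cells <- gt_field[j, -1L]
    gt <- vapply(strsplit(cells, ":", fixed = TRUE), function(x) {
      if (gt_idx[j] > length(x)) "." else x[gt_idx[j]]
    }, character(1))
    geno[, j] <- encode_gt(gt)
  }

  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    vid = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                 paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- variants$vid

  list(
    variants = variants,
    samples = data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
    geno = geno,
    n_skipped = n_skipped
  )
}

# "0/1", "1|0", "./.", ".", "0/." -> alt-allele count or NA
encode_gt <- function(gt) {
  gt[is.na(gt)] <- "."
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    if (length(x) == 0L) return(NA_integer_)
    if (any(x == "." | x == "")) return(NA_integer_)
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) return(NA_integer_)
    as.integer(sum(v > 0L))
  }, integer(1))
}

#' Read the sample metadata table
#'
#' Tab-separated file with header columns `sample_id`, `sex`,
#' `subpopulation` and optionally `organization`. Sex values are normalized
#' case-insensitively: m/male -> male, f/female -> female, anything else ->
#' unknown (with a warning listing the affected samples).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample_id, sex, subpopulation,
#'   organization.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "sex", "subpopulation")
  miss <- setdiff(required, names(md))
  if (length(miss)) {
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in metadata: ", paste(unique(dup), collapse = ", "))
  }
  if (!"organization" %in% names(md)) md$organization <- NA_character_
  md$sex <- normalize_sex(md$sex)
  unk <- md$sample_id[md$sex == "unknown"]
  if (length(unk)) {
    warning("sample(s) with unknown sex: ", paste(unk, collapse = ", "))
  }
  md[, c("sample_id", "sex", "subpopulation", "organization")]
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

#' Check that every VCF sample has metadata
#'
#' @param samples sample table (or stub) from [read_vcf()].
#' @param metadata sample table from [read_metadata()].
#' @return the metadata rows reordered to match `samples$sample_id`.
#' @export
match_metadata <- function(samples, metadata) {
  i <- match(samples$sample_id, metadata$sample_id)
  if (anyNA(i)) {
    stop("sample(s) in VCF absent from metadata: ",
         paste(samples$sample_id[is.na(i)], collapse = ", "))
  }
  out <- metadata[i, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write genotypes as a VCF 4.2 file
#'
#' Records are written sorted by (chromosome, position); genotypes are
#' unphased and missing values are written as `./.`.
#'
#' @param path output path.
#' @param variants variant table as returned by [read_vcf()].
#' @param samples sample table (only `sample_id` is used).
#' @param geno integer genotype matrix, samples x variants.
#' @return invisibly, the path written.
#' @export
write_vcf <- function(path, variants, samples, geno) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(variants))
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]

  gt_str <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt_str[!is.na(geno) & geno == 0L] <- "0/0"
  gt_str[!is.na(geno) & geno == 1L] <- "0/1"
  gt_str[!is.na(geno) & geno == 2L] <- "1/1"

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=breedsel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  ), con)
  body <- paste(
    variants$chrom, variants$pos, variants$vid, variants$ref, variants$alt,
    ".", "PASS", ".", "GT",
    apply(gt_str, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}

#' Write a TSV report with '#'-prefixed comment lines
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comments optional character vector written as `# `-prefixed lines.
#' @return invisibly, the path.
#' @export
write_report_tsv <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
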