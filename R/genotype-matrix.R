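#' Construct a genotype matrix object
#'
#' A `genotype_matrix` couples a samples-by-SNPs dosage matrix (values in
#' `[0, 2]`, `NA` allowed) with per-SNP metadata. Allele B is the counted
#' (effect) allele throughout: a dosage of 2 means two copies of allele B.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries in
#'   `[0, 2]` or `NA`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_info data.frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `allele_A`, `allele_B`, and optionally `impute_quality`.
#' @return An object of class `genotype_matrix` with components `dosage`,
#'   `sample_ids` and `snp` (metadata including the folded minor allele
#'   frequency `maf`, `NA` for all-missing SNPs).
#' @export
genotype_matrix <- function(dosage, sample_ids, snp_info) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(sample_ids))
    stop("dosage rows (", nrow(dosage), ") != length(sample_ids) (",
         length(sample_ids), ")")
  if (ncol(dosage) != nrow(snp_info))
    stop("dosage columns (", ncol(dosage), ") != nrow(snp_info) (",
         nrow(snp_info), ")")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(snp_info$snp_id)) stop("duplicate SNP ids")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- snp_info$snp_id
  snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
  snp_info$maf <- folded_maf(dosage)
  structure(
    list(dosage = dosage, sample_ids = as.character(sample_ids),
         snp = snp_info),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$snp), "SNPs\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  cat("  MAF range:", paste(signif(range(x$snp$maf, na.rm = TRUE), 3),
                            collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Folded minor allele frequency per SNP column; NA where all dosages missing.
folded_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

# Allele frequency of the counted (B) allele, unfolded.
allele_freq <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  p
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  vi <- if (is.null(snps)) seq_len(nrow(x$snp)) else {
    if (is.character(snps)) match(snps, x$snp$snp_id) else snps
  }
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown SNP id in subset")
  info <- x$snp[vi, setdiff(names(x$snp), "maf"), drop = FALSE]
  genotype_matrix(x$dosage[si, vi, drop = FALSE], x$sample_ids[si], info)
}
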