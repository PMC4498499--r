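#' Read a SNP annotation file
#'
#' YAML schema: a top-level `snps` list; each entry has `snp_id`,
#' `effect_allele`, `hypothesized_direction` (one of `risk_increasing`,
#' `risk_decreasing`, `unknown`), `flip` (whether the published reference
#' allele must be flipped so the counted allele is risk-increasing),
#' `in_score` (member of the 8-SNP multi-SNP score), `role`
#' (`exposure`/`outcome`), optional `chrom`, `pos`, `freq`, `trait` (for
#' outcome SNPs) and `published_beta` (named per-trait betas; may be null).
#'
#' A direction of `unknown` marks SNPs whose published biomarker effects do
#' not map consistently onto an atherosclerosis-risk hypothesis; these are
#' excluded from the multi-SNP score and never scored for direction
#' consistency.
#'
#' @param path YAML file.
#' @return data.frame of class `snp_annotation`; `published_beta` entries
#'   become `beta_<trait>` columns.
#' @export
read_snp_annotation <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$snps)) stop("annotation file has no 'snps' list")
  rows <- lapply(x$snps, function(s) {
    d <- data.frame(
      snp_id = s$snp_id,
      effect_allele = if (is.null(s$effect_allele)) NA_character_
                      else s$effect_allele,
      chrom = if (is.null(s$chrom)) NA_integer_ else s$chrom,
      pos = if (is.null(s$pos)) NA_real_ else s$pos,
      freq = if (is.null(s$freq)) NA_real_ else s$freq,
      hypothesized_direction = s$hypothesized_direction,
      flip = isTRUE(s$flip),
      in_score = isTRUE(s$in_score),
      role = if (is.null(s$role)) "exposure" else s$role,
      trait = if (is.null(s$trait)) NA_character_ else s$trait,
      stringsAsFactors = FALSE
    )
    if (!is.null(s$published_beta)) {
      for (nm in names(s$published_beta)) {
        v <- s$published_beta[[nm]]
        d[[paste0("beta_", nm)]] <- if (is.null(v)) NA_real_ else v
      }
    }
    d
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA
    d[all_cols]
  })
  ann <- do.call(rbind, rows)
  validate_snp_annotation(ann)
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

validate_snp_annotation <- function(ann) {
  ok_dir <- c("risk_increasing", "risk_decreasing", "unknown")
  if (!all(ann$hypothesized_direction %in% ok_dir))
    stop("hypothesized_direction must be one of: ",
         paste(ok_dir, collapse = ", "))
  if (anyDuplicated(ann$snp_id)) stop("duplicate snp_id in annotation")
  bad <- ann$in_score & ann$hypothesized_direction == "unknown"
  if (any(bad))
    stop("unknown-direction SNP(s) marked in_score: ",
         paste(ann$snp_id[bad], collapse = ", "))
  invisible(ann)
}

#' Built-in annotation of the 12 iron-status SNPs
#'
#' The 12 variants from the iron-status GWAS meta-analysis used as Mendelian
#' randomization instruments, with the tested allele, its frequency,
#' genomic position (build 37) and the hypothesized atherosclerosis-risk
#' direction of the tested allele. Five SNPs carry `flip = TRUE`: their
#' published reference allele lowers risk, so orientation to the
#' risk-increasing allele requires `2 - dosage`. The eight SNPs with a known
#' direction form the multi-SNP score; the four `unknown` SNPs (effects
#' confined to transferrin, or discordant across biomarkers) are excluded.
#'
#' @return A `snp_annotation` data.frame with 12 rows.
#' @export
iron_snp_annotation <- function() {
  read_snp_annotation(
    system.file("extdata", "iron_snps.yaml", package = "irongc",
                mustWork = TRUE))
}

#' Built-in annotation of the 6 atherosclerosis-outcome SNPs
#'
#' Genome-wide significant loci for carotid intima-media thickness, plaque
#' presence and ankle-brachial index from their respective GWAS
#' meta-analyses, used for cross-trait association with the iron biomarkers.
#'
#' @return A `snp_annotation` data.frame with 6 rows (`role = "outcome"`).
#' @export
nima_snp_annotation <- function() {
  read_snp_annotation(
    system.file("extdata", "nima_snps.yaml", package = "irongc",
                mustWork = TRUE))
}

#' Orient dosages to the hypothesized risk-increasing allele
#'
#' Applies [flip_effect_allele()] to the columns whose annotation carries
#' `flip = TRUE`; other columns pass through unchanged.
#'
#' @param dosage samples-by-SNPs matrix with columns named by `snp_id`.
#' @param annotation a `snp_annotation` covering the columns.
#' @return The oriented dosage matrix.
#' @export
orient_dosages <- function(dosage, annotation) {
  idx <- match(colnames(dosage), annotation$snp_id)
  if (anyNA(idx)) stop("dosage columns missing from annotation: ",
                       paste(colnames(dosage)[is.na(idx)], collapse = ", "))
  fl <- annotation$flip[idx]
  dosage[, fl] <- flip_effect_allele(dosage[, fl, drop = FALSE])
  dosage
}
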