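#' Read PLINK bed/bim/fam genotypes
#'
#' Reads SNP-major PLINK 1 binary genotypes. The bim A1 allele is taken as
#' allele B (the counted/effect allele), so a dosage of 2 means two copies of
#' A1; missing calls become `NA`. SNPs with all calls missing get `maf = NA`
#' and are flagged in the `all_missing` metadata column.
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist. Explicit
#'   paths can be given instead via `bed`, `bim`, `fam`.
#' @param bed,bim,fam optional explicit file paths.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)

  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  names(fam_df)[1:2] <- c("fid", "iid")
  names(bim_df) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  if (anyDuplicated(fam_df$iid)) stop("duplicate sample IDs in fam")
  if (anyDuplicated(bim_df$snp_id)) stop("duplicate SNP IDs in bim")
  n <- nrow(fam_df)
  m <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed bed magic bytes")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) != 3 + bps * m)
    stop("bed size inconsistent with fam/bim dimensions")

  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit fields: sample s of SNP j sits in bits (2s, 2s+1)
  codes <- matrix(NA_integer_, 4 * bps, m)
  block <- matrix(body, bps, m)
  for (k in 0:3) {
    codes[seq.int(k + 1, 4 * bps, by = 4), ] <- block %% 4
    block <- block %/% 4
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  dosage <- matrix(NA_real_, n, m)
  dosage[codes == 0L] <- 2
  dosage[codes == 2L] <- 1
  dosage[codes == 3L] <- 0

  info <- data.frame(snp_id = bim_df$snp_id, chrom = bim_df$chrom,
                     pos = bim_df$pos, allele_A = bim_df$a2,
                     allele_B = bim_df$a1, stringsAsFactors = FALSE)
  info$all_missing <- colSums(!is.na(dosage)) == 0
  genotype_matrix(dosage, fam_df$iid, info)
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' Dosages must be hard calls (`{0, 1, 2}` or `NA`). Allele B is written as
#' the bim A1 allele, matching [read_plink()], so a write/read round trip is
#' exact. Soft dosages are rejected rather than silently rounded.
#'
#' @param genotypes a `genotype_matrix`.
#' @param prefix output path prefix.
#' @param sex optional per-sample factor/character (`male`/`female`) for the
#'   fam sex column.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, sex = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (!all(d[!is.na(d)] %in% 0:2))
    stop("write_plink requires hard-called dosages in {0, 1, 2}")
  n <- nrow(d)
  m <- ncol(d)

  fam <- data.frame(fid = genotypes$sample_ids, iid = genotypes$sample_ids,
                    pat = 0, mat = 0,
                    sex = if (is.null(sex)) 0
                          else ifelse(as.character(sex) == "male", 1, 2),
                    pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = genotypes$snp$chrom, snp_id = genotypes$snp$snp_id,
                    cm = 0, pos = genotypes$snp$pos,
                    a1 = genotypes$snp$allele_B, a2 = genotypes$snp$allele_A)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  code <- matrix(1L, n, m)          # 01 = missing
  code[!is.na(d) & d == 2] <- 0L    # 00 = two copies of A1 (allele B)
  code[!is.na(d) & d == 1] <- 2L    # 10 = het
  code[!is.na(d) & d == 0] <- 3L    # 11 = zero copies of A1
  bps <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bps - n, m)
  full <- rbind(code, pad)
  w <- c(1L, 4L, 16L, 64L)
  bytes <- full[seq.int(1, 4 * bps, 4), , drop = FALSE] * w[1] +
           full[seq.int(2, 4 * bps, 4), , drop = FALSE] * w[2] +
           full[seq.int(3, 4 * bps, 4), , drop = FALSE] * w[3] +
           full[seq.int(4, 4 * bps, 4), , drop = FALSE] * w[4]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}
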