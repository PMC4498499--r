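# shared fixture builders -- everything is generated in code

# two-trait cohort with given heritability and genetic correlation,
# no covariate effects (so raw scaled traits are analysis-ready)
biv_config <- function(n, m, h2 = 0.5, rg = 0.5, seed = 1L, ...) {
  simulation_config(
    n_samples = n, n_snps = m,
    genetic_cov = matrix(c(h2, rg * h2, rg * h2, h2), 2),
    residual_cov = diag(1 - h2, 2),
    covariate_effects = list(age = 0, sex = 0, time = c(0, 0)),
    seed = seed, ...)
}

# genotype_matrix straight from a dosage matrix
toy_genotypes <- function(dosage, chrom = 1L) {
  m <- ncol(dosage)
  genotype_matrix(dosage, sprintf("S%03d", seq_len(nrow(dosage))),
                  data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                             chrom = chrom, pos = seq_len(m) * 100L,
                             allele_A = "A", allele_B = "B"))
}

# brute-force GRM: double loop over sample pairs (independent oracle)
grm_oracle <- function(dosage) {
  n <- nrow(dosage)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    terms <- (dosage[j, ] - 2 * p) * (dosage[k, ] - 2 * p) /
      (2 * p * (1 - p))
    A[j, k] <- mean(terms)
  }
  A
}

# NBS-like cohort whose 18 SNP columns carry the annotated rs ids
# (12 exposure + 6 outcome SNPs); optional true effect of rs1800562 on IMT
mr_fixture <- function(n, seed, beta_imt = 0) {
  ann <- rbind(iron_snp_annotation(), nima_snp_annotation())
  cfg <- nbs_like_config(
    n_samples = n, n_snps = 18, seed = seed,
    maf_range = c(0.2, 0.5),
    fixed_effects = if (beta_imt != 0)
      data.frame(snp = "rs1800562", trait = "IMT", beta = beta_imt))
  g <- simulate_genotypes(cfg)
  info <- g$snp[setdiff(names(g$snp), "maf")]
  info$snp_id <- ann$snp_id
  g <- genotype_matrix(g$dosage, g$sample_ids, info)
  ph <- simulate_phenotypes(g, cfg)
  list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth,
       annotation = ann)
}

# exhaustive all-pairs LD pruning oracle for small SNP sets: repeatedly
# remove the later member of the strongest violating pair
prune_oracle <- function(dosage, r2_max) {
  keep <- seq_len(ncol(dosage))
  repeat {
    r2 <- suppressWarnings(stats::cor(dosage[, keep, drop = FALSE])^2)
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    viol <- which(r2 > r2_max, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    drop <- min(viol[, 2])  # earliest later-member, deterministic
    keep <- keep[-drop]
  }
  keep
}
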