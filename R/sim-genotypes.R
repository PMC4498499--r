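#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per-SNP allele frequencies are drawn uniformly from `config$maf_range`;
#' unrelated individuals receive `Binomial(2, p)` allele-B counts. If
#' `config$n_sib_pairs > 0`, the first `2 * n_sib_pairs` samples are full-sib
#' pairs built from explicit parental gametes: each pair shares two parents
#' whose four alleles are drawn once, and each sib inherits one random gamete
#' from each parent. This yields the correct expected genome-wide relationship
#' (0.5) for sibs without any correlation shortcut.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_matrix()] with dosages in `{0, 1, 2}`. SNP ids are
#'   `snp0001 ...`, samples `S0001 ...` (sibs first, as consecutive pairs).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  geno <- matrix(0L, n, m)
  n_sib <- 2L * config$n_sib_pairs
  if (n_sib > 0) {
    for (k in seq_len(config$n_sib_pairs)) {
      # parental allele pairs: rows = the two alleles, columns = SNPs
      mom <- matrix(stats::rbinom(2 * m, 1, rep(p, each = 2)), 2, m)
      dad <- matrix(stats::rbinom(2 * m, 1, rep(p, each = 2)), 2, m)
      for (child in 1:2) {
        gm <- mom[cbind(sample(1:2, m, replace = TRUE), seq_len(m))]
        gd <- dad[cbind(sample(1:2, m, replace = TRUE), seq_len(m))]
        geno[2L * (k - 1L) + child, ] <- gm + gd
      }
    }
  }
  n_unrel <- n - n_sib
  if (n_unrel > 0) {
    geno[(n_sib + 1L):n, ] <- matrix(
      stats::rbinom(n_unrel * m, 2, rep(p, each = n_unrel)), n_unrel, m)
  }

  ids <- sprintf("S%04d", seq_len(n))
  info <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = rep(1L, m),
    pos = seq_len(m) * 1000L,
    allele_A = "A", allele_B = "B",
    true_freq = p,
    stringsAsFactors = FALSE
  )
  genotype_matrix(geno, ids, info)
}

#' Expand hard genotypes into genotype-probability triples
#'
#' Each sample/SNP genotype call becomes a probability triple
#' `(P_AA, P_AB, P_BB)` with mass `certainty` on the true genotype and the
#' remainder split evenly over the other two classes, emulating imputed
#' genotype probabilities of a given quality.
#'
#' @param genotypes a `genotype_matrix` with hard calls in `{0, 1, 2}`.
#' @param certainty probability mass on the true genotype, in (1/3, 1].
#' @return A data.frame with columns `sample_id`, `snp_id`, `P_AA`, `P_AB`,
#'   `P_BB` (one row per sample/SNP); rows sum to 1 exactly.
#' @export
simulate_genotype_probabilities <- function(genotypes, certainty = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (certainty <= 1 / 3 || certainty > 1)
    stop("certainty must be in (1/3, 1]")
  d <- genotypes$dosage
  if (anyNA(d) || !all(d %in% 0:2))
    stop("genotypes must be hard calls in {0, 1, 2}")
  g <- as.integer(t(d))  # row-major: sample blocks of SNPs
  off <- (1 - certainty) / 2
  prob <- matrix(off, length(g), 3)
  prob[cbind(seq_along(g), g + 1L)] <- certainty
  data.frame(
    sample_id = rep(genotypes$sample_ids, each = ncol(d)),
    snp_id = rep(genotypes$snp$snp_id, times = nrow(d)),
    P_AA = prob[, 1], P_AB = prob[, 2], P_BB = prob[, 3],
    stringsAsFactors = FALSE
  )
}
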