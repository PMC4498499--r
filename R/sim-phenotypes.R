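#' Simulate multi-trait phenotypes with known genetic architecture
#'
#' Genetic values are built from causal-SNP effect vectors drawn jointly
#' across traits from a multivariate normal with covariance
#' `genetic_cov / n_causal` on the standardized-genotype scale
#' (`(x - 2p) / sqrt(2p(1-p))`, realized allele frequencies), so that the
#' trait-pair genetic covariances match `genetic_cov` in expectation
#' regardless of the MAF spectrum. Residuals are multivariate normal with
#' `residual_cov`. Fixed allelic effects are added on the effect-allele dosage
#' scale; covariate effects (age, sex, time of blood sampling) are added with
#' the configured coefficients. Binary traits are produced by thresholding the
#' standardized trait liability at the (1 - prevalence) quantile; outcome
#' traits are masked to `NA` outside a random subset.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param config the same [simulation_config()].
#' @return A list with `phenotypes` (data.frame: `sample_id`, `sex`, `age`,
#'   `age_squared`, `time_of_sampling`, one column per trait, and lipids `TC`,
#'   `LDL`, `HDL`, `TGC`) and `truth` (class `sim_truth`: true covariance
#'   matrices, true rG, causal SNP ids, per-SNP effect vectors, realized
#'   genetic values, liability thresholds, outcome-subset ids).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  n <- length(genotypes$sample_ids)
  m <- nrow(genotypes$snp)
  if (n != config$n_samples || m != config$n_snps)
    stop("genotypes do not match config dimensions")
  k <- config$n_traits
  # separate stream from the genotype draw, still fully determined by seed
  set.seed(config$seed + 1L)

  n_causal <- max(1L, as.integer(round(config$causal_fraction * m)))
  causal <- sort(sample.int(m, n_causal))
  X <- genotypes$dosage[, causal, drop = FALSE]
  p <- colMeans(X) / 2
  sd2p <- sqrt(2 * p * (1 - p))
  ok <- sd2p > 0
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, ifelse(ok, sd2p, 1), "/")
  W[, !ok] <- 0

  cg <- chol_psd(config$genetic_cov)
  B <- matrix(stats::rnorm(n_causal * k), n_causal, k) %*% cg / sqrt(n_causal)
  G <- W %*% B
  E <- matrix(stats::rnorm(n * k), n, k) %*% chol_psd(config$residual_cov)

  age <- stats::runif(n, 42, 76)
  sex <- factor(ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male"),
                levels = c("male", "female"))
  tos <- factor(sample(c("morning", "afternoon", "evening"), n,
                       replace = TRUE, prob = c(0.21, 0.64, 0.15)),
                levels = c("morning", "afternoon", "evening"))

  ce <- config$covariate_effects
  age_b <- rep_len(if (is.null(ce$age)) 0 else ce$age, k)
  sex_b <- rep_len(if (is.null(ce$sex)) 0 else ce$sex, k)
  time_b <- ce$time
  if (is.null(time_b)) time_b <- c(0, 0)
  Y <- G + E
  Y <- Y + outer(age - mean(age), age_b)
  Y <- Y + outer(as.numeric(sex == "female"), sex_b)
  Y <- Y + outer(as.numeric(tos == "afternoon"), rep_len(time_b[1], k))
  Y <- Y + outer(as.numeric(tos == "evening"), rep_len(time_b[2], k))
  colnames(Y) <- config$trait_names

  if (!is.null(config$fixed_effects)) {
    fe <- config$fixed_effects
    for (i in seq_len(nrow(fe))) {
      j <- fe$snp[i]
      if (is.character(j)) j <- match(j, genotypes$snp$snp_id)
      t <- match(fe$trait[i], config$trait_names)
      if (is.na(j) || is.na(t)) stop("fixed effect references unknown snp/trait")
      Y[, t] <- Y[, t] + fe$beta[i] * genotypes$dosage[, j]
    }
  }

  thresholds <- stats::setNames(rep(NA_real_, k), config$trait_names)
  if (!is.null(config$binary_traits)) {
    for (i in seq_len(nrow(config$binary_traits))) {
      tr <- config$binary_traits$trait[i]
      prev <- config$binary_traits$prevalence[i]
      z <- as.vector(scale(Y[, tr]))
      thr <- stats::qnorm(1 - prev)
      thresholds[tr] <- thr
      Y[, tr] <- as.numeric(z > thr)
    }
  }

  subset_ids <- genotypes$sample_ids
  if (length(config$outcome_traits) > 0 && config$outcome_subset_fraction < 1) {
    n_sub <- max(1L, as.integer(round(config$outcome_subset_fraction * n)))
    keep <- sort(sample.int(n, n_sub))
    subset_ids <- genotypes$sample_ids[keep]
    Y[-keep, config$outcome_traits] <- NA_real_
  }

  # lipid panel (mmol/L), mildly age/sex dependent, genetically inert
  lipids <- data.frame(
    TC  = 5.5 + 0.010 * (age - 59) - 0.10 * (sex == "female") + stats::rnorm(n, 0, 1.0),
    LDL = 3.5 + 0.008 * (age - 59) - 0.10 * (sex == "female") + stats::rnorm(n, 0, 0.9),
    HDL = 1.3 + 0.002 * (age - 59) + 0.25 * (sex == "female") + stats::rnorm(n, 0, 0.35),
    TGC = 1.6 + 0.005 * (age - 59) - 0.15 * (sex == "female") + stats::rnorm(n, 0, 0.8)
  )

  phen <- data.frame(sample_id = genotypes$sample_ids, sex = sex, age = age,
                     age_squared = age^2, time_of_sampling = tos,
                     Y, lipids, stringsAsFactors = FALSE)
  rownames(phen) <- NULL

  effects <- matrix(0, m, k,
                    dimnames = list(genotypes$snp$snp_id, config$trait_names))
  effects[causal, ] <- B
  truth <- structure(
    list(genetic_cov = config$genetic_cov,
         residual_cov = config$residual_cov,
         rG = true_rg(config),
         causal_snp_ids = genotypes$snp$snp_id[causal],
         effects = effects,
         genetic_values = stats::setNames(as.data.frame(G),
                                          config$trait_names),
         liability_thresholds = thresholds,
         outcome_subset = subset_ids),
    class = "sim_truth"
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_phenotypes()].
#'
#' @param config a [simulation_config()].
#' @return List with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth)
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes data.frame as returned by [simulate_phenotypes()].
#' @param path output file.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#'
#' @param path TSV file with a header; `sex` and `time_of_sampling` are
#'   restored as factors with their canonical level order.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("sex" %in% names(x))
    x$sex <- factor(x$sex, levels = c("male", "female"))
  if ("time_of_sampling" %in% names(x))
    x$time_of_sampling <- factor(x$time_of_sampling,
                                 levels = c("morning", "afternoon", "evening"))
  x
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices.
chol_psd <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}
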