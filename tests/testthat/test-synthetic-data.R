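test_that("config validation rejects bad inputs", {
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(causal_fraction = 0), "causal_fraction")
  expect_error(
    simulation_config(genetic_cov = matrix(c(1, 2, 2, 1), 2),
                      trait_names = c("a", "b")),
    "positive semidefinite")
  expect_error(
    simulation_config(trait_names = c("a", "b"),
                      binary_traits = data.frame(trait = "a",
                                                 prevalence = 1.2)),
    "prevalence")
  expect_error(simulation_config(n_samples = 10, n_sib_pairs = 6),
               "n_sib_pairs")
})

test_that("simulated genotypes respect shape, range and HWE structure", {
  cfg <- simulation_config(n_samples = 4, n_snps = 3,
                           maf_range = c(0.5, 0.5), seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(4L, 3L))
  expect_true(all(g$dosage %in% 0:2))

  # rare-allele mean dosage: E[x] = 2 * MAF, binomial SE bound
  cfg <- simulation_config(n_samples = 400, n_snps = 10000,
                           maf_range = c(0.01, 0.01), seed = 2)
  g <- simulate_genotypes(cfg)
  p <- 0.01
  se <- sqrt(2 * p * (1 - p) / (400 * 10000))
  expect_lt(abs(mean(g$dosage) - 2 * p), 3 * se)

  # HWE p-values approximately uniform under the null (KS test)
  cfg <- simulation_config(n_samples = 500, n_snps = 1000,
                           maf_range = c(0.2, 0.5), seed = 3)
  g <- simulate_genotypes(cfg)
  pv <- apply(g$dosage, 2, hwe_test)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sibling pairs share half their genome on average", {
  cfg <- simulation_config(n_samples = 150, n_snps = 5000, n_sib_pairs = 50,
                           maf_range = c(0.1, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  A <- grm_oracle(g$dosage)  # brute-force oracle, not compute_grm
  sib <- vapply(1:50, function(k) A[2 * k - 1, 2 * k], 0)
  expect_lt(abs(mean(sib) - 0.5), 0.05)
  # unrelated block stays near 0
  unrel <- A[101:150, 101:150]
  expect_lt(abs(mean(unrel[upper.tri(unrel)])), 0.02)
})

test_that("genotype probability triples are consistent", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 2), 2, 2))
  pr <- simulate_genotype_probabilities(g, certainty = 1)
  expect_equal(pr$P_BB[pr$sample_id == "S001" & pr$snp_id == "s002"], 1)
  pr9 <- simulate_genotype_probabilities(g, certainty = 0.9)
  het <- pr9[pr9$sample_id == "S002" & pr9$snp_id == "s001", ]  # genotype 1
  expect_equal(unlist(het[c("P_AA", "P_AB", "P_BB")], use.names = FALSE),
               c(0.05, 0.9, 0.05))
  expect_true(all(abs(pr9$P_AA + pr9$P_AB + pr9$P_BB - 1) < 1e-12))
  expect_error(simulate_genotype_probabilities(g, certainty = 0.2),
               "certainty")
})

test_that("zero genetic covariance gives phenotypes driven by residuals", {
  cfg <- simulation_config(
    n_samples = 1000, n_snps = 300,
    genetic_cov = matrix(0, 2, 2),
    residual_cov = matrix(c(1, 0.6, 0.6, 1), 2),
    covariate_effects = list(age = 0, sex = 0, time = c(0, 0)), seed = 7)
  sim <- simulate_cohort(cfg)
  gv <- as.matrix(sim$truth$genetic_values)
  expect_lt(max(apply(gv, 2, var)), 1e-20)
  r <- cor(sim$phenotypes$trait1, sim$phenotypes$trait2)
  expect_lt(abs(r - 0.6), 3 * (1 - 0.6^2) / sqrt(1000))
})

test_that("realized heritability and genetic correlation match the truth", {
  h2s <- rgs <- numeric(10)
  for (r in 1:10) {
    sim <- simulate_cohort(biv_config(2000, 2000, h2 = 0.5, rg = 0.5,
                                      seed = 100 + r))
    gv <- as.matrix(sim$truth$genetic_values)
    ph <- as.matrix(sim$phenotypes[c("trait1", "trait2")])
    h2s[r] <- var(gv[, 1]) / var(ph[, 1])
    rgs[r] <- cor(gv)[1, 2]
  }
  expect_lt(abs(mean(h2s) - 0.5), 0.1)
  expect_lt(abs(mean(rgs) - 0.5), 0.1)
})

test_that("binary traits hit the target prevalence and outcome masking works", {
  cfg <- nbs_like_config(n_samples = 1819, n_snps = 300, seed = 11)
  sim <- simulate_cohort(cfg)
  ph <- sim$phenotypes
  n_sub <- sum(!is.na(ph$plaque))
  expect_equal(n_sub, 549L)
  prev <- mean(ph$plaque, na.rm = TRUE)
  expect_lt(abs(prev - 0.42), 3 * sqrt(0.42 * 0.58 / n_sub))
  # biomarkers observed on everyone
  expect_true(all(!is.na(ph$hepcidin)))
  # time-of-sampling proportions near 21/64/15
  tos <- prop.table(table(ph$time_of_sampling))
  expect_lt(max(abs(tos - c(0.21, 0.64, 0.15))), 0.05)
  expect_true(all(ph$age >= 42 & ph$age <= 76))
})

test_that("fixed allelic effects enter on the dosage scale", {
  cfg <- simulation_config(
    n_samples = 3000, n_snps = 50, trait_names = "y",
    genetic_cov = matrix(0), residual_cov = matrix(0.01),
    fixed_effects = data.frame(snp = "snp0001", trait = "y", beta = 0.8),
    covariate_effects = list(age = 0, sex = 0, time = c(0, 0)), seed = 13)
  sim <- simulate_cohort(cfg)
  b <- coef(lm(sim$phenotypes$y ~ sim$genotypes$dosage[, 1]))[2]
  expect_lt(abs(b - 0.8), 0.05)
})

test_that("simulation is bit-reproducible and round-trips through writers", {
  cfg <- biv_config(40, 30, seed = 17, n_sib_pairs = 3)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$effects, s2$truth$effects)

  tmp <- withr::local_tempdir()
  cfg_path <- file.path(tmp, "cfg.yaml")
  write_sim_config(cfg, cfg_path)
  cfg2 <- read_sim_config(cfg_path)
  expect_equal(cfg2$genetic_cov, cfg$genetic_cov)
  s3 <- simulate_cohort(cfg2)
  expect_identical(s3$genotypes$dosage, s1$genotypes$dosage)

  ph_path <- file.path(tmp, "pheno.tsv")
  write_phenotypes(s1$phenotypes, ph_path)
  ph2 <- read_phenotypes(ph_path)
  expect_equal(ph2$trait1, s1$phenotypes$trait1, tolerance = 1e-12)
  expect_identical(levels(ph2$time_of_sampling),
                   c("morning", "afternoon", "evening"))
})
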