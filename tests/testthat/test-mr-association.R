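make_oriented <- function(dos_rows) {
  m <- matrix(dos_rows, nrow = length(dos_rows) / 8, ncol = 8, byrow = TRUE)
  rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  colnames(m) <- iron_snp_annotation()$snp_id[iron_snp_annotation()$in_score]
  m
}

test_that("multi-SNP score sums oriented dosages with missingness rules", {
  ann <- iron_snp_annotation()
  sc <- build_multi_snp_score(make_oriented(c(
    rep(1, 8),
    rep(2, 8),
    c(2, 1, 0, 1, 1, 2, 0, 1),
    c(1, NA, rep(1, 6)),
    rep(0, 8), rep(0.5, 8), rep(1.5, 8), c(2, rep(0, 7)))), ann)
  expect_equal(sc$score[1:3], c(8, 16, 8))
  expect_true(is.na(sc$score[4]))

  # wrong count / unknown-direction guards
  expect_error(build_multi_snp_score(matrix(1, 2, 7)), "exactly 8")
  bad <- make_oriented(rep(1, 16))
  colnames(bad)[1] <- "rs174577"  # unknown-direction SNP
  expect_error(build_multi_snp_score(bad, ann), "unknown|in_score")
})

test_that("score is invariant to SNP order", {
  ann <- iron_snp_annotation()
  m <- make_oriented(c(rep(1, 8), c(2, 1, 0, 1, 1, 2, 0, 1)))
  set.seed(4)
  perm <- sample(8)
  s1 <- build_multi_snp_score(m, ann)$score
  s2 <- build_multi_snp_score(m[, perm], ann)$score
  expect_identical(s1, s2)
})

test_that("quartile assignment follows the interpolated-boundary tie rule", {
  expect_identical(assign_quartiles(1:8),
                   c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  # hand-worked ties: boundaries (type 7) at 1, 1.5, 3.25; ties fall lower
  x <- c(1, 1, 1, 1, 2, 3, 4, 5)
  expect_identical(assign_quartiles(x),
                   c("Q1", "Q1", "Q1", "Q1", "Q3", "Q3", "Q4", "Q4"))
  expect_error(assign_quartiles(rep(2, 10)), "identical")
  expect_error(assign_quartiles(1:5), "at least 8")
})

test_that("fit_linear matches hand-computed least squares", {
  r <- fit_linear(1:10, 1:10)
  expect_equal(r$effect, 1)
  expect_equal(r$se, 0)

  r <- fit_linear(rep(2, 10), seq(-4.5, 4.5))
  expect_equal(r$effect, 0)

  # normal equations by hand: Sxy/Sxx = 4/4
  r <- fit_linear(c(0, 1, 1, 2, 2, 3), c(0, 0, 1, 1, 2, 2))
  expect_equal(r$effect, 1)
  expect_equal(r$ci_lo, r$effect - 1.96 * r$se)

  expect_error(fit_linear(c(1, 2, 3), c(1, 2, 3)), "too few")
  x <- rnorm(20)
  expect_error(fit_linear(rnorm(20), x, covariates = data.frame(z = 2 * x)),
               "rank-deficient")
})

test_that("fit_logistic matches the saturated 2x2 closed form", {
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  x <- c(rep(1, 30), rep(0, 30))
  r <- fit_logistic(y, x)
  expect_equal(unname(r$or), 0.25, tolerance = 1e-8)

  # balanced null: OR near 1
  set.seed(5)
  y <- rbinom(4000, 1, 0.5)
  x <- rbinom(4000, 1, 0.5)
  r <- fit_logistic(y, x)
  expect_lt(abs(log(r$or)), 3 * r$se)

  expect_error(fit_logistic(rep(1, 30), rnorm(30)), "single class")
})

test_that("per-allele logistic model matches a likelihood grid search", {
  # 2x3 genotype table: cases (10, 25, 30), controls (40, 25, 10)
  y <- rep(c(1, 0, 1, 0, 1, 0), c(10, 40, 25, 25, 30, 10))
  x <- rep(c(0, 0, 1, 1, 2, 2), c(10, 40, 25, 25, 30, 10))
  r <- fit_logistic(y, x)
  # brute-force profile over (intercept, beta) on a fine grid
  ll <- function(b0, b1) sum(y * (b0 + b1 * x) - log(1 + exp(b0 + b1 * x)))
  bgrid <- seq(r$effect - 0.2, r$effect + 0.2, by = 1e-4)
  prof <- vapply(bgrid, function(b1) {
    stats::optimize(function(b0) ll(b0, b1), c(-5, 5), maximum = TRUE)$objective
  }, 0)
  expect_lt(abs(bgrid[which.max(prof)] - r$effect), 1e-4)
})

test_that("separation is flagged, not silently reported", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rep(0, 20), rep(1, 20))
  r <- fit_logistic(y, x)
  expect_identical(r$status, "separation")
})

test_that("flipping the counted allele negates beta and inverts the OR", {
  set.seed(6)
  n <- 300
  x <- rbinom(n, 2, 0.3)
  yl <- 0.2 * x + rnorm(n)
  yb <- rbinom(n, 1, plogis(-0.5 + 0.3 * x))
  b1 <- fit_linear(yl, x)$effect
  b2 <- fit_linear(yl, flip_effect_allele(x))$effect
  expect_equal(b1, -b2, tolerance = 1e-10)
  o1 <- fit_logistic(yb, x)$or
  o2 <- fit_logistic(yb, flip_effect_allele(x))$or
  expect_equal(o1, 1 / o2, tolerance = 1e-8)
})

test_that("Wald CIs achieve nominal-ish coverage under the null", {
  set.seed(7)
  n <- 500
  hits <- 0L
  for (r in 1:200) {
    x <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    fit <- fit_linear(y, x)
    if (fit$ci_lo <= 0 && fit$ci_hi >= 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})

test_that("direction consistency scores strict sign patterns", {
  mk <- function(snp, eff) {
    data.frame(predictor = snp, outcome = c("plaque", "IMT", "ABI_rest",
                                            "ABI_exercise"),
               term = "dosage", model = c("logistic", rep("linear", 3)),
               stratum = "all", adjusted = FALSE, effect = eff, se = 0.1,
               ci_lo = NA, ci_hi = NA, or = NA, p = NA, n = 100,
               status = "ok")
  }
  ann <- iron_snp_annotation()
  res <- rbind(mk("rs1800562", c(log(1.2), 0.01, -0.02, -0.01)),  # increasing
               mk("rs9990333", c(log(1.2), 0.01, 0.02, -0.01)),   # broken ABI
               mk("rs7385804", c(log(1.2), 0, -0.02, -0.01)),     # beta == 0
               mk("rs174577", c(log(1.2), 0.01, -0.02, -0.01)))   # unknown
  cons <- evaluate_direction_consistency(res, ann)
  get <- function(s) cons$consistent[cons$predictor == s]
  expect_true(get("rs1800562"))
  expect_false(get("rs9990333"))
  expect_false(get("rs7385804"))
  expect_true(is.na(get("rs174577")))

  # risk-decreasing mirror: protective pattern is consistent
  res2 <- mk("rs651007", c(log(0.8), -0.01, 0.02, 0.01))
  expect_true(evaluate_direction_consistency(res2, ann)$consistent)
  # missing one NIMA errors
  expect_error(evaluate_direction_consistency(res2[-2, ], ann), "missing")
})

test_that("run_mr_suite wires genotypes, score and strata together", {
  sim <- mr_fixture(n = 700, seed = 23)
  res <- run_mr_suite(sim$genotypes, sim$phenotypes, sim$annotation,
                      strata = "all", lipid_adjust = FALSE)
  # 12 SNP rows + 3 quartile terms, x 4 outcomes
  expect_equal(nrow(res), (12 + 3) * 4)
  expect_setequal(unique(res$model[res$outcome == "plaque"]), "logistic")
  # empty outcome subset errors
  ph2 <- sim$phenotypes
  ph2[c("plaque", "IMT", "ABI_rest", "ABI_exercise")] <- NA_real_
  expect_error(run_mr_suite(sim$genotypes, ph2, sim$annotation,
                            strata = "all", lipid_adjust = FALSE),
               "no samples")
})

test_that("an exposure SNP with a real effect is detected by the suite", {
  sim <- mr_fixture(n = 1500, seed = 29, beta_imt = 0.4)
  res <- run_mr_suite(sim$genotypes, sim$phenotypes, sim$annotation,
                      strata = "all", lipid_adjust = FALSE)
  hit <- res[res$predictor == "rs1800562" & res$outcome == "IMT", ]
  expect_gt(hit$effect, 0)
  expect_lt(hit$p, 0.05)
})

test_that("cross-trait table covers outcome SNPs by biomarkers", {
  sim <- mr_fixture(n = 400, seed = 31)
  # simulated traits are already on the (log) analysis scale
  resid <- prepare_trait_panel(sim$phenotypes, c("hepcidin", "iron", "TIBC"),
                               mode = "exclude", log_traits = character())
  ct <- run_cross_trait(sim$genotypes, resid, sim$annotation)
  expect_equal(nrow(ct), 6 * 3)
  expect_setequal(unique(ct$model), "linear")
})
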