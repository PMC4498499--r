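test_that("LD pruning removes duplicated columns deterministically", {
  set.seed(11)
  base <- matrix(rbinom(60 * 10, 2, 0.4), 60, 10)
  dup <- cbind(base[, 1:5], base[, 3], base[, 6:10])  # col 6 duplicates col 3
  g <- toy_genotypes(dup)
  kept <- ld_prune(g, window = 20, step = 5)
  expect_equal(length(kept), 10)
  expect_true("s003" %in% kept)   # first of the pair kept
  expect_false("s006" %in% kept)

  # triple (A, B = A, C independent): matches exhaustive-pair oracle
  trip <- cbind(base[, 1], base[, 1], base[, 2])
  gt <- toy_genotypes(trip)
  kept <- ld_prune(gt, window = 10, step = 1)
  expect_identical(kept, c("s001", "s003"))
  oracle <- prune_oracle(trip, 0.98)
  expect_identical(match(kept, gt$snp$snp_id), oracle)
})

test_that("independent SNPs survive pruning at r2 = 0.98", {
  cfg <- simulation_config(n_samples = 100, n_snps = 500,
                           maf_range = c(0.1, 0.5), seed = 13)
  g <- simulate_genotypes(cfg)
  kept <- ld_prune(g)
  # null r2 is Beta-ish with mean 1/(n-1); exceeding 0.98 is essentially
  # impossible at n = 100
  expect_equal(length(kept), 500)
})

test_that("pruning agrees with the brute-force oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:5) {
    base <- matrix(rbinom(50 * 30, 2, runif(1, 0.2, 0.5)), 50, 30)
    # inject correlated pairs by duplication with sporadic flips
    for (j in sample(25, 5)) {
      col <- base[, j]
      base <- cbind(base, col)
    }
    g <- toy_genotypes(base)
    kept <- ld_prune(g, window = 50, step = 1)
    oracle <- prune_oracle(base, 0.98)
    expect_identical(match(kept, g$snp$snp_id), oracle)
  }
})

test_that("compute_grm matches the formula and the brute-force oracle", {
  # single SNP, realized p = 0.5: sample with x = 2 has diagonal 2.0
  g <- toy_genotypes(matrix(c(2, 0, 1, 1), 4, 1))
  A <- compute_grm(g)$A
  expect_equal(A[1, 1], (2 - 1)^2 / (2 * 0.5 * 0.5))

  cfg <- simulation_config(n_samples = 20, n_snps = 50, seed = 19)
  gg <- simulate_genotypes(cfg)
  grm <- compute_grm(gg)
  expect_lt(max(abs(grm$A - grm_oracle(gg$dosage))), 1e-10)
  expect_identical(grm$A, t(grm$A))
  expect_equal(grm$n_snps_used, 50)

  # identical twins: off-diagonal equals both diagonals
  tw <- gg$dosage[c(1, 1, 2:20), ]
  gt <- toy_genotypes(tw)
  At <- compute_grm(gt)$A
  expect_equal(At[1, 2], At[1, 1])
  expect_equal(At[1, 2], At[2, 2])

  expect_error(compute_grm(toy_genotypes(matrix(c(0, 0, 0, 1), 2, 2))),
               "monomorphic")
})

test_that("GRM diagonal centers near 1 and is allele-label invariant", {
  cfg <- simulation_config(n_samples = 200, n_snps = 1500, seed = 23)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  expect_gt(mean(diag(grm$A)), 0.95)
  expect_lt(mean(diag(grm$A)), 1.05)

  flipped <- g
  flipped$dosage[, 1:700] <- 2 - flipped$dosage[, 1:700]
  g2 <- toy_genotypes(flipped$dosage)
  expect_lt(max(abs(compute_grm(g2)$A - grm$A)), 1e-12)
})

test_that("relatedness filter removes the minimal offenders", {
  ids <- sprintf("S%03d", 1:4)
  mk <- function(A) structure(list(A = A, sample_ids = ids[seq_len(nrow(A))],
                                   n_snps_used = 100), class = "grm")
  # no pair above cutoff
  A <- diag(4) * 1
  A[upper.tri(A)] <- A[lower.tri(A)] <- 0.01
  expect_identical(filter_relatedness(mk(A)), ids)

  # one sib pair: exactly one removed
  A <- diag(4)
  A[1, 2] <- A[2, 1] <- 0.5
  kept <- filter_relatedness(mk(A))
  expect_equal(length(kept), 3)
  expect_true(sum(c("S001", "S002") %in% kept) == 1)

  # chain A-B, B-C above, A-C below: only B removed
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 0.1
  A[2, 3] <- A[3, 2] <- 0.1
  A[1, 3] <- A[3, 1] <- 0.001
  expect_identical(filter_relatedness(mk(A[1:3, 1:3])),
                   c("S001", "S003"))
})

test_that("relatedness filter matches exhaustive subset search on small GRMs", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 8
    A <- diag(n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    hot <- pairs[sample(nrow(pairs), 5), , drop = FALSE]
    for (k in seq_len(nrow(hot)))
      A[hot[k, 1], hot[k, 2]] <- A[hot[k, 2], hot[k, 1]] <- 0.3
    grm <- structure(list(A = A, sample_ids = sprintf("S%03d", 1:n),
                          n_snps_used = 10), class = "grm")
    kept <- filter_relatedness(grm, cutoff = 0.025)
    ki <- match(kept, grm$sample_ids)
    # validity: no retained pair at/above cutoff
    sub <- A[ki, ki]
    diag(sub) <- 0
    expect_lt(max(sub), 0.025)
    # optimality: exhaustive search over all subsets
    best <- 0
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(idx) <= best) next
      s <- A[idx, idx, drop = FALSE]
      diag(s) <- 0
      if (all(s < 0.025)) best <- length(idx)
    }
    expect_equal(length(kept), best)
  }
})

test_that("sib-pair GRM entries land in [0.4, 0.6] at m = 5000", {
  cfg <- simulation_config(n_samples = 120, n_snps = 5000, n_sib_pairs = 40,
                           maf_range = c(0.1, 0.5), seed = 31)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  sib <- vapply(1:40, function(k) grm$A[2 * k - 1, 2 * k], 0)
  expect_gt(mean(sib), 0.4)
  expect_lt(mean(sib), 0.6)
  # and the filter removes one of each pair
  kept <- filter_relatedness(grm)
  expect_lte(length(intersect(kept, g$sample_ids[1:80])), 40)
})

test_that("eigendecomposition reconstructs and flags negatives", {
  idm <- structure(list(A = diag(5), sample_ids = letters[1:5],
                        n_snps_used = 1), class = "grm")
  e <- eigendecompose(idm)
  expect_equal(e$values, rep(1, 5))

  v <- c(1, 2, 3, 4)
  r1 <- structure(list(A = tcrossprod(v), sample_ids = letters[1:4],
                       n_snps_used = 1), class = "grm")
  e <- eigendecompose(r1)
  expect_equal(e$values[1], sum(v^2))
  expect_equal(e$values[-1], rep(0, 3), tolerance = 1e-10)

  cfg <- simulation_config(n_samples = 50, n_snps = 200, seed = 37)
  grm <- compute_grm(simulate_genotypes(cfg))
  e <- eigendecompose(grm)
  recon <- e$vectors %*% (e$values * t(e$vectors))
  expect_lt(max(abs(recon - grm$A)), 1e-8)
  expect_lt(max(abs(crossprod(e$vectors) - diag(50))), 1e-10)
  expect_error(eigendecompose(matrix(1:4, 2)), "symmetric")
})

test_that("GCTA binary GRM round trip holds to float32 precision", {
  cfg <- simulation_config(n_samples = 30, n_snps = 100, seed = 41)
  grm <- compute_grm(simulate_genotypes(cfg))
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "test")
  write_gcta_grm(grm, prefix)
  grm2 <- read_gcta_grm(prefix)
  expect_identical(grm2$sample_ids, grm$sample_ids)
  expect_equal(grm2$n_snps_used, grm$n_snps_used)
  expect_lt(max(abs(grm2$A - grm$A)), 1e-6)
  tsv <- read.delim(paste0(prefix, ".grm.tsv"))
  expect_equal(nrow(tsv), 30 * 31 / 2)
})
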