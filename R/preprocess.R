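#' Genotype-probability to dosage transform
#'
#' `dosage = 0 * P_AA + 1 * P_AB + 2 * P_BB`, where allele B is the effect
#' allele. Vectorized over triples.
#'
#' @param p_aa,p_ab,p_bb probabilities of the three genotype classes; each
#'   component must be non-negative and each triple must sum to 1 within 1e-6.
#' @return numeric dosages in `[0, 2]`.
#' @export
compute_dosage <- function(p_aa, p_ab, p_bb) {
  if (any(p_aa < 0 | p_ab < 0 | p_bb < 0, na.rm = TRUE))
    stop("negative genotype probability")
  s <- p_aa + p_ab + p_bb
  if (any(abs(s - 1) > 1e-6, na.rm = TRUE))
    stop("genotype probabilities must sum to 1 (max dev ",
         signif(max(abs(s - 1), na.rm = TRUE), 3), ")")
  p_ab + 2 * p_bb
}

#' Flip the counted allele of a dosage
#'
#' Re-expresses a dosage on the opposite allele: `2 - dosage`. Used to orient
#' SNPs so that the counted allele is the hypothesized risk-increasing allele.
#'
#' @param dosage numeric in `[0, 2]` (`NA` allowed).
#' @return `2 - dosage`.
#' @export
flip_effect_allele <- function(dosage) {
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage out of [0, 2]")
  2 - dosage
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against HWE expectations. Soft dosages are rounded to the nearest
#' hard call first; monomorphic SNPs get p = 1 (the test carries no
#' information there; the MAF filter handles them).
#'
#' @param dosage numeric vector of dosages for one SNP.
#' @return p-value.
#' @export
hwe_test <- function(dosage) {
  g <- round(dosage[!is.na(dosage)])
  n <- length(g)
  if (n == 0) return(NA_real_)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP quality-control filter
#'
#' Retains SNPs with folded MAF >= `maf_min` and HWE p-value > `hwe_p_min`
#' (chi-square test on hard calls). All-missing SNPs are dropped. The filter
#' is idempotent.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf_min minimum folded minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value, exclusive (default 1e-6).
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (data.frame: `snp_id`, `maf`, `hwe_p`, `kept`, `reason`).
#' @export
qc_filter_snps <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  maf <- genotypes$snp$maf
  hwe_p <- apply(genotypes$dosage, 2, hwe_test)
  reason <- rep(NA_character_, length(maf))
  reason[is.na(maf)] <- "all_missing"
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & hwe_p <= hwe_p_min] <- "hwe"
  kept <- is.na(reason)
  if (!any(kept)) warning("no SNPs survive QC")
  report <- data.frame(snp_id = genotypes$snp$snp_id, maf = maf,
                       hwe_p = hwe_p, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(genotypes = subset_genotypes(genotypes, snps = which(kept)),
       report = report)
}

#' Sex-stratified residualization and standardization of a trait
#'
#' Implements the trait-preparation chain used ahead of both the SNP
#' association and the genomic-correlation arms: optional natural-log
#' transform; within each sex stratum, ordinary least-squares residuals on
#' age, squared age and (optionally) time-of-sampling dummies; outlier
#' handling at 4 SD (`exclude`: set to missing and re-standardize;
#' `winsorize`: clamp to mean +/- 4 SD then standardize); final
#' standardization to zero mean, unit variance within stratum. Missing trait
#' or covariate values propagate as missing for that sample only.
#'
#' @param trait numeric vector.
#' @param covariates data.frame with `age` and optionally `time_of_sampling`
#'   (factor, first level is the reference); squared age is derived
#'   internally.
#' @param sex factor/character with two levels defining the strata.
#' @param mode `"exclude"` (drop |z| > 4 then re-standardize) or
#'   `"winsorize"` (clamp to mean +/- 4 SD then standardize).
#' @param log_transform apply `log()` first (requires positive values).
#' @param use_time include time-of-sampling dummies when present (biomarkers
#'   yes, outcome traits no).
#' @return Object of class `residualized_trait`: list with `values`
#'   (standardized residuals, `NA` where missing/excluded), `stratum`,
#'   `n_excluded` (per stratum, mode = exclude only).
#' @export
prepare_trait <- function(trait, covariates, sex,
                          mode = c("exclude", "winsorize"),
                          log_transform = FALSE, use_time = TRUE) {
  mode <- match.arg(mode)
  n <- length(trait)
  stopifnot(length(sex) == n, nrow(covariates) == n)
  y <- as.numeric(trait)
  if (log_transform) {
    if (any(y <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive trait values")
    y <- log(y)
  }

  X <- cbind(age = covariates$age, age_squared = covariates$age^2)
  if (use_time && "time_of_sampling" %in% names(covariates)) {
    tos <- covariates$time_of_sampling
    lev <- levels(factor(tos))
    for (l in lev[-1])
      X <- cbind(X, as.numeric(tos == l))
    colnames(X)[(ncol(X) - length(lev) + 2):ncol(X)] <-
      paste0("time_", lev[-1])
  }

  out <- rep(NA_real_, n)
  sexf <- factor(sex)
  n_excl <- stats::setNames(integer(nlevels(sexf)), levels(sexf))
  for (s in levels(sexf)) {
    idx <- which(sexf == s & !is.na(y) & stats::complete.cases(X))
    if (length(idx) < ncol(X) + 2)
      stop("stratum '", s, "' too small (", length(idx), " complete cases)")
    fit <- stats::lm.fit(cbind(1, X[idx, , drop = FALSE]), y[idx])
    r <- fit$residuals
    if (stats::sd(r) < 1e-12)
      stop("zero-variance trait within stratum '", s, "' after adjustment")
    z <- (r - mean(r)) / stats::sd(r)
    if (mode == "exclude") {
      bad <- abs(z) > 4
      n_excl[s] <- sum(bad)
      z[bad] <- NA
      keep <- !bad
      z[keep] <- (z[keep] - mean(z[keep])) / stats::sd(z[keep])
    } else {
      lo <- mean(r) - 4 * stats::sd(r)
      hi <- mean(r) + 4 * stats::sd(r)
      rc <- pmin(pmax(r, lo), hi)
      z <- (rc - mean(rc)) / stats::sd(rc)
    }
    out[idx] <- z
  }
  structure(list(values = out, stratum = as.character(sexf),
                 n_excluded = n_excl, mode = mode),
            class = "residualized_trait")
}

#' @export
print.residualized_trait <- function(x, ...) {
  cat("residualized_trait:", sum(!is.na(x$values)), "values,",
      sum(x$n_excluded), "excluded (mode =", x$mode, ")\n")
  invisible(x)
}

#' Prepare the full trait panel of a phenotype table
#'
#' Applies [prepare_trait()] to each named trait with the conventions of the
#' analysis: hepcidin, ferritin and the hepcidin ratios are log-transformed;
#' biomarkers are adjusted for time of sampling, outcome traits are not.
#' Binary traits (detected as 0/1) skip the log transform and, like all
#' traits, end standardized on the observed scale.
#'
#' @param phenotypes phenotype data.frame (see [simulate_phenotypes()]).
#' @param traits character vector of trait column names.
#' @param mode outlier mode passed to [prepare_trait()]; the SNP-association
#'   arm uses `"exclude"`, the genomic-correlation arm `"winsorize"`.
#' @param log_traits traits to log-transform; defaults to the conventional
#'   set intersected with `traits`.
#' @param time_traits traits adjusted for time of sampling; defaults to the
#'   biomarker set.
#' @return data.frame of standardized residuals (`sample_id` plus one column
#'   per trait).
#' @export
prepare_trait_panel <- function(phenotypes, traits,
                                mode = c("exclude", "winsorize"),
                                log_traits = NULL, time_traits = NULL) {
  mode <- match.arg(mode)
  biomarkers <- c("hepcidin", "ferritin", "hepcidin_ferritin", "hepcidin_TS",
                  "iron", "TIBC", "TS")
  if (is.null(log_traits))
    log_traits <- intersect(c("hepcidin", "ferritin", "hepcidin_ferritin",
                              "hepcidin_TS"), traits)
  if (is.null(time_traits)) time_traits <- intersect(biomarkers, traits)
  res <- data.frame(sample_id = phenotypes$sample_id,
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    y <- phenotypes[[tr]]
    if (is.null(y)) stop("trait not found: ", tr)
    is_binary <- all(y[!is.na(y)] %in% 0:1)
    rt <- prepare_trait(y, phenotypes, phenotypes$sex, mode = mode,
                        log_transform = (tr %in% log_traits) && !is_binary,
                        use_time = tr %in% time_traits)
    res[[tr]] <- rt$values
  }
  res
}
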