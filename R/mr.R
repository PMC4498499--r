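#' Multi-SNP allele score
#'
#' Sums per-sample oriented dosages over the eight score SNPs (risk-increasing
#' allele counted at each SNP), giving a score in `[0, 16]`. Samples missing
#' any dosage get a missing score. Quartile labels are attached when at least
#' 8 non-missing, non-constant scores are available.
#'
#' @param oriented samples-by-SNPs dosage matrix, already oriented to the
#'   risk-increasing allele (see [orient_dosages()]); must have exactly 8
#'   columns named by `snp_id`.
#' @param annotation optional `snp_annotation`; when given, the 8 columns must
#'   be its `in_score` SNPs and none may have unknown direction.
#' @return data.frame (`sample_id`, `score`, `quartile`).
#' @export
build_multi_snp_score <- function(oriented, annotation = NULL) {
  oriented <- as.matrix(oriented)
  if (ncol(oriented) != 8)
    stop("multi-SNP score requires exactly 8 SNPs, got ", ncol(oriented))
  if (!is.null(annotation)) {
    idx <- match(colnames(oriented), annotation$snp_id)
    if (anyNA(idx)) stop("score SNP missing from annotation")
    if (any(annotation$hypothesized_direction[idx] == "unknown"))
      stop("unknown-direction SNP cannot enter the score")
    want <- sort(annotation$snp_id[annotation$in_score])
    if (!identical(sort(colnames(oriented)), want))
      stop("score columns do not match the annotation's in_score SNPs")
  }
  score <- rowSums(oriented)  # NA if any dosage missing
  q <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  if (sum(ok) >= 8 && stats::sd(score[ok]) > 0)
    q[ok] <- assign_quartiles(score[ok])
  data.frame(sample_id = rownames(oriented) %||% seq_along(score),
             score = score, quartile = q, stringsAsFactors = FALSE)
}

#' Assign empirical quartile labels
#'
#' Boundaries are the empirical 25/50/75 percentiles (linear interpolation,
#' `quantile` type 7); values tied at a boundary fall in the lower quartile.
#'
#' @param scores numeric vector with at least 8 non-missing values.
#' @return character vector of labels `Q1`-`Q4` (`NA` where `scores` is `NA`).
#' @export
assign_quartiles <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 8) stop("need at least 8 non-missing scores")
  if (stats::sd(scores[ok]) == 0) stop("all scores identical")
  br <- stats::quantile(scores[ok], c(0.25, 0.5, 0.75), type = 7)
  out <- rep(NA_character_, length(scores))
  out[ok] <- paste0("Q", findInterval(scores[ok], br, left.open = TRUE) + 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

association_row <- function(predictor, outcome, term, model, est, se, n,
                            stratum = "all", adjusted = FALSE,
                            status = "ok", df = Inf) {
  # exact t reference for OLS (df = residual df), normal Wald for logistic
  p <- if (is.na(se) || se == 0) {
    if (!is.na(est) && est == 0) 1 else 0
  } else 2 * stats::pt(-abs(est / se), df = df)
  data.frame(predictor = predictor, outcome = outcome, term = term,
             model = model, stratum = stratum, adjusted = adjusted,
             effect = est, se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             or = if (model == "logistic") exp(est) else NA_real_,
             p = p, n = n, status = status, stringsAsFactors = FALSE)
}

#' Linear association model
#'
#' Ordinary least squares of an outcome on a predictor (allele dosage, or
#' quartile indicators Q2/Q3/Q4 versus Q1) plus optional covariates. Effects
#' carry Wald 95% confidence intervals (+/- 1.96 SE) and two-sided normal
#' p-values.
#'
#' @param y numeric outcome.
#' @param x numeric dosage, or a factor whose first level is the reference.
#' @param covariates optional data.frame of additional linear covariates.
#' @param predictor,outcome labels recorded in the result.
#' @param stratum,adjusted labels recorded in the result.
#' @return data.frame with one row per predictor term (see package README for
#'   the column layout).
#' @export
fit_linear <- function(y, x, covariates = NULL, predictor = "x",
                       outcome = "y", stratum = "all", adjusted = FALSE) {
  d <- assemble_design(y, x, covariates)
  if (nrow(d$X) <= ncol(d$X) + 2) stop("too few complete cases")
  fit <- stats::lm.fit(d$X, d$y)
  if (fit$rank < ncol(d$X)) stop("rank-deficient design")
  r <- fit$residuals
  df <- length(d$y) - ncol(d$X)
  s2 <- sum(r^2) / df
  XtXinv <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(pmax(s2 * diag(XtXinv), 0))
  do.call(rbind, lapply(seq_along(d$terms), function(i) {
    j <- d$term_cols[i]
    association_row(predictor, outcome, d$terms[i], "linear",
                    unname(fit$coefficients[j]), se[j], length(d$y),
                    stratum, adjusted, df = df)
  }))
}

#' Logistic association model
#'
#' Maximum-likelihood logistic regression (IRLS, log-likelihood tolerance
#' 1e-8, max 100 iterations). Effects are log odds ratios with Wald CIs; the
#' per-allele OR is `exp(effect)`. Separation is detected as a fitted
#' |log-OR| > 15 or non-convergence and flagged in `status` rather than
#' reported as a finite estimate of quality.
#'
#' @inheritParams fit_linear
#' @param y binary outcome (0/1); both classes must be present.
#' @return data.frame with one row per predictor term.
#' @export
fit_logistic <- function(y, x, covariates = NULL, predictor = "x",
                         outcome = "y", stratum = "all", adjusted = FALSE) {
  d <- assemble_design(y, x, covariates)
  yy <- d$y
  if (length(unique(yy)) < 2) stop("outcome has a single class")
  if (nrow(d$X) <= ncol(d$X) + 2) stop("too few complete cases")
  fit <- suppressWarnings(
    stats::glm.fit(d$X, yy, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (fit$rank < ncol(d$X)) stop("rank-deficient design")
  cov <- chol2inv(chol(crossprod(d$X * sqrt(fit$weights))))
  se <- sqrt(diag(cov))
  status <- if (!fit$converged || any(abs(fit$coefficients[-1]) > 15))
    "separation" else "ok"
  do.call(rbind, lapply(seq_along(d$terms), function(i) {
    j <- d$term_cols[i]
    association_row(predictor, outcome, d$terms[i], "logistic",
                    unname(fit$coefficients[j]), se[j], length(yy),
                    stratum, adjusted, status)
  }))
}

# Shared design assembly: intercept + predictor term(s) + covariates,
# complete cases only. Factor predictors expand to treatment contrasts.
assemble_design <- function(y, x, covariates) {
  n <- length(y)
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    terms <- levels(x)[-1]
    # treatment contrasts vs the first level; NA propagates by arithmetic
    P <- vapply(terms, function(l) as.numeric(x == l), numeric(n))
    P <- matrix(P, n, length(terms))
  } else {
    P <- matrix(as.numeric(x), ncol = 1)
    terms <- "dosage"
  }
  C <- if (is.null(covariates)) NULL else
    as.matrix(as.data.frame(lapply(covariates, as.numeric)))
  X <- cbind(1, P, C)
  ok <- stats::complete.cases(X) & !is.na(y)
  list(X = X[ok, , drop = FALSE], y = y[ok],
       terms = terms, term_cols = 1 + seq_along(terms))
}

#' Run the full Mendelian-randomization association suite
#'
#' Fits, for each of the 12 exposure SNPs (per tested-allele dosage) and for
#' the multi-SNP score quartiles (Q2/Q3/Q4 versus Q1), association models
#' against the four atherosclerosis outcomes — logistic for plaque presence,
#' linear for IMT and the two ABI measures — in three strata (all, men,
#' women) and with and without lipid adjustment (TC, LDL, HDL, TGC as linear
#' covariates). Age and squared age are always included as covariates.
#'
#' @param genotypes a `genotype_matrix` whose columns cover the exposure SNPs
#'   (dosages counted on the annotation's effect allele).
#' @param phenotypes phenotype data.frame with the outcome traits, `sex`,
#'   `age`, `age_squared` and the lipid panel.
#' @param annotation `snp_annotation` for the exposure SNPs.
#' @param strata subset of `c("all", "men", "women")`.
#' @param lipid_adjust run the lipid-adjusted arm in addition to unadjusted.
#' @param quartiles_on compute score quartile boundaries on the full
#'   genotyped sample (`"all"`, default) or within the outcome subset
#'   (`"subset"`).
#' @param outcomes outcome trait names; `plaque` is modelled logistically.
#' @return data.frame of association results, one row per
#'   (predictor term, outcome, stratum, adjustment).
#' @export
run_mr_suite <- function(genotypes, phenotypes, annotation,
                         strata = c("all", "men", "women"),
                         lipid_adjust = TRUE,
                         quartiles_on = c("all", "subset"),
                         outcomes = c("plaque", "IMT", "ABI_rest",
                                      "ABI_exercise")) {
  quartiles_on <- match.arg(quartiles_on)
  strata <- match.arg(strata, c("all", "men", "women"), several.ok = TRUE)
  miss <- setdiff(outcomes, names(phenotypes))
  if (length(miss)) stop("outcome trait(s) missing: ",
                         paste(miss, collapse = ", "))
  if (all(is.na(as.matrix(phenotypes[outcomes]))))
    stop("no samples with outcome data")
  exp_ann <- annotation[annotation$role == "exposure", , drop = FALSE]
  dos <- genotypes$dosage[, exp_ann$snp_id, drop = FALSE]
  stopifnot(identical(rownames(dos), phenotypes$sample_id))

  score_snps <- exp_ann$snp_id[exp_ann$in_score]
  oriented <- orient_dosages(dos[, score_snps, drop = FALSE], exp_ann)
  if (quartiles_on == "subset") {
    in_sub <- rowSums(!is.na(as.matrix(phenotypes[outcomes]))) > 0
    sc_sub <- build_multi_snp_score(oriented[in_sub, , drop = FALSE], exp_ann)
    quart <- rep(NA_character_, nrow(dos))
    quart[in_sub] <- sc_sub$quartile
  } else {
    quart <- build_multi_snp_score(oriented, exp_ann)$quartile
  }
  quart <- factor(quart, levels = paste0("Q", 1:4))

  lipids <- c("TC", "LDL", "HDL", "TGC")
  adj_arms <- if (lipid_adjust) c(FALSE, TRUE) else FALSE
  res <- list()
  for (st in strata) {
    keep <- switch(st, all = rep(TRUE, nrow(phenotypes)),
                   men = phenotypes$sex == "male",
                   women = phenotypes$sex == "female")
    ph <- phenotypes[keep, , drop = FALSE]
    for (adj in adj_arms) {
      covs <- data.frame(age = ph$age, age_squared = ph$age^2)
      if (adj) covs <- cbind(covs, ph[lipids])
      for (oc in outcomes) {
        fitter <- if (oc == "plaque") fit_logistic else fit_linear
        res[[length(res) + 1L]] <- fitter(
          ph[[oc]], quart[keep], covs, predictor = "multi_snp_score",
          outcome = oc, stratum = st, adjusted = adj)
        for (s in exp_ann$snp_id) {
          res[[length(res) + 1L]] <- fitter(
            ph[[oc]], dos[keep, s], covs, predictor = s,
            outcome = oc, stratum = st, adjusted = adj)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-trait association of outcome SNPs with biomarker residuals
#'
#' Linear models of each standardized biomarker residual on each outcome
#' SNP's dosage (no further covariates: the residuals are already adjusted).
#'
#' @param genotypes `genotype_matrix` covering the outcome SNPs.
#' @param residuals data.frame of standardized biomarker residuals
#'   (`sample_id` plus one column per trait), e.g. from
#'   [prepare_trait_panel()].
#' @param annotation `snp_annotation` with `role = "outcome"` rows.
#' @return data.frame of association results (6 SNPs x traits).
#' @export
run_cross_trait <- function(genotypes, residuals, annotation) {
  out_ann <- annotation[annotation$role == "outcome", , drop = FALSE]
  if (nrow(out_ann) == 0) stop("annotation has no outcome SNPs")
  dos <- genotypes$dosage[, out_ann$snp_id, drop = FALSE]
  stopifnot(identical(rownames(dos), residuals$sample_id))
  traits <- setdiff(names(residuals), "sample_id")
  res <- list()
  for (s in out_ann$snp_id) for (tr in traits) {
    res[[length(res) + 1L]] <- fit_linear(
      residuals[[tr]], dos[, s], predictor = s, outcome = tr)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Direction-consistency evaluation against the iron hypothesis
#'
#' A risk-increasing predictor is consistent iff its point estimates worsen
#' every atherosclerosis measure: OR(plaque) > 1, beta(IMT) > 0,
#' beta(ABI at rest) < 0 and beta(ABI after exercise) < 0; mirrored for
#' risk-decreasing predictors. Strict inequalities on point estimates — a
#' beta of exactly 0 is inconsistent; significance plays no role.
#' Unknown-direction SNPs are reported with `consistent = NA`.
#'
#' @param results association results from [run_mr_suite()].
#' @param annotation `snp_annotation` giving each predictor's hypothesized
#'   direction; the multi-SNP score and its quartile terms are treated as
#'   risk-increasing by construction.
#' @return data.frame with one row per (predictor, term, stratum, adjusted)
#'   group: the four signed effects and a `consistent` flag.
#' @export
evaluate_direction_consistency <- function(results, annotation) {
  need <- c("plaque", "IMT", "ABI_rest", "ABI_exercise")
  keys <- unique(results[c("predictor", "term", "stratum", "adjusted")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- results[results$predictor == k$predictor &
                   results$term == k$term &
                   results$stratum == k$stratum &
                   results$adjusted == k$adjusted, ]
    if (!all(need %in% sub$outcome))
      stop("missing NIMA result for predictor ", k$predictor,
           " term ", k$term)
    eff <- stats::setNames(sub$effect[match(need, sub$outcome)], need)
    dir <- if (k$predictor == "multi_snp_score") "risk_increasing" else
      annotation$hypothesized_direction[match(k$predictor,
                                              annotation$snp_id)]
    cons <- if (is.na(dir) || dir == "unknown") NA else {
      sgn <- if (dir == "risk_increasing") 1 else -1
      (sgn * eff["plaque"] > 0) && (sgn * eff["IMT"] > 0) &&
        (sgn * eff["ABI_rest"] < 0) && (sgn * eff["ABI_exercise"] < 0)
    }
    cbind(k, data.frame(direction = dir %||% NA_character_,
                        log_or_plaque = unname(eff["plaque"]),
                        beta_IMT = unname(eff["IMT"]),
                        beta_ABI_rest = unname(eff["ABI_rest"]),
                        beta_ABI_exercise = unname(eff["ABI_exercise"]),
                        consistent = cons))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
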