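# Bayesian multivariate genomic model: random regression on scaled GRM
# eigenvectors with latent genetic (and residual) factors carrying the
# cross-trait covariance. Gibbs sampling with uniform(0, 10) priors on all
# variance parameters, N(0, 1) priors on free loadings, lower-triangular
# loading matrices with non-negative diagonal for identifiability.

#' Genomic regression design from a GRM eigendecomposition
#'
#' `Z = U diag(sqrt(d))`, so `Z Z' = A`; columns with eigenvalue below 1e-10
#' are dropped (they carry no genetic signal).
#'
#' @param eig an [eigendecompose()] result.
#' @return matrix `Z` (samples x retained eigenvectors) with attribute
#'   `"eigenvalues"`.
#' @export
build_design <- function(eig) {
  stopifnot(inherits(eig, "eigen_grm"))
  if (any(eig$values < -1e-8)) stop("negative eigenvalue beyond tolerance")
  keep <- which(eig$values > 1e-10)
  Z <- eig$vectors[, keep, drop = FALSE] *
    rep(sqrt(eig$values[keep]), each = nrow(eig$vectors))
  rownames(Z) <- eig$sample_ids
  attr(Z, "eigenvalues") <- eig$values[keep]
  Z
}

# inverse-CDF draw from the conditional of a variance under a uniform(0, max)
# prior: density ~ (s2)^(-k/2) exp(-ss/(2 s2)) on (0, max). In precision
# space this is Gamma(k/2 - 1, ss/2) truncated to (1/max, Inf).
draw_variance <- function(k, ss, max_var = 10) {
  shape <- k / 2 - 1
  rate <- ss / 2
  if (shape <= 0 || rate <= 0) return(stats::runif(1, 1e-8, max_var))
  lo <- stats::pgamma(1 / max_var, shape, rate)
  u <- stats::runif(1, lo, 1)
  u <- min(u, 1 - 1e-15)
  prec <- stats::qgamma(u, shape, rate)
  max(1 / prec, 1e-10)
}

# truncated-at-zero normal draw (for diagonal loadings)
draw_halfnormal <- function(mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(1, lo, 1)
  u <- min(max(u, 1e-15), 1 - 1e-15)
  stats::qnorm(u, mean, sd)
}

#' Gibbs sampler for the multi-trait latent-factor genomic model
#'
#' Traits (standardized residuals; `NA` allowed and imputed by data
#' augmentation each sweep) are modelled as
#' `y_t = Z a_t + sum_l lambda_g[t,l] Z c_l + sum_r lambda_e[t,r] h_r + eps_t`
#' where `Z` comes from [build_design()]. The implied genetic covariance is
#' `G0 = L_g diag(s2_f) L_g' + diag(psi_g)` (PSD by construction, so every
#' per-sample rG lies in [-1, 1]); likewise for the residual side. Variances
#' carry uniform(0, 10) priors (vacuous for standardized traits), free
#' loadings N(0, 1); loading matrices are lower-triangular with non-negative
#' diagonals. DIC uses the deviance conditional on the latent genetic and
#' residual-factor states.
#'
#' @param Y matrix/data.frame of traits (samples x traits), aligned with the
#'   rows of `Z`; standardized residuals, `NA` = not measured.
#' @param Z design from [build_design()] (its eigenvector basis must match
#'   the samples of `Y`).
#' @param eig the [eigendecompose()] result that produced `Z` (used to rotate
#'   in and out of the eigenbasis).
#' @param n_latent_g,n_latent_e number of genetic / residual latent factors.
#' @param sweeps,burn_in,thin chain settings (defaults 30000/10000/20; tests
#'   and small fixtures use far fewer).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   chains.
#' @param max_var upper bound of the uniform variance priors.
#' @return Object of class `posterior_summary`: posterior mean/SD matrices
#'   for rG, G0, R0, per-trait h2, DIC and pD, effective sample sizes for
#'   the rG entries, and the thinned draws.
#' @export
run_gibbs <- function(Y, Z, eig, n_latent_g = 1, n_latent_e = 1,
                      sweeps = 30000, burn_in = 10000, thin = 20,
                      seed = 1L, max_var = 10) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Tt <- ncol(Y)
  if (Tt > 8) stop("at most 8 traits per model")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(Tt))
  traits <- colnames(Y)
  stopifnot(nrow(Z) == n)
  Lg <- max(0L, as.integer(n_latent_g))
  Le <- max(0L, as.integer(n_latent_e))
  n_keep <- floor((sweeps - burn_in) / thin)
  if (n_keep < 100)
    stop("fewer than 100 retained samples; increase sweeps or lower thin")
  set.seed(seed)

  U <- eig$vectors
  s <- sqrt(pmax(eig$values, 0))   # design in the eigenbasis is diag(s)
  miss <- is.na(Y)
  any_miss <- any(miss)
  obs_n <- sum(!miss)
  Yfull <- Y
  # initialize missing entries at trait means (0 for standardized traits)
  if (any_miss) {
    for (t in seq_len(Tt))
      Yfull[miss[, t], t] <- mean(Y[!miss[, t], t])
  }
  Yt <- crossprod(U, Yfull)   # rotated data, n x T

  # state
  Ag <- matrix(0, n, Tt)              # trait-specific genetic coefficients
  Cg <- matrix(0, n, max(Lg, 1))      # factor coefficients (rotated)
  Lamg <- matrix(0, Tt, max(Lg, 1))
  if (Lg > 0) diag(Lamg)[seq_len(min(Tt, Lg))] <- 0.5
  He <- matrix(0, n, max(Le, 1))      # residual factor scores (rotated)
  Lame <- matrix(0, Tt, max(Le, 1))
  if (Le > 0) diag(Lame)[seq_len(min(Tt, Le))] <- 0.5
  psi_g <- rep(0.2, Tt)
  psi_e <- rep(0.5, Tt)
  s2_f <- rep(1, max(Lg, 1))
  s2_h <- rep(1, max(Le, 1))

  ssq <- s^2
  keep_G0 <- array(0, c(Tt, Tt, n_keep))
  keep_R0 <- array(0, c(Tt, Tt, n_keep))
  keep_rg <- array(0, c(Tt, Tt, n_keep))
  keep_var <- matrix(0, n_keep, 2 * Tt,
                     dimnames = list(NULL, c(paste0("psi_g_", traits),
                                             paste0("psi_e_", traits))))
  dev <- numeric(n_keep)
  mu_sum <- matrix(0, n, Tt)
  psi_e_sum <- numeric(Tt)
  ik <- 0L

  genetic_part <- function() {
    G <- Ag * s
    if (Lg > 0) G <- G + (Cg[, seq_len(Lg), drop = FALSE] * s) %*%
        t(Lamg[, seq_len(Lg), drop = FALSE])
    G
  }
  resid_factor_part <- function() {
    if (Le > 0) He[, seq_len(Le), drop = FALSE] %*%
      t(Lame[, seq_len(Le), drop = FALSE]) else matrix(0, n, Tt)
  }

  for (sw in seq_len(sweeps)) {
    Fg <- if (Lg > 0) (Cg[, seq_len(Lg), drop = FALSE] * s) else NULL
    RF <- resid_factor_part()

    # trait-specific genetic coefficients a_t
    for (t in seq_len(Tt)) {
      r <- Yt[, t] - RF[, t]
      if (Lg > 0) r <- r - Fg %*% Lamg[t, seq_len(Lg)]
      prec <- ssq / psi_e[t] + 1 / psi_g[t]
      mu <- (s * r / psi_e[t]) / prec
      Ag[, t] <- mu + stats::rnorm(n) / sqrt(prec)
    }
    Gts <- Ag * s   # trait-specific genetic values (rotated)

    # genetic factor coefficients c_l and loadings
    if (Lg > 0) {
      for (l in seq_len(Lg)) {
        other <- if (Lg > 1)
          (Cg[, setdiff(seq_len(Lg), l), drop = FALSE] * s) %*%
            t(Lamg[, setdiff(seq_len(Lg), l), drop = FALSE]) else 0
        R <- Yt - Gts - RF - other
        lam <- Lamg[, l]
        prec <- ssq * sum(lam^2 / psi_e) + 1 / s2_f[l]
        mu <- (s * (R %*% (lam / psi_e))) / prec
        Cg[, l] <- mu + stats::rnorm(n) / sqrt(prec)
      }
      Fg <- Cg[, seq_len(Lg), drop = FALSE] * s
      for (t in seq_len(Tt)) {
        for (l in seq_len(min(t, Lg))) {
          others <- setdiff(seq_len(Lg), l)
          r <- Yt[, t] - Gts[, t] - RF[, t]
          if (length(others))
            r <- r - Fg[, others, drop = FALSE] %*% Lamg[t, others]
          f <- Fg[, l]
          prec <- sum(f^2) / psi_e[t] + 1
          mu <- sum(f * r) / psi_e[t] / prec
          Lamg[t, l] <- if (t == l) draw_halfnormal(mu, 1 / sqrt(prec))
                        else mu + stats::rnorm(1) / sqrt(prec)
        }
      }
    }
    Gen <- genetic_part()

    # residual factor scores and loadings
    if (Le > 0) {
      for (l in seq_len(Le)) {
        other <- if (Le > 1)
          He[, setdiff(seq_len(Le), l), drop = FALSE] %*%
            t(Lame[, setdiff(seq_len(Le), l), drop = FALSE]) else 0
        R <- Yt - Gen - other
        lam <- Lame[, l]
        prec <- sum(lam^2 / psi_e) + 1 / s2_h[l]
        mu <- (R %*% (lam / psi_e)) / prec
        He[, l] <- mu + stats::rnorm(n) / sqrt(prec)
      }
      for (t in seq_len(Tt)) {
        for (l in seq_len(min(t, Le))) {
          others <- setdiff(seq_len(Le), l)
          r <- Yt[, t] - Gen[, t]
          if (length(others))
            r <- r - He[, others, drop = FALSE] %*% Lame[t, others]
          h <- He[, l]
          prec <- sum(h^2) / psi_e[t] + 1
          mu <- sum(h * r) / psi_e[t] / prec
          Lame[t, l] <- if (t == l) draw_halfnormal(mu, 1 / sqrt(prec))
                        else mu + stats::rnorm(1) / sqrt(prec)
        }
      }
    }
    RF <- resid_factor_part()

    # variances
    for (t in seq_len(Tt))
      psi_g[t] <- draw_variance(n, sum(Ag[, t]^2), max_var)
    if (Lg > 0) for (l in seq_len(Lg))
      s2_f[l] <- draw_variance(n, sum(Cg[, l]^2), max_var)
    if (Le > 0) for (l in seq_len(Le))
      s2_h[l] <- draw_variance(n, sum(He[, l]^2), max_var)
    Eps <- Yt - Gen - RF
    for (t in seq_len(Tt))
      psi_e[t] <- draw_variance(n, sum(Eps[, t]^2), max_var)

    if (!all(is.finite(c(psi_g, psi_e, s2_f, s2_h, Lamg, Lame))))
      stop("chain divergence: non-finite state at sweep ", sw)

    # data augmentation for missing trait values
    if (any_miss) {
      Mu <- U %*% (Gen + RF)
      for (t in seq_len(Tt)) {
        mi <- which(miss[, t])
        if (length(mi))
          Yfull[mi, t] <- Mu[mi, t] +
            stats::rnorm(length(mi)) * sqrt(psi_e[t])
      }
      Yt <- crossprod(U, Yfull)
    }

    if (sw > burn_in && (sw - burn_in) %% thin == 0 && ik < n_keep) {
      ik <- ik + 1L
      G0 <- tcrossprod(Lamg[, seq_len(max(Lg, 1)), drop = FALSE] *
                         rep(sqrt(s2_f), each = Tt)) * (Lg > 0) +
            diag(psi_g, Tt)
      R0 <- tcrossprod(Lame[, seq_len(max(Le, 1)), drop = FALSE] *
                         rep(sqrt(s2_h), each = Tt)) * (Le > 0) +
            diag(psi_e, Tt)
      dg <- sqrt(diag(G0))
      rg <- G0 / tcrossprod(dg)
      keep_G0[, , ik] <- G0
      keep_R0[, , ik] <- R0
      keep_rg[, , ik] <- rg
      keep_var[ik, ] <- c(psi_g, psi_e)
      if (any_miss) {
        # conditional (on latent states) deviance over observed entries
        Mu <- U %*% (Gen + RF)
        d2 <- 0
        for (t in seq_len(Tt)) {
          oi <- which(!miss[, t])
          d2 <- d2 + sum(stats::dnorm(Y[oi, t], Mu[oi, t], sqrt(psi_e[t]),
                                      log = TRUE))
        }
        dev[ik] <- -2 * d2
        mu_sum <- mu_sum + Mu
        psi_e_sum <- psi_e_sum + psi_e
      } else {
        # marginal deviance given the (co)variance parameters only — the
        # deviance that DIC-based selection of the factor count needs
        dev[ik] <- marginal_deviance(Yt, pmax(eig$values, 0), G0, R0)
      }
    }
  }

  if (any_miss) {
    mu_bar <- mu_sum / ik
    psi_bar <- psi_e_sum / ik
    d_at_mean <- 0
    for (t in seq_len(Tt)) {
      oi <- which(!miss[, t])
      d_at_mean <- d_at_mean +
        sum(stats::dnorm(Y[oi, t], mu_bar[oi, t], sqrt(psi_bar[t]),
                         log = TRUE))
    }
    d_at_mean <- -2 * d_at_mean
  } else {
    d_at_mean <- marginal_deviance(Yt, pmax(eig$values, 0),
                                   apply(keep_G0, 1:2, mean),
                                   apply(keep_R0, 1:2, mean))
  }
  dic <- compute_dic(dev, d_at_mean)

  rg_mean <- apply(keep_rg, 1:2, mean)
  rg_sd <- apply(keep_rg, 1:2, stats::sd)
  G0_mean <- apply(keep_G0, 1:2, mean)
  R0_mean <- apply(keep_R0, 1:2, mean)
  dimnames(rg_mean) <- dimnames(rg_sd) <- dimnames(G0_mean) <-
    dimnames(R0_mean) <- list(traits, traits)
  h2 <- diag(G0_mean) / (diag(G0_mean) + diag(R0_mean))
  ess <- matrix(NA_real_, Tt, Tt, dimnames = list(traits, traits))
  for (i in seq_len(Tt)) for (j in seq_len(Tt)) if (i != j)
    ess[i, j] <- ess_chain(keep_rg[i, j, ])

  structure(
    list(traits = traits, rg_mean = rg_mean, rg_sd = rg_sd,
         G0_mean = G0_mean, R0_mean = R0_mean, h2 = h2,
         dic = dic$dic, p_d = dic$p_d, mean_deviance = dic$mean_deviance,
         ess_rg = ess, n_retained = ik,
         draws = list(rg = keep_rg, variances = keep_var, deviance = dev),
         settings = list(n_latent_g = Lg, n_latent_e = Le, sweeps = sweeps,
                         burn_in = burn_in, thin = thin, seed = seed)),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary:", length(x$traits), "traits,",
      x$n_retained, "retained draws, DIC", signif(x$dic, 6),
      "(pD", signif(x$p_d, 4), ")\n")
  cat("posterior mean rG:\n")
  print(signif(x$rg_mean, 3))
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + pD` with `pD = mean(D) - D(at posterior mean)`.
#'
#' @param deviances per-retained-sample deviances `-2 log L`.
#' @param deviance_at_mean deviance evaluated at the posterior mean of the
#'   parameters.
#' @return list with `dic`, `p_d`, `mean_deviance`.
#' @export
compute_dic <- function(deviances, deviance_at_mean) {
  if (length(deviances) < 100)
    stop("need at least 100 retained samples for DIC")
  if (!all(is.finite(deviances)) || !is.finite(deviance_at_mean))
    stop("non-finite deviance")
  dbar <- mean(deviances)
  p_d <- dbar - deviance_at_mean
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

# Marginal deviance of complete rotated data given (G0, R0): per
# eigen-coordinate k, y_k ~ N(0, d_k G0 + R0). Simultaneous diagonalization
# (R0^{-1/2} G0 R0^{-1/2} = Q L Q') makes this O(n T^2).
marginal_deviance <- function(Yt, d, G0, R0) {
  Tt <- ncol(Yt)
  n <- nrow(Yt)
  eR <- eigen((R0 + t(R0)) / 2, symmetric = TRUE)
  ev <- pmax(eR$values, 1e-10)
  Rih <- eR$vectors %*% (t(eR$vectors) / sqrt(ev))
  M <- Rih %*% G0 %*% Rih
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eM$values, 0)
  Zm <- Yt %*% Rih %*% eM$vectors
  Dk <- outer(d, lam) + 1
  ll <- -0.5 * (n * Tt * log(2 * pi) + n * sum(log(ev)) +
                sum(log(Dk)) + sum(Zm^2 / Dk))
  -2 * ll
}

# effective sample size via initial-positive-sequence autocorrelation sum
ess_chain <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' DIC scan over the number of latent genetic factors
#'
#' Fits the model for each candidate `L` with a common seed schedule and
#' returns the DIC table and the argmin.
#'
#' @param Y,Z,eig as in [run_gibbs()].
#' @param candidates integer vector of latent-factor counts to try.
#' @param ... passed to [run_gibbs()] (chain settings).
#' @param seed base seed; candidate `L` runs with `seed + L`.
#' @return list with `chosen` (L minimizing DIC), `table` (data.frame of L,
#'   DIC, pD) and `fits`.
#' @export
select_n_latent <- function(Y, Z, eig, candidates = 1:2, seed = 1L, ...) {
  fits <- lapply(candidates, function(L)
    run_gibbs(Y, Z, eig, n_latent_g = L, seed = seed + L, ...))
  tab <- data.frame(L = candidates,
                    dic = vapply(fits, function(f) f$dic, 0),
                    p_d = vapply(fits, function(f) f$p_d, 0))
  list(chosen = candidates[which.min(tab$dic)], table = tab, fits = fits)
}

#' The four-model trait rosters
#'
#' Highly dependent variables are never modelled jointly: a ratio trait must
#' not co-occur with both of its components (hepcidin/ferritin with hepcidin
#' and ferritin; TS with iron and TIBC; hepcidin/TS with hepcidin and TS).
#' Model 1 carries the four directly measured biomarkers and supplies most
#' rG rows; models 2-4 supply the hepcidin/ferritin, hepcidin/TS and TS rows
#' respectively.
#'
#' @return named list of four character vectors of trait names.
#' @export
model_suite_config <- function() {
  list(
    model1 = c("hepcidin", "ferritin", "iron", "TIBC",
               "plaque", "IMT", "ABI_rest", "ABI_exercise"),
    model2 = c("hepcidin_ferritin", "iron", "TIBC",
               "plaque", "IMT", "ABI_rest", "ABI_exercise"),
    model3 = c("hepcidin_TS", "ferritin",
               "plaque", "IMT", "ABI_rest", "ABI_exercise"),
    model4 = c("hepcidin", "ferritin", "TS",
               "plaque", "IMT", "ABI_rest", "ABI_exercise")
  )
}

ratio_components <- function() {
  list(hepcidin_ferritin = c("hepcidin", "ferritin"),
       hepcidin_TS = c("hepcidin", "TS"),
       TS = c("iron", "TIBC"))
}

validate_roster <- function(roster) {
  rc <- ratio_components()
  for (ratio in names(rc)) {
    if (ratio %in% roster && all(rc[[ratio]] %in% roster))
      stop("roster includes ratio '", ratio,
           "' together with both components (",
           paste(rc[[ratio]], collapse = ", "), ")")
  }
  invisible(roster)
}

#' Run the four-model Bayesian suite and merge the rG report
#'
#' Fits [run_gibbs()] on each roster of [model_suite_config()] (after
#' checking the ratio-component exclusion) and assembles the merged
#' biomarker-by-outcome genomic-correlation report: hepcidin, ferritin, iron
#' and TIBC rows from model 1, hepcidin/ferritin from model 2, hepcidin/TS
#' from model 3, TS from model 4 — 7 biomarker rows by 4 outcome columns of
#' posterior means, with a matching posterior-SD matrix.
#'
#' @param residuals data.frame of standardized residuals (`sample_id` plus
#'   trait columns covering all roster traits; `NA` allowed).
#' @param eig [eigendecompose()] of the GRM on the same samples.
#' @param rosters list of trait rosters (default [model_suite_config()]).
#' @param ... chain settings passed to [run_gibbs()].
#' @param seed base seed; model `i` runs at `seed + i`.
#' @return list with `fits` (one `posterior_summary` per roster), `rg`
#'   (7 x 4 posterior-mean matrix), `rg_sd`, and `source_model` per row.
#' @export
run_model_suite <- function(residuals, eig, rosters = model_suite_config(),
                            seed = 1L, ...) {
  lapply(rosters, validate_roster)
  Z <- build_design(eig)
  stopifnot(identical(residuals$sample_id, eig$sample_ids))
  fits <- vector("list", length(rosters))
  names(fits) <- names(rosters)
  for (i in seq_along(rosters)) {
    Y <- as.matrix(residuals[rosters[[i]]])
    rownames(Y) <- residuals$sample_id
    fits[[i]] <- run_gibbs(Y, Z, eig, seed = seed + i, ...)
  }
  outcome <- c("plaque", "IMT", "ABI_rest", "ABI_exercise")
  rows <- c(hepcidin = "model1", ferritin = "model1", hepcidin_ferritin = "model2",
            hepcidin_TS = "model3", iron = "model1", TIBC = "model1",
            TS = "model4")
  rows <- rows[names(rows) %in% unlist(lapply(rosters, identity))]
  rg <- matrix(NA_real_, length(rows), length(outcome),
               dimnames = list(names(rows), outcome))
  rg_sd <- rg
  for (b in names(rows)) {
    f <- fits[[rows[[b]]]]
    if (is.null(f) || !(b %in% f$traits)) next
    oc_in <- intersect(outcome, f$traits)
    rg[b, oc_in] <- f$rg_mean[b, oc_in]
    rg_sd[b, oc_in] <- f$rg_sd[b, oc_in]
  }
  list(fits = fits, rg = rg, rg_sd = rg_sd, source_model = rows)
}
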