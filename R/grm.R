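#' Sliding-window LD pruning
#'
#' Within each window of `window` SNPs, advanced by `step`, any pair with
#' squared Pearson correlation of dosages above `r2_max` loses its
#' later-positioned member (the first SNP in file order is kept), repeated
#' until no window contains a violating pair. Deterministic.
#'
#' @param genotypes a `genotype_matrix`; SNPs with zero dosage variance are
#'   removed up front (their correlation is undefined).
#' @param window window size in SNPs (default 100).
#' @param step window advance in SNPs (default 5).
#' @param r2_max squared-correlation threshold (default 0.98, exclusive).
#' @return character vector of retained `snp_id`s, in original order.
#' @export
ld_prune <- function(genotypes, window = 100, step = 5, r2_max = 0.98) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (window < 2) stop("window must be >= 2")
  if (step < 1) stop("step must be >= 1")
  d <- genotypes$dosage
  v <- apply(d, 2, stats::var, na.rm = TRUE)
  keep <- which(!is.na(v) & v > 0)
  m <- ncol(d)
  alive <- logical(m)
  alive[keep] <- TRUE

  # passes of sliding windows over the currently retained SNPs, repeated
  # until a full pass removes nothing (PLINK-style semantics)
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    changed <- FALSE
    s <- 1L
    while (s <= length(idx) - 1L) {
      w <- idx[s:min(s + window - 1L, length(idx))]
      w <- w[alive[w]]
      if (length(w) >= 2) {
        r2 <- suppressWarnings(stats::cor(d[, w, drop = FALSE],
                                          use = "pairwise")^2)
        r2[!is.finite(r2)] <- 0
        # greedy: keep the earliest SNP of each violating pair
        for (a in seq_len(length(w) - 1L)) {
          if (!alive[w[a]]) next
          hit <- which(r2[a, ] > r2_max)
          hit <- hit[hit > a & alive[w[hit]]]
          if (length(hit)) {
            alive[w[hit]] <- FALSE
            changed <- TRUE
          }
        }
      }
      s <- s + step
    }
    if (!changed) break
  }
  genotypes$snp$snp_id[alive]
}

#' Genetic relationship matrix (GRM)
#'
#' GCTA-style genome-wide average standardized cross-product:
#' `A[j,k] = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample frequency of the counted allele. Missing dosages are
#' mean-imputed per SNP (equivalently contribute 0 after centering).
#' Monomorphic SNPs must be removed first (QC does this).
#'
#' @param genotypes a `genotype_matrix` with at least 2 samples.
#' @return Object of class `grm`: list with symmetric matrix `A`,
#'   `sample_ids`, `n_snps_used`.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (nrow(d) < 2) stop("need at least 2 samples")
  p <- allele_freq(d)
  if (any(is.na(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing SNP present; run qc_filter_snps first")
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  A <- tcrossprod(W) / ncol(W)
  A <- (A + t(A)) / 2
  dimnames(A) <- list(genotypes$sample_ids, genotypes$sample_ids)
  structure(list(A = A, sample_ids = genotypes$sample_ids,
                 n_snps_used = ncol(W)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$sample_ids), "samples,", x$n_snps_used, "SNPs\n")
  cat("  mean diagonal:", signif(mean(diag(x$A)), 4), "\n")
  invisible(x)
}

#' Cryptic-relatedness filter
#'
#' Iteratively removes the individual involved in the most pairwise
#' relationships at or above `cutoff` (ties broken by lowest sample index)
#' until no retained pair remains at or above the cutoff.
#'
#' @param grm a `grm`.
#' @param cutoff relationship threshold (default 0.025); retained pairs are
#'   strictly below it.
#' @return character vector of retained sample ids.
#' @export
filter_relatedness <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$A
  rel <- A >= cutoff
  diag(rel) <- FALSE
  alive <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(rel[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    drop <- which.max(deg)  # ties -> lowest index
    alive[drop] <- FALSE
    rel[drop, ] <- FALSE
    rel[, drop] <- FALSE
  }
  grm$sample_ids[alive]
}

#' Subset a GRM to a set of samples
#'
#' @param grm a `grm`.
#' @param sample_ids ids to keep (order preserved as given).
#' @return A `grm` on the subset.
#' @export
subset_grm <- function(grm, sample_ids) {
  idx <- match(sample_ids, grm$sample_ids)
  if (anyNA(idx)) stop("unknown sample id")
  structure(list(A = grm$A[idx, idx, drop = FALSE],
                 sample_ids = grm$sample_ids[idx],
                 n_snps_used = grm$n_snps_used),
            class = "grm")
}

#' Eigendecomposition of a GRM
#'
#' Full spectral decomposition with eigenvalues in descending order;
#' eigenvalues in `[-1e-8, 0)` are clipped to 0 (with a count kept), anything
#' more negative is an error for a matrix that should be PSD up to numerical
#' noise.
#'
#' @param grm a `grm` (or symmetric matrix).
#' @return Object of class `eigen_grm`: `values`, `vectors` (orthonormal
#'   columns), `sample_ids`, `n_clipped`.
#' @export
eigendecompose <- function(grm) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ids <- if (inherits(grm, "grm")) grm$sample_ids else rownames(A)
  if (max(abs(A - t(A))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  neg <- e$values < 0
  if (any(e$values < -1e-8 * max(1, abs(e$values[1]))))
    warning(sum(neg), " eigenvalue(s) below -1e-8 clipped to 0")
  n_clip <- sum(neg)
  e$values[neg] <- 0
  structure(list(values = e$values, vectors = e$vectors,
                 sample_ids = ids, n_clipped = n_clip),
            class = "eigen_grm")
}

#' Write / read a GRM in GCTA binary format
#'
#' `prefix.grm.bin` holds the lower triangle (including diagonal) row by row
#' as float32, `prefix.grm.N.bin` the per-pair SNP counts (float32), and
#' `prefix.grm.id` tab-separated FID/IID pairs. A text TSV sidecar
#' (`prefix.grm.tsv`) is written for inspection.
#'
#' @param grm a `grm`.
#' @param prefix output path prefix.
#' @return `read_gcta_grm` returns a `grm` (float32 round-off applies).
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  lower <- grm$A[upper.tri(grm$A, diag = TRUE)]  # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps_used), length(lower)), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ut <- which(upper.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  utils::write.table(
    data.frame(id1 = grm$sample_ids[ut[, 2]], id2 = grm$sample_ids[ut[, 1]],
               n_snps = grm$n_snps_used, value = lower),
    paste0(prefix, ".grm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  npair <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = npair, size = 4)
  nsnp <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = npair,
                  size = 4)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A))
  structure(list(A = A, sample_ids = ids,
                 n_snps_used = as.integer(round(nsnp[1]))),
            class = "grm")
}
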