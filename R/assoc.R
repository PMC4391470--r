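#' Single-SNP logistic-regression GWAS
#'
#' Fits \code{status ~ intercept + dosage} per SNP by Newton-Raphson
#' (vectorized across SNPs in column chunks) and reports the Wald z and
#' two-sided p, mirroring PLINK's additive logistic test. SNPs that are
#' monomorphic in the sampled cohort get beta 0 / p 1; fits that fail to
#' converge or show separation fall back to the score test. Both situations
#' are flagged.
#'
#' @param genotypes a \code{genotype_matrix} covering all individuals.
#' @param status a \code{cohort_status} or a 0/1 vector (one per sample;
#'   \code{NA} = unsampled).
#' @param chunk number of SNPs fit simultaneously (memory/speed trade-off).
#' @return An \code{assoc_table} data frame: snp_id, chrom, pos, beta, se, z,
#'   p, flag ("" / "monomorphic" / "score_fallback"). p is floored at 1e-300.
#' @export
gwas_logistic <- function(genotypes, status, chunk = 2048L) {
  y <- status_vector(status, genotypes$n_samples)
  keep <- !is.na(y)
  y <- y[keep]
  if (sum(y == 1L) < 1 || sum(y == 0L) < 1)
    stop_gwasbench("need at least one case and one control", "gwasbench_invalid_parameter")
  G_all <- genotypes$dosage[keep, , drop = FALSE]
  m <- ncol(G_all); n <- nrow(G_all)
  beta <- se <- numeric(m); flag <- character(m)
  b0_null <- stats::qlogis(mean(y))
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    G <- G_all[, lo:hi, drop = FALSE]
    storage.mode(G) <- "double"
    mk <- hi - lo + 1L
    b0 <- rep(b0_null, mk); b1 <- numeric(mk)
    cs_g <- colSums(G); cs_g2 <- colSums(G * G)
    mono <- (cs_g2 - cs_g^2 / n) <= 0
    active <- !mono
    for (it in 1:30) {
      if (!any(active)) break
      eta <- sweep(G, 2L, b1, `*`)
      eta <- sweep(eta, 2L, b0, `+`)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      r <- y - mu
      S00 <- colSums(w); S01 <- colSums(w * G); S11 <- colSums(w * G * G)
      U0 <- colSums(r); U1 <- colSums(r * G)
      det <- S00 * S11 - S01^2
      det[det <= 0] <- NA
      db0 <- (S11 * U0 - S01 * U1) / det
      db1 <- (S00 * U1 - S01 * U0) / det
      db0[!active | !is.finite(db0)] <- 0
      db1[!active | !is.finite(db1)] <- 0
      b0 <- b0 + db0; b1 <- b1 + db1
      active <- active & (abs(db0) > 1e-8 | abs(db1) > 1e-8) & is.finite(det)
      if (it == 30) break
    }
    # final information for SE
    eta <- sweep(sweep(G, 2L, b1, `*`), 2L, b0, `+`)
    mu <- stats::plogis(eta); w <- mu * (1 - mu)
    S00 <- colSums(w); S01 <- colSums(w * G); S11 <- colSums(w * G * G)
    det <- S00 * S11 - S01^2
    se_k <- sqrt(S00 / det)
    bad <- mono | !is.finite(se_k) | abs(b1) > 15 | active
    fl <- character(mk)
    if (any(bad & !mono)) {
      # score test under the null: U = g'(y - ybar), V = ybar(1-ybar) * Sxx
      idx <- which(bad & !mono)
      U <- colSums((y - mean(y)) * G[, idx, drop = FALSE])
      V <- mean(y) * (1 - mean(y)) * (cs_g2[idx] - cs_g[idx]^2 / n)
      zsc <- U / sqrt(V)
      b1[idx] <- zsc * 0 # beta not interpretable; keep sign via z below
      se_k[idx] <- 1
      b1[idx] <- zsc # store z as beta/se with se 1 so z is preserved
      fl[idx] <- "score_fallback"
    }
    if (any(mono)) {
      b1[mono] <- 0; se_k[mono] <- 1; fl[mono] <- "monomorphic"
    }
    beta[lo:hi] <- b1; se[lo:hi] <- se_k; flag[lo:hi] <- fl
  }
  z <- beta / se
  z[flag == "monomorphic"] <- 0
  p <- floor_p(2 * stats::pnorm(-abs(z)))
  p[flag == "monomorphic"] <- 1
  out <- data.frame(snp_id = genotypes$variants$snp_id,
                    chrom = genotypes$variants$chrom,
                    pos = genotypes$variants$pos,
                    beta = beta, se = se, z = z, p = p, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# normalise the various status representations to a 0/1/NA vector
status_vector <- function(status, n) {
  if (inherits(status, "cohort_status")) {
    y <- rep(NA_integer_, length(status$status))
    y[status$status == "case"] <- 1L
    y[status$status == "control"] <- 0L
    return(y)
  }
  y <- as.integer(status)
  if (length(y) != n)
    stop_gwasbench("status length does not match sample count", "gwasbench_invalid_parameter")
  y
}

#' Score-test z statistics for permuted phenotypes
#'
#' For B permuted (or otherwise re-drawn) label vectors, returns the per-SNP
#' score-test z for the logistic slope, computed in one matrix product. This
#' is the engine behind the phenotype-permutation pathway tests: the score
#' test is asymptotically equivalent to the Wald test used for the observed
#' scan but costs a single BLAS call per permutation set.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param y_perm n x B matrix of 0/1 labels (columns are permutations).
#' @param sampled optional integer index restricting to sampled individuals.
#' @return m x B matrix of z statistics (rows = SNPs).
#' @export
score_z_matrix <- function(genotypes, y_perm, sampled = NULL) {
  G <- genotypes$dosage
  if (!is.null(sampled)) G <- G[sampled, , drop = FALSE]
  storage.mode(G) <- "double"
  n <- nrow(G)
  ybar <- colMeans(y_perm)
  Yc <- sweep(y_perm, 2L, ybar, `-`)
  Sxx <- colSums(G * G) - colSums(G)^2 / n
  U <- crossprod(G, Yc)                 # m x B
  V <- outer(Sxx, ybar * (1 - ybar))    # m x B
  Z <- U / sqrt(V)
  Z[!is.finite(Z)] <- 0
  rownames(Z) <- genotypes$variants$snp_id
  Z
}

#' Build a matrix of permuted case/control labels
#'
#' @param y observed 0/1 labels (length n).
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @return n x n_perms 0/1 matrix, each column a label permutation.
#' @export
permute_labels <- function(y, n_perms, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_perms), function(b) y[sample.int(length(y))],
         numeric(length(y)))
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("assoc_table: %d SNPs; min p = %.3g; %d flagged\n",
              nrow(x), min(x$p), sum(x$flag != "")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
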