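#' Fisher's combination test
#'
#' Combines m SNP p-values as \code{X = -2 sum log p}, referred to a
#' chi-square with 2m degrees of freedom. Assumes independence, so it
#' inflates under LD.
#'
#' @param p vector of p-values in (0, 1].
#' @return gene-level p-value.
#' @export
fisher_combination <- function(p) {
  check_pvec(p)
  x <- -2 * sum(log(floor_p(p)))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Sidak's combination test
#'
#' \code{1 - (1 - min p)^m}: the minimum SNP p-value corrected for the number
#' of SNPs in the gene.
#'
#' @inheritParams fisher_combination
#' @return gene-level p-value.
#' @export
sidak_min <- function(p) {
  check_pvec(p)
  -expm1(length(p) * log1p(-min(p)))
}

#' Simes' test
#'
#' \code{min over j of m * p_(j) / j} on the sorted p-values.
#'
#' @inheritParams fisher_combination
#' @return gene-level p-value.
#' @export
simes <- function(p) {
  check_pvec(p)
  m <- length(p)
  min(m * sort(p) / seq_len(m))
}

#' Minimum Benjamini-Hochberg adjusted p-value
#'
#' Applies the BH step-up within the gene and returns the smallest adjusted
#' value. Numerically equal to Simes on a plain p vector; reported as its own
#' method because the benchmark treats the FDR reduction as a distinct
#' procedure.
#'
#' @inheritParams fisher_combination
#' @return gene-level p-value.
#' @export
fdr_min <- function(p) {
  check_pvec(p)
  min(stats::p.adjust(p, method = "BH"))
}

#' Truncated product method
#'
#' Multiplies only the p-values at or below \code{tau} and evaluates the tail
#' probability of that truncated product under m independent uniforms with
#' the closed-form sum over the number of truncated terms. An empty product
#' (no p below tau) gives gene p 1. At \code{tau = 1} the statistic is the
#' full Fisher product.
#'
#' @inheritParams fisher_combination
#' @param tau truncation threshold in (0, 1].
#' @return gene-level p-value.
#' @export
tpm <- function(p, tau = 0.1) {
  check_pvec(p)
  if (tau <= 0 || tau > 1) stop_gwasbench("tau must lie in (0, 1]", "gwasbench_invalid_parameter")
  m <- length(p)
  sel <- p <= tau
  if (!any(sel)) return(1)
  logw <- sum(log(floor_p(p[sel])))
  # P(W <= w) = sum_k C(m,k) (1-tau)^(m-k) *
  #   { w * sum_{s<k} (k ln tau - ln w)^s / s!   if w <= tau^k
  #     tau^k                                    otherwise }
  total <- 0
  for (k in seq_len(m)) {
    lchoose_k <- lchoose(m, k)
    lt <- if (k == m) 0 else (m - k) * log1p(-tau) # -Inf at tau = 1 kills k < m
    if (logw <= k * log(tau)) {
      a <- k * log(tau) - logw
      s <- 0:(k - 1)
      lterms <- logw + s * log(a) - lgamma(s + 1)
      mx <- max(lterms)
      lsum <- mx + log(sum(exp(lterms - mx)))
      total <- total + exp(lchoose_k + lt + lsum)
    } else {
      total <- total + exp(lchoose_k + lt + k * log(tau))
    }
  }
  min(total, 1)
}

#' Monte-Carlo reference for the truncated product method
#'
#' Simulates the truncated-product statistic under m independent uniforms;
#' used to cross-check the closed form.
#'
#' @inheritParams tpm
#' @param n_sims number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return empirical gene-level p-value (with +1/+1 correction).
#' @export
tpm_mc <- function(p, tau = 0.1, n_sims = 1e5, seed = 1) {
  check_pvec(p)
  m <- length(p)
  sel <- p <= tau
  logw <- if (any(sel)) sum(log(p[sel])) else 0
  set.seed(seed)
  u <- matrix(stats::runif(n_sims * m), n_sims, m)
  lu <- log(u) * (u <= tau)
  logw_sim <- rowSums(lu)
  (1 + sum(logw_sim <= logw)) / (1 + n_sims)
}

# GATES core: extended Simes with effective test counts from the p-value
# correlation matrix. Returns the gene p and the index (into the original
# order) of the SNP attaining the minimum ("key SNP", needed by HYST).
gates_core <- function(p, rho) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  rho_s <- rho[o, o, drop = FALSE]
  me_j <- vapply(seq_len(m), function(j)
    effective_tests(rho_s[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  me_m <- me_j[m]
  vals <- me_m * ps / me_j
  j_star <- which.min(vals)
  list(p = min(min(vals), 1), key = o[j_star], m_e = me_m)
}

#' GATES gene-based test
#'
#' Extended Simes procedure: sorted SNP p-values are weighted by the ratio of
#' the effective number of tests among all m SNPs to the effective number
#' among the top j, with effective counts derived from the p-value
#' correlation matrix implied by LD. Reduces to Simes under independence.
#'
#' @param p vector of SNP p-values (position order).
#' @param ld LD (genotype Pearson r) matrix for the same SNPs; may be omitted
#'   when there is a single SNP.
#' @param weights optional non-negative per-SNP weights (normalized to mean
#'   1); p-values are divided by the weights before sorting.
#' @return gene-level p-value.
#' @export
gates <- function(p, ld = NULL, weights = NULL) {
  check_pvec(p)
  m <- length(p)
  if (m == 1L) return(unname(p))
  if (is.null(ld)) stop_gwasbench("ld matrix required for m > 1", "gwasbench_invalid_parameter")
  if (!is.null(weights)) {
    if (any(weights < 0)) stop_gwasbench("weights must be non-negative", "gwasbench_invalid_parameter")
    w <- weights / mean(weights)
    p <- pmin(p / w, 1)
  }
  rho <- pvalue_correlation(ld)
  gates_core(p, rho)$p
}

#' Weighted GATES
#'
#' [gates()] with per-SNP weights; uniform weights reproduce the unweighted
#' test exactly.
#'
#' @inheritParams gates
#' @export
weighted_gates <- function(p, ld = NULL, weights = rep(1, length(p))) {
  gates(p, ld, weights = weights)
}

# Brown-style combination of per-block key p-values given the p-value
# correlation between key SNPs. Independence gives c = 1, f = 2B (Fisher).
brown_combine <- function(p_blocks, rho_keys) {
  B <- length(p_blocks)
  x <- -2 * sum(log(floor_p(p_blocks)))
  if (B == 1L) return(unname(p_blocks))
  E <- 2 * B
  rr <- rho_keys[upper.tri(rho_keys)]
  rr <- pmax(rr, 0)
  V <- 4 * B + 2 * sum(rr * (3.25 + 0.75 * rr))
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  stats::pchisq(x / cc, df = f, lower.tail = FALSE)
}

#' HYST gene-based test
#'
#' Hybrid set-based test: the gene is partitioned into contiguous LD blocks,
#' each block contributes its GATES p-value and key SNP, and the block
#' p-values are combined with a Brown-style scaled chi-square whose scale and
#' degrees of freedom match the mean and variance implied by the between-block
#' key-SNP p-value correlations. With a single block this is exactly the
#' block's GATES p; with independent blocks it is Fisher over block p-values.
#'
#' @inheritParams gates
#' @param block_threshold r-squared threshold for the block partition.
#' @return gene-level p-value.
#' @export
hyst_gene <- function(p, ld = NULL, weights = NULL, block_threshold = 0.3) {
  check_pvec(p)
  m <- length(p)
  if (m == 1L) return(unname(p))
  if (is.null(ld)) stop_gwasbench("ld matrix required for m > 1", "gwasbench_invalid_parameter")
  if (!is.null(weights)) {
    if (any(weights < 0)) stop_gwasbench("weights must be non-negative", "gwasbench_invalid_parameter")
    w <- weights / mean(weights)
    p <- pmin(p / w, 1)
  }
  blk <- ld_blocks(ld^2, threshold = block_threshold)
  rho <- pvalue_correlation(ld)
  p_blocks <- numeric(max(blk)); keys <- integer(max(blk))
  for (b in seq_len(max(blk))) {
    idx <- which(blk == b)
    if (length(idx) == 1L) {
      p_blocks[b] <- p[idx]; keys[b] <- idx
    } else {
      g <- gates_core(p[idx], rho[idx, idx, drop = FALSE])
      p_blocks[b] <- g$p; keys[b] <- idx[g$key]
    }
  }
  brown_combine(p_blocks, rho[keys, keys, drop = FALSE])
}

#' VEGAS gene-based test
#'
#' Converts SNP p-values to 1-df chi-squares, sums the k largest (k =
#' \code{ceil(top_fraction * m)}, floored at 1), and estimates the gene
#' p-value by simulating the same statistic from multivariate normal draws
#' with the gene's LD correlation matrix (ridge-stabilized before the
#' Cholesky factorization). The empirical p uses the +1/+1 correction and so
#' never returns 0.
#'
#' @inheritParams gates
#' @param top_fraction fraction of top SNPs entering the sum (1 = all SNPs,
#'   0.1 = the "top 10 percent" variant).
#' @param n_sims number of null simulations (>= 100).
#' @param seed integer seed.
#' @param ridge diagonal stabilizer added before factorization.
#' @return gene-level p-value.
#' @export
vegas <- function(p, ld = NULL, top_fraction = 1, n_sims = 1000, seed = 1,
                  ridge = 1e-6) {
  check_pvec(p)
  if (n_sims < 100) stop_gwasbench("n_sims must be >= 100", "gwasbench_invalid_parameter")
  if (top_fraction <= 0 || top_fraction > 1)
    stop_gwasbench("top_fraction must lie in (0, 1]", "gwasbench_invalid_parameter")
  m <- length(p)
  if (m > 1L && is.null(ld)) stop_gwasbench("ld matrix required for m > 1", "gwasbench_invalid_parameter")
  chi_obs <- stats::qchisq(floor_p(p), df = 1, lower.tail = FALSE)
  k <- max(1L, as.integer(ceiling(top_fraction * m)))
  t_obs <- sum(sort(chi_obs, decreasing = TRUE)[seq_len(k)])
  set.seed(seed)
  if (m == 1L) {
    chi_sim <- matrix(stats::rnorm(n_sims)^2, ncol = 1)
  } else {
    R <- ld + diag(ridge, m)
    C <- tryCatch(chol(R), error = function(e)
      stop_gwasbench("LD matrix not factorizable after ridge stabilization",
                     "gwasbench_numeric_error"))
    chi_sim <- (matrix(stats::rnorm(n_sims * m), n_sims, m) %*% C)^2
  }
  t_sim <- if (k == m) rowSums(chi_sim) else if (k == 1L)
    do.call(pmax, as.data.frame(chi_sim))
  else
    apply(chi_sim, 1L, function(r) sum(sort(r, decreasing = TRUE)[seq_len(k)]))
  (1 + sum(t_sim >= t_obs)) / (1 + n_sims)
}

# ---------------------------------------------------------------------------

#' Run the gene-level method panel
#'
#' Builds one SNP set per gene (p-values from the association scan, LD from
#' the cohort genotypes) and applies the requested gene-level tests.
#'
#' @param assoc an \code{assoc_table}.
#' @param genotypes the \code{genotype_matrix} used for LD estimation
#'   (cohort-subset recommended).
#' @param genes gene annotation.
#' @param methods character vector out of \code{"fisher", "sidak", "simes",
#'   "fdr", "tpm", "gates", "wgates", "hyst", "whyst", "vegas", "vegas10"}.
#' @param weights optional named list gene_id -> per-SNP weight vector for
#'   the weighted variants (default uniform).
#' @param tau truncation threshold for the TPM.
#' @param n_sims VEGAS simulation count per gene.
#' @param flank_bp flank; defaults to the annotation attribute.
#' @param seed integer seed (VEGAS).
#' @return A \code{gene_result} data frame: one row per gene with a p-value
#'   column per method, plus n_snps. Genes with no SNPs are dropped.
#' @export
gene_tests <- function(assoc, genotypes, genes,
                       methods = c("fisher", "sidak", "simes", "fdr", "tpm",
                                   "gates", "wgates", "hyst", "whyst",
                                   "vegas", "vegas10"),
                       weights = NULL, tau = 0.1, n_sims = 1000,
                       flank_bp = NULL, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  map <- snps_by_gene(genotypes$variants, genes, flank_bp)
  keep <- vapply(map, length, integer(1)) > 0
  map <- map[keep]
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  needs_ld <- any(methods %in% c("gates", "wgates", "hyst", "whyst", "vegas", "vegas10"))
  res <- matrix(NA_real_, length(map), length(methods),
                dimnames = list(names(map), methods))
  n_snps <- integer(length(map))
  for (i in seq_along(map)) {
    idx <- map[[i]]
    ids <- genotypes$variants$snp_id[idx]
    p <- unname(p_all[ids])
    ok <- !is.na(p)
    p <- p[ok]; idx <- idx[ok]
    n_snps[i] <- length(p)
    if (!length(p)) next
    ld <- NULL
    if (needs_ld && length(p) > 1L)
      ld <- ld_r(genotypes, idx)
    w <- weights[[names(map)[i]]]
    for (mth in methods) {
      res[i, mth] <- switch(mth,
        fisher = fisher_combination(p),
        sidak = sidak_min(p),
        simes = simes(p),
        fdr = fdr_min(p),
        tpm = tpm(p, tau = tau),
        gates = gates(p, ld),
        wgates = if (length(p) == 1L) p else weighted_gates(p, ld, w %||% rep(1, length(p))),
        hyst = hyst_gene(p, ld),
        whyst = if (length(p) == 1L) p else hyst_gene(p, ld, weights = w %||% rep(1, length(p))),
        vegas = vegas(p, ld, top_fraction = 1, n_sims = n_sims,
                      seed = derive_seed(seed, paste0("vegas_", names(map)[i]))),
        vegas10 = vegas(p, ld, top_fraction = 0.1, n_sims = n_sims,
                        seed = derive_seed(seed, paste0("vegas10_", names(map)[i]))))
    }
  }
  out <- data.frame(gene_id = names(map), n_snps = n_snps, res,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_result", "data.frame")
  attr(out, "params") <- list(tau = tau, n_sims = n_sims, methods = methods)
  out
}
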