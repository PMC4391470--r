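#' Pairwise LD (Pearson r) between SNP dosage columns
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param snp_ids SNP ids (or column indices) to include; default all.
#' @return symmetric correlation matrix with unit diagonal and SNP ids as
#'   dimnames; zero-variance SNPs get correlation 0 to all others and are
#'   listed in the \code{"monomorphic"} attribute.
#' @export
ld_r <- function(genotypes, snp_ids = NULL) {
  dos <- genotypes$dosage
  if (!is.null(snp_ids)) dos <- dos[, snp_ids, drop = FALSE]
  if (nrow(dos) < 2) stop_gwasbench("need >= 2 samples for LD", "gwasbench_invalid_parameter")
  v <- apply(dos, 2, stats::var)
  r <- suppressWarnings(stats::cor(dos))
  bad <- which(v == 0)
  if (length(bad)) {
    r[bad, ] <- 0; r[, bad] <- 0
  }
  diag(r) <- 1
  attr(r, "monomorphic") <- colnames(dos)[bad]
  r
}

#' Map genotype correlations to p-value correlations
#'
#' Sixth-degree polynomial approximation relating the Pearson correlation of
#' two SNPs' genotypes to the correlation of their association p-values, used
#' by the extended-Simes (GATES) family. The diagonal is forced to 1.
#'
#' @param r LD matrix (or any numeric array of correlations).
#' @return matrix of p-value correlations.
#' @export
pvalue_correlation <- function(r) {
  rho <- 0.2982 * r^6 - 0.0127 * r^5 + 0.0588 * r^4 +
    0.0099 * r^3 + 0.6281 * r^2 - 0.0009 * r
  if (is.matrix(rho)) diag(rho) <- 1
  rho
}

#' Effective number of independent tests
#'
#' Eigenvalue-based count: \code{m_e = m - sum over i of (lambda_i - 1) for
#' lambda_i > 1}, computed on a p-value correlation matrix.
#'
#' @param rho square symmetric correlation matrix.
#' @return a real number in [1, m].
#' @export
effective_tests <- function(rho) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop_gwasbench("rho must be a square matrix", "gwasbench_invalid_parameter")
  m <- nrow(rho)
  if (m == 1L) return(1)
  lambda <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  m - sum(pmax(lambda - 1, 0))
}

#' Greedy LD pruning
#'
#' Scans SNPs in the given priority order and keeps a SNP iff its r-squared
#' with every already-kept SNP is at most \code{threshold}. The priority is
#' positional for design-time pruning and ascending p for set tests.
#'
#' @param r2 square matrix of pairwise r-squared values.
#' @param threshold keep threshold in (0, 1].
#' @param priority integer order in which SNPs are considered.
#' @return integer indices of kept SNPs, in priority order.
#' @export
greedy_prune <- function(r2, threshold = 0.2, priority = seq_len(nrow(r2))) {
  if (threshold <= 0 || threshold > 1)
    stop_gwasbench("threshold must lie in (0, 1]", "gwasbench_invalid_parameter")
  kept <- integer(0)
  for (j in priority) {
    if (!length(kept) || all(r2[j, kept] <= threshold)) kept <- c(kept, j)
  }
  kept
}

#' Contiguous LD-block partition
#'
#' Greedy left-to-right scan over position-ordered SNPs: the current block is
#' extended while the incoming SNP has r-squared above \code{threshold} with
#' any SNP already in the block, otherwise a new block starts.
#'
#' @param r2 square matrix of pairwise r-squared values (position order).
#' @param threshold block-extension threshold (default 0.3).
#' @return integer vector of block labels (1, 2, ...), one per SNP.
#' @export
ld_blocks <- function(r2, threshold = 0.3) {
  m <- nrow(r2)
  if (m == 0L) return(integer(0))
  blk <- integer(m)
  blk[1] <- 1L
  start <- 1L
  for (j in seq_len(m)[-1]) {
    if (any(r2[j, start:(j - 1L)] > threshold)) blk[j] <- blk[j - 1L]
    else { blk[j] <- blk[j - 1L] + 1L; start <- j }
  }
  blk
}
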