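#' Simulate LD-structured SNP genotypes
#'
#' Draws biallelic autosomal genotypes for unrelated individuals under a
#' latent-Gaussian haplotype model. SNPs are organised in LD blocks; within a
#' block the latent Gaussian follows an AR(1) process with parameter
#' \code{rho}, and each haplotype carries the minor allele where the latent
#' value falls below the MAF quantile. Two independent haplotype draws are
#' summed per person, so Hardy-Weinberg equilibrium holds by construction and
#' dosages count minor alleles (0/1/2).
#'
#' @param n_samples number of individuals (>= 2).
#' @param n_snps total number of SNPs across the genome.
#' @param block_sizes integer vector of LD-block sizes to sample from; a
#'   single value gives fixed-size blocks.
#' @param rho within-block AR(1) latent correlation, in [0, 1).
#' @param maf_range interval from which per-SNP minor allele frequencies are
#'   drawn uniformly; must lie within (0, 0.5].
#' @param n_chrom number of chromosomes the SNPs are split across.
#' @param spacing_bp mean base-pair spacing between adjacent SNPs.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return A \code{genotype_matrix}: list with \code{variants} (data frame of
#'   snp_id, chrom, pos, allele_minor, allele_major, maf, block) and
#'   \code{dosage} (n_samples x n_snps integer matrix, columns named by SNP).
#' @export
generate_genotypes <- function(n_samples, n_snps,
                               block_sizes = c(2:12),
                               rho = 0.8,
                               maf_range = c(0.05, 0.5),
                               n_chrom = 4,
                               spacing_bp = 3000,
                               seed = 1) {
  if (n_samples < 2) stop_gwasbench("n_samples must be >= 2", "gwasbench_invalid_parameter")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop_gwasbench("rho must lie in [0, 1)", "gwasbench_invalid_parameter")
  if (length(block_sizes) < 1L || any(block_sizes < 1))
    stop_gwasbench("block_sizes must be a non-empty vector of positive sizes",
                   "gwasbench_invalid_parameter")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_gwasbench("maf_range must lie within (0, 0.5]", "gwasbench_invalid_parameter")
  set.seed(seed)

  # carve n_snps into blocks
  sizes <- integer(0)
  while (sum(sizes) < n_snps)
    sizes <- c(sizes, sample_from(block_sizes, max(16L, ceiling(n_snps / mean(block_sizes) / 4))))
  sizes <- sizes[cumsum(sizes) - sizes < n_snps]
  sizes[length(sizes)] <- n_snps - sum(sizes[-length(sizes)])
  block <- rep(seq_along(sizes), sizes)

  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  # chromosome boundaries fall on block edges so LD never spans chromosomes
  first_of_block <- !duplicated(block)
  chrom_of_block <- ceiling(seq_along(sizes) / (length(sizes) / n_chrom))
  chrom <- chrom_of_block[block]
  pos <- integer(n_snps)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    gaps <- pmax(1L, as.integer(round(stats::runif(length(idx), 0.5, 1.5) * spacing_bp)))
    pos[idx] <- cumsum(gaps)
  }

  alleles <- c("A", "C", "G", "T")
  a_pair <- replicate(n_snps, sample(alleles, 2L))
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = as.integer(chrom),
    pos = pos,
    allele_minor = a_pair[1L, ],
    allele_major = a_pair[2L, ],
    maf = maf,
    block = block,
    stringsAsFactors = FALSE
  )

  thresh <- stats::qnorm(maf)
  dos <- matrix(0L, n_samples, n_snps)
  new_block <- first_of_block
  sq <- sqrt(1 - rho^2)
  for (hap in 1:2) {
    z <- stats::rnorm(n_samples)
    for (j in seq_len(n_snps)) {
      e <- stats::rnorm(n_samples)
      z <- if (new_block[j]) e else rho * z + sq * e
      dos[, j] <- dos[, j] + (z < thresh[j])
    }
  }
  colnames(dos) <- variants$snp_id

  structure(list(variants = variants, dosage = dos, n_samples = n_samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              x$n_samples, nrow(x$variants), length(unique(x$variants$chrom))))
  cat(sprintf("  MAF range %.3f-%.3f, %d LD blocks\n",
              min(x$variants$maf), max(x$variants$maf),
              length(unique(x$variants$block))))
  invisible(x)
}

#' Subset a genotype matrix to a sample index
#' @param gt a \code{genotype_matrix}
#' @param samples integer or logical index over rows
#' @return a \code{genotype_matrix} for the selected samples
#' @export
subset_samples <- function(gt, samples) {
  stopifnot(inherits(gt, "genotype_matrix"))
  dos <- gt$dosage[samples, , drop = FALSE]
  structure(list(variants = gt$variants, dosage = dos, n_samples = nrow(dos)),
            class = "genotype_matrix")
}
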