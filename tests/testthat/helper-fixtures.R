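# Shared fixture builders. Everything is generated in code at test time.

# small end-to-end simulation used by several files
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gt <- generate_genotypes(400, 2000, block_sizes = 5, rho = 0.8, seed = 3)
    genes <- generate_annotation(gt$variants, gene_size_spec = 40000,
                                 gap_spec = 50000, seed = 2)
    pw <- generate_pathways(genes, n_large = 3, n_small = 3,
                            large_sizes = 8:10, small_sizes = 3:5,
                            causal_classes = c(single = 1, frac20 = 1, frac50 = 1),
                            seed = 4)
    des <- select_causal_snps(gt, genes, pw, seed = 5)
    sc <- liability_scores(gt, des)
    y <- assign_status(sc, 0.5, seed = 6)
    coh <- sample_cohort(y, "balanced_cc", n_cases = 150, seed = 7)
    assoc <- gwas_logistic(gt, coh)
    cache <<- list(gt = gt, genes = genes, pw = pw, des = des, sc = sc,
                   y = y, coh = coh, assoc = assoc,
                   gt_cohort = subset_samples(gt, coh$sampled),
                   y_cohort = ifelse(coh$status[coh$sampled] == "case", 1L, 0L))
    cache
  }
})

# an assoc_table built directly from a p-value vector (for oracle toys)
toy_assoc <- function(p, chrom = 1L, pos = seq_along(p) * 1000L) {
  out <- data.frame(snp_id = sprintf("s%03d", seq_along(p)), chrom = chrom,
                    pos = pos, beta = 0, se = 1,
                    z = -stats::qnorm(p / 2), p = p, flag = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# genotype_matrix wrapper around an explicit dosage matrix
toy_genotypes <- function(dos, chrom = 1L, pos = seq_len(ncol(dos)) * 1000L) {
  m <- ncol(dos)
  colnames(dos) <- sprintf("s%03d", seq_len(m))
  variants <- data.frame(snp_id = colnames(dos), chrom = chrom, pos = pos,
                         allele_minor = "A", allele_major = "G",
                         maf = pmax(colMeans(dos) / 2, 1e-3), block = 1L,
                         stringsAsFactors = FALSE)
  structure(list(variants = variants, dosage = dos, n_samples = nrow(dos)),
            class = "genotype_matrix")
}

# one gene per SNP, no flank: lets oracle toys control the SNP-gene map
one_snp_genes <- function(variants) {
  genes <- data.frame(gene_id = paste0("g_", variants$snp_id),
                      chrom = variants$chrom,
                      start = variants$pos, end = variants$pos,
                      stringsAsFactors = FALSE)
  attr(genes, "flank_bp") <- 0
  genes
}

# pathway_collection from a plain named list of gene-id vectors
toy_pathways <- function(sets, size_class = NULL) {
  if (is.null(size_class)) size_class <- rep("large", length(sets))
  info <- data.frame(name = names(sets), size = lengths(sets),
                     size_class = size_class,
                     causal_class = NA_character_, n_causal = NA_integer_,
                     stringsAsFactors = FALSE)
  structure(list(sets = sets,
                 causal = stats::setNames(vector("list", length(sets)), names(sets)),
                 info = info),
            class = "pathway_collection")
}
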