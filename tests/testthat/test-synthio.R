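test_that("genotype generator respects independence, determinism and MAF targets", {
  # independence case: rho = 0 gives near-zero off-diagonal genotype r^2
  gt0 <- generate_genotypes(600, 100, block_sizes = 10, rho = 0, seed = 1)
  r <- stats::cor(gt0$dosage)
  off <- r[upper.tri(r)]
  expect_lt(abs(mean(off^2) - 1 / (600 - 1)), 3 * stats::sd(off^2) / sqrt(length(off)) + 2e-3)
  expect_true(all(gt0$dosage %in% 0:2))

  # strong LD: adjacent-pair genotype correlation is high
  gt9 <- generate_genotypes(5000, 10, block_sizes = 10, rho = 0.95,
                            maf_range = c(0.3, 0.3), seed = 2)
  adj <- vapply(1:9, function(j) stats::cor(gt9$dosage[, j], gt9$dosage[, j + 1]),
                numeric(1))
  expect_gt(mean(adj), 0.5)

  # determinism: same seed -> identical matrices
  a <- generate_genotypes(50, 60, block_sizes = 5, rho = 0.5, seed = 7)
  b <- generate_genotypes(50, 60, block_sizes = 5, rho = 0.5, seed = 7)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$variants, b$variants)
  d <- generate_genotypes(50, 60, block_sizes = 5, rho = 0.5, seed = 8)
  expect_false(identical(a$dosage, d$dosage))

  # empirical MAF tracks the nominal MAF (3 binomial SE, allowing the
  # expected ~0.3% of SNPs outside the band)
  gt <- generate_genotypes(1000, 500, block_sizes = 5, rho = 0.6, seed = 3)
  emp <- colMeans(gt$dosage) / 2
  se <- sqrt(gt$variants$maf * (1 - gt$variants$maf) / (2 * 1000))
  expect_gt(mean(abs(emp - gt$variants$maf) <= 3 * se), 0.98)

  # positions strictly increasing within chromosome
  v <- gt$variants
  for (cc in unique(v$chrom)) expect_true(all(diff(v$pos[v$chrom == cc]) > 0))

  expect_error(generate_genotypes(1, 10), class = "gwasbench_invalid_parameter")
  expect_error(generate_genotypes(10, 10, rho = 1), class = "gwasbench_invalid_parameter")
  expect_error(generate_genotypes(10, 10, block_sizes = integer(0)),
               class = "gwasbench_invalid_parameter")
})

test_that("annotation tiles chromosomes and each flanked span captures SNPs", {
  # 100 evenly spaced SNPs on one chromosome; 5 equal genes each catch >= 20
  variants <- data.frame(snp_id = sprintf("s%03d", 1:100), chrom = 1L,
                         pos = seq(1000, by = 1000, length.out = 100),
                         allele_minor = "A", allele_major = "G",
                         maf = 0.3, block = 1L, stringsAsFactors = FALSE)
  genes <- generate_annotation(variants, gene_size_spec = 19000, gap_spec = 1000,
                               flank_bp = 20000, seed = 1)
  expect_gte(nrow(genes), 5)
  map <- snps_by_gene(variants, genes)
  expect_true(all(vapply(map, length, integer(1)) >= 20))
  expect_true(all(genes$end >= genes$start))

  # zero genes requested
  g0 <- generate_annotation(variants, n_genes = 0, seed = 1)
  expect_identical(nrow(g0), 0L)

  # incompatible spacing errors and names the chromosome
  sparse <- variants[c(1, 100), ]
  cond <- expect_error(
    generate_annotation(sparse, gene_size_spec = 100, gap_spec = 100,
                        flank_bp = 10, seed = 1),
    class = "gwasbench_generation_error")
  expect_match(conditionMessage(cond), "chromosome 1")
})

test_that("pathway design realizes the 1-gene/20%/50% architecture per size class", {
  sim <- small_sim()
  gt_big <- generate_genotypes(50, 6000, block_sizes = 5, rho = 0.7, seed = 11)
  genes <- generate_annotation(gt_big$variants, gene_size_spec = 30000,
                               gap_spec = 30000, seed = 12)
  pw <- generate_pathways(genes, seed = 13)
  expect_length(pw$sets, 20)
  info <- pw$info
  expect_identical(sum(info$size_class == "large"), 10L)
  expect_identical(sum(info$size_class == "small"), 10L)
  for (cls in c("large", "small")) {
    tab <- table(info$causal_class[info$size_class == cls])
    expect_identical(as.integer(tab[c("single", "frac20", "frac50")]),
                     c(4L, 4L, 2L))
  }
  expect_true(all(info$size[info$size_class == "large"] > 28))
  expect_true(all(info$size[info$size_class == "small"] <= 28))
  # single-gene pathways carry exactly one causal gene; fractions use ceiling
  expect_true(all(info$n_causal[info$causal_class == "single"] == 1L))
  expect_identical(info$n_causal[info$causal_class == "frac20"],
                   pmax(1L, as.integer(ceiling(0.2 * info$size[info$causal_class == "frac20"]))))
  # causal genes unique across pathways, all members resolve to gene models
  expect_false(anyDuplicated(unlist(pw$causal)) > 0)
  expect_true(all(unlist(pw$sets) %in% genes$gene_id))

  # single pathway request
  p1 <- generate_pathways(genes, n_large = 0, n_small = 1, seed = 4)
  expect_length(p1$sets, 1)

  # infeasible design errors with required vs available
  few <- genes[1:5, ]
  cond <- expect_error(generate_pathways(few, seed = 1),
                       class = "gwasbench_design_error")
  expect_match(conditionMessage(cond), "required")
})

test_that("causal SNP selection enforces LD independence and the even OR split", {
  sim <- small_sim()
  des <- sim$des
  # every causal SNP lies in its gene's flanked span
  map <- snps_by_gene(sim$gt$variants, sim$genes)
  for (i in seq_len(nrow(des$snps))) {
    idx <- map[[des$snps$gene_id[i]]]
    expect_true(des$snps$snp_id[i] %in% sim$gt$variants$snp_id[idx])
  }
  # within a gene all causal SNPs share the gene OR and have pairwise r2 <= 0.2
  for (g in unique(des$snps$gene_id)) {
    sn <- des$snps[des$snps$gene_id == g, ]
    expect_length(unique(sn$odds_ratio), 1)
    if (nrow(sn) > 1) {
      r2 <- stats::cor(sim$gt$dosage[, sn$snp_id])^2
      expect_true(all(r2[upper.tri(r2)] <= 0.2 + 1e-12))
    }
  }
  # causal-SNP counts drawn from {1,2,5}
  expect_true(all(des$genes$n_snps %in% c(1L, 2L, 5L)))
  # even OR split with the extra gene at the larger effect
  tab <- table(des$genes$odds_ratio)
  expect_true(abs(tab[["1.2"]] - tab[["2"]]) <= 1)
  if (sum(tab) %% 2 == 1) expect_gt(tab[["2"]], tab[["1.2"]])
  # no causal gene in two causal lists
  expect_false(anyDuplicated(des$genes$gene_id) > 0)
  # determinism
  des2 <- select_causal_snps(sim$gt, sim$genes, sim$pw, seed = 5)
  expect_identical(des, des2)

  # degenerate LD: a gene whose SNPs are all in perfect LD cannot host 2 SNPs
  dup <- matrix(rep(rbinom(60, 2, 0.4), 4), ncol = 4)
  gtd <- toy_genotypes(dup)
  genes1 <- data.frame(gene_id = "gA", chrom = 1L, start = 1L, end = 5000L)
  attr(genes1, "flank_bp") <- 0
  pwd <- toy_pathways(list(P1 = "gA"))
  pwd$causal$P1 <- "gA"
  expect_error(
    select_causal_snps(gtd, genes1, pwd, n_snp_choices = 2L, n_snp_probs = 1,
                       seed = 1),
    class = "gwasbench_design_infeasible")
  # r2_max = 1 keeps all SNPs, so the same request succeeds
  ok <- select_causal_snps(gtd, genes1, pwd, r2_max = 1, n_snp_choices = 2L,
                           n_snp_probs = 1, seed = 1)
  expect_identical(nrow(ok$snps), 2L)
})

test_that("plink/BED/GMT writers round-trip", {
  gt <- generate_genotypes(30, 25, block_sizes = 5, rho = 0.5, seed = 21)
  tmp <- withr::local_tempdir()
  # ped/map
  write_plink_ped(gt, file.path(tmp, "toy"))
  rt <- read_plink_ped(file.path(tmp, "toy"))
  expect_identical(unname(rt$genotypes$dosage), unname(gt$dosage))
  expect_identical(rt$genotypes$variants$pos, gt$variants$pos)
  # tped/tfam with phenotype column
  y <- assign_status(rnorm(30), 0.5, seed = 1)
  coh <- sample_cohort(y, "case_cohort", seed = 2)
  write_plink_tped(gt, file.path(tmp, "toy2"), status = coh)
  rt2 <- read_plink_tped(file.path(tmp, "toy2"))
  expect_identical(unname(rt2$genotypes$dosage), unname(gt$dosage))
  expect_identical(as.integer(rt2$pheno), as.integer(y) + 1L)
  # BED round trip (0-based half-open on disk, 1-based inclusive in memory)
  genes <- generate_annotation(gt$variants, gene_size_spec = 20000,
                               gap_spec = 10000, seed = 3)
  write_bed(genes, file.path(tmp, "genes.bed"))
  genes_rt <- read_bed(file.path(tmp, "genes.bed"))
  expect_identical(genes_rt$start, genes$start)
  expect_identical(genes_rt$end, genes$end)
  expect_identical(genes_rt$gene_id, genes$gene_id)
  # GMT round trip
  pw <- toy_pathways(list(A = c("g1", "g2", "g3"), B = c("g2", "g4")),
                     size_class = c("large", "small"))
  write_gmt(pw, file.path(tmp, "sets.gmt"))
  pw_rt <- read_gmt(file.path(tmp, "sets.gmt"))
  expect_identical(pw_rt$sets, pw$sets)
  expect_identical(pw_rt$info$size_class, pw$info$size_class)
  # assoc TSV round trip (PLINK dialect)
  sim <- small_sim()
  write_assoc(sim$assoc, file.path(tmp, "assoc.tsv"))
  a_rt <- read_assoc(file.path(tmp, "assoc.tsv"))
  expect_equal(a_rt$p, sim$assoc$p, tolerance = 1e-6)
  expect_equal(a_rt$beta, sim$assoc$beta, tolerance = 1e-6)
  # minimal dialect
  utils::write.table(data.frame(snp_id = "s1", chrom = 1, pos = 10,
                                beta = 0.5, p = 0.01),
                     file.path(tmp, "mini.tsv"), row.names = FALSE, sep = "\t",
                     quote = FALSE)
  mini <- read_assoc(file.path(tmp, "mini.tsv"))
  expect_s3_class(mini, "assoc_table")
  expect_equal(mini$p, 0.01)
})
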