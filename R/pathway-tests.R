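#' Per-gene summary scores and confounders
#'
#' Collapses the association scan to one row per gene: best SNP p, k-th
#' smallest SNP p, their -log transforms, the largest 1-df chi-square, and
#' the confounders used by confounder-corrected enrichment (gene span in kb,
#' SNP count, number of LD-independent SNPs at r-squared <= 0.2).
#'
#' @param assoc an \code{assoc_table}.
#' @param genotypes the cohort \code{genotype_matrix} (for LD).
#' @param genes gene annotation.
#' @param k which order statistic the "k-th best p" score uses (default 2;
#'   genes with fewer SNPs use their last order statistic).
#' @param flank_bp flank; defaults to the annotation attribute.
#' @return A \code{gene_score_table} data frame: gene_id, best_p, kth_p,
#'   score_best (-log best_p), score_k (-log kth_p), max_chi2, span_kb,
#'   n_snps, n_indep.
#' @export
gene_scores <- function(assoc, genotypes, genes, k = 2, flank_bp = NULL) {
  map <- snps_by_gene(genotypes$variants, genes, flank_bp)
  keep <- vapply(map, length, integer(1)) > 0
  map <- map[keep]
  gmeta <- genes[match(names(map), genes$gene_id), ]
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  rows <- lapply(seq_along(map), function(i) {
    idx <- map[[i]]
    p <- unname(p_all[genotypes$variants$snp_id[idx]])
    p <- p[!is.na(p)]
    ps <- sort(p)
    kth <- ps[min(k, length(ps))]
    n_indep <- if (length(idx) == 1L) 1L else {
      r2 <- ld_r(genotypes, idx)^2
      length(greedy_prune(r2, threshold = 0.2))
    }
    data.frame(gene_id = names(map)[i],
               best_p = ps[1], kth_p = kth,
               score_best = -log(floor_p(ps[1])),
               score_k = -log(floor_p(kth)),
               max_chi2 = stats::qchisq(floor_p(ps[1]), 1, lower.tail = FALSE),
               span_kb = (gmeta$end[i] - gmeta$start[i] + 1) / 1000,
               n_snps = length(p), n_indep = n_indep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

pw_result <- function(p, method, extra = NULL) {
  stopifnot(!is.null(names(p)))
  ord <- order(p, names(p))
  rk <- integer(length(p)); rk[ord] <- seq_along(p)
  out <- data.frame(pathway = names(p), method = method, p = unname(p),
                    rank = rk, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' GSA-SNP style competitive Z test
#'
#' Gene score is \code{-log} of the k-th smallest SNP p-value in the gene;
#' each pathway is tested with \code{Z = (mean in-set score - mean all-gene
#' score) / (sd all / sqrt(set size))} against the upper normal tail. A
#' BH-adjusted column is included.
#'
#' @param scores a \code{gene_score_table}.
#' @param pathways a \code{pathway_collection}.
#' @return data frame: pathway, method, p, rank, z, p_adj, flagged.
#' @export
gsa_snp <- function(scores, pathways) {
  sc <- stats::setNames(scores$score_k, scores$gene_id)
  mu <- mean(sc); sdev <- stats::sd(sc)
  p <- z <- stats::setNames(numeric(length(pathways$sets)), names(pathways$sets))
  flagged <- logical(length(p))
  for (i in seq_along(pathways$sets)) {
    g <- intersect(pathways$sets[[i]], names(sc))
    if (length(g) < 2) { p[i] <- 1; z[i] <- 0; flagged[i] <- TRUE; next }
    z[i] <- (mean(sc[g]) - mu) / (sdev / sqrt(length(g)))
    p[i] <- stats::pnorm(z[i], lower.tail = FALSE)
  }
  pw_result(floor_p(p), "gsa_snp",
            data.frame(z = unname(z), p_adj = stats::p.adjust(unname(p), "BH"),
                       flagged = flagged))
}

# weighted KS running-sum enrichment score over a gene ranking
enrichment_score <- function(stat, in_set, weight_exponent = 1) {
  N <- length(stat)
  n_out <- N - sum(in_set)
  if (n_out == 0)
    stop_gwasbench("gene set contains every scored gene", "gwasbench_design_error")
  ord <- order(stat, decreasing = TRUE)
  s <- abs(stat[ord])^weight_exponent
  hit <- in_set[ord]
  denom <- sum(s[hit])
  if (denom == 0) return(0)
  run <- cumsum(ifelse(hit, s / denom, -1 / n_out))
  max(run)
}

#' Phenotype-permutation GSEA engine (GenGen / GSEA-SNP)
#'
#' Ranks genes by an association statistic, computes the weighted
#' Kolmogorov-Smirnov enrichment score per pathway, and assesses significance
#' by permuting case/control labels and recomputing the genome-wide scan and
#' gene statistics for every permutation. \code{gene_stat = "max_chi2"}
#' (largest 1-df chi-square in the gene) is the GenGen-style configuration;
#' \code{"max_abs_z"} gives the GSEA-SNP-style variant. Permuted scans use
#' the score test, asymptotically equivalent to the observed Wald scan.
#'
#' @param genotypes cohort \code{genotype_matrix}.
#' @param status \code{cohort_status} or 0/1 vector.
#' @param pathways \code{pathway_collection}.
#' @param genes gene annotation.
#' @param assoc observed \code{assoc_table} (recomputed if omitted).
#' @param gene_stat \code{"max_chi2"} or \code{"max_abs_z"}.
#' @param n_perms number of label permutations (>= 100).
#' @param weight_exponent KS weighting exponent (1 = classic weighted GSEA).
#' @param seed integer seed.
#' @param z_perm optional precomputed SNP x permutation score-z matrix (from
#'   [score_z_matrix()]), shared across permutation methods.
#' @param method_label column label for the output.
#' @return data frame: pathway, method, p, rank, es, nes.
#' @export
gsea_permutation <- function(genotypes, status, pathways, genes, assoc = NULL,
                             gene_stat = c("max_chi2", "max_abs_z"),
                             n_perms = 1000, weight_exponent = 1, seed = 1,
                             z_perm = NULL, method_label = NULL) {
  gene_stat <- match.arg(gene_stat)
  if (n_perms < 100) stop_gwasbench("n_perms must be >= 100", "gwasbench_invalid_parameter")
  y <- status_vector(status, genotypes$n_samples)
  sampled <- which(!is.na(y))
  if (is.null(assoc)) assoc <- gwas_logistic(genotypes, status)
  map <- snps_by_gene(genotypes$variants, genes)
  map <- map[vapply(map, length, integer(1)) > 0]
  z_obs <- stats::qnorm(floor_p(assoc$p) / 2) # |z| magnitude via p; sign irrelevant
  stat_from_z <- function(zcol) {
    v <- if (gene_stat == "max_chi2") zcol^2 else abs(zcol)
    vapply(map, function(idx) max(v[idx]), numeric(1))
  }
  obs_stat <- stat_from_z(z_obs)
  if (is.null(z_perm)) {
    yp <- permute_labels(y[sampled], n_perms, seed = derive_seed(seed, "gsea_perm"))
    z_perm <- score_z_matrix(genotypes, yp, sampled = sampled)
  }
  n_perms <- ncol(z_perm)
  sets <- lapply(pathways$sets, function(g) names(map) %in% g)
  es_obs <- vapply(sets, function(s) enrichment_score(obs_stat, s, weight_exponent), numeric(1))
  es_perm <- matrix(0, n_perms, length(sets))
  for (b in seq_len(n_perms)) {
    st <- stat_from_z(z_perm[, b])
    for (j in seq_along(sets))
      es_perm[b, j] <- enrichment_score(st, sets[[j]], weight_exponent)
  }
  p <- vapply(seq_along(sets), function(j)
    (1 + sum(es_perm[, j] >= es_obs[j])) / (1 + n_perms), numeric(1))
  names(p) <- names(pathways$sets)
  nes <- es_obs / pmax(colMeans(es_perm), .Machine$double.eps)
  pw_result(p, method_label %||% if (gene_stat == "max_chi2") "gengen" else "gsea_snp",
            data.frame(es = unname(es_obs), nes = unname(nes)))
}

#' ALIGATOR-style resampled over-representation test
#'
#' A gene is "significant" when it contains at least one SNP below
#' \code{snp_p_threshold}. Null replicates draw SNPs uniformly without
#' replacement until the number of distinct significant genes matches the
#' observed genome-wide count, which corrects for gene size by construction;
#' the pathway p-value compares observed and null in-set significant-gene
#' counts.
#'
#' @param assoc an \code{assoc_table}.
#' @param genotypes cohort \code{genotype_matrix} (for SNP-gene geometry).
#' @param genes gene annotation.
#' @param pathways \code{pathway_collection}.
#' @param snp_p_threshold SNP significance threshold (default 0.01).
#' @param n_resamples number of null replicates.
#' @param seed integer seed.
#' @return data frame: pathway, method, p, rank, n_sig_genes, flagged.
#' @export
aligator <- function(assoc, genotypes, genes, pathways,
                     snp_p_threshold = 0.01, n_resamples = 1000, seed = 1) {
  map <- snps_by_gene(genotypes$variants, genes)
  map <- map[vapply(map, length, integer(1)) > 0]
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  gene_best <- vapply(map, function(idx)
    min(p_all[genotypes$variants$snp_id[idx]], na.rm = TRUE), numeric(1))
  sig <- gene_best < snp_p_threshold
  n_obs_sig <- sum(sig)
  member <- lapply(pathways$sets, function(g) names(map) %in% g)
  obs_counts <- vapply(member, function(mb) sum(sig & mb), numeric(1))
  pnames <- names(pathways$sets)
  if (n_obs_sig == 0 || n_obs_sig == length(map)) {
    out <- pw_result(stats::setNames(rep(1, length(pnames)), pnames), "aligator",
                     data.frame(n_sig_genes = unname(obs_counts), flagged = TRUE))
    return(out)
  }
  m_snps <- nrow(assoc)
  gene_f <- factor(rep(names(map), vapply(map, length, integer(1))),
                   levels = names(map))
  snp_idx <- unlist(map, use.names = FALSE)
  set.seed(derive_seed(seed, "aligator"))
  ge <- matrix(0, n_resamples, length(pnames))
  for (b in seq_len(n_resamples)) {
    rk <- sample.int(m_snps)               # position of each SNP in the draw order
    first_hit <- tapply(rk[snp_idx], gene_f, min)
    cutoff <- sort(first_hit, partial = n_obs_sig)[n_obs_sig]
    hit <- first_hit <= cutoff
    for (j in seq_along(member)) ge[b, j] <- sum(hit & member[[j]])
  }
  p <- vapply(seq_along(pnames), function(j)
    (1 + sum(ge[, j] >= obs_counts[j])) / (1 + n_resamples), numeric(1))
  names(p) <- pnames
  pw_result(p, "aligator", data.frame(n_sig_genes = unname(obs_counts), flagged = FALSE))
}

#' MAGENTA-like confounder-corrected enrichment
#'
#' Gene score is \code{-log} best SNP p, regressed on gene-level confounders
#' (span in kb, SNP count, number of independent SNPs); the residual score
#' replaces the raw one. Enrichment counts set genes above the
#' \code{cutoff_percentile} of all residual scores, with significance from
#' random gene sets of equal size.
#'
#' @param scores a \code{gene_score_table} (confounders populated).
#' @param pathways \code{pathway_collection}.
#' @param cutoff_percentile enrichment cutoff (default 75).
#' @param n_set_perms number of random-set draws.
#' @param seed integer seed.
#' @return data frame: pathway, method, p, rank, n_above, flagged.
#' @export
magenta_like <- function(scores, pathways, cutoff_percentile = 75,
                         n_set_perms = 1000, seed = 1) {
  fit <- stats::lm(score_best ~ span_kb + n_snps + n_indep, data = scores)
  if (anyNA(stats::coef(fit)))
    warning("collinear confounders dropped from the gene-score correction")
  res <- stats::setNames(stats::residuals(fit), scores$gene_id)
  cutoff <- stats::quantile(res, cutoff_percentile / 100)
  above <- res > cutoff
  set.seed(derive_seed(seed, "magenta"))
  p <- stats::setNames(numeric(length(pathways$sets)), names(pathways$sets))
  n_above <- integer(length(p)); flagged <- logical(length(p))
  for (i in seq_along(pathways$sets)) {
    g <- intersect(pathways$sets[[i]], names(res))
    if (!length(g)) { p[i] <- 1; flagged[i] <- TRUE; next }
    obs <- sum(above[g])
    n_above[i] <- obs
    null <- vapply(seq_len(n_set_perms), function(b)
      sum(above[sample_from(names(res), length(g), replace = FALSE)]), numeric(1))
    p[i] <- (1 + sum(null >= obs)) / (1 + n_set_perms)
  }
  pw_result(p, "magenta", data.frame(n_above = n_above, flagged = flagged))
}

#' SNP Ratio Test
#'
#' Observed statistic: the fraction of pathway SNPs with association p below
#' \code{snp_p_threshold}. Significance by phenotype permutation, with the
#' per-permutation scans from the score-test engine.
#'
#' @inheritParams gsea_permutation
#' @param snp_p_threshold SNP threshold (default 0.05).
#' @return data frame: pathway, method, p, rank, ratio, flagged.
#' @export
snp_ratio_test <- function(assoc, genotypes, status, genes, pathways,
                           snp_p_threshold = 0.05, n_perms = 1000, seed = 1,
                           z_perm = NULL) {
  if (n_perms < 100) stop_gwasbench("n_perms must be >= 100", "gwasbench_invalid_parameter")
  y <- status_vector(status, genotypes$n_samples)
  sampled <- which(!is.na(y))
  if (is.null(z_perm)) {
    yp <- permute_labels(y[sampled], n_perms, seed = derive_seed(seed, "srt_perm"))
    z_perm <- score_z_matrix(genotypes, yp, sampled = sampled)
  }
  n_perms <- ncol(z_perm)
  z_crit <- stats::qnorm(snp_p_threshold / 2) # two-sided threshold on |z|
  map <- snps_by_gene(genotypes$variants, genes)
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  p <- stats::setNames(numeric(length(pathways$sets)), names(pathways$sets))
  ratio <- numeric(length(p)); flagged <- logical(length(p))
  for (i in seq_along(pathways$sets)) {
    idx <- sort(unique(unlist(map[intersect(pathways$sets[[i]], names(map))])))
    if (!length(idx)) { p[i] <- 1; flagged[i] <- TRUE; next }
    obs <- mean(p_all[genotypes$variants$snp_id[idx]] < snp_p_threshold)
    ratio[i] <- obs
    if (obs == 0) { p[i] <- 1; next }
    perm_ratio <- colMeans(abs(z_perm[idx, , drop = FALSE]) > abs(z_crit))
    p[i] <- (1 + sum(perm_ratio >= obs)) / (1 + n_perms)
  }
  pw_result(p, "srt", data.frame(ratio = ratio, flagged = flagged))
}

# greedy best-SNP selection used by the set test: ascending-p scan, keep SNPs
# with p below p_cut that are LD-independent of those already kept
set_test_stat <- function(p, Gn, p_cut, r2_cut, max_snps) {
  cand <- which(p < p_cut)
  if (!length(cand)) return(0)
  cand <- cand[order(p[cand])]
  kept <- integer(0)
  n <- nrow(Gn)
  for (j in cand) {
    if (length(kept)) {
      r <- crossprod(Gn[, kept, drop = FALSE], Gn[, j]) / n
      if (any(r^2 > r2_cut)) next
    }
    kept <- c(kept, j)
    if (length(kept) >= max_snps) break
  }
  mean(-log(floor_p(p[kept])))
}

#' Plink-style set test
#'
#' Per pathway: SNPs are scanned in ascending p order, greedily pruned at
#' r-squared <= \code{r2_cut}, and those below \code{p_cut} (up to
#' \code{max_snps}) contribute their mean -log p. Phenotype permutations
#' repeat the whole selection; empirical p with the +1/+1 correction.
#'
#' @inheritParams snp_ratio_test
#' @param p_cut SNP inclusion threshold.
#' @param r2_cut pruning threshold.
#' @param max_snps maximum SNPs retained per set.
#' @return data frame: pathway, method, p, rank, stat, flagged.
#' @export
plink_set_test <- function(assoc, genotypes, status, genes, pathways,
                           p_cut = 0.05, r2_cut = 0.5, max_snps = 5,
                           n_perms = 1000, seed = 1, z_perm = NULL) {
  if (n_perms < 100) stop_gwasbench("n_perms must be >= 100", "gwasbench_invalid_parameter")
  y <- status_vector(status, genotypes$n_samples)
  sampled <- which(!is.na(y))
  if (is.null(z_perm)) {
    yp <- permute_labels(y[sampled], n_perms, seed = derive_seed(seed, "pst_perm"))
    z_perm <- score_z_matrix(genotypes, yp, sampled = sampled)
  }
  n_perms <- ncol(z_perm)
  map <- snps_by_gene(genotypes$variants, genes)
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  p <- stats::setNames(numeric(length(pathways$sets)), names(pathways$sets))
  stat <- numeric(length(p)); flagged <- logical(length(p))
  for (i in seq_along(pathways$sets)) {
    idx <- sort(unique(unlist(map[intersect(pathways$sets[[i]], names(map))])))
    if (!length(idx)) { p[i] <- 1; flagged[i] <- TRUE; next }
    G <- genotypes$dosage[sampled, idx, drop = FALSE]
    storage.mode(G) <- "double"
    Gn <- scale(G)                        # unit-variance columns -> r from crossprod
    Gn[, attr(Gn, "scaled:scale") == 0] <- 0
    p_obs <- unname(p_all[genotypes$variants$snp_id[idx]])
    s_obs <- set_test_stat(p_obs, Gn, p_cut, r2_cut, max_snps)
    stat[i] <- s_obs
    if (s_obs == 0) { p[i] <- 1; next }
    zp <- abs(z_perm[idx, , drop = FALSE])
    s_perm <- vapply(seq_len(n_perms), function(b) {
      pb <- 2 * stats::pnorm(-zp[, b])
      set_test_stat(pb, Gn, p_cut, r2_cut, max_snps)
    }, numeric(1))
    p[i] <- (1 + sum(s_perm >= s_obs)) / (1 + n_perms)
  }
  pw_result(p, "pst", data.frame(stat = stat, flagged = flagged))
}

# per-gene HYST block decomposition, reusable across pathways
hyst_gene_blocks <- function(assoc, genotypes, genes, flank_bp = NULL,
                             block_threshold = 0.3) {
  map <- snps_by_gene(genotypes$variants, genes, flank_bp)
  map <- map[vapply(map, length, integer(1)) > 0]
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  lapply(map, function(idx) {
    p <- unname(p_all[genotypes$variants$snp_id[idx]])
    if (length(idx) == 1L)
      return(list(p_blocks = p, rho_keys = matrix(1, 1, 1)))
    ld <- ld_r(genotypes, idx)
    rho <- pvalue_correlation(ld)
    blk <- ld_blocks(ld^2, threshold = block_threshold)
    pb <- numeric(max(blk)); keys <- integer(max(blk))
    for (b in seq_len(max(blk))) {
      ii <- which(blk == b)
      if (length(ii) == 1L) { pb[b] <- p[ii]; keys[b] <- ii }
      else {
        g <- gates_core(p[ii], rho[ii, ii, drop = FALSE])
        pb[b] <- g$p; keys[b] <- ii[g$key]
      }
    }
    list(p_blocks = pb, rho_keys = rho[keys, keys, drop = FALSE])
  })
}

#' Pathway-level HYST
#'
#' Applies the HYST combination over all LD blocks of all genes in each
#' pathway: one Brown-style scaled chi-square over the block-level GATES
#' p-values, with between-block key-SNP correlations taken from LD within a
#' gene and zero between genes.
#'
#' @inheritParams aligator
#' @param block_threshold r-squared threshold for the block partition.
#' @param gene_blocks optional precomputed output of the internal per-gene
#'   decomposition (shared with the gene-level HYST run).
#' @return data frame: pathway, method, p, rank, n_blocks, flagged.
#' @export
hyst_pathway <- function(assoc, genotypes, genes, pathways,
                         block_threshold = 0.3, flank_bp = NULL,
                         gene_blocks = NULL) {
  gb <- gene_blocks %||%
    hyst_gene_blocks(assoc, genotypes, genes, flank_bp, block_threshold)
  p <- stats::setNames(numeric(length(pathways$sets)), names(pathways$sets))
  n_blocks <- integer(length(p)); flagged <- logical(length(p))
  for (i in seq_along(pathways$sets)) {
    g <- intersect(pathways$sets[[i]], names(gb))
    if (!length(g)) { p[i] <- 1; flagged[i] <- TRUE; next }
    pb <- unlist(lapply(gb[g], `[[`, "p_blocks"))
    B <- length(pb)
    rho <- matrix(0, B, B); diag(rho) <- 1
    off <- 0L
    for (gg in g) {
      k <- length(gb[[gg]]$p_blocks)
      rho[(off + 1):(off + k), (off + 1):(off + k)] <- gb[[gg]]$rho_keys
      off <- off + k
    }
    p[i] <- brown_combine(pb, rho)
    n_blocks[i] <- B
  }
  pw_result(floor_p(p), "hyst", data.frame(n_blocks = n_blocks, flagged = flagged))
}

#' Run the pathway-level method panel
#'
#' Executes the requested pathway tests with one shared set of phenotype
#' permutations for the permutation-based methods, and returns a long table
#' of pathway-level p-values with within-method ranks (ties broken by
#' pathway name).
#'
#' @inheritParams gsea_permutation
#' @param methods subset of \code{"gsa_snp", "gengen", "gsea_snp",
#'   "aligator", "magenta", "srt", "pst", "hyst"}.
#' @param n_perms label permutations for the permutation engines.
#' @param n_resamples replicates for ALIGATOR and the MAGENTA-like test.
#' @return A \code{pathway_result} data frame: pathway, method, p, rank.
#' @export
pathway_tests <- function(assoc, genotypes, status, genes, pathways,
                          methods = c("gsa_snp", "gengen", "gsea_snp",
                                      "aligator", "magenta", "srt", "pst", "hyst"),
                          n_perms = 1000, n_resamples = 1000, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  perm_methods <- intersect(methods, c("gengen", "gsea_snp", "srt", "pst"))
  z_perm <- NULL
  if (length(perm_methods)) {
    y <- status_vector(status, genotypes$n_samples)
    sampled <- which(!is.na(y))
    yp <- permute_labels(y[sampled], n_perms, seed = derive_seed(seed, "pathway_perm"))
    z_perm <- score_z_matrix(genotypes, yp, sampled = sampled)
  }
  scores <- if (any(methods %in% c("gsa_snp", "magenta")))
    gene_scores(assoc, genotypes, genes) else NULL
  out <- list()
  for (mth in methods) {
    res <- switch(mth,
      gsa_snp = gsa_snp(scores, pathways),
      gengen = gsea_permutation(genotypes, status, pathways, genes, assoc,
                                gene_stat = "max_chi2", n_perms = n_perms,
                                seed = seed, z_perm = z_perm),
      gsea_snp = gsea_permutation(genotypes, status, pathways, genes, assoc,
                                  gene_stat = "max_abs_z", n_perms = n_perms,
                                  seed = seed, z_perm = z_perm,
                                  method_label = "gsea_snp"),
      aligator = aligator(assoc, genotypes, genes, pathways,
                          n_resamples = n_resamples, seed = seed),
      magenta = magenta_like(scores, pathways, n_set_perms = n_resamples,
                             seed = seed),
      srt = snp_ratio_test(assoc, genotypes, status, genes, pathways,
                           n_perms = n_perms, seed = seed, z_perm = z_perm),
      pst = plink_set_test(assoc, genotypes, status, genes, pathways,
                           n_perms = n_perms, seed = seed, z_perm = z_perm),
      hyst = hyst_pathway(assoc, genotypes, genes, pathways))
    out[[mth]] <- res[, c("pathway", "method", "p", "rank")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pathway_result", "data.frame")
  res
}
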