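#' Label genes as true positives / true negatives
#'
#' True positive genes are designed causal genes that realized at least one
#' SNP with association p below \code{snp_p} (the simulation is stochastic,
#' so not every causal gene contributes signal). True negatives are
#' non-causal genes whose span lies more than \code{exclusion_kb} from every
#' causal gene's span; everything else is excluded. Each pathway also gets
#' its realized causal proportion: the fraction of member genes that are
#' true positives.
#'
#' @param design a \code{causal_design}.
#' @param assoc an \code{assoc_table}.
#' @param genotypes the \code{genotype_matrix} (for SNP-gene geometry).
#' @param genes gene annotation.
#' @param pathways optional \code{pathway_collection} for realized causal
#'   proportions.
#' @param snp_p SNP-level signal threshold defining a realized causal gene.
#' @param exclusion_kb buffer around causal genes excluded from the TN set.
#' @return A \code{truth_labels}: list with \code{gene_labels} (gene_id,
#'   label in tp/tn/excluded, best_p) and \code{pathway_prop} (named vector).
#' @export
label_truth <- function(design, assoc, genotypes, genes, pathways = NULL,
                        snp_p = 0.01, exclusion_kb = 50) {
  map <- snps_by_gene(genotypes$variants, genes)
  p_all <- stats::setNames(assoc$p, assoc$snp_id)
  best_p <- vapply(map, function(idx)
    if (length(idx)) min(p_all[genotypes$variants$snp_id[idx]], na.rm = TRUE) else NA_real_,
    numeric(1))
  causal_ids <- if (is.null(design)) character(0) else design$genes$gene_id
  is_causal <- genes$gene_id %in% causal_ids
  lab <- rep("excluded", nrow(genes))
  lab[is_causal & !is.na(best_p) & best_p < snp_p] <- "tp"
  # TN: span-to-span distance from every causal gene above the buffer
  buffer <- exclusion_kb * 1000
  near_causal <- rep(FALSE, nrow(genes))
  cz <- genes[is_causal, , drop = FALSE]
  if (nrow(cz)) {
    for (i in which(!is_causal)) {
      same <- cz$chrom == genes$chrom[i]
      if (!any(same)) next
      d <- pmax(cz$start[same] - genes$end[i], genes$start[i] - cz$end[same])
      near_causal[i] <- any(d <= buffer)
    }
  }
  lab[!is_causal & !near_causal & !is.na(best_p)] <- "tn"
  gl <- data.frame(gene_id = genes$gene_id, label = lab,
                   best_p = best_p[match(genes$gene_id, names(best_p))],
                   stringsAsFactors = FALSE)
  pw <- NULL
  if (!is.null(pathways)) {
    tp_genes <- gl$gene_id[gl$label == "tp"]
    pw <- vapply(pathways$sets, function(g) mean(g %in% tp_genes), numeric(1))
  }
  structure(list(gene_labels = gl, pathway_prop = pw), class = "truth_labels")
}

#' Confusion metrics for the gene-level methods
#'
#' Sensitivity is the fraction of true-positive genes detected at
#' \code{alpha}; specificity is computed on a fixed-size random subset of
#' true negatives (to keep the two cells comparable), while the
#' false-positive and false-negative percentages use the full labeled sets.
#'
#' @param results a \code{gene_result}.
#' @param labels a \code{truth_labels}.
#' @param alpha significance threshold(s); a vector gives one row per
#'   threshold per method.
#' @param n_tn_subset size of the true-negative subset for specificity.
#' @param seed seed for the subset draw (recorded in the output attribute).
#' @return data frame: method, alpha, sensitivity, specificity, fp_pct,
#'   fn_pct, n_tp, n_tn.
#' @export
confusion_metrics <- function(results, labels, alpha = 0.001,
                              n_tn_subset = 50, seed = 1) {
  gl <- labels$gene_labels
  methods <- attr(results, "params")$methods %||%
    setdiff(names(results), c("gene_id", "n_snps"))
  tp_ids <- intersect(gl$gene_id[gl$label == "tp"], results$gene_id)
  tn_ids <- intersect(gl$gene_id[gl$label == "tn"], results$gene_id)
  if (!length(tp_ids)) warning("no true-positive genes; sensitivity undefined")
  set.seed(derive_seed(seed, "tn_subset"))
  tn_sub <- if (length(tn_ids) > n_tn_subset)
    sample_from(tn_ids, n_tn_subset, replace = FALSE) else tn_ids
  rows <- list()
  for (mth in methods) {
    pv <- stats::setNames(results[[mth]], results$gene_id)
    for (a in alpha) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, alpha = a,
        sensitivity = if (length(tp_ids)) mean(pv[tp_ids] < a) else NA_real_,
        specificity = if (length(tn_sub)) mean(pv[tn_sub] > a) else NA_real_,
        fp_pct = if (length(tn_ids)) 100 * mean(pv[tn_ids] < a) else NA_real_,
        fn_pct = if (length(tp_ids)) 100 * mean(pv[tp_ids] >= a) else NA_real_,
        n_tp = length(tp_ids), n_tn = length(tn_ids),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tn_subset") <- tn_sub
  attr(out, "tn_subset_seed") <- seed
  out
}

#' Sensitivity stratified by effect size or causal-SNP count
#'
#' @param results a \code{gene_result}.
#' @param labels a \code{truth_labels}.
#' @param design the \code{causal_design} (provides the strata).
#' @param stratify \code{"or"} (odds ratio) or \code{"n_snps"} (causal-SNP
#'   count).
#' @param alpha significance threshold.
#' @return data frame: method, stratum, sensitivity, n_genes.
#' @export
stratified_sensitivity <- function(results, labels, design,
                                   stratify = c("or", "n_snps"),
                                   alpha = 0.001) {
  stratify <- match.arg(stratify)
  gl <- labels$gene_labels
  tp_ids <- intersect(gl$gene_id[gl$label == "tp"], results$gene_id)
  key <- if (stratify == "or") design$genes$odds_ratio else design$genes$n_snps
  strat <- stats::setNames(key, design$genes$gene_id)[tp_ids]
  methods <- attr(results, "params")$methods %||%
    setdiff(names(results), c("gene_id", "n_snps"))
  rows <- list()
  for (mth in methods) {
    pv <- stats::setNames(results[[mth]], results$gene_id)
    for (s in sort(unique(strat))) {
      ids <- tp_ids[strat == s]
      if (!length(ids)) { warning(sprintf("empty stratum %s", s)); next }
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, stratum = s, sensitivity = mean(pv[ids] < alpha),
        n_genes = length(ids), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

fisher_z_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pathway rank analysis
#'
#' Within each method, pathways are ranked by p-value (1 = strongest, ties
#' broken by name); the mean rank across methods is taken per pathway, and
#' the Pearson correlation of each method's ranks with the realized
#' causal-gene proportion and with the mean ranking is reported with
#' Fisher-z 95\% confidence intervals. By default only the large pathways
#' enter the correlations, avoiding over-representation of zero-causal sets.
#'
#' @param results a \code{pathway_result} (long table).
#' @param labels a \code{truth_labels} with pathway proportions.
#' @param pathways the \code{pathway_collection} (for size classes).
#' @param large_only restrict correlations to the large size class.
#' @return list with \code{ranks} (pathway x method rank matrix),
#'   \code{mean_rank}, and \code{correlations} (method, cor_causal, ci,
#'   cor_mean_rank, ci).
#' @export
pathway_rank_analysis <- function(results, labels, pathways, large_only = TRUE) {
  keep_pw <- if (large_only)
    pathways$info$name[pathways$info$size_class == "large"] else
    pathways$info$name
  if (length(keep_pw) < 3)
    stop_gwasbench("need >= 3 pathways for rank analysis", "gwasbench_invalid_parameter")
  res <- results[results$pathway %in% keep_pw, ]
  methods <- unique(res$method)
  # re-rank within the retained pathways
  rank_mat <- sapply(methods, function(mth) {
    sub <- res[res$method == mth, ]
    ord <- order(sub$p, sub$pathway)
    rk <- integer(nrow(sub)); rk[ord] <- seq_len(nrow(sub))
    stats::setNames(rk, sub$pathway)[keep_pw]
  })
  mean_rank <- rowMeans(rank_mat)
  prop <- labels$pathway_prop[keep_pw]
  cor_or_na <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  n <- length(keep_pw)
  corr <- do.call(rbind, lapply(methods, function(mth) {
    r1 <- cor_or_na(rank_mat[, mth], prop)
    r2 <- cor_or_na(rank_mat[, mth], mean_rank)
    ci1 <- fisher_z_ci(r1, n); ci2 <- fisher_z_ci(r2, n)
    data.frame(method = mth, cor_causal = r1, cor_causal_lo = ci1[1],
               cor_causal_hi = ci1[2], cor_mean_rank = r2,
               cor_mean_lo = ci2[1], cor_mean_hi = ci2[2],
               stringsAsFactors = FALSE)
  }))
  list(ranks = rank_mat, mean_rank = mean_rank, prop = prop,
       correlations = corr)
}

#' Pairwise method agreement
#'
#' Pearson correlation matrix of p-values over shared units (genes or
#' pathways), plus a -log10 p matrix for heatmap rendering.
#'
#' @param results a \code{gene_result} or \code{pathway_result}.
#' @return list with \code{cor} (method x method) and \code{neglog10}
#'   (unit x method matrix of -log10 p).
#' @export
method_agreement <- function(results) {
  if (inherits(results, "pathway_result") ||
      all(c("pathway", "method", "p") %in% names(results))) {
    units <- sort(unique(results$pathway))
    methods <- unique(results$method)
    mat <- sapply(methods, function(mth) {
      sub <- results[results$method == mth, ]
      stats::setNames(sub$p, sub$pathway)[units]
    })
    rownames(mat) <- units
  } else {
    methods <- attr(results, "params")$methods %||%
      setdiff(names(results), c("gene_id", "n_snps"))
    mat <- as.matrix(results[, methods, drop = FALSE])
    rownames(mat) <- results$gene_id
  }
  if (ncol(mat) < 2)
    stop_gwasbench("need >= 2 methods for agreement", "gwasbench_invalid_parameter")
  cc <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  list(cor = cc, neglog10 = -log10(floor_p(mat)))
}
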