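#' Tile gene models over a simulated variant panel
#'
#' Places non-overlapping genes along each chromosome by alternately drawing a
#' gene length and an intergenic gap. Every gene's flanked span
#' (\code{[start - flank_bp, end + flank_bp]}) must contain at least one SNP;
#' otherwise generation fails naming the offending chromosome.
#'
#' @param variants variant table (as in \code{genotype_matrix$variants}).
#' @param gene_size_spec numeric vector of gene lengths (bp) to sample from.
#' @param gap_spec numeric vector of intergenic gap lengths (bp) to sample from.
#' @param n_genes optional cap on the total number of genes; 0 gives an empty
#'   annotation.
#' @param flank_bp flanking distance used for SNP-to-gene assignment (20 kb by
#'   default, following standard eQTL-distance practice).
#' @param seed integer seed.
#' @return data frame of \code{gene_id, chrom, start, end} (1-based inclusive)
#'   with attribute \code{flank_bp}.
#' @export
generate_annotation <- function(variants, gene_size_spec = 60000,
                                gap_spec = 90000, n_genes = Inf,
                                flank_bp = 20000, seed = 1) {
  if (nrow(variants) == 0) stop_gwasbench("variants must be non-empty", "gwasbench_invalid_parameter")
  set.seed(seed)
  out <- list()
  total <- 0L
  for (cc in sort(unique(variants$chrom))) {
    if (total >= n_genes) break
    vpos <- variants$pos[variants$chrom == cc]
    lo <- min(vpos); hi <- max(vpos)
    cur <- lo
    k <- 0L
    while (cur < hi && total < n_genes) {
      len <- sample_from(gene_size_spec)
      gap <- sample_from(gap_spec)
      start <- as.integer(cur)
      end <- as.integer(min(cur + len - 1, hi))
      if (end < start) break
      n_in <- sum(vpos >= start - flank_bp & vpos <= end + flank_bp)
      if (n_in == 0)
        stop_gwasbench(sprintf(
          "gene size spec incompatible with SNP spacing on chromosome %s", cc),
          "gwasbench_generation_error")
      k <- k + 1L; total <- total + 1L
      out[[length(out) + 1L]] <- data.frame(
        gene_id = sprintf("gene_c%d_%04d", cc, k), chrom = cc,
        start = start, end = end, stringsAsFactors = FALSE)
      cur <- cur + len + gap
    }
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), chrom = integer(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  attr(genes, "flank_bp") <- flank_bp
  genes
}

#' Assign SNPs to genes through flanked spans
#'
#' A SNP belongs to every gene whose \code{[start - flank_bp, end + flank_bp]}
#' span covers it (overlapping spans assign the SNP to both genes).
#'
#' @param variants variant table.
#' @param genes gene annotation from [generate_annotation()].
#' @param flank_bp flank; defaults to the annotation's own attribute.
#' @return named list: gene_id -> integer vector of SNP row indices
#'   (position-ordered).
#' @export
snps_by_gene <- function(variants, genes, flank_bp = NULL) {
  flank_bp <- flank_bp %||% attr(genes, "flank_bp") %||% 20000
  res <- vector("list", nrow(genes))
  names(res) <- genes$gene_id
  ord <- order(variants$chrom, variants$pos)
  for (i in seq_len(nrow(genes))) {
    sel <- which(variants$chrom == genes$chrom[i] &
                 variants$pos >= genes$start[i] - flank_bp &
                 variants$pos <= genes$end[i] + flank_bp)
    res[[i]] <- sel[order(variants$pos[sel])]
  }
  res
}

#' Build a two-tier pathway collection with a causal-gene design
#'
#' Draws \code{n_large} pathways above and \code{n_small} at or below the
#' median gene-set size, then designates causal genes within each size class
#' following the benchmark architecture: 4 pathways with a single causal gene,
#' 4 with 20\% causal genes, and 2 with 50\% causal genes. Causal genes are
#' unique across pathways (genes in several sets are never designated causal);
#' non-causal members may be shared between pathways.
#'
#' @param genes gene annotation.
#' @param n_large,n_small pathway counts per size class.
#' @param median_size size threshold separating the classes.
#' @param large_sizes,small_sizes integer vectors of set sizes to sample from.
#' @param causal_classes per-class design: counts of pathways with a single
#'   causal gene, 20\% causal and 50\% causal (recycled to both size classes).
#' @param seed integer seed.
#' @return A \code{pathway_collection}: list with \code{sets} (named list of
#'   gene-id vectors), \code{causal} (named list of designated causal gene
#'   ids) and \code{info} (data frame: name, size, size_class, causal_class,
#'   n_causal).
#' @export
generate_pathways <- function(genes, n_large = 10, n_small = 10,
                              median_size = 28,
                              large_sizes = 29:45, small_sizes = 8:27,
                              causal_classes = c(single = 4, frac20 = 4, frac50 = 2),
                              seed = 1) {
  set.seed(seed)
  ids <- genes$gene_id
  mk_class <- function(n_path, sizes, class_label) {
    if (n_path == 0) return(NULL)
    # causal-class labels for this size class, padded with "single" if the
    # stated design does not fill n_path (only reachable off the default)
    lab <- rep(names(causal_classes), causal_classes)
    lab <- rep_len(lab, n_path)
    data.frame(size = sample_from(sizes, n_path),
               size_class = class_label, causal_class = lab,
               stringsAsFactors = FALSE)
  }
  info <- rbind(mk_class(n_large, large_sizes, "large"),
                mk_class(n_small, small_sizes, "small"))
  if (is.null(info)) stop_gwasbench("no pathways requested", "gwasbench_design_error")
  info$name <- sprintf("PW_%s_%02d", toupper(substr(info$size_class, 1, 1)),
                       seq_len(nrow(info)))
  n_causal <- ifelse(info$causal_class == "single", 1L,
              ifelse(info$causal_class == "frac20", pmax(1L, as.integer(ceiling(0.2 * info$size))),
                     pmax(1L, as.integer(ceiling(0.5 * info$size)))))
  info$n_causal <- pmin(n_causal, info$size)
  need_causal <- sum(info$n_causal)
  if (need_causal > length(ids))
    stop_gwasbench(sprintf(
      "insufficient genes for pathway design: %d causal genes required, %d available",
      need_causal, length(ids)), "gwasbench_design_error")

  causal_pool <- sample(ids, need_causal)
  rest_pool <- setdiff(ids, causal_pool)
  sets <- vector("list", nrow(info)); names(sets) <- info$name
  causal <- vector("list", nrow(info)); names(causal) <- info$name
  off <- 0L
  for (i in seq_len(nrow(info))) {
    cg <- causal_pool[(off + 1L):(off + info$n_causal[i])]
    off <- off + info$n_causal[i]
    n_fill <- info$size[i] - info$n_causal[i]
    if (n_fill > length(rest_pool))
      stop_gwasbench(sprintf(
        "insufficient genes for pathway design: set %s needs %d non-causal members, %d available",
        info$name[i], n_fill, length(rest_pool)), "gwasbench_design_error")
    fill <- sample(rest_pool, n_fill)
    sets[[i]] <- sort(c(cg, fill))
    causal[[i]] <- sort(cg)
  }
  rownames(info) <- NULL
  structure(list(sets = sets, causal = causal,
                 info = info[, c("name", "size", "size_class", "causal_class", "n_causal")]),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d sets (%d large, %d small), %d designated causal genes\n",
              length(x$sets), sum(x$info$size_class == "large"),
              sum(x$info$size_class == "small"),
              length(unique(unlist(x$causal)))))
  invisible(x)
}

#' Select causal SNPs and effect sizes for a pathway design
#'
#' For every designated causal gene, candidate SNPs in the flanked span are
#' greedily pruned by ascending position so that all kept SNPs have pairwise
#' r-squared at most \code{r2_max}; the required number of causal SNPs (1, 2
#' or 5, drawn with \code{n_snp_probs}) is then sampled from the kept set.
#' All causal SNPs in a gene share its odds ratio; causal genes are split
#' evenly between the two effect sizes, with any odd gene out assigned the
#' larger effect.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param genes gene annotation.
#' @param pathways a \code{pathway_collection} carrying the designated causal
#'   genes.
#' @param r2_max LD-independence threshold for causal SNPs (default 0.2).
#' @param n_snp_choices,n_snp_probs causal-SNP counts and their sampling
#'   probabilities (defaults 1/2/5 with weights 8:22:20).
#' @param or_values the two odds ratios (small, large).
#' @param flank_bp flank; defaults to the annotation attribute.
#' @param seed integer seed.
#' @return A \code{causal_design}: list with \code{genes} (gene_id, pathway,
#'   odds_ratio, n_snps) and \code{snps} (snp_id, gene_id, odds_ratio).
#' @export
select_causal_snps <- function(genotypes, genes, pathways, r2_max = 0.2,
                               n_snp_choices = c(1L, 2L, 5L),
                               n_snp_probs = c(8, 22, 20) / 50,
                               or_values = c(1.2, 2.0),
                               flank_bp = NULL, seed = 1) {
  set.seed(seed)
  map <- snps_by_gene(genotypes$variants, genes, flank_bp)
  cg <- unlist(lapply(names(pathways$causal), function(nm)
    stats::setNames(pathways$causal[[nm]], rep(nm, length(pathways$causal[[nm]])))))
  if (anyDuplicated(cg))
    stop_gwasbench("a causal gene appears in more than one pathway's causal list",
                   "gwasbench_design_error")
  n_req <- sample_from(n_snp_choices, length(cg), prob = n_snp_probs)
  # even odds-ratio split; the extra gene (odd count) gets the larger effect
  shuffled <- sample(length(cg))
  or_gene <- numeric(length(cg))
  half <- floor(length(cg) / 2)
  or_gene[shuffled[seq_len(half)]] <- or_values[1]
  or_gene[shuffled[-seq_len(half)]] <- or_values[2]

  gene_rows <- snp_rows <- list()
  for (i in seq_along(cg)) {
    g <- cg[i]
    idx <- map[[g]]
    if (is.null(idx) || length(idx) == 0)
      stop_gwasbench(sprintf("causal gene %s has no SNPs in its flanked span", g),
                     "gwasbench_design_error")
    dos <- genotypes$dosage[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(dos))^2
    r2[is.na(r2)] <- 1 # zero-variance columns: treat as fully dependent
    kept <- greedy_prune(r2, threshold = r2_max, priority = seq_along(idx))
    if (length(kept) < n_req[i])
      stop_gwasbench(sprintf(
        "design infeasible: gene %s has %d independent SNPs at r2 <= %.2f but %d causal SNPs requested",
        g, length(kept), r2_max, n_req[i]), "gwasbench_design_infeasible")
    pick <- sort(sample_from(kept, n_req[i], replace = FALSE))
    snp_ids <- unname(genotypes$variants$snp_id[idx[pick]])
    g <- unname(g)
    gene_rows[[i]] <- data.frame(gene_id = g, pathway = names(cg)[i],
                                 odds_ratio = or_gene[i], n_snps = n_req[i],
                                 stringsAsFactors = FALSE)
    snp_rows[[i]] <- data.frame(snp_id = snp_ids, gene_id = g,
                                odds_ratio = or_gene[i], stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, gene_rows),
                 snps = do.call(rbind, snp_rows)),
            class = "causal_design")
}

#' @export
print.causal_design <- function(x, ...) {
  cat(sprintf("causal_design: %d genes, %d causal SNPs; OR split %s\n",
              nrow(x$genes), nrow(x$snps),
              paste(sprintf("%g x%d", sort(unique(x$genes$odds_ratio)),
                            table(x$genes$odds_ratio)), collapse = ", ")))
  invisible(x)
}
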