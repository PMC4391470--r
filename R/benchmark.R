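#' Default benchmark configuration
#'
#' Nested configuration for the end-to-end benchmark. Defaults give the
#' desk-scale study: 2,000 individuals, 20,000 SNPs in AR(1) LD blocks,
#' about 400 genes tiling four chromosomes, 20 pathways (10 large / 10
#' small) with the 1-gene / 20\% / 50\% causal architecture, a 50\%
#' prevalence balanced case-control phenotype, and the full gene- and
#' pathway-level method panels. Override any field via \code{...} using
#' nested lists, e.g. \code{benchmark_config(synthetic = list(n_samples =
#' 500))}.
#'
#' @param ... named overrides merged over the defaults (one level of
#'   nesting).
#' @param seed master seed; every stage seed is derived from it.
#' @return a \code{benchmark_config} list.
#' @export
benchmark_config <- function(..., seed = 1) {
  cfg <- list(
    seed = seed,
    synthetic = list(n_samples = 2000, n_snps = 20000, block_sizes = 2:12,
                     rho = 0.8, maf_range = c(0.05, 0.5), n_chrom = 4,
                     spacing_bp = 3000),
    annotation = list(gene_size_spec = c(30000, 60000, 90000),
                      gap_spec = c(60000, 90000, 120000),
                      flank_bp = 20000),
    pathways = list(n_large = 10, n_small = 10, median_size = 28,
                    large_sizes = 29:45, small_sizes = 8:27),
    causal = list(r2_max = 0.2, n_snp_choices = c(1L, 2L, 5L),
                  n_snp_probs = c(8, 22, 20) / 50, or_values = c(1.2, 2.0)),
    phenotype = list(prevalence = 0.5, slope = 1, design = "balanced_cc",
                     n_cases = NULL, n_controls = NULL, max_redraws = 5),
    gene_methods = list(methods = c("fisher", "sidak", "simes", "fdr", "tpm",
                                    "gates", "wgates", "hyst", "whyst",
                                    "vegas", "vegas10"),
                        tau = 0.1, n_sims = 1000),
    pathway_methods = list(methods = c("gsa_snp", "gengen", "gsea_snp",
                                       "aligator", "magenta", "srt", "pst",
                                       "hyst"),
                           n_perms = 1000, n_resamples = 1000),
    evaluation = list(alpha = 0.001, alpha_grid = c(1e-3, 1e-4, 1e-5, 2.9e-6),
                      snp_p = 0.01, exclusion_kb = 50, n_tn_subset = 50)
  )
  dots <- list(...)
  for (i in seq_along(dots)) { # by index: the same block may repeat, last wins
    nm <- names(dots)[i]
    if (nm == "seed") { cfg$seed <- dots[[i]]; next }
    if (!nm %in% names(cfg)) stop_gwasbench(sprintf("unknown config block '%s'", nm),
                                            "gwasbench_invalid_parameter")
    for (k in names(dots[[i]]))
      cfg[[nm]][k] <- list(dots[[i]][[k]]) # list-assign keeps explicit NULLs
  }
  if (cfg$phenotype$design != "case_cohort" && is.null(cfg$phenotype$n_cases))
    cfg$phenotype$n_cases <- floor(0.45 * cfg$synthetic$n_samples)
  structure(cfg, class = "benchmark_config")
}

#' Read / write a benchmark configuration as YAML
#' @param cfg a \code{benchmark_config}.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1
  raw$seed <- NULL
  do.call(benchmark_config, c(raw, list(seed = seed)))
}

#' Run the full simulation benchmark
#'
#' Executes the pipeline end to end: genotype simulation, gene/pathway
#' design, causal-SNP selection, liability phenotype, cohort sampling,
#' single-SNP GWAS, the gene-level and pathway-level method panels, truth
#' labeling and all evaluation metrics. Every stage is seeded from the
#' master seed, so identical configurations give identical reports. When
#' \code{out_dir} is given, the standard-format stage outputs (.tped/.tfam,
#' BED, GMT, association TSV, phenotype TSV, report TSVs) are written there.
#'
#' @param config a \code{benchmark_config}.
#' @param out_dir optional output directory for stage artifacts.
#' @param quiet suppress per-stage progress messages.
#' @return A \code{benchmark_report}: list with the design objects, the
#'   association table, \code{gene_results}, \code{pathway_results},
#'   \code{labels}, \code{confusion} (threshold grid), \code{stratified_or},
#'   \code{stratified_nsnp}, \code{rank_analysis}, \code{agreement} and
#'   stage timings.
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          quiet = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
    if (!quiet) message(sprintf("[%s] done (%.1fs)", stage, timings[[stage]]))
  }
  cfg <- config
  sy <- cfg$synthetic
  gt <- generate_genotypes(sy$n_samples, sy$n_snps, sy$block_sizes, sy$rho,
                           sy$maf_range, sy$n_chrom, sy$spacing_bp,
                           seed = derive_seed(cfg$seed, "genotypes"))
  tick("genotypes")
  an <- cfg$annotation
  genes <- generate_annotation(gt$variants, an$gene_size_spec, an$gap_spec,
                               flank_bp = an$flank_bp,
                               seed = derive_seed(cfg$seed, "annotation"))
  pw <- cfg$pathways
  pathways <- generate_pathways(genes, pw$n_large, pw$n_small, pw$median_size,
                                pw$large_sizes, pw$small_sizes,
                                seed = derive_seed(cfg$seed, "pathways"))
  ca <- cfg$causal
  # a sparse gene may not hold 5 independent SNPs; redraw the per-gene
  # causal-SNP counts rather than silently under-assigning
  design <- NULL
  for (try in 1:10) {
    design <- tryCatch(
      select_causal_snps(gt, genes, pathways, ca$r2_max,
                         ca$n_snp_choices, ca$n_snp_probs, ca$or_values,
                         seed = derive_seed(cfg$seed, paste0("causal", try))),
      gwasbench_design_infeasible = function(e) NULL)
    if (!is.null(design)) break
  }
  if (is.null(design))
    stop_gwasbench("causal design infeasible after redraws; use denser genes",
                   "gwasbench_design_infeasible")
  tick("design")
  ph <- cfg$phenotype
  scores <- liability_scores(gt, design)
  cohort <- NULL
  for (try in seq_len(ph$max_redraws)) {
    y <- assign_status(scores, ph$prevalence, ph$slope,
                       seed = derive_seed(cfg$seed, paste0("status", try)))
    cohort <- tryCatch(
      sample_cohort(y, ph$design, ph$n_cases, ph$n_controls,
                    seed = derive_seed(cfg$seed, paste0("cohort", try))),
      gwasbench_resimulate = function(e) NULL)
    if (!is.null(cohort)) break
  }
  if (is.null(cohort))
    stop_gwasbench("could not realize the requested cohort after redraws",
                   "gwasbench_resimulate")
  tick("phenotype")
  assoc <- gwas_logistic(gt, cohort)
  tick("gwas")
  gt_cohort <- subset_samples(gt, cohort$sampled)
  y_cohort <- status_vector(cohort, gt$n_samples)[cohort$sampled]
  gm <- cfg$gene_methods
  gene_results <- gene_tests(assoc, gt_cohort, genes, gm$methods,
                             tau = gm$tau, n_sims = gm$n_sims,
                             seed = derive_seed(cfg$seed, "genetests"))
  tick("gene_tests")
  pm <- cfg$pathway_methods
  pathway_results <- if (length(pm$methods))
    pathway_tests(assoc, gt_cohort, y_cohort, genes, pathways,
                  methods = pm$methods, n_perms = pm$n_perms,
                  n_resamples = pm$n_resamples,
                  seed = derive_seed(cfg$seed, "pathtests")) else NULL
  tick("pathway_tests")
  ev <- cfg$evaluation
  labels <- label_truth(design, assoc, gt, genes, pathways,
                        snp_p = ev$snp_p, exclusion_kb = ev$exclusion_kb)
  confusion <- confusion_metrics(gene_results, labels, alpha = ev$alpha_grid,
                                 n_tn_subset = ev$n_tn_subset,
                                 seed = derive_seed(cfg$seed, "tn_subset"))
  strat_or <- stratified_sensitivity(gene_results, labels, design, "or", ev$alpha)
  strat_nsnp <- stratified_sensitivity(gene_results, labels, design, "n_snps", ev$alpha)
  rank_analysis <- if (!is.null(pathway_results))
    pathway_rank_analysis(pathway_results, labels, pathways) else NULL
  agreement <- method_agreement(gene_results)
  tick("evaluation")
  report <- structure(list(
    config = cfg, variants = gt$variants, genes = genes, pathways = pathways,
    design = design, cohort = cohort, assoc = assoc,
    gene_results = gene_results, pathway_results = pathway_results,
    labels = labels, confusion = confusion,
    stratified_or = strat_or, stratified_nsnp = strat_nsnp,
    rank_analysis = rank_analysis, agreement = agreement,
    timings = unlist(timings)), class = "benchmark_report")
  if (!is.null(out_dir)) write_report(report, gt, out_dir)
  report
}

write_report <- function(report, gt, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_plink_tped(gt, file.path(out_dir, "genotypes"), report$cohort)
  write_bed(report$genes, file.path(out_dir, "genes.bed"))
  write_gmt(report$pathways, file.path(out_dir, "pathways.gmt"))
  write_assoc(report$assoc, file.path(out_dir, "assoc.tsv"))
  utils::write.table(report$gene_results, file.path(out_dir, "gene_results.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  if (!is.null(report$pathway_results))
    utils::write.table(report$pathway_results,
                       file.path(out_dir, "pathway_results.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
  utils::write.table(report$confusion, file.path(out_dir, "confusion.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  if (!is.null(report$rank_analysis)) {
    utils::write.table(report$rank_analysis$correlations,
                       file.path(out_dir, "pathway_correlations.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    # heatmap matrix: pathways ordered by realized causal proportion
    nl <- report$agreement$neglog10
    ord <- order(report$labels$pathway_prop[rownames(report$rank_analysis$ranks)])
    utils::write.table(report$rank_analysis$ranks[ord, , drop = FALSE],
                       file.path(out_dir, "pathway_rank_matrix.tsv"),
                       quote = FALSE, sep = "\t")
  }
  invisible(out_dir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("gwasbench benchmark report\n")
  cat(sprintf("  %d samples (%d cases / %d controls), %d SNPs, %d genes, %d pathways\n",
              length(x$cohort$status), x$cohort$n_cases, x$cohort$n_controls,
              nrow(x$variants), nrow(x$genes), length(x$pathways$sets)))
  gl <- x$labels$gene_labels
  cat(sprintf("  truth: %d TP genes, %d TN genes, %d excluded\n",
              sum(gl$label == "tp"), sum(gl$label == "tn"),
              sum(gl$label == "excluded")))
  cat("  gene-level confusion at alpha =", x$config$evaluation$alpha, "\n")
  cm <- x$confusion[x$confusion$alpha == x$config$evaluation$alpha, ]
  print(cm[, c("method", "sensitivity", "specificity", "fp_pct", "fn_pct")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$rank_analysis)) {
    cat("  pathway rank correlation with causal proportion:\n")
    print(x$rank_analysis$correlations[, c("method", "cor_causal", "cor_mean_rank")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.benchmark_report <- function(object, ...) print(object, ...)

#' Replicate the benchmark for stability assessment
#'
#' Repeats [run_benchmark()] with per-replicate seeds derived from the
#' master seed and summarizes the dispersion (mean and SD) of sensitivity,
#' specificity and false-positive percentage per method.
#'
#' @param config a \code{benchmark_config}; each replicate reuses it with a
#'   different master seed.
#' @param n_replicates number of replicates (>= 2).
#' @param seeds optional explicit master seeds (length \code{n_replicates}).
#' @return list with \code{reports} (per replicate confusion tables) and
#'   \code{summary} (method x metric mean/sd data frame).
#' @export
replicate_benchmark <- function(config = benchmark_config(), n_replicates = 10,
                                seeds = NULL) {
  if (n_replicates < 2)
    stop_gwasbench("n_replicates must be >= 2", "gwasbench_invalid_parameter")
  seeds <- seeds %||% vapply(seq_len(n_replicates), function(i)
    derive_seed(config$seed, paste0("replicate", i)), integer(1))
  stopifnot(length(seeds) == n_replicates)
  tabs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    rep_out <- run_benchmark(cfg)
    cm <- rep_out$confusion
    cm[cm$alpha == cfg$evaluation$alpha, ]
  })
  all <- do.call(rbind, Map(cbind, tabs, replicate = seq_along(tabs)))
  agg <- do.call(rbind, lapply(split(all, all$method), function(d)
    data.frame(method = d$method[1],
               sens_mean = mean(d$sensitivity), sens_sd = stats::sd(d$sensitivity),
               spec_mean = mean(d$specificity), spec_sd = stats::sd(d$specificity),
               fp_mean = mean(d$fp_pct), fp_sd = stats::sd(d$fp_pct),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(reports = tabs, summary = agg, seeds = seeds)
}
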