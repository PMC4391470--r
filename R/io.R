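# Readers/writers for the standard text formats: PLINK .ped/.map and
# .tped/.tfam, BED gene annotation, GMT gene sets, association TSV and
# phenotype TSV. All whitespace-delimited plain text; all round-trip tested.

fam_frame <- function(gt, status = NULL) {
  n <- gt$n_samples
  pheno <- rep(-9L, n)
  if (!is.null(status)) {
    y <- status_vector(status, n)
    pheno <- ifelse(is.na(y), -9L, y + 1L) # 1 = control, 2 = case
  }
  data.frame(fid = sprintf("F%04d", seq_len(n)), iid = sprintf("I%04d", seq_len(n)),
             pat = 0L, mat = 0L, sex = 0L, pheno = pheno)
}

#' Write genotypes as PLINK .ped/.map
#'
#' @param gt a \code{genotype_matrix}.
#' @param prefix file prefix; writes \code{prefix.ped} and \code{prefix.map}.
#' @param status optional \code{cohort_status} / 0-1 vector for column 6
#'   (1 = control, 2 = case, -9 = unsampled/missing).
#' @return the prefix, invisibly.
#' @export
write_plink_ped <- function(gt, prefix, status = NULL) {
  v <- gt$variants
  utils::write.table(data.frame(v$chrom, v$snp_id, 0, v$pos),
                     paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- gt$n_samples; m <- nrow(v)
  a1 <- matrix(ifelse(gt$dosage >= 1, rep(v$allele_minor, each = n),
                      rep(v$allele_major, each = n)), n, m)
  a2 <- matrix(ifelse(gt$dosage == 2, rep(v$allele_minor, each = n),
                      rep(v$allele_major, each = n)), n, m)
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, 2L)] <- a1
  geno[, seq(2L, 2L * m, 2L)] <- a2
  utils::write.table(cbind(fam_frame(gt, status), geno), paste0(prefix, ".ped"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

#' Read PLINK .ped/.map genotypes
#'
#' The minor allele per SNP is inferred from allele frequency (ties keep the
#' first allele seen), so dosages count minor alleles as in the simulator.
#'
#' @param prefix file prefix of \code{prefix.ped} / \code{prefix.map}.
#' @return list: \code{genotypes} (a \code{genotype_matrix}; MAF and block
#'   recomputed from data) and \code{pheno} (column-6 vector).
#' @export
read_plink_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(ped); m <- nrow(map)
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- geno[, seq(1L, 2L * m, 2L), drop = FALSE]
  a2 <- geno[, seq(2L, 2L * m, 2L), drop = FALSE]
  dos <- matrix(0L, n, m)
  minor <- major <- character(m)
  maf <- numeric(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    tab <- table(factor(al, levels = unique(al)))
    minor[j] <- names(tab)[which.min(tab)]
    major[j] <- names(tab)[which.max(tab)]
    if (length(tab) == 2L && minor[j] == major[j])
      major[j] <- setdiff(names(tab), minor[j]) # exact frequency tie
    dos[, j] <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    maf[j] <- mean(al == minor[j])
  }
  variants <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                         allele_minor = minor, allele_major = major,
                         maf = maf, block = NA_integer_, stringsAsFactors = FALSE)
  colnames(dos) <- map$snp_id
  list(genotypes = structure(list(variants = variants, dosage = dos, n_samples = n),
                             class = "genotype_matrix"),
       pheno = ped[, 6])
}

#' Write genotypes as PLINK .tped/.tfam
#' @inheritParams write_plink_ped
#' @export
write_plink_tped <- function(gt, prefix, status = NULL) {
  utils::write.table(fam_frame(gt, status), paste0(prefix, ".tfam"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  v <- gt$variants
  n <- gt$n_samples
  con <- file(paste0(prefix, ".tped"), "w")
  on.exit(close(con))
  for (j in seq_len(nrow(v))) {
    d <- gt$dosage[, j]
    a1 <- ifelse(d >= 1, v$allele_minor[j], v$allele_major[j])
    a2 <- ifelse(d == 2, v$allele_minor[j], v$allele_major[j])
    alle <- character(2L * n)
    alle[seq(1L, 2L * n, 2L)] <- a1
    alle[seq(2L, 2L * n, 2L)] <- a2
    cat(v$chrom[j], v$snp_id[j], 0, v$pos[j], alle, "\n", file = con)
  }
  invisible(prefix)
}

#' Read PLINK .tped/.tfam genotypes
#' @inheritParams read_plink_ped
#' @export
read_plink_tped <- function(prefix) {
  tfam <- utils::read.table(paste0(prefix, ".tfam"), header = FALSE,
                            stringsAsFactors = FALSE)
  tp <- utils::read.table(paste0(prefix, ".tped"), header = FALSE,
                          stringsAsFactors = FALSE)
  m <- nrow(tp); n <- nrow(tfam)
  dos <- matrix(0L, n, m)
  minor <- major <- character(m); maf <- numeric(m)
  am <- as.matrix(tp[, -(1:4), drop = FALSE])
  for (j in seq_len(m)) {
    a1 <- am[j, seq(1L, 2L * n, 2L)]; a2 <- am[j, seq(2L, 2L * n, 2L)]
    al <- c(a1, a2)
    tab <- table(factor(al, levels = unique(al)))
    minor[j] <- names(tab)[which.min(tab)]
    major[j] <- names(tab)[which.max(tab)]
    if (length(tab) == 2L && minor[j] == major[j])
      major[j] <- setdiff(names(tab), minor[j]) # exact frequency tie
    dos[, j] <- (a1 == minor[j]) + (a2 == minor[j])
    maf[j] <- mean(al == minor[j])
  }
  variants <- data.frame(snp_id = tp[, 2], chrom = tp[, 1], pos = tp[, 4],
                         allele_minor = minor, allele_major = major,
                         maf = maf, block = NA_integer_, stringsAsFactors = FALSE)
  colnames(dos) <- variants$snp_id
  list(genotypes = structure(list(variants = variants, dosage = dos, n_samples = n),
                             class = "genotype_matrix"),
       pheno = tfam[, 6])
}

#' Write gene annotation as BED (0-based half-open)
#' @param genes gene annotation data frame (1-based inclusive internally).
#' @param path output file.
#' @export
write_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read BED gene annotation (back to 1-based inclusive)
#' @param path BED file.
#' @param flank_bp flank attribute to attach (default 20000).
#' @export
read_bed <- function(path, flank_bp = 20000) {
  b <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = b[, 4], chrom = b[, 1],
                      start = b[, 2] + 1L, end = b[, 3],
                      stringsAsFactors = FALSE)
  attr(genes, "flank_bp") <- flank_bp
  genes
}

#' Write a pathway collection as GMT
#'
#' One set per line: name, description (the size/causal class), member gene
#' ids, tab-delimited.
#'
#' @param pathways a \code{pathway_collection}.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pathways$sets)) {
    desc <- paste0(pathways$info$size_class[i], ":", pathways$info$causal_class[i])
    cat(paste(c(names(pathways$sets)[i], desc, pathways$sets[[i]]),
              collapse = "\t"), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path GMT file.
#' @return A \code{pathway_collection} (causal designations parsed from the
#'   description field are not recoverable; \code{causal} is empty).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  cls <- strsplit(desc, ":", fixed = TRUE)
  info <- data.frame(name = names(sets),
                     size = lengths(sets),
                     size_class = vapply(cls, `[[`, character(1), 1L),
                     causal_class = vapply(cls, function(x) x[2] %||% NA_character_, character(1)),
                     n_causal = NA_integer_, stringsAsFactors = FALSE)
  structure(list(sets = sets, causal = stats::setNames(vector("list", length(sets)), names(sets)),
                 info = info),
            class = "pathway_collection")
}

#' Write an association table as TSV (PLINK .assoc.logistic dialect)
#' @param assoc an \code{assoc_table}.
#' @param path output file.
#' @export
write_assoc <- function(assoc, path) {
  out <- data.frame(CHR = assoc$chrom, SNP = assoc$snp_id, BP = assoc$pos,
                    A1 = "m", TEST = "ADD", NMISS = NA, OR = exp(assoc$beta),
                    SE = assoc$se, STAT = assoc$z, P = assoc$p)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read an association table (PLINK dialect or minimal TSV)
#'
#' Accepts either PLINK-style columns (CHR, SNP, BP, OR/STAT/P) or a minimal
#' table with snp_id, chrom, pos, beta, p.
#'
#' @param path TSV file.
#' @return an \code{assoc_table}.
#' @export
read_assoc <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if ("SNP" %in% names(d)) {
    se <- if ("SE" %in% names(d)) d$SE else NA_real_
    z <- if ("STAT" %in% names(d)) d$STAT else stats::qnorm(d$P / 2) * -sign(log(d$OR))
    out <- data.frame(snp_id = d$SNP, chrom = d$CHR, pos = d$BP,
                      beta = log(d$OR), se = se, z = z, p = d$P,
                      flag = "", stringsAsFactors = FALSE)
  } else {
    out <- data.frame(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
                      beta = d$beta,
                      se = if ("se" %in% names(d)) d$se else NA_real_,
                      z = if ("z" %in% names(d)) d$z else stats::qnorm(pmin(d$p, 1) / 2) * -sign(d$beta),
                      p = d$p, flag = "", stringsAsFactors = FALSE)
  }
  out$p <- floor_p(out$p)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write phenotype as TSV (sample_id, status, liability)
#' @param status a \code{cohort_status}.
#' @param scores optional \code{liability_scores}.
#' @param path output file.
#' @export
write_phenotype <- function(status, path, scores = NULL) {
  n <- length(status$status)
  d <- data.frame(sample_id = sprintf("I%04d", seq_len(n)),
                  status = as.character(status$status),
                  liability = if (!is.null(scores)) scores$standardized else NA_real_)
  utils::write.table(d, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
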