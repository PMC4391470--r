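#' Additive polygenic liability scores
#'
#' Per individual, sums minor-allele dosage times the log odds ratio over all
#' causal SNPs of the design, then standardizes to mean 0 / sd 1. The
#' standardized score is the latent liability that drives case probability.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param design a \code{causal_design}.
#' @return list of class \code{liability_scores}: \code{raw} and
#'   \code{standardized} numeric vectors (one entry per sample).
#' @export
liability_scores <- function(genotypes, design) {
  snps <- design$snps
  missing <- setdiff(snps$snp_id, genotypes$variants$snp_id)
  if (length(missing))
    stop_gwasbench(sprintf("causal SNPs absent from genotypes: %s",
                           paste(utils::head(missing, 5), collapse = ", ")),
                   "gwasbench_invalid_parameter")
  dos <- genotypes$dosage[, snps$snp_id, drop = FALSE]
  raw <- as.numeric(dos %*% log(snps$odds_ratio))
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop_gwasbench("liability has zero variance (all odds ratios 1?)",
                   "gwasbench_degenerate_liability")
  structure(list(raw = raw, standardized = (raw - mean(raw)) / s),
            class = "liability_scores")
}

#' Assign case/control status from liability
#'
#' Case probability follows a logistic link on the standardized liability,
#' \code{P(case) = plogis(alpha + slope * L)}, with the intercept solved by
#' bisection so the mean case probability equals the target prevalence
#' (tolerance 1e-6). One Bernoulli draw per individual.
#'
#' @param scores a \code{liability_scores} object (or numeric vector taken as
#'   standardized liability).
#' @param prevalence target population prevalence in (0, 1).
#' @param slope effect of one liability SD on the log-odds of disease
#'   (default 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return integer vector of case indicators (1 = case, 0 = control) with
#'   attributes \code{prob} (per-sample case probability) and \code{alpha}
#'   (solved intercept).
#' @export
assign_status <- function(scores, prevalence = 0.5, slope = 1, seed = 1) {
  check_prob(prevalence, "prevalence")
  L <- if (inherits(scores, "liability_scores")) scores$standardized else as.numeric(scores)
  f <- function(a) mean(stats::plogis(a + slope * L)) - prevalence
  sol <- stats::uniroot(f, lower = -60, upper = 60, tol = 1e-9)
  alpha <- sol$root
  prob <- stats::plogis(alpha + slope * L)
  set.seed(seed)
  y <- as.integer(stats::rbinom(length(L), 1L, prob))
  attr(y, "prob") <- prob
  attr(y, "alpha") <- alpha
  y
}

#' Sample a study cohort from simulated case status
#'
#' Three designs: \code{balanced_cc} draws equal numbers of cases and
#' controls; \code{case_cohort} keeps every individual; \code{subsampled_cc}
#' draws the stated (possibly unequal) counts uniformly without replacement.
#'
#' @param indicators per-sample case indicator (from [assign_status()]).
#' @param design one of \code{"balanced_cc"}, \code{"case_cohort"},
#'   \code{"subsampled_cc"}.
#' @param n_cases,n_controls requested counts (ignored for
#'   \code{case_cohort}; \code{n_controls} defaults to \code{n_cases} for
#'   \code{balanced_cc}).
#' @param seed integer seed.
#' @return A \code{cohort_status}: list with \code{status} (factor case /
#'   control / unsampled), \code{n_cases}, \code{n_controls} and
#'   \code{sampled} (integer index of sampled individuals).
#' @export
sample_cohort <- function(indicators, design = c("balanced_cc", "case_cohort", "subsampled_cc"),
                          n_cases = NULL, n_controls = NULL, seed = 1) {
  design <- match.arg(design)
  y <- as.integer(indicators)
  cases <- which(y == 1L); controls <- which(y == 0L)
  status <- factor(rep("unsampled", length(y)),
                   levels = c("case", "control", "unsampled"))
  set.seed(seed)
  if (design == "case_cohort") {
    status[cases] <- "case"; status[controls] <- "control"
  } else {
    if (design == "balanced_cc") n_controls <- n_controls %||% n_cases
    if (is.null(n_cases) || is.null(n_controls))
      stop_gwasbench("n_cases (and n_controls) required for this design",
                     "gwasbench_invalid_parameter")
    if (length(cases) < n_cases || length(controls) < n_controls)
      stop_gwasbench(sprintf(
        "too few cases/controls realized (%d/%d, need %d/%d); redraw status with a new seed",
        length(cases), length(controls), n_cases, n_controls),
        "gwasbench_resimulate")
    status[sample_from(cases, n_cases, replace = FALSE)] <- "case"
    status[sample_from(controls, n_controls, replace = FALSE)] <- "control"
  }
  structure(list(status = status,
                 n_cases = sum(status == "case"),
                 n_controls = sum(status == "control"),
                 sampled = which(status != "unsampled"),
                 design = design),
            class = "cohort_status")
}

#' @export
print.cohort_status <- function(x, ...) {
  cat(sprintf("cohort_status (%s): %d cases, %d controls, %d unsampled\n",
              x$design, x$n_cases, x$n_controls,
              sum(x$status == "unsampled")))
  invisible(x)
}
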