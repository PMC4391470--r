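---
title: "Benchmarking gene- and pathway-level GWAS methods on simulated data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene- and pathway-level GWAS methods on simulated data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gwasbench` is a closed-loop benchmark: it simulates a case–control GWAS
with a fully known causal architecture, applies eleven gene-level and seven
pathway-level aggregation methods to the scan, and scores each method
against the planted truth. This vignette documents the generative model and
its assumptions, the statistical methods as implemented, the tunable
parameters that matter, the numerical choices, and what the benchmark can
and cannot say about real data.

## The generative model

### Genotypes

Real GWAS genotypes carry block-structured linkage disequilibrium. We
emulate this with a latent-Gaussian haplotype model: SNPs are grouped into
blocks (block sizes drawn from a configurable set, default 2–12 SNPs), and
within a block a latent standard normal follows an AR(1) process with
parameter `rho` (default 0.8). A haplotype carries the minor allele at SNP
*j* when its latent value falls below `qnorm(maf_j)`; two independent
haplotypes are summed per individual, so dosages count minor alleles and
Hardy–Weinberg equilibrium holds by construction. Adjacent-SNP genotype
correlation is a monotone (tetrachoric-type) function of `rho`, decaying
geometrically with distance inside a block and vanishing across block
boundaries; blocks never span chromosomes.

This one-parameter LD model was chosen over resampling real haplotypes
because it is fully self-contained, seeded, and gives analytic control of
the independence structure the LD-aware methods must undo. What it does
*not* reproduce: allele-frequency-dependent LD, recombination hotspots,
long-range admixture LD, or any population structure — the simulated cohort
is homogeneous by design, mirroring a post-QC, PCA-screened analysis
sample.

Minor allele frequencies are drawn Uniform(0.05, 0.5). A 1 % MAF floor
would mimic a common QC filter; the 5 % floor keeps every per-SNP logistic
fit well-conditioned at desk-scale sample sizes, and no method under study
targets rare variants.

### Genes, pathways and causal architecture

Genes tile each chromosome with lengths and gaps drawn from configurable
sets (defaults: 30/60/90 kb genes, 60–120 kb gaps). SNPs are assigned to a
gene if they fall within its span ± 20 kb, the conventional *cis*-eQTL
distance; overlapping flanked spans assign a SNP to both genes.

Twenty pathways are drawn in two size classes — ten larger than the median
gene-set size of 28 and ten at or below it — and, within each class, 4
pathways receive a single causal gene, 4 receive 20 % causal genes and 2
receive 50 %. Fractional counts round up, so every designated pathway has
at least one causal gene. Causal genes are unique across pathways (a gene
designated causal in one set is never causal in another), while non-causal
members may be shared; this keeps the per-pathway causal dose
interpretable.

Within each causal gene, candidate SNPs in the flanked span are greedily
pruned by ascending position at pairwise r² ≤ 0.2, and 1, 2 or 5 causal
SNPs are sampled from the pruned set with weights 8 : 22 : 20, the default
mix of mono-, bi- and penta-signal genes in the benchmark design. Greedy
positional r² pruning is the standard stand-in for tag-SNP selection. Each
gene's causal SNPs share one odds ratio, 1.2 or 2.0, with genes split
evenly between the two (an odd gene out gets 2.0). If a gene cannot supply
the requested number of independent SNPs, generation fails loudly rather
than silently under-assigning.

### Phenotype

The liability of individual *i* is the additive burden
`L_i = sum_j g_ij * ln(OR_j)` over all causal SNPs, standardized to mean 0
and SD 1. Case probability follows a logistic link,
`P(case_i) = plogis(alpha + slope * L_i)`, with `slope = 1` per liability
SD and `alpha` solved by bisection so the mean case probability equals the
target prevalence (tolerance 1e-6; default prevalence 0.5). One Bernoulli
draw per individual yields status.

Two modelling choices deserve flagging. First, the link from standardized
liability to case probability is not uniquely determined by a phrase like
"assigned using a binomial distribution"; we use the logistic link because
it matches the analysis model (additive logistic regression), making the
generative and analytic scales commensurate. A probit or hard-threshold
link would change absolute power but not the relative ordering of methods.
Second, standardizing the liability before the link rescales every per-SNP
effect by 1/SD(raw liability): with hundreds of causal SNPs the realized
per-SNP odds ratios in the GWAS are much closer to 1 than the nominal 1.2
or 2.0. This dilution is inherent to the design being emulated and is why
absolute sensitivities are modest; the benchmark's claims are therefore
about the *relative* performance of methods, never absolute power.

Cohorts: `balanced_cc` samples equal numbers of cases and controls (default
45 % of the population each, leaving head-room for the binomial draw),
`case_cohort` keeps everyone, and `subsampled_cc` draws stated unequal
counts — the latter two support prevalence-sensitivity designs such as 14 %
prevalence with 633 cases against 3,867 or 633 controls.

## The association scan

Each SNP is tested with an unadjusted additive logistic regression
(`status ~ dosage`), fit by Newton–Raphson vectorized across SNPs; the
reported p is the two-sided Wald test, the convention of standard GWAS
software. SNPs monomorphic in the cohort are flagged with beta 0, p 1.
Fits that fail to converge or show separation fall back to the score test
and are flagged. P-values are floored at 1e-300 before any log transform.
The genome-wide significance constant 5e-7 is stored for reporting only
and never used as a filter.

Phenotype-permutation methods need thousands of full rescans; these use
the logistic *score* test, computed for all SNPs and all permutations in a
single matrix product. The score and Wald tests are asymptotically
equivalent, and at the benchmark sample sizes their z statistics correlate
above 0.99; the observed scan stays Wald so that the headline association
table matches standard output.

## Gene-level methods

All methods consume the vector of SNP p-values in one gene (plus its LD
matrix where stated) and return one gene-level p:

* **Fisher** `X = -2 * sum(log p)` against chi-square with 2m df — assumes
  independence and inflates under LD.
* **Sidak** `1 - (1 - min p)^m`.
* **Simes** `min_j m * p_(j) / j`.
* **FDR-min** the smallest Benjamini–Hochberg-adjusted p in the gene.
  Numerically this equals Simes on a plain vector; it is kept as its own
  column because the two are distinct procedures with distinct reporting
  conventions, and they diverge once weights enter.
* **TPM** multiplies only p-values ≤ τ (default 0.1) and evaluates the
  truncated-product tail with the exact closed-form sum over the number of
  truncated terms; at τ = 1 it reproduces Fisher exactly. Computed in log
  space with a log-sum-exp reduction; a Monte-Carlo cross-check is
  exported.
* **GATES** extended Simes: SNP p-values are sorted and the Simes bound is
  corrected by the effective number of tests
  `m_e = m - sum((lambda_i - 1)+)` computed from the p-value correlation
  matrix, itself obtained from genotype correlation through a fixed
  sixth-degree polynomial. Reduces exactly to Simes under identity LD.
* **Weighted GATES** divides p-values by per-SNP weights (normalized to
  mean 1) before sorting. The published weighting scheme is not specified
  in the original software's description; the default is uniform weights,
  which reproduce the unweighted test exactly. The weight hook is exposed
  for users with genuine priors.
* **HYST** partitions the gene into contiguous LD blocks (greedy scan,
  block extended while the incoming SNP has r² > 0.3 with any block
  member; the threshold is configurable since no blocking rule is
  published), takes each block's GATES p and key SNP, and combines blocks
  with a Brown-style scaled chi-square whose scale and df match the
  moments implied by between-block key-SNP p-value correlations
  (`cov = rho * (3.25 + 0.75 * rho)`, positive part). One block gives
  exactly that block's GATES p; independent blocks give exactly Fisher.
* **VEGAS** converts p-values to 1-df chi-squares, sums the top-k
  (k = `ceil(top_fraction * m)`, floored at 1 so the "top 10 %" of a
  5-SNP gene is never empty), and simulates the null by multivariate
  normal draws with the gene's LD matrix, ridge-stabilized with 1e-6 on
  the diagonal before the Cholesky factorization. Empirical p uses the
  (1 + hits)/(1 + sims) correction and never returns 0.

## Pathway-level methods

Competitive methods compare in-set signal against the genome-wide
background; self-contained methods test the set's own joint null.

* **GSA-SNP** (competitive): gene score −log(2nd-smallest SNP p); pathway
  Z = (in-set mean − all-gene mean)/(all-gene SD/√set size), upper-tail
  normal, with a BH-adjusted column.
* **GSEA engine** (competitive): genes ranked by an association statistic;
  weighted Kolmogorov–Smirnov running-sum enrichment score per set;
  significance by case/control label permutation with the full scan and
  gene statistics recomputed per permutation. Two configurations share
  the engine — max 1-df chi-square per gene (GenGen-style) and max |z|
  (GSEA-SNP-style) — because the two published programs differ only in
  plumbing not described algorithmically.
* **ALIGATOR** (competitive): a gene is significant if it contains a SNP
  with p < 0.01; null replicates draw SNPs without replacement until the
  replicate's distinct significant-gene count matches the observed one,
  correcting for gene size by construction.
* **MAGENTA-like** (competitive): gene score −log(best p) regressed on
  gene span, SNP count and independent-SNP count; enrichment counts set
  genes above the 75th percentile of residual scores (cutoff
  configurable; the published cutoff is not stated), with significance
  from equal-size random gene sets.
* **SNP Ratio Test** (competitive): fraction of set SNPs with p < 0.05,
  against label permutations.
* **Plink-style set test** (self-contained): within the set, SNPs are
  scanned by ascending p, greedily pruned at r² ≤ 0.5, and up to 5 SNPs
  with p < 0.05 contribute their mean −log p; label permutations repeat
  the entire selection.
* **Pathway HYST** (self-contained): the Brown combination applied across
  all LD blocks of all member genes, with between-gene key-SNP
  correlations set to zero (genes are separated by at least an intergenic
  gap, and blocks never cross genes' chromosomes).

Permutation defaults are 1,000 label permutations / resamples per method
at benchmark scale; all engines share one permutation block per run and
every empirical p respects the 1/(B+1) floor. Ranks within a method break
ties lexicographically by pathway name for determinism. When a SNP maps to
two overlapping flanked spans it counts for both genes, the standard
practice.

## Evaluation

True-positive genes are designed causal genes that realized at least one
SNP with p < 0.01 — the simulation is stochastic and not every causal gene
contributes signal, so TP status is defined by realized signal rather than
by design. True negatives are non-causal genes more than 50 kb
from every causal gene; everything else is excluded. Sensitivity
(fraction of TP genes with gene p < 0.001) and specificity (fraction of a
50-gene TN subset with p > 0.001) are computed on the balanced subset —
the TN subset is drawn with a dedicated, recorded seed — while FP% and
FN% use the full labeled sets. A threshold sweep
{1e-3, 1e-4, 1e-5, 2.9e-6} brackets the range from the headline threshold
to a Bonferroni bound of 0.05/17,000. Sensitivities are additionally
stratified by odds ratio and by causal-SNP count.

Pathways are scored by ranks: within each method, rank 1 is the smallest
p; the consensus is the mean rank across methods; and each method's ranks
are correlated (Pearson, with Fisher-z 95 % CIs) against the realized
causal-gene proportion and against the consensus. Only the ten large
pathways enter the correlations — the small classes' causal genes rarely
realize signal, and including ten near-null sets would swamp the
comparison. The realized (post-simulation) causal proportion is used as
the x-axis rather than the designed fraction, because the evaluation
defines causality by realized signal.

## Problem sizes and runtime

The default configuration — 2,000 individuals, 20,000 SNPs, roughly 400
genes, 20 pathways, 1,000 VEGAS simulations per gene and 1,000
permutations per pathway engine — was chosen as the largest round-number
study that keeps a complete end-to-end run near one minute on a single
core, so that the three-replicate directional analyses and the
ten-replicate stability check remain interactive. The stability
replication restricts to two representative gene-level methods (Fisher and
VEGAS) with no pathway panel, which is where stability is informative:
FP% and specificity are computed over hundreds of true-negative genes. The null-calibration
panels use 2,000 ten-SNP genes at 1,000 samples, enough for a ±0.015
three-SE band around a nominal 0.05.

## What passing this benchmark does and does not show

The simulation reproduces the *structural* phenomena the methods differ
on: LD-driven inflation of independence-assuming combiners, the effective
number of tests, allelic heterogeneity (multiple independent causal SNPs
per gene), competitive versus self-contained set testing, and gene-size
confounding. It does not reproduce realistic allele-frequency spectra,
fine-scale recombination, population stratification, genotyping error or
missingness — so absolute sensitivities and false-positive rates here do
not transfer to any particular real cohort, while the relative ordering
and the directional contrasts (which methods inflate under LD, which gain
from multiple causal SNPs, which pathway methods track causal dose) are
the reproducible content.

## Numerical and degenerate-input conventions

* p-values floored at 1e-300 before logs; empirical p never 0.
* LD matrices get ridge 1e-6 on the diagonal before factorization.
* Monomorphic SNPs: association p 1, LD correlation 0, flagged.
* Genes with no SNPs in the flanked span are dropped from method panels;
  pathways with no scored genes are flagged with p 1.
* Ties in ranks break by name; the TN subset seed is recorded in the
  report; every stage seed derives deterministically from one master seed,
  and identical configurations are byte-identical in their results.
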