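---
title: "Models and methods behind pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
options(pleioscan.verbose = FALSE)
```

`pleioscan` detects pleiotropic loci — variants associated with two
distinct complex traits — from GWAS summary statistics alone. This
vignette documents the statistical models, the defaults and why they were
chosen, the synthetic-data generators used to validate everything, and
the limitations a user should keep in mind.

## Input model and harmonization

Each trait arrives as a per-SNP table: rsid, chromosome and 1-based
position, effect and other allele, effect size with standard error,
two-sided p-value in (0, 1], sample size, imputation INFO and
effect-allele frequency. Validation drops rows that violate these ranges
(a p-value of exactly 0 is invalid on input; downstream code clips p to
1e-300 before any log transform). QC retains SNPs with INFO strictly
above 0.9 and minor allele frequency strictly above 0.01; records with
*missing* INFO or frequency fail QC, because an unevaluable filter
applied permissively would silently admit exactly the SNPs the filter
exists to remove.

Merging joins on rsid (the convention of HapMap3-labelled workflows, and
robust to build differences that would break positional joins). Allele
reconciliation handles coding swaps (flip the second trait's z sign) and
strand flips (complement, then compare); palindromic A/T and C/G SNPs are
dropped outright since strand cannot be resolved from the alleles alone.
The pipeline is p-value-driven downstream, so this conservative loss
costs little. Chromosomes are normalized to autosomes 1–22; both GWAS
types this package targets are autosome-dominated and sex-chromosome
association models differ enough that silently mixing them would be worse
than excluding them.

## LD pruning

The pruning rule is pairwise: whenever two retained SNPs have squared
genotype correlation r² **strictly greater than** 0.2 (computed from a
reference panel), the member with the smaller minor allele frequency is
discarded; an exact MAF tie discards the later-positioned SNP so the
result is deterministic. Mechanically this runs as a greedy sliding
window (50 SNPs wide, advancing by 5, both configurable) in the manner of
the standard pruning toolkits; within a window the worst offending pair
is resolved first. The window mechanics are a package choice — only the
pairwise rule and threshold are fixed by the method — and are surfaced in
the configuration. Tests verify the windowed implementation against an
exhaustive full-pair-scan enumeration on small fixtures, plus the
invariants: pruned output is a subset of its input, re-pruning is a
no-op, and raising the threshold never shrinks the survivor set.

LD scores sum bias-adjusted squared correlations `r² − (1 − r²)/(n − 2)`
over a positional window around each SNP (self term included). The
default window is 1 Mb, the conventional proxy for 1 centimorgan when no
genetic map is available.

## LD score regression

Single-trait: `E[chi²_j] = intercept + (n h²/m) ℓ_j`. Cross-trait:
`E[z1_j z2_j] = intercept + (sqrt(n1 n2) gencov/m) ℓ_j`, with
`r_g = gencov / sqrt(h²_1 h²_2)`. Both are weighted least squares with
weights `1/(max(ℓ,1) · max(1, predicted)²)`, iterated twice: the first
factor discounts LD-redundant SNPs, the second is the usual variance
proxy for a chi-square-like response. The cross-trait fit deliberately
reuses the *same* reweighting scheme on the product statistic; this keeps
the estimator exactly symmetric in the two traits and makes regressing a
trait on itself return its own heritability (hence r_g = 1) identically,
at the cost of a slightly cruder variance model than the product-form
`pred1·pred2 + pred_cross²`.

Standard errors come from a delete-block jackknife over 200 contiguous
SNP blocks (block structure absorbs residual LD between neighbouring
SNPs). The r_g jackknife holds the two heritabilities fixed, so the
reported SE ignores their sampling error; the p-value for r_g = 0 is a
normal approximation on rg/se. r_g is clamped to [−1, 1] with the raw
value retained. Only the free-intercept variant is implemented — the
intercept is itself the confounding diagnostic (values near 1 mean no
inflation) — and no liability-scale conversion is attempted for binary
traits. On simulated GWAS (block-LD panel, disjoint cohorts of 5,000 per
trait, 2,000 SNPs, h² = 0.25, r_g = 0.5) the estimates land within three
jackknife SEs of the truth and the intercept within three SEs of 1; the
jackknife SE itself tracks the replicate spread within a factor of two.

## Conditional and conjunction FDR

The conditional FDR of SNP s for the principal trait, given the
conditional trait, is the posterior probability of the principal null
when both observed p-values bound the truth:
`cFDR(p_i | p_j) = Pr(H0_i | P_i <= p_i, P_j <= p_j)`. The estimator is
the empirical plug-in

```
cFDR(s) = p_i(s) * N_j(s) / N_ij(s)
```

with `N_j = #{t : p_j(t) <= p_j(s)}` and
`N_ij = #{t : p_i(t) <= p_i(s), p_j(t) <= p_j(s)}`, counts *inclusive* of
SNP s itself (ties use <=, matching the "as small as or smaller"
definition, and inclusivity guarantees N_ij >= 1 so the estimator is
always defined). Values are capped at 1. Direct counting is exact:
some published implementations interpolate over a two-dimensional
p-value grid, but exact counting is O(n log n) with a Fenwick tree over
dense p-ranks and leaves nothing to a smoothing choice. A quadratic
double-loop implementation is kept in the test suite as the oracle;
agreement is exact, ties included. No monotonicity enforcement across
conditioning strata is applied — the raw estimator can be locally
non-monotone — and cFDR is computed on the LD-pruned set, where the
near-independence assumption behind the empirical counts is most
defensible.

The conjunction statistic ccFDR is the per-SNP maximum of the two
reciprocal cFDRs: a SNP only scores well if it looks non-null for *both*
traits. Calls use strict thresholds, 0.05 for both cFDR and ccFDR.

## The four-group mixture (GPA)

Each SNP j carries a latent label: null for both traits (probability
pi00), trait-1 only (pi10), trait-2 only (pi01), or jointly associated
(pi11). Given the label the two p-values are independent, Uniform(0,1)
in a null margin and Beta(alpha_k, 1) with 0 < alpha_k < 1 in an
associated margin — a density `alpha p^(alpha-1)` that concentrates near
zero. Both EM steps are closed-form: responsibilities from the
factorized densities, proportions as responsibility means, and each
alpha from the Beta(alpha, 1) MLE `-sum(w) / sum(w log p)` with weights
given by the trait's associated-class responsibilities, projected into
[1e-4, 1 − 1e-4].

Numerical choices: p-values are clipped to [1e-30, 1] before the log
transform (the Beta density explodes at 0; the floor is far below any
GWAS-meaningful p-value and keeps log-densities finite). Initialization
is pi = (0.7, 0.1, 0.1, 0.1), alpha = (0.5, 0.5); convergence is a
relative log-likelihood change below 1e-8 with a 5,000-iteration cap.
The log-likelihood trace is stored and asserted non-decreasing in the
tests — the EM guarantee doubles as a regression test on the M-step
algebra.

One boundary deserves care: at alpha = 1 the Beta margin *is* Uniform,
so mass can drift between a null class and its alpha-at-bound associated
class without changing the likelihood. On data with little or no signal
the EM can wander along this ridge. When a fitted alpha reaches its
upper bound the package folds the affected classes' mass back into the
matching null classes — the identifiable representative on the ridge,
and the scientifically conservative one — and flags the fit
(`alpha_at_bound`).

Per-SNP local fdrs follow from the responsibilities: `fdr_A = gamma00 +
gamma01` (no trait-A association), analogously `fdr_B`, and
`fdr11 = 1 − gamma11` (not jointly associated). The conventional call
threshold is 0.2, a configuration default rather than a constant.
Proportion standard errors are delta-method values from a numerically
differentiated observed information matrix in an unconstrained
parameterization (softmax for the proportions, logit for the alphas);
classes collapsed at the boundary are profiled out with SE 0, and a
singular information matrix yields missing SEs with a warning. Whether
to use observed information was an open choice; it is the cheapest
option consistent with the reported replicate-spread checks.

### The pleiotropy LRT

Pleiotropic enrichment means joint association occurs more often than
independent marginal associations would produce:
`pi11 > (pi10 + pi11)(pi01 + pi11)`. The test refits the mixture under
the independence constraint, reparameterized through the two marginal
association probabilities q1, q2 (two free proportion parameters instead
of three; the constrained M-step stays closed-form), and refers
`2 (loglik_full − loglik_constrained)` to chi-square with **1 degree of
freedom** — one equality constraint, in the parameter interior, so no
boundary correction applies. The df is corroborated numerically: the
chi-square(1) upper tail at a published statistic of 79.352 reproduces
its published p-value of 5.2e-19. If the constrained likelihood ever
exceeds the full one (a local EM maximum), the full model is re-run from
the constrained solution before the statistic is formed. Calibration is
verified by simulation: 500 replicates at n = 20,000 under the
independence null give a rejection rate within three binomial SEs of
0.05 and LRT statistics that pass a Kolmogorov–Smirnov test against
chi-square(1).

## Enrichment diagnostics

The stratified Q–Q table conditions the principal trait's p-values on
successively stricter thresholds of the other trait
(t in {1, 0.1, 0.01, 0.001}, the four-curve convention of this
literature) and pairs each stratum's sorted observed −log10 p with
expected null quantiles `−log10((rank − 0.5)/n_t)`; the (rank − 0.5)/n
convention is a package choice among the standard plotting positions.
Pleiotropic enrichment appears as curves leaving the null line earlier
in stricter strata. Fold-enrichment curves show the ratio of each
stratum's empirical tail CDF to the full set's on a −log10 grid (the
full-set curve is identically 1 and anchors the reading). Manhattan
tables carry −log10 cFDR or ccFDR against a cumulative genome
coordinate with the −log10(0.05) ≈ 1.30 line attached. All assertions
in the test suite target these tables; the `autoplot()` layers are thin
ggplot2 views with no logic of their own.

## Synthetic data: what it emulates and what it does not

`simulate_fourgroup()` draws labels from a multinomial and p-values
independently given the label, exactly the mixture's factorization. Its
default proportions (0.857, 0.048, 0.090, 0.005) mirror the fitted
decomposition of the childhood-BMI / coronary-artery-disease pair that
the package's worked examples revolve around, with alpha = (0.3, 0.4) as
a representative signal strength. LD is deliberately absent from this
generator: the mixture is fitted after pruning, so near-independence is
the working assumption being emulated.

`simulate_panel()` builds genotypes by thresholding block-AR(1) latent
Gaussians (two independent haplotypes per individual), giving
block-diagonal LD with tunable within-block correlation.
`simulate_two_trait_gwas()` draws per-SNP effect pairs that are
bivariate normal with covariance `rg sqrt(h²_1 h²_2)/m`, splits the
panel into disjoint cohorts (no sample overlap, so no cross-trait
intercept inflation), and runs per-SNP marginal regressions.

What passing tests on this synthetic world *do not* show: robustness to
realistic allele-frequency spectra, population structure and relatedness,
residual post-pruning LD, sample overlap between the two GWAS,
case-control liability-scale effects, or p-values produced by
meta-analysis pipelines. The generators exist to verify the estimators
under their own assumptions, not to certify behaviour on arbitrary real
data.

All generators are seeded, thread the seed through every draw, and leave
the caller's RNG state untouched; the same seed reproduces outputs
bit-for-bit.

## Problem sizes and determinism

Validation uses sizes chosen to exercise the asymptotics this class of
estimator relies on while remaining comfortable on a single CPU:
parameter recovery at n = 100,000 over a ten-seed grid (each proportion
recovered within ±0.01, each alpha within ±0.05 in the median), LRT
calibration with 500 replicates at n = 20,000, LD score regression on a
10,000-individual, 2,000-SNP panel, and exact cFDR/oracle agreement up
to n = 2,000. The acceptance script (`scripts/acceptance.R`) recomputes
the same quantities from scratch at a caller-chosen seed.

## Combining the two methods

The default combined call set intersects the cFDR calls with the GPA
calls, per trait and for pleiotropy: a SNP is reported only when two
methodologically unrelated estimators — one empirical-counting, one
model-based — agree. A configuration switch (`combine = "union"`) is
available for sensitivity analysis.

## Known limitations

- Two traits only; no annotation covariates in the mixture (the
  annotation-augmented variant of the four-group model is out of scope).
- No permutation null for cFDR, and no FDR control by averaging sorted
  local fdrs — thresholding is applied to the per-SNP quantities
  directly, as is conventional for these methods.
- Observed-scale heritability only; interpreting h² for binary traits on
  the liability scale is left to the user.
- rsid-keyed merging assumes consistent rsid dictionaries between the two
  studies; no liftover, VCF parsing, or multi-allelic support.
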