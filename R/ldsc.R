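# Simplified LD score regression.
#
# Single-trait model:  E[chi2_j] = intercept + (n * h2 / m) * ell_j
# Cross-trait model:   E[z1_j z2_j] = intercept + (sqrt(n1 n2) * gencov / m) * ell_j
#
# Both are fitted by iteratively reweighted least squares with weights
# 1 / (max(ell, 1) * max(1, predicted)^2): the max(ell,1) factor discounts
# LD-redundant SNPs, the squared prediction approximates the chi2 (resp.
# product) variance. Standard errors come from a delete-block jackknife
# over contiguous SNP blocks.

# closed-form weighted least squares of y on (1, x); returns c(intercept, slope)
wls_fit <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  assert_that(abs(det) > 0, "degenerate regression design (constant LD scores?)")
  c((sxx * sy - sx * sxy) / det, (sw * sxy - sx * sy) / det)
}

# IRLS as described above; returns list(coef, w)
ldsc_irls <- function(ell, y, n_iter = 2) {
  w <- 1 / pmax(ell, 1)
  cf <- wls_fit(ell, y, w)
  for (i in seq_len(n_iter)) {
    pred <- cf[1] + cf[2] * ell
    w <- 1 / (pmax(ell, 1) * pmax(1, pred)^2)
    cf <- wls_fit(ell, y, w)
  }
  list(coef = cf, w = w)
}

# delete-block jackknife of the WLS coefficients at fixed weights;
# returns 2 x n_blocks matrix of leave-one-block-out coefficients
jackknife_coefs <- function(x, y, w, n_blocks) {
  m <- length(x)
  assert_that(m > n_blocks, "fewer SNPs than jackknife blocks")
  block <- ceiling(seq_along(x) / (m / n_blocks))
  stats_all <- c(sum(w), sum(w * x), sum(w * y), sum(w * x * x), sum(w * x * y))
  per_block <- rbind(
    tapply(w, block, sum), tapply(w * x, block, sum), tapply(w * y, block, sum),
    tapply(w * x * x, block, sum), tapply(w * x * y, block, sum)
  )
  vapply(seq_len(ncol(per_block)), function(b) {
    s <- stats_all - per_block[, b]
    det <- s[1] * s[4] - s[2]^2
    c((s[4] * s[3] - s[2] * s[5]) / det, (s[1] * s[5] - s[2] * s[3]) / det)
  }, numeric(2))
}

jackknife_se <- function(theta) {
  b <- length(theta)
  sqrt((b - 1) / b * sum((theta - mean(theta))^2))
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores under
#' `E[chi2_j] = intercept + (n h2 / m) ell_j`; the slope gives the SNP
#' heritability, and an intercept near 1 indicates absence of confounding
#' inflation. Standard errors come from a delete-block jackknife over
#' contiguous blocks of SNPs.
#'
#' @param z Per-SNP z-scores (aligned with `ld`).
#' @param ld LD scores: a numeric vector or the tibble from [ld_scores()].
#' @param n GWAS sample size.
#' @param m Number of SNPs the heritability is spread over (defaults to
#'   `length(z)`).
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return An object of class `ldsc_fit`: list with `h2`, `intercept`,
#'   `se_h2`, `se_intercept`, `m`, `n`, `n_blocks`.
#' @export
fit_h2 <- function(z, ld, n, m = length(z), n_blocks = 200) {
  ell <- if (is.data.frame(ld)) ld$ld_score else as.numeric(ld)
  assert_that(length(z) == length(ell), "z and ld lengths differ")
  assert_that(length(z) >= 200, "need at least 200 SNPs for a stable fit")
  chi2 <- z^2
  fit <- ldsc_irls(ell, chi2)
  h2 <- fit$coef[2] * m / n
  jk <- jackknife_coefs(ell, chi2, fit$w, n_blocks)
  structure(
    list(h2 = h2, intercept = fit$coef[1],
         se_h2 = jackknife_se(jk[2, ] * m / n),
         se_intercept = jackknife_se(jk[1, ]),
         m = m, n = n, n_blocks = n_blocks),
    class = "ldsc_fit"
  )
}

#' Estimate cross-trait genetic covariance and correlation
#'
#' Regresses the per-SNP product `z1_j z2_j` on LD scores under
#' `E[z1 z2] = intercept + (sqrt(n1 n2) gencov / m) ell_j`, using the same
#' iteratively reweighted scheme as [fit_h2()] applied to the product
#' statistic. The genetic correlation is `rg = gencov / sqrt(h2_1 h2_2)`,
#' clamped to [-1, 1] (the raw value is kept in `rg_unclamped`); its
#' jackknife standard error treats the input heritabilities as fixed, and
#' the p-value for rg = 0 uses a normal approximation to `rg / se_rg`.
#'
#' @param z1,z2 Per-SNP z-scores for the two traits (harmonized signs).
#' @param ld LD scores aligned with the z vectors.
#' @param n1,n2 The two GWAS sample sizes.
#' @param m Number of SNPs (defaults to `length(z1)`).
#' @param h2_1,h2_2 SNP heritabilities of the two traits (from [fit_h2()]);
#'   must be positive.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return An object of class `ldsc_rg_fit`: list with `rg`, `gencov`,
#'   `se_rg`, `p_rg`, `cross_intercept`, `rg_unclamped`.
#' @export
fit_rg <- function(z1, z2, ld, n1, n2, m = length(z1), h2_1, h2_2,
                   n_blocks = 200) {
  ell <- if (is.data.frame(ld)) ld$ld_score else as.numeric(ld)
  assert_that(length(z1) == length(z2) && length(z1) == length(ell),
              "z1, z2 and ld lengths differ")
  assert_that(h2_1 > 0 && h2_2 > 0, "nonpositive heritability: rg undefined")
  y <- z1 * z2
  fit <- ldsc_irls(ell, y)
  gencov <- fit$coef[2] * m / sqrt(n1 * n2)
  rg_raw <- gencov / sqrt(h2_1 * h2_2)
  jk <- jackknife_coefs(ell, y, fit$w, n_blocks)
  se_rg <- jackknife_se(jk[2, ] * m / sqrt(n1 * n2)) / sqrt(h2_1 * h2_2)
  rg <- max(-1, min(1, rg_raw))
  if (rg != rg_raw) ps_log("rg clamped: raw value ", signif(rg_raw, 4))
  p_rg <- if (se_rg > 0) 2 * stats::pnorm(-abs(rg_raw / se_rg)) else NA_real_
  structure(
    list(rg = rg, rg_unclamped = rg_raw, gencov = gencov, se_rg = se_rg,
         p_rg = max(p_rg, .Machine$double.xmin), cross_intercept = fit$coef[1],
         m = m, n1 = n1, n2 = n2, n_blocks = n_blocks),
    class = "ldsc_rg_fit"
  )
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD score regression (single trait)\n",
      "  h2        = ", signif(x$h2, 4), " (se ", signif(x$se_h2, 3), ")\n",
      "  intercept = ", signif(x$intercept, 4), " (se ", signif(x$se_intercept, 3), ")\n",
      "  m = ", x$m, ", n = ", x$n, ", jackknife blocks = ", x$n_blocks, "\n", sep = "")
  invisible(x)
}

#' @export
print.ldsc_rg_fit <- function(x, ...) {
  cat("LD score regression (cross trait)\n",
      "  rg     = ", signif(x$rg, 4), " (se ", signif(x$se_rg, 3),
      ", p = ", format(x$p_rg, digits = 3), ")\n",
      "  gencov = ", signif(x$gencov, 4),
      ", cross intercept = ", signif(x$cross_intercept, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method
tidy.ldsc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h2", "intercept"),
    estimate = c(x$h2, x$intercept),
    std.error = c(x$se_h2, x$se_intercept)
  )
}

#' @exportS3Method
glance.ldsc_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, intercept = x$intercept, m = x$m, n = x$n,
                 n_blocks = x$n_blocks)
}

#' @exportS3Method
tidy.ldsc_rg_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg", "gencov", "cross_intercept"),
    estimate = c(x$rg, x$gencov, x$cross_intercept),
    std.error = c(x$se_rg, NA_real_, NA_real_),
    p.value = c(x$p_rg, NA_real_, NA_real_)
  )
}

#' @exportS3Method
glance.ldsc_rg_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, se_rg = x$se_rg, p_rg = x$p_rg,
                 gencov = x$gencov, m = x$m)
}
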