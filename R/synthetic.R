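# Seeded generators for every input the pipeline consumes, with ground
# truth attached. All randomness goes through R's Mersenne-Twister with an
# explicit seed, so the same seed gives identical output on any platform.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# default generating parameters for the canonical demo scenario: the
# mixture proportions match the fitted childhood-BMI / coronary-artery-
# disease decomposition this package's worked examples revolve around.
fourgroup_defaults <- function() {
  list(pi = c(0.857, 0.048, 0.090, 0.005), alpha = c(0.3, 0.4))
}

#' Simulate paired p-values from the four-group mixture
#'
#' Draws latent class labels from a multinomial with proportions `pi`
#' (classes 00, 10, 01, 11), then p-values independently given the label:
#' Uniform(0,1) for a null margin, Beta(alpha, 1) for an associated margin
#' (sampled as U^(1/alpha)).
#'
#' @param n Number of SNPs.
#' @param pi Length-4 mixture proportions (00, 10, 01, 11); must sum to 1.
#'   Default: the canonical demo scenario (0.857, 0.048, 0.090, 0.005).
#' @param alpha Length-2 Beta shapes in (0,1), default (0.3, 0.4).
#' @param seed Integer seed (mandatory: every generated table is
#'   reproducible by construction).
#' @return List with `paired` (a tibble with `snp_id`, `chrom`, `pos`,
#'   `p_A`, `p_B`, `maf`) and `truth` (a tibble with the latent `label`
#'   per SNP plus the generating parameters as attributes).
#' @export
simulate_fourgroup <- function(n, pi = fourgroup_defaults()$pi,
                               alpha = fourgroup_defaults()$alpha, seed) {
  assert_that(abs(sum(pi) - 1) < 1e-8 && all(pi >= 0), "pi must be a probability 4-vector")
  assert_that(length(alpha) == 2 && all(alpha > 0 & alpha < 1),
              "alpha must be two values in (0,1)")
  with_seed(seed, {
    lab <- sample.int(4L, n, replace = TRUE, prob = pi)
    assoc1 <- lab %in% c(2L, 4L)
    assoc2 <- lab %in% c(3L, 4L)
    p1 <- stats::runif(n)
    p2 <- stats::runif(n)
    p1[assoc1] <- p1[assoc1]^(1 / alpha[1])
    p2[assoc2] <- p2[assoc2]^(1 / alpha[2])
    chrom <- as.character(rep_len(1:22, n))
    paired <- tibble::tibble(
      snp_id = sprintf("rs%07d", seq_len(n)),
      chrom = chrom,
      pos = 1000L * (seq_len(n) %/% 22L + 1L) + seq_len(n) %% 22L,
      p_A = p1, p_B = p2,
      maf = stats::runif(n, 0.05, 0.5)
    )
    truth <- tibble::tibble(snp_id = paired$snp_id,
                            label = GPA_CLASSES[lab])
    attr(truth, "pi") <- pi
    attr(truth, "alpha") <- alpha
    attr(truth, "seed") <- seed
    list(paired = paired, truth = truth)
  })
}

#' Simulate an LD-structured reference genotype panel
#'
#' Haplotypes come from thresholding block-AR(1) latent Gaussians: within
#' each block of `block_size` consecutive SNPs the latent variables follow
#' an AR(1) with parameter `rho`, blocks are independent, and each of the
#' two haplotypes per individual is drawn independently. Per-SNP target
#' allele frequencies are Uniform over `maf_range`. SNPs are placed 1 kb
#' apart on chromosome 1.
#'
#' @param n_ind Number of individuals.
#' @param m_snp Number of SNPs.
#' @param block_size SNPs per LD block (default 10).
#' @param rho AR(1) latent correlation in [0, 1) (default 0.9).
#' @param maf_range Target allele-frequency range, within (0, 0.5]
#'   (default c(0.05, 0.5)).
#' @param seed Integer seed.
#' @return A [genotype_panel()].
#' @export
simulate_panel <- function(n_ind, m_snp, block_size = 10, rho = 0.9,
                           maf_range = c(0.05, 0.5), seed) {
  assert_that(rho >= 0 && rho < 1, "rho must be in [0,1)")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range must satisfy 0 < lo <= hi <= 0.5")
  with_seed(seed, {
    f <- stats::runif(m_snp, maf_range[1], maf_range[2])
    thr <- stats::qnorm(f)
    hap <- function() {
      z <- matrix(stats::rnorm(n_ind * m_snp), n_ind, m_snp)
      if (rho > 0) {
        for (j in 2:m_snp) {
          if ((j - 1) %% block_size != 0) {
            z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
          }
        }
      }
      z
    }
    dos <- (hap() < rep(thr, each = n_ind)) + (hap() < rep(thr, each = n_ind))
    storage.mode(dos) <- "double"
    genotype_panel(dos, snp_id = sprintf("snp%06d", seq_len(m_snp)),
                   pos = 1000L * seq_len(m_snp))
  })
}

#' Draw correlated per-SNP effect sizes for two polygenic traits
#'
#' Effects on standardized genotypes are bivariate normal per SNP with
#' covariance `[[h2_1/m, rg*sqrt(h2_1*h2_2)/m], [., h2_2/m]]`, so the
#' genetic variance of trait k is `h2_k` and the effect correlation is
#' `rg` (the genetic correlation).
#'
#' @param m Number of SNPs.
#' @param h2_1,h2_2 SNP heritabilities in [0, 1).
#' @param rg Genetic correlation in [-1, 1].
#' @param n1,n2 Sample sizes the GWAS simulator should use per trait.
#' @param seed Integer seed.
#' @return A list of class `polygenic_truth`: `beta1`, `beta2`, `h2_1`,
#'   `h2_2`, `rg`, `n1`, `n2`, `seed`.
#' @export
simulate_polygenic_truth <- function(m, h2_1, h2_2, rg, n1, n2, seed) {
  assert_that(h2_1 >= 0 && h2_1 < 1 && h2_2 >= 0 && h2_2 < 1,
              "heritabilities must lie in [0,1)")
  assert_that(abs(rg) <= 1, "rg must lie in [-1,1]")
  with_seed(seed, {
    z1 <- stats::rnorm(m)
    z2 <- rg * z1 + sqrt(1 - rg^2) * stats::rnorm(m)
    structure(
      list(beta1 = z1 * sqrt(h2_1 / m), beta2 = z2 * sqrt(h2_2 / m),
           h2_1 = h2_1, h2_2 = h2_2, rg = rg, n1 = n1, n2 = n2, seed = seed),
      class = "polygenic_truth"
    )
  })
}

#' Simulate two single-trait GWAS from a shared genotype panel
#'
#' Splits the panel's individuals into two disjoint cohorts (no sample
#' overlap), builds each trait's phenotype as standardized-genotype
#' polygenic score plus Gaussian noise scaled so the genetic variance is
#' `h2_k`, then performs per-SNP simple linear regression to produce the
#' usual summary statistics (beta, se, p, z).
#'
#' @param panel A [genotype_panel()] with at least `n1 + n2` individuals.
#' @param truth A `polygenic_truth` from [simulate_polygenic_truth()].
#' @param seed Integer seed for the environmental noise.
#' @return List of two summary-statistics tibbles (`trait1`, `trait2`) in
#'   the schema [read_sumstats()] returns, with INFO = 1 and the panel
#'   allele frequency.
#' @export
simulate_two_trait_gwas <- function(panel, truth, seed) {
  m <- length(panel$snp_id)
  assert_that(length(truth$beta1) == m, "truth and panel dimensions differ")
  n1 <- truth$n1; n2 <- truth$n2
  assert_that(panel$n_ind >= n1 + n2,
              "panel too small for disjoint cohorts of n1 + n2 individuals")
  gwas_one <- function(rows, beta, h2, label) {
    x <- panel$dosage[rows, , drop = FALSE]
    xs <- scale(x)
    xs[, !is.finite(colSums(xs))] <- 0
    n <- length(rows)
    g <- as.numeric(xs %*% beta)
    y <- g + stats::rnorm(n, sd = sqrt(max(1 - h2, 1e-12)))
    xty <- as.numeric(crossprod(xs, y)) / (n - 1)    # per-SNP marginal coef
    sd_y <- stats::sd(y)
    bhat <- xty
    resid_var <- pmax(sd_y^2 - bhat^2, 1e-12) * (n - 1) / (n - 2)
    se <- sqrt(resid_var / (n - 1))
    z <- bhat / se
    p <- 2 * stats::pt(-abs(z), df = n - 2)
    tibble::tibble(
      snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
      a1 = "A", a2 = "G", beta = bhat, se = se,
      pvalue = clip_p(p), n = n, info = 1,
      freq = colMeans(x) / 2
    )
  }
  with_seed(seed, {
    t1 <- gwas_one(seq_len(n1), truth$beta1, truth$h2_1, "trait1")
    t2 <- gwas_one(n1 + seq_len(n2), truth$beta2, truth$h2_2, "trait2")
    attr(t1, "trait_label") <- "trait1"
    attr(t2, "trait_label") <- "trait2"
    list(trait1 = t1, trait2 = t2)
  })
}
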