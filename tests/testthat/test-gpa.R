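test_that("pure-null data collapses onto the null component", {
  sim <- simulate_fourgroup(50000, pi = c(1, 0, 0, 0), alpha = c(0.3, 0.4),
                            seed = 101)
  fit <- fit_gpa(sim$paired)
  expect_gte(unname(fit$pi["pi00"]), 0.99)
})

test_that("generating parameters are recovered at large n", {
  pi0 <- c(0.85, 0.05, 0.09, 0.01)
  a0 <- c(0.3, 0.4)
  sim <- simulate_fourgroup(100000, pi = pi0, alpha = a0, seed = 103)
  fit <- fit_gpa(sim$paired)
  expect_true(all(abs(fit$pi - pi0) < 0.01))
  expect_true(all(abs(fit$alpha - a0) < 0.05))
})

test_that("the EM log-likelihood is monotone non-decreasing on varied inputs", {
  for (seed in c(1, 2, 3)) {
    pi0 <- switch(seed, c(1, 0, 0, 0), c(0.7, 0.1, 0.1, 0.1),
                  c(0.5, 0.2, 0.2, 0.1))
    sim <- simulate_fourgroup(5000, pi = pi0, alpha = c(0.2, 0.6), seed = seed)
    fit <- fit_gpa(sim$paired)
    expect_true(all(diff(fit$loglik_trace) >= -1e-7 * abs(fit$loglik)))
  }
})

test_that("responsibilities are proper and consistent with the proportions", {
  sim <- simulate_fourgroup(8000, seed = 107)
  fit <- fit_gpa(sim$paired)
  g <- fit$responsibilities
  expect_equal(rowSums(g), rep(1, nrow(g)))
  # M-step fixed point: column means equal fitted proportions at convergence
  expect_equal(unname(colMeans(g)), unname(fit$pi), tolerance = 1e-4)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
})

test_that("swapping the traits swaps (pi10, pi01) and (alpha1, alpha2)", {
  sim <- simulate_fourgroup(30000, pi = c(0.8, 0.08, 0.1, 0.02),
                            alpha = c(0.25, 0.45), seed = 109)
  swapped <- dplyr::rename(sim$paired, p_A = "p_B", p_B = "p_A")
  f1 <- fit_gpa(sim$paired)
  f2 <- fit_gpa(swapped)
  expect_equal(unname(f1$pi[c("pi00", "pi01", "pi10", "pi11")]),
               unname(f2$pi[c("pi00", "pi10", "pi01", "pi11")]),
               tolerance = 1e-6)
  expect_equal(unname(f1$alpha), unname(rev(f2$alpha)), tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  l1 <- lrt_pleiotropy(sim$paired, f1)
  l2 <- lrt_pleiotropy(swapped, f2)
  expect_equal(l1$lrt_stat, l2$lrt_stat, tolerance = 1e-4)
})

test_that("degenerate all-ones input converges to the null corner and is flagged", {
  paired <- tibble::tibble(p_A = rep(1, 1000), p_B = rep(1, 1000))
  fit <- fit_gpa(paired)
  expect_gte(unname(fit$pi["pi00"]), 0.999)
  expect_true("alpha_at_bound" %in% fit$flags)
})

test_that("local fdr values follow the responsibility identities", {
  sim <- simulate_fourgroup(20000, pi = c(0.8, 0.05, 0.1, 0.05),
                            alpha = c(0.3, 0.4), seed = 113)
  fit <- fit_gpa(sim$paired)
  fdr <- local_fdr(fit)
  g <- fit$responsibilities
  expect_equal(fdr$fdr_A, g[, "gamma00"] + g[, "gamma01"])
  expect_equal(fdr$fdr11, 1 - g[, "gamma11"])
  expect_true(all(fdr$fdr_A >= 0 & fdr$fdr_A <= 1))
  # a SNP surely jointly associated has all three fdr values at 0; a sure
  # null has all three at 1 (checked through synthetic responsibilities)
  fake <- fit
  fake$responsibilities <- rbind(c(0, 0, 0, 1), c(1, 0, 0, 0))
  colnames(fake$responsibilities) <- paste0("gamma", c("00", "10", "01", "11"))
  fake$snp_id <- NULL
  f2 <- local_fdr(fake)
  expect_equal(unlist(f2[1, ]), c(fdr_A = 0, fdr_B = 0, fdr11 = 0))
  expect_equal(unlist(f2[2, ]), c(fdr_A = 1, fdr_B = 1, fdr11 = 1))
  # joint-call consistency: 1 - fdr11 <= min(1 - fdr_A, 1 - fdr_B)
  expect_true(all(1 - fdr$fdr11 <= pmin(1 - fdr$fdr_A, 1 - fdr$fdr_B) + 1e-12))
})

test_that("calling fdr11 < 0.2 controls the false discovery proportion", {
  sim <- simulate_fourgroup(100000, pi = c(0.85, 0.05, 0.05, 0.05),
                            alpha = c(0.3, 0.4), seed = 115)
  fit <- fit_gpa(sim$paired)
  fdr <- local_fdr(fit)
  called <- fdr$fdr11 < 0.2
  expect_gt(sum(called), 0)
  fdp <- mean(sim$truth$label[called] != "11")
  expect_lte(fdp, 0.25)
})

test_that("the pleiotropy LRT rejects under enrichment and stays calm under independence", {
  # pi11 far above the product of marginals
  sim <- simulate_fourgroup(30000, pi = c(0.86, 0.04, 0.08, 0.02),
                            alpha = c(0.3, 0.4), seed = 117)
  fit <- fit_gpa(sim$paired)
  lrt <- lrt_pleiotropy(sim$paired, fit)
  expect_lt(lrt$pvalue, 1e-6)
  expect_equal(lrt$df, 1L)
  # constrained solution satisfies the independence factorization
  cpi <- lrt$constrained$pi
  expect_equal(unname(cpi["pi11"]),
               unname((cpi["pi10"] + cpi["pi11"]) * (cpi["pi01"] + cpi["pi11"])),
               tolerance = 1e-8)

  # independence: pi11 == product of marginals -> small statistic
  q1 <- 0.06; q2 <- 0.1
  pi_ind <- c((1 - q1) * (1 - q2), q1 * (1 - q2), (1 - q1) * q2, q1 * q2)
  sim0 <- simulate_fourgroup(30000, pi = pi_ind, alpha = c(0.3, 0.4), seed = 119)
  fit0 <- fit_gpa(sim0$paired)
  lrt0 <- lrt_pleiotropy(sim0$paired, fit0)
  expect_gt(lrt0$pvalue, 1e-4)
})

test_that("a zero statistic maps to p = 1 and tidy exposes the test", {
  expect_equal(stats::pchisq(0, 1, lower.tail = FALSE), 1)
  sim <- simulate_fourgroup(5000, seed = 121)
  fit <- fit_gpa(sim$paired)
  lrt <- lrt_pleiotropy(sim$paired, fit)
  td <- tidy(lrt)
  expect_equal(names(td), c("statistic", "df", "p.value"))
  expect_gte(lrt$lrt_stat, 0)
})

test_that("proportion standard errors shrink with n and track replicate spread", {
  sim_small <- simulate_fourgroup(5000, pi = c(0.8, 0.08, 0.1, 0.02),
                                  alpha = c(0.3, 0.4), seed = 131)
  sim_big <- simulate_fourgroup(50000, pi = c(0.8, 0.08, 0.1, 0.02),
                                alpha = c(0.3, 0.4), seed = 131)
  se_small <- pi_standard_errors(fit_gpa(sim_small$paired))$se_pi
  se_big <- pi_standard_errors(fit_gpa(sim_big$paired))$se_pi
  expect_true(all(se_big < se_small))

  # replicate-based check on pi00
  ests <- ses <- numeric(30)
  for (r in 1:30) {
    s <- simulate_fourgroup(4000, pi = c(0.8, 0.08, 0.1, 0.02),
                            alpha = c(0.3, 0.4), seed = 1000 + r)
    f <- pi_standard_errors(fit_gpa(s$paired))
    ests[r] <- f$pi["pi00"]; ses[r] <- f$se_pi["pi00"]
  }
  ratio <- mean(ses) / stats::sd(ests)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("all-null fits put pi00 within three standard errors of 1", {
  sim <- simulate_fourgroup(20000, pi = c(1, 0, 0, 0), alpha = c(0.3, 0.4),
                            seed = 137)
  fit <- pi_standard_errors(fit_gpa(sim$paired))
  expect_gte(unname(fit$pi["pi00"] + 3 * max(fit$se_pi["pi00"], 1e-6)), 1)
  td <- tidy(fit)
  expect_equal(td$term, c("pi00", "pi10", "pi01", "pi11", "alpha1", "alpha2"))
})
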