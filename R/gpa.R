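# Four-group Uniform/Beta mixture for paired GWAS p-values.
#
# Each SNP belongs to one of four latent classes: (00) null for both traits,
# (10) associated with trait 1 only, (01) trait 2 only, (11) both. Null
# p-values are U[0,1]; associated p-values are Beta(alpha, 1) with
# 0 < alpha < 1, whose density alpha * p^(alpha - 1) concentrates near zero.
# Given the class, the two traits' p-values are independent, so the mixture
# density factorizes and both the E-step and the M-step are closed-form.

GPA_CLASSES <- c("00", "10", "01", "11")

# component density matrix (n x 4) on the log-p scale inputs
gpa_components <- function(lp1, lp2, pi, a1, a2) {
  b1 <- a1 * exp((a1 - 1) * lp1)
  b2 <- a2 * exp((a2 - 1) * lp2)
  cbind(pi[1], pi[2] * b1, pi[3] * b2, pi[4] * b1 * b2)
}

# one EM pass shared by the full and the independence-constrained model.
# constrained = TRUE reparameterizes pi through the two marginal association
# probabilities q1, q2 with pi11 = q1 * q2 (independence of the two traits'
# association indicators).
gpa_em <- function(lp1, lp2, pi, a1, a2, tol, max_iter, constrained = FALSE) {
  n <- length(lp1)
  a_lo <- 1e-4; a_hi <- 1 - 1e-4
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  flag <- character(0)
  iter <- 0L
  gamma <- NULL
  repeat {
    iter <- iter + 1L
    comp <- gpa_components(lp1, lp2, pi, a1, a2)
    tot <- comp[, 1] + comp[, 2] + comp[, 3] + comp[, 4]
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    gamma <- comp / tot
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll

    cs <- colMeans(gamma)
    if (constrained) {
      q1 <- cs[2] + cs[4]
      q2 <- cs[3] + cs[4]
      pi <- c((1 - q1) * (1 - q2), q1 * (1 - q2), (1 - q1) * q2, q1 * q2)
    } else {
      pi <- cs
    }
    w1 <- gamma[, 2] + gamma[, 4]
    w2 <- gamma[, 3] + gamma[, 4]
    d1 <- sum(w1 * lp1); d2 <- sum(w2 * lp2)
    a1 <- if (d1 < 0) min(max(-sum(w1) / d1, a_lo), a_hi) else a_lo
    a2 <- if (d2 < 0) min(max(-sum(w2) / d2, a_lo), a_hi) else a_lo
    if (d1 >= 0 || d2 >= 0) flag <- union(flag, "alpha_at_bound")
  }
  if (!converged) flag <- union(flag, "not_converged")
  # At alpha = 1 the Beta(alpha, 1) margin IS Uniform, so any mass in the
  # affected non-null classes is observationally equivalent to null mass:
  # the likelihood is flat along that ridge. Pick the identifiable boundary
  # representative by folding such mass back into the matching null class.
  if (a1 >= a_hi) {
    pi <- c(pi[1] + pi[2], 0, pi[3] + pi[4], 0)
    flag <- union(flag, "alpha_at_bound")
  }
  if (a2 >= a_hi) {
    pi <- c(pi[1] + pi[3], pi[2] + pi[4], 0, 0)
    flag <- union(flag, "alpha_at_bound")
  }
  if (any(c("alpha_at_bound") %in% flag)) {
    comp <- gpa_components(lp1, lp2, pi, a1, a2)
    gamma <- comp / (comp[, 1] + comp[, 2] + comp[, 3] + comp[, 4])
  }
  list(pi = stats::setNames(pi, paste0("pi", GPA_CLASSES)),
       alpha = c(alpha1 = a1, alpha2 = a2),
       loglik = trace[length(trace)], loglik_trace = trace,
       responsibilities = `colnames<-`(gamma, paste0("gamma", GPA_CLASSES)),
       n_iter = iter, converged = converged, flags = flag, n = n)
}

#' Fit the four-group pleiotropy mixture by expectation-maximization
#'
#' Fits mixture proportions (pi00, pi10, pi01, pi11) and Beta shape
#' parameters (alpha1, alpha2) to the paired p-values of two traits. The
#' E-step computes per-SNP class responsibilities from the factorized
#' component densities; the M-step updates the proportions as responsibility
#' means and each alpha by the closed-form Beta(alpha, 1) maximum-likelihood
#' solution, projected into [1e-4, 1 - 1e-4]. The log-likelihood is
#' non-decreasing across iterations (EM guarantee, asserted in the tests).
#'
#' @param paired A paired tibble with columns `p_A`, `p_B` (from
#'   [harmonize_and_merge()], [ld_prune()] or [simulate_fourgroup()]).
#' @param init Optional initial values: list with `pi` (length-4, sums
#'   to 1) and `alpha` (length-2 in (0,1)). Default pi = (0.7, 0.1, 0.1,
#'   0.1), alpha = (0.5, 0.5).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 5000).
#' @param p_floor P-values are clipped to `[p_floor, 1]` before the log
#'   transform; the default 1e-30 keeps Beta log-densities finite and is
#'   far below any GWAS-meaningful p-value.
#' @return An object of class `gpa_fit`: mixture parameters, `loglik`,
#'   `loglik_trace`, per-SNP `responsibilities` (n x 4 matrix), `n_iter`,
#'   `converged`, `flags`, `se_pi` (filled by [pi_standard_errors()]), and
#'   the clipped log p-values used (for refits and standard errors).
#' @export
fit_gpa <- function(paired, init = NULL, tol = 1e-8, max_iter = 5000,
                    p_floor = 1e-30) {
  assert_that(all(c("p_A", "p_B") %in% names(paired)), "need columns p_A, p_B")
  assert_that(nrow(paired) >= 4, "too few SNPs to fit a 4-component mixture")
  pi0 <- init$pi %||% c(0.7, 0.1, 0.1, 0.1)
  a0 <- init$alpha %||% c(0.5, 0.5)
  assert_that(abs(sum(pi0) - 1) < 1e-8 && all(pi0 >= 0), "init$pi must be a probability 4-vector")
  assert_that(all(a0 > 0 & a0 < 1), "init$alpha must lie in (0,1)")
  lp1 <- log(clip_p(paired$p_A, p_floor))
  lp2 <- log(clip_p(paired$p_B, p_floor))
  fit <- gpa_em(lp1, lp2, pi0, a0[1], a0[2], tol, max_iter)
  fit$snp_id <- paired[["snp_id"]]
  fit$lp1 <- lp1
  fit$lp2 <- lp2
  fit$tol <- tol
  fit$max_iter <- max_iter
  fit$se_pi <- rep(NA_real_, 4)
  class(fit) <- "gpa_fit"
  fit
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Four-group pleiotropy mixture (EM", if (!x$converged) ", NOT converged" else "",
      ")\n", sep = "")
  est <- sprintf("%.4f", x$pi)
  if (!all(is.na(x$se_pi))) est <- paste0(est, " (", sprintf("%.4f", x$se_pi), ")")
  cat(paste0("  ", names(x$pi), " = ", est, collapse = "\n"), "\n", sep = "")
  cat("  alpha1 = ", signif(x$alpha[1], 4), ", alpha2 = ", signif(x$alpha[2], 4),
      "\n  loglik = ", format(x$loglik, digits = 8), " after ", x$n_iter,
      " iteration(s), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.gpa_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$pi), names(x$alpha)),
    estimate = c(unname(x$pi), unname(x$alpha)),
    std.error = c(x$se_pi, NA_real_, NA_real_)
  )
}

#' @exportS3Method
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Per-SNP local false discovery rates from a fitted mixture
#'
#' Under the fitted model, the local fdr for trait A is the posterior
#' probability that the SNP carries no trait-A association
#' (responsibility mass of classes 00 and 01), analogously for trait B;
#' `fdr11` is the posterior probability that the SNP is NOT associated
#' with both traits (1 - gamma11). SNPs with values below 0.2 are the
#' conventional call sets.
#'
#' @param model A fitted `gpa_fit`.
#' @return A tibble with columns `snp_id` (if available), `fdr_A`, `fdr_B`,
#'   `fdr11`.
#' @export
local_fdr <- function(model) {
  g <- model$responsibilities
  out <- tibble::tibble(
    fdr_A = g[, "gamma00"] + g[, "gamma01"],
    fdr_B = g[, "gamma00"] + g[, "gamma10"],
    fdr11 = 1 - g[, "gamma11"]
  )
  if (!is.null(model$snp_id)) out <- tibble::add_column(out, snp_id = model$snp_id,
                                                        .before = 1)
  out
}

#' Likelihood-ratio test for pleiotropic enrichment
#'
#' Refits the mixture under the independence constraint
#' `pi11 = (pi10 + pi11) * (pi01 + pi11)` — the two traits' association
#' indicators independent, leaving 2 free proportion parameters instead
#' of 3 — and compares maximized log-likelihoods. The statistic
#' `2 * (loglik_full - loglik_constrained)` is referred to a chi-square
#' with 1 degree of freedom (one equality constraint). If the constrained
#' likelihood exceeds the full one (a local EM maximum in the full fit),
#' the full model is re-run from the constrained solution first.
#'
#' @param paired The paired tibble the full model was fitted to.
#' @param full A fitted `gpa_fit` for the unconstrained model.
#' @return An object of class `gpa_lrt`: list with `lrt_stat`, `df`,
#'   `pvalue`, the `constrained` fit, and the (possibly improved) `full`
#'   fit actually used.
#' @export
lrt_pleiotropy <- function(paired, full) {
  con <- gpa_em(full$lp1, full$lp2,
                pi = c(0.7, 0.1, 0.1, 0.1), a1 = 0.5, a2 = 0.5,
                tol = full$tol, max_iter = full$max_iter, constrained = TRUE)
  if (con$loglik > full$loglik + 1e-6) {
    refit <- gpa_em(full$lp1, full$lp2, pi = unname(con$pi),
                    a1 = con$alpha[1], a2 = con$alpha[2],
                    tol = full$tol, max_iter = full$max_iter)
    if (refit$loglik > full$loglik) {
      for (f in c("pi", "alpha", "loglik", "loglik_trace", "responsibilities",
                  "n_iter", "converged", "flags")) full[[f]] <- refit[[f]]
    }
  }
  stat <- max(0, 2 * (full$loglik - con$loglik))
  structure(
    list(lrt_stat = stat, df = 1L,
         pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         constrained = con, full = full),
    class = "gpa_lrt"
  )
}

#' @export
print.gpa_lrt <- function(x, ...) {
  cat("Pleiotropy likelihood-ratio test\n  LRT = ", signif(x$lrt_stat, 6),
      ", df = ", x$df, ", p = ", format(x$pvalue, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.gpa_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$lrt_stat, df = x$df, p.value = x$pvalue)
}

#' Standard errors of the mixture proportions
#'
#' Delta-method standard errors for (pi00, pi10, pi01, pi11) from the
#' inverse of a numerically differentiated observed information matrix,
#' evaluated at the fitted maximum in an unconstrained parameterization
#' (softmax for the proportions, logit for the Beta shapes).
#'
#' Components whose alpha collapsed onto the Uniform boundary carry zero
#' proportion in the identifiable representative; they are profiled out of
#' the parameter vector (their standard error is reported as 0) so the
#' information matrix stays non-singular for the remaining parameters.
#'
#' @param model A converged `gpa_fit`.
#' @return The model with `se_pi` filled in (named, aligned with `pi`);
#'   a singular information matrix yields `NA` standard errors with a
#'   warning.
#' @export
pi_standard_errors <- function(model) {
  p <- as.numeric(model$pi)
  active <- p > 1e-8
  active[1] <- TRUE                               # null class is the reference
  free_a1 <- any(active[c(2, 4)])
  free_a2 <- any(active[c(3, 4)])
  k_eta <- which(active[-1])                      # free softmax dims among 10,01,11
  if (length(k_eta) == 0) {                       # fully collapsed: pi00 = 1
    model$se_pi <- stats::setNames(rep(0, 4), names(model$pi))
    return(model)
  }
  expand <- function(theta) {
    e <- numeric(4)
    e[1 + k_eta] <- theta[seq_along(k_eta)]
    pi_full <- ifelse(c(TRUE, active[-1]), exp(e), 0)
    pi_full <- pi_full / sum(pi_full)
    i <- length(k_eta)
    a1 <- if (free_a1) stats::plogis(theta[i + 1]) else model$alpha[1]
    a2 <- if (free_a2) stats::plogis(theta[i + free_a1 + 1]) else model$alpha[2]
    list(pi = pi_full, a1 = a1, a2 = a2)
  }
  negll <- function(theta) {
    par <- expand(theta)
    comp <- gpa_components(model$lp1, model$lp2, par$pi, par$a1, par$a2)
    -sum(log(comp[, 1] + comp[, 2] + comp[, 3] + comp[, 4]))
  }
  theta <- c(log(p[1 + k_eta] / p[1]),
             if (free_a1) stats::qlogis(model$alpha[1]),
             if (free_a2) stats::qlogis(model$alpha[2]))
  H <- pracma::hessian(negll, theta)
  Sigma <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Sigma) || any(!is.finite(Sigma))) {
    warning("singular observed information; pi standard errors unavailable")
    model$se_pi <- stats::setNames(rep(NA_real_, 4), names(model$pi))
    return(model)
  }
  # delta method through the softmax: d pi_c / d eta_k = pi_c (1[c=k] - pi_k)
  J <- matrix(0, 4, length(theta))
  for (c in 1:4) {
    for (j in seq_along(k_eta)) {
      cls <- 1 + k_eta[j]
      J[c, j] <- p[c] * ((c == cls) - p[cls])
    }
  }
  V <- J %*% Sigma %*% t(J)
  vv <- diag(V)
  vv[vv < 0] <- NA_real_
  se <- sqrt(vv)
  se[!active] <- 0                                # collapsed classes are fixed
  model$se_pi <- stats::setNames(se, names(model$pi))
  model
}
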